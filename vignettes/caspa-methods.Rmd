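---
title: "Predicting action errors from SDA-M memory structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting action errors from SDA-M memory structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspa)
```

## The problem

Structural-dimensional analysis of mental representations (SDA-M) retrieves
how a person's long-term memory organises the actions of a task. In its
survey stage, the *split procedure*, every action serves once as a reference
("target") and the participant judges for each other action whether the two
are directly associated during task execution. Traditionally the resulting
structure is clustered, drawn as a dendrogram, and read by a trained expert
who decides where the person is likely to go wrong. This package implements
that computational chain and two algorithms that replace the human reader:
a binary minimal-distance heuristic (AMPA, *Analysis of Most Probable
Actions*) and a probabilistic Boltzmann-selection model (CASPA, *Correct
Action Selection Probability Analysis*), together with the statistics needed
to compare their decisions against a rater panel.

## From split judgments to the Z, R and D matrices

For a task of $n$ actions, the split procedure yields $n(n-1)$ directed
judgments. For target $t$, every action in the "associated" node of size
$|N|$ scores $x = +|N|$ and every action in the "not associated" node scores
$x = -|N|$; with a single splitting step per target (the case supported
here) the associated node holds the $k$ actions judged associated, so those
score $+k$ and the rest $-(n-1-k)$.

Two conventions are deliberately exposed as parameters because the scaling
method itself does not fix them:

* **Self column** (`self_column`). The target's score against itself is not
  surveyed. The default `self_max` counts the target into its own
  associated node ($x_t = k+1$): a target trivially belongs with its
  associates. The alternative `pairwise_exclude` leaves the entry missing
  and drops columns $i$ and $j$ pairwise before comparing rows $i$ and $j$.
  `self_max` is the default because, with height-1 split trees and
  neighbour-only association patterns, pairwise exclusion leaves the rows
  of adjacent actions in an ordered activity with no shared positive
  column, which contradicts the tightly clustered expert dendrograms the
  method is known to produce.
* **Standard-deviation denominator** (`sd`). Rows are $z$-standardised;
  the default divides by $n$ (population form). Pearson correlations are
  scale-free, so the R matrix is identical under either choice, but only
  the population form gives the exact closed-form link below.

Row $t$ of the **Z matrix** is the standardised score vector of target $t$;
the **R matrix** holds Pearson correlations between all row pairs and the
**D matrix** their Euclidean distances. Under the default conventions every
row has mean 0 and $\sum_c z_{tc}^2 = n$, hence the identity

$$D_{ij} = \sqrt{2n\,(1 - R_{ij})}$$

holds to machine precision; R and D are the same information on two scales.
The test suite asserts this at $10^{-9}$ on random datasets. Under
`pairwise_exclude` each pair is computed on its own column subset, the
identity fails, and — less obviously — D is no longer even a monotone
function of R across pairs; only the per-pair construction is guaranteed.
This is asserted as such in the tests, and is a good reason to treat
`pairwise_exclude` as a sensitivity check rather than a default.

A participant who gives the same verdict for everything against some target
produces a constant row once the self entry is out of play. Rather than
crash, the package sets that row's z-scores to zero, defines its
correlations as 0 and its distances as $\sqrt{2n}$ (the values an exactly
uncorrelated row would take), and warns naming the target.

## Clustering and dendrograms

The D matrix feeds hierarchical agglomerative average-linkage clustering
(UPGMA): the distance between clusters is the unweighted mean of all
cross-pair distances, merges proceed from the closest pair, and merge
heights are non-decreasing. Ties at the minimum are broken by the smallest
(min id of first cluster, min id of second cluster) pair so results are
bit-reproducible; the clustering literature leaves tie order open, and
floating-point reproducibility across platforms is worth fixing it. The
implementation updates distances incrementally (Lance–Williams); the test
suite checks it merge-for-merge against a from-scratch re-scan oracle and
against `stats::hclust`.

`cut_dendrogram()` removes merges above a critical distance `d_crit` and
returns the connected components. `d_crit` is a user parameter: the
original method derives a critical value from a significance level and the
number of actions, but the derivation is not reproducible from public
sources, so no default is invented. Newick export halves merge heights into
child branch lengths, so leaf-to-leaf path distances in the exported tree
equal the cophenetic merge heights; trees round-trip through `ape`.

## AMPA: competence as minimal distance

In a situation where the person has executed a prefix ending in the most
recent action $a_j$ (with second-most recent $a_i$), the candidate set is
*all* actions except $a_i$ and $a_j$ — including actions executed earlier,
since revisiting them is exactly the kind of error worth predicting. AMPA
declares the person competent iff some correct follow-up is among the
candidates at minimal distance from $a_j$:

$$\mathrm{competent}(S) = 1 \iff \exists\, a_c \in C_S:\;
  D_{a_j,a_c} \le D_{a_j,a_x} \;\; \forall a_x \notin \{a_i, a_j\}$$

Ties count in favour of competence: a correct action need only be *among*
the closest. The excluded $a_i$ reflects that distances are undirected —
the predecessor is often the nearest action, yet repeating it is
improbable.

Predicting the very first action of a task is unsupported by construction
(there is no $a_j$), and completed sequences have nothing to predict; both
are errors rather than guesses.

## CASPA: Boltzmann selection over activations

CASPA maps the correlation between $a_j$ and a candidate to an activation
in log-odds form, the same functional shape that ACT-R uses for chunk
activation and production utility,

$$\rho(r) = \log \frac{r}{1-r},$$

and treats as *applicable* exactly the candidates strictly positively
correlated with $a_j$ ($r > 0$; $r = 0$ is inapplicable). The probability
of selecting a correct follow-up is the softmax weight of the correct
applicable actions:

$$P_S = \frac{\sum_{a_c \in C_S,\, r > 0} e^{\rho(r_{a_j,a_c})/s}}
             {\sum_{a_x \notin \{a_i,a_j\},\, r > 0} e^{\rho(r_{a_j,a_x})/s}}$$

with noise temperature $s = 0.4$ by default, the conventional ACT-R
chunk-activation noise. Numerical choices:

* Weights combine on the log scale (log-sum-exp), so small $s$ cannot
  overflow; the tests compare against naive direct summation at $10^{-9}$
  and check the $s \to 0$ limit at $s = 10^{-4}$.
* Correlations are clipped to $1 - 10^{-12}$ before the log-odds, so
  identical rows ($r = 1$) yield a large finite activation instead of
  infinity.
* If no applicable action exists at all — a fully dissociated most recent
  action — $P_S$ is defined as 0 with a warning; the situation carries no
  usable signal and "assistance required" is the conservative reading.

The older exponential association measure $\pi(r) = e^{-(1-r)/(1-r_{krit})}$
is provided (`pi_lander()`) for comparison and plotting only: it stays
positive for uncorrelated and even negatively correlated actions, which is
the discrimination failure that motivates the log-odds form, and it is
never used inside CASPA. Its two printed forms equate an exponential in
distance with one in $1-r$, while Euclidean distance on standardised rows
scales with $\sqrt{1-r}$; the package computes $\pi$ from the correlation
form and leaves the distance form alone.

A binary decision uses `binarize(p, threshold)` with $P_S \ge$ threshold
counting as competent (the boundary is optimistic, matching AMPA's tie
rule). The default threshold 0.5 asks whether competence is more likely
than not; the *informed* threshold is the mean of $P_S$ over a reference
set of cases and compensates scale biases, e.g. the mechanical downward
pressure on $P_S$ as the number of actions grows.

## How the two algorithms relate

Restricting attention to situations with at least one applicable candidate,
four relations are theorems of the two definitions under the default matrix
conventions (where higher $r$ is exactly lower $D$):

1. every applicable action correct $\Rightarrow$ AMPA $= 1$ and $P_S = 1$;
2. no applicable correct action $\Rightarrow$ AMPA $= 0$ and $P_S = 0$;
3. a correct applicable action attains maximal activation $\Rightarrow$
   AMPA $= 1$ and $0 < P_S \le 1$;
4. correct applicable actions exist but none attains the maximum
   $\Rightarrow$ AMPA $= 0$ and $0 < P_S < 1$.

The test suite checks these on thousands of randomized synthetic instances.
The restriction matters: when *nothing* is positively correlated with
$a_j$, $P_S := 0$ by definition while AMPA, which only ranks distances, can
still return 1 (all candidates then sit at $D \ge \sqrt{2n}$ and a correct
one may attain the minimum). The Boltzmann frame presumes a non-empty
conflict set, so such instances are outside the relations' domain; they are
rare under realistic noise and are excluded explicitly rather than
silently.

## The synthetic generator

`simulate_split()` emulates a participant whose memory structure is the
task's ideal association pattern — within an ordered activity, an action
associates with its immediate predecessor and successor; within an
unordered activity, with every other member (any of them may legitimately
precede or follow); never across activities — corrupted by flipping each
directed judgment independently with probability $\varepsilon \in [0, 0.5]$.
$\varepsilon$ is the single expertise dial: 0 is an ideal expert, 0.5 pure
guessing. The two directions of a pair flip independently because the
split procedure asks them separately. An `unordered = "adjacent"` variant
restricts unordered activities to list-order adjacency for studies of
ordered-style structures; asymmetric false-positive/false-negative rates
are out of scope.

`generate_test_cases()` draws execution prefixes the way a balanced
assessment set is built: pick an activity uniformly (so large unordered
activities do not dominate by sheer permutation count), draw a correct
ordering, cut at a uniform length in $[1, m-1]$. Every case therefore has
a non-empty follow-up set; a two-action activity always yields its
one-action prefix.

What the generator does *not* emulate: response biases that differ between
targets, participants drifting during the survey, systematically
asymmetric confusion between specific activities, and rater panels (test
panels are constructed directly in test code). Passing tests show the
pipeline recovers planted structure under independent symmetric noise; they
do not certify behaviour on real psychometric data.

### Exact zero-noise behaviour, and a deliberate red test

At $\varepsilon = 0$ AMPA is competent on every one of the 249 distinct
correct kiosk prefixes (verified exhaustively). $P_S$, however, is *not*
uniformly high: inside an unordered activity of size $m$ with $k$ actions
executed, the $k-2$ older executed actions remain applicable with exactly
the same correlation as the $m-k$ correct remaining ones, so

$$P_S = \frac{m-k}{m - \min(k, 2)}$$

— e.g. $1/3$ after four of the five preparation actions. This is a
property of the model, not a bug: the memory structure alone cannot tell
an already-done action from a still-to-do one, and the probability mass
honestly splits. The unit suite asserts this exact value. One acceptance
check instead asserts the cruder expectation $P_S > 0.5$ for *all*
zero-noise cases; it fails for exactly these long unordered prefixes and
is intentionally left failing, since weakening it would hide a real and
instructive property of the model. An informed threshold estimated from a
reference case pool tends to sit below such values on tasks of this size,
which is one practical reason to prefer it over the a-priori 0.5 cutoff.

Degradation and separation are checked as distribution-level properties:
mean $P_S$ over 200 cases and 50 simulated participants per level is
non-increasing across $\varepsilon \in \{0, 0.1, ..., 0.5\}$ (allowance
0.01 for sampling error), and experts ($\varepsilon = 0.05$) beat novices
($\varepsilon = 0.4$) on mean $P_S$ in essentially all of 100 paired
replicates (binomial $p < 0.01$).

## Evaluating against a rater panel

Raters judge each case competent (1) or needing assistance (0). Screening
computes, per rater, the correlation between their judgments and the mean
judgment of the *other* raters — leaving the rater out avoids
self-correlation inflation, which is why the leave-one-out form is used
where a plain group average would be ambiguous — and drops raters with
negative correlation (a sign of a misread task, not a divergent opinion).
Constant raters have undefined correlations and are retained with a
warning. The retained panel aggregates to per-case majority decisions
(median = majority for odd panels; even-panel ties resolve to "assistance
required" and are flagged) and to $P_E$, the fraction judging competent,
which is directly comparable to $P_S$.

Confusion counts $N_{ab}$ index (panel, algorithm) with 0 = assistance
required; a true positive ($N_{00}$) is joint agreement that assistance is
needed. Six metrics follow: accuracy (simple matching coefficient),
sensitivity $N_{00}/(N_{00}+N_{01})$, specificity
$N_{11}/(N_{11}+N_{10})$, PPV $N_{00}/(N_{00}+N_{10})$, NPV
$N_{11}/(N_{11}+N_{01})$, and balanced accuracy — implemented, in its
default variant, as the mean of the two *predictive values*
$\tfrac12(\mathrm{PPV} + \mathrm{NPV})$, which is the form that guards a
classifier against exploiting an imbalanced test set and reduces to plain
accuracy when the two predictive values agree. The textbook
sensitivity/specificity mean is available as `variant = "sens_spec"`.
Zero-denominator metrics surface as `NaN` with an `undefined` flag, never
as silent zeros. Above-chance agreement uses the exact one-tailed binomial
tail at $p_0 = 0.5$; binary-vector agreement uses the phi coefficient
(Pearson on 0/1 vectors); correlations average through Fisher's
$z$-transform.

## Problem sizes and budgets

The shipped tests run the relation suite on ~2,000+ instances (90
participants × 25 cases), the oracle equivalences on 100 random matrices
each, the degradation sweep on 6 noise levels × 50 participants × 200
cases, and the expert/novice separation on 100 paired replicates — sizes
chosen so the full suite completes in well under a minute per property
while keeping Monte-Carlo error far from the asserted margins. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch at the same sizes.

## Known limitations

* Single splitting step per target: the scoring hook (`node_scores()`)
  isolates the $x = s\,|N|$ rule, but multi-step split trees are not
  implemented.
* Factor-dimension extraction and the cluster-solution invariance measure
  are out of scope, as is any critical-distance derivation from a
  significance level.
* Recurring actions must be modelled by the user as distinct labelled
  steps; correctness is context-independent by assumption.
* The original SDA-M software's exact self-column and sd conventions are
  not documented publicly; they are configuration here, not recovered
  fact, and results under `pairwise_exclude` should be read with the
  monotonicity caveat above.
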