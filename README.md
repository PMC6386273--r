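# caspa

Predicting human action errors from SDA-M mental representation structures.

## What this is for

*Structural-dimensional analysis of mental representations* (SDA-M) measures
how a person's long-term memory organises the actions of a task. Its survey
stage — the **split procedure** — presents each of the task's `n` actions as
a reference and asks whether every other action is directly associated with
it during task execution. Traditionally the resulting structure is clustered
into a dendrogram that a trained expert reads to judge where the person will
need assistance. `caspa` automates that judgment, so it can run inside
adaptive assistance systems (smart glasses, driver information systems,
training software) instead of a human reader.

The package covers the whole chain:

* **Scoring and scaling** — split judgments to node scores
  (`x = s · |N|`), z-standardised rows (**Z**), Pearson correlations
  (**R**) and Euclidean distances (**D**); under the default conventions
  `D_ij = sqrt(2n (1 − R_ij))` exactly.
* **Clustering** — average-linkage (UPGMA) dendrograms with deterministic
  tie-breaking, cutting at a critical distance, Newick export.
* **AMPA** (*Analysis of Most Probable Actions*) — binary competence:
  competent iff some correct follow-up `a_c` of the executed prefix
  satisfies `D(a_j, a_c) ≤ D(a_j, a_x)` for every candidate `a_x` (all
  actions except the last executed `a_j` and its predecessor `a_i`), ties
  in favour.
* **CASPA** (*Correct Action Selection Probability Analysis*) — the
  probability of choosing a correct follow-up as a Boltzmann softmax over
  ACT-R-style activations `ρ(r) = log(r / (1 − r))` of the actions
  positively correlated with `a_j`:

  `P_S = Σ_{correct, r>0} exp(ρ/s) / Σ_{candidates, r>0} exp(ρ/s)`,  `s = 0.4`

  binarised at the default 0.5 or at an *informed* threshold (the mean
  `P_S` over a reference case set).
* **Evaluation** — rater-panel screening (leave-one-out correlations),
  majority aggregation, confusion counts with assistance-required as the
  positive class, accuracy / sensitivity / specificity / PPV / NPV /
  balanced accuracy (mean of the predictive values), exact one-tailed
  binomial tests, phi correlations, Fisher-z averaging.
* **Synthetic data** — a built-in 15-action kiosk task (4 activities,
  ordered and unordered) plus a split-response simulator with a single
  expertise parameter `epsilon` (the probability of flipping each directed
  judgment), so the entire pipeline is testable without any external data.

## Worked example

```r
library(caspa)

task <- kiosk_task()
task
#> SDA-M task model: 15 actions, 4 activities
#>   [1] Kiosk preparation (unordered): 1, 2, 3, 4, 5
#>   [2] Kiosk customer service (ordered): 6 > 7 > 8 > 9
#>   [3] Kiosk wrap-up (unordered): 10, 11, 12, 13
#>   [4] Laundry (ordered): 14 > 15

# three simulated participants: near-expert, intermediate, near-guessing
splits <- do.call(rbind, lapply(1:3, function(p)
  as.data.frame(simulate_split(task, epsilon = c(0.05, 0.2, 0.45)[p],
                               participant_id = p, seed = 100 + p))))
cases <- generate_test_cases(task, 8, seed = 42)
res <- run_pipeline(task, splits, cases, config = read_config())
print(res$predictions, digits = 3)
#>   case_id participant_id ampa caspa_p caspa_default caspa_informed caspa_decision
#> 1       1              1    1  1.0000             1              1              1
#> 2       2              3    0  0.0000             0              0              0
#> 3       3              1    1  0.9996             1              1              1
#> 4       4              2    1  0.3603             0              0              0
#> 5       5              1    1  0.9996             1              1              1
#> 6       6              3    0  0.0000             0              0              0
#> 7       7              3    0  0.0307             0              0              0
#> 8       8              2    1  0.3603             0              0              0
cat("informed threshold:", round(res$informed_threshold, 4), "\n")
#> informed threshold: 0.4688
```

Each row is one test situation (an executed action prefix paired with one
participant's memory structure): `ampa` is the binary minimal-distance
verdict, `caspa_p` the estimated probability `P_S` of selecting a correct
follow-up, and the remaining columns binarise `P_S` at the default (0.5)
and informed (mean `P_S` = 0.4688 here) thresholds. The near-expert
participant 1 is judged competent with `P_S ≈ 1`; the near-guessing
participant 3 is flagged as needing assistance everywhere.

The expert's dendrogram recovers the four activities:

```r
d <- res$dendrograms[["1"]]
cut_dendrogram(d, 3.5)
#> [[1]] "1" "2" "3" "4" "5"      # preparation
#> [[2]] "6"                      # service start
#> [[3]] "7" "8"                  # service core
#> [[4]] "9"
#> [[5]] "10" "11" "12" "13"      # wrap-up
#> [[6]] "14" "15"                # laundry
to_newick(d)   # Newick string, round-trips through ape
```

A command-line front end with subcommands `simulate`, `testcases`,
`matrices`, `cluster`, `predict`, `calibrate` and `evaluate` is installed
as `exec/sdam`:

```sh
Rscript exec/sdam testcases --task builtin:kiosk --n 80 --seed 7 --out cases.csv
Rscript exec/sdam simulate  --task builtin:kiosk --epsilon 0.2 --participants 27 --seed 42 --out splits.csv
Rscript exec/sdam predict   --task builtin:kiosk --splits splits.csv --cases cases.csv --out predictions.csv
```

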