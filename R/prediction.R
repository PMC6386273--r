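#' AMPA: Analysis of Most Probable Actions
#'
#' Binary competence assessment. The person is deemed competent in a
#' situation iff some correct follow-up action is among the actions with
#' minimal memory distance from the most recent action `a_j`, where the
#' minimum is taken over all actions except `a_j` itself and its immediate
#' predecessor `a_i` (less recent executed actions stay in the running —
#' revisiting them would be an error the algorithm must be able to predict).
#' Ties at the minimum count in favor of competence: a correct action only
#' has to be *among* the closest, not strictly closest.
#'
#' @param D distance matrix with action ids as dimnames (e.g. the `D` of
#'   [build_matrices()], or the matrix bundle itself).
#' @param situation an [make_situation()] result.
#' @return list with `competent` (0/1) and `cmpa_set` (integer ids of the
#'   Correct Most-Probable Actions; empty when `competent == 0`).
#' @export
ampa <- function(D, situation) {
  if (inherits(D, "sdam_matrices")) D <- D$D
  stopifnot(inherits(situation, "sdam_situation"))
  need <- as.character(c(situation$a_j, situation$candidates))
  miss <- setdiff(need, rownames(D))
  if (length(miss))
    stop("distance matrix is missing action(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- D[as.character(situation$a_j), as.character(situation$candidates)]
  dmin <- min(d)
  closest <- situation$candidates[d <= dmin]
  cmpa <- intersect(situation$C_S, closest)
  list(competent = as.integer(length(cmpa) > 0L), cmpa_set = sort(cmpa))
}

#' Activation: log-odds transform of the correlation analogon
#'
#' `rho(r) = log(r / (1 - r))`, the ACT-R-style activation of an action
#' given its correlation `r` with the most recent action. Only positively
#' correlated ("applicable") actions have a defined activation; callers
#' must filter on `r > 0` first. Correlations are clipped to
#' `1 - r_clip` before the transform so that `r = 1` (identical rows)
#' yields a large finite activation rather than infinity.
#'
#' @param r numeric vector of correlations in (0, 1].
#' @param r_clip clipping margin, 0 < r_clip < 1.
#' @return activations in log-odds units; `rho(0.5) == 0`.
#' @export
rho_activation <- function(r, r_clip = 1e-12) {
  stopifnot(r_clip > 0, r_clip < 1)
  if (any(r <= 0))
    stop("rho is undefined for r <= 0; filter applicability (r > 0) first",
         call. = FALSE)
  r <- pmin(r, 1 - r_clip)
  log(r / (1 - r))
}

#' Lander's association strength measure
#'
#' `pi(r) = exp(-(1 - r) / (1 - r_krit))`, the exponential association
#' measure of the original SDA method, anchored at a critical correlation
#' `r_krit` (where it evaluates to `1/e`). Kept for comparison and plotting:
#' it stays positive even for uncorrelated or negatively correlated actions,
#' which is the very drawback that motivates the log-odds activation, and it
#' is never used inside CASPA.
#'
#' @param r numeric vector of correlations, `r <= 1`.
#' @param r_krit critical correlation, `r_krit < 1`.
#' @return association strengths in (0, 1].
#' @export
pi_lander <- function(r, r_krit) {
  if (any(r_krit >= 1))
    stop("r_krit must be < 1", call. = FALSE)
  if (any(r > 1))
    stop("correlations cannot exceed 1", call. = FALSE)
  exp(-(1 - r) / (1 - r_krit))
}

#' CASPA: probability of selecting a correct follow-up action
#'
#' Boltzmann (softmax) selection over activations. The applicable actions in
#' a situation are the candidates (all actions except `a_j` and `a_i`)
#' positively correlated with the most recent action `a_j`; each applicable
#' action `a_x` carries weight `exp(rho(r(a_j, a_x)) / s)`. The estimated
#' probability that the person selects a *correct* follow-up is the weight
#' of the correct applicable actions over the weight of all applicable
#' actions. With no applicable correct action the probability is 0; with no
#' applicable action at all it is 0 with a warning (a fully dissociated
#' most-recent action carries no usable signal).
#'
#' Weights are combined on the log scale (log-sum-exp) so small noise
#' temperatures cannot overflow.
#'
#' @param R correlation matrix with action ids as dimnames (or a matrix
#'   bundle).
#' @param situation an [make_situation()] result.
#' @param s noise temperature, > 0. The default 0.4 is the conventional
#'   ACT-R chunk-activation noise value.
#' @param r_clip clipping margin applied before the log-odds transform.
#' @return probability `P_S` in \code{[0, 1]}.
#' @export
caspa_probability <- function(R, situation, s = 0.4, r_clip = 1e-12) {
  if (inherits(R, "sdam_matrices")) R <- R$R
  stopifnot(inherits(situation, "sdam_situation"), s > 0)
  need <- as.character(c(situation$a_j, situation$candidates))
  miss <- setdiff(need, rownames(R))
  if (length(miss))
    stop("correlation matrix is missing action(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  r <- R[as.character(situation$a_j), as.character(situation$candidates)]
  applicable <- situation$candidates[r > 0]
  if (length(applicable) == 0L) {
    warning("no applicable action: every candidate is uncorrelated or ",
            "negatively correlated with the most recent action; P_S = 0",
            call. = FALSE)
    return(0)
  }
  a <- rho_activation(r[r > 0], r_clip) / s
  correct <- applicable %in% situation$C_S
  if (!any(correct)) return(0)
  m <- max(a)
  sum(exp(a[correct] - m)) / sum(exp(a - m))
}

# Pre-adjustment softmax variant: the denominator runs over an explicit
# (C_S union I_S) \ {a_i, a_j} rather than all positively correlated
# candidates. With I_S = candidates \ C_S this coincides with
# caspa_probability; kept internal for regression tests.
caspa_probability_explicit <- function(R, situation, I_S = NULL, s = 0.4,
                                       r_clip = 1e-12) {
  if (inherits(R, "sdam_matrices")) R <- R$R
  if (is.null(I_S)) I_S <- setdiff(situation$candidates, situation$C_S)
  pool <- setdiff(union(situation$C_S, I_S),
                  c(situation$a_i, situation$a_j))
  pool <- intersect(pool, situation$candidates)
  r <- R[as.character(situation$a_j), as.character(pool)]
  pool <- pool[r > 0]
  if (length(pool) == 0L) return(0)
  a <- rho_activation(r[r > 0], r_clip) / s
  correct <- pool %in% situation$C_S
  if (!any(correct)) return(0)
  m <- max(a)
  sum(exp(a[correct] - m)) / sum(exp(a - m))
}

#' Informed decision threshold for CASPA
#'
#' The informed threshold is the arithmetic mean of CASPA probabilities over
#' a reference set of cases; using it instead of the a-priori 0.5 cutoff
#' compensates systematic biases of the probability scale (task size, split
#' survey artifacts).
#'
#' @param values numeric vector of P_S values, non-empty.
#' @return the mean.
#' @export
informed_threshold <- function(values) {
  if (length(values) == 0L)
    stop("need at least one P_S value", call. = FALSE)
  mean(values)
}

#' Binarize a CASPA probability
#'
#' @param p probability in \code{[0, 1]}.
#' @param threshold decision cutoff; the default 0.5 asks whether competence
#'   is more likely than not. A probability exactly at the threshold counts
#'   as competent, mirroring AMPA's optimistic tie handling.
#' @return 0/1 integer vector.
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  as.integer(p >= threshold)
}

#' Run both predictors over a set of test cases
#'
#' Convenience wrapper: builds each situation, applies AMPA on the distance
#' matrix and CASPA on the correlation matrix, and binarizes CASPA at the
#' default (0.5) and informed (mean P_S over these cases) thresholds.
#'
#' @param task an [sdam_task()].
#' @param bundle an `sdam_matrices` bundle for the participant.
#' @param cases data.frame with columns `case_id` and `executed` (action ids
#'   as a space-separated string), or a list of integer vectors.
#' @param s CASPA noise temperature.
#' @return data.frame with columns `case_id`, `participant_id`, `ampa`,
#'   `caspa_p`, `caspa_default`, `caspa_informed`, plus attribute
#'   `informed_threshold`.
#' @export
predict_cases <- function(task, bundle, cases, s = 0.4) {
  execs <- parse_cases(cases)
  ps <- numeric(length(execs))
  am <- integer(length(execs))
  for (k in seq_along(execs)) {
    sit <- make_situation(task, execs[[k]])
    am[k] <- ampa(bundle, sit)$competent
    ps[k] <- caspa_probability(bundle, sit, s = s)
  }
  thr <- informed_threshold(ps)
  out <- data.frame(
    case_id = names(execs),
    participant_id = bundle$participant_id,
    ampa = am,
    caspa_p = ps,
    caspa_default = binarize(ps, 0.5),
    caspa_informed = binarize(ps, thr),
    stringsAsFactors = FALSE
  )
  attr(out, "informed_threshold") <- thr
  out
}

parse_cases <- function(cases) {
  if (is.data.frame(cases)) {
    execs <- lapply(strsplit(as.character(cases$executed), "[ ;]+"),
                    as.integer)
    names(execs) <- as.character(cases$case_id)
  } else {
    execs <- lapply(cases, as.integer)
    if (is.null(names(execs)) || any(names(execs) == ""))
      names(execs) <- as.character(seq_along(execs))
  }
  execs
}
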