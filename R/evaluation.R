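#' Screen raters by leave-one-out correlation
#'
#' For each rater, computes the Pearson correlation between their judgment
#' vector and the mean judgment vector of the *other* raters (leaving the
#' rater under test out avoids self-correlation inflation). Raters whose
#' correlation is negative are dropped: a negative correlation with the rest
#' of the panel signals a misunderstood task rather than a divergent but
#' valid opinion. A rater with a constant judgment vector (or a constant
#' rest-of-panel mean) has an undefined correlation and is retained with a
#' warning.
#'
#' @param judgments rater x case binary matrix (rownames = rater ids),
#'   entries 1 = competent, 0 = assistance required.
#' @return list with `retained` (rater ids), `dropped` (rater ids) and
#'   `loo_cor` (named numeric, NA where undefined).
#' @export
screen_raters <- function(judgments) {
  judgments <- as.matrix(judgments)
  if (nrow(judgments) < 3L)
    stop("need at least 3 raters to screen", call. = FALSE)
  if (!all(judgments %in% c(0, 1)))
    stop("judgments must be 0/1", call. = FALSE)
  raters <- rownames(judgments)
  if (is.null(raters)) raters <- as.character(seq_len(nrow(judgments)))
  loo <- stats::setNames(rep(NA_real_, nrow(judgments)), raters)
  for (i in seq_len(nrow(judgments))) {
    own <- judgments[i, ]
    rest <- colMeans(judgments[-i, , drop = FALSE])
    if (stats::sd(own) == 0 || stats::sd(rest) == 0) {
      warning("rater ", raters[i],
              ": constant judgments, correlation undefined; retained",
              call. = FALSE)
      next
    }
    loo[i] <- stats::cor(own, rest)
  }
  drop <- !is.na(loo) & loo < 0
  list(retained = raters[!drop], dropped = raters[drop], loo_cor = loo)
}

#' Aggregate a rater panel into majority decisions and agreement fractions
#'
#' `P_E` is, per case, the fraction of raters judging the subject competent;
#' the majority decision is 1 where `P_E > 0.5`. With an odd number of
#' raters this equals the per-case median. Even panels can tie
#' (`P_E == 0.5`); ties resolve to 0 ("assistance required" as the cautious
#' default) and are flagged with a warning and the `ties` attribute.
#'
#' @param judgments rater x case binary matrix (screened raters only).
#' @return list with `majority` (0/1 vector), `P_E` (fraction vector) and
#'   `ties` (indices of tied cases, even panels only).
#' @export
aggregate_panel <- function(judgments) {
  judgments <- as.matrix(judgments)
  if (!all(judgments %in% c(0, 1)))
    stop("judgments must be 0/1", call. = FALSE)
  P_E <- colMeans(judgments)
  ties <- which(P_E == 0.5)
  if (nrow(judgments) %% 2L == 0L && length(ties))
    warning(length(ties), " tied case(s) in an even panel; resolved to 0",
            call. = FALSE)
  list(majority = as.integer(P_E > 0.5), P_E = as.numeric(P_E),
       ties = as.integer(ties))
}

#' Confusion table of panel truth vs algorithm prediction
#'
#' Counts `N_ab`: first index `a` = panel verdict, second `b` = algorithm
#' verdict; 0 = assistance required, 1 = competent. In this convention a
#' "true positive" is `N00` — panel and algorithm agree that assistance is
#' required, the event the assistance system exists to catch.
#'
#' @param truth,pred equal-length 0/1 vectors.
#' @return object of class `sdam_confusion`: named list `N00,N01,N10,N11`.
#' @export
confusion_table <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("truth and pred must be 0/1", call. = FALSE)
  structure(list(N00 = sum(truth == 0 & pred == 0),
                 N01 = sum(truth == 0 & pred == 1),
                 N10 = sum(truth == 1 & pred == 0),
                 N11 = sum(truth == 1 & pred == 1)),
            class = "sdam_confusion")
}

#' @export
print.sdam_confusion <- function(x, ...) {
  cat("Confusion counts (panel, algorithm):\n")
  cat(sprintf("  N00 = %d  N01 = %d\n  N10 = %d  N11 = %d\n",
              x$N00, x$N01, x$N10, x$N11))
  invisible(x)
}

#' Classifier metrics from a confusion table
#'
#' With "positive" = assistance required (panel verdict 0):
#' accuracy (simple matching coefficient) `(N00+N11)/N`; sensitivity
#' `N00/(N00+N01)`; specificity `N11/(N11+N10)`; positive predictive value
#' `N00/(N00+N10)`; negative predictive value `N11/(N11+N01)`.
#'
#' Balanced accuracy, in its default `"ppv_npv"` variant, is the mean of the
#' two *predictive values*, `(PPV + NPV)/2` — the form that safeguards
#' against a classifier exploiting an imbalanced test set and reduces to the
#' conventional accuracy when PPV = NPV. `variant = "sens_spec"` gives the
#' textbook mean of sensitivity and specificity instead.
#'
#' A metric with a zero denominator is returned as `NaN`, and the names of
#' undefined metrics are listed in the `undefined` attribute; they are never
#' silently coerced to 0.
#'
#' @param table an [confusion_table()] result.
#' @param variant balanced-accuracy variant.
#' @return named list of the six metrics, with attribute `undefined`.
#' @export
confusion_metrics <- function(table, variant = c("ppv_npv", "sens_spec")) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "sdam_confusion"))
  N <- table$N00 + table$N01 + table$N10 + table$N11
  if (N == 0) stop("empty confusion table", call. = FALSE)
  frac <- function(num, den) if (den == 0) NaN else num / den
  acc <- (table$N00 + table$N11) / N
  sens <- frac(table$N00, table$N00 + table$N01)
  spec <- frac(table$N11, table$N11 + table$N10)
  ppv <- frac(table$N00, table$N00 + table$N10)
  npv <- frac(table$N11, table$N11 + table$N01)
  bal <- if (variant == "ppv_npv")
    0.5 * (frac(table$N11, table$N11 + table$N01) +
           frac(table$N00, table$N00 + table$N10))
  else
    0.5 * (sens + spec)
  out <- list(accuracy = acc, sensitivity = sens, specificity = spec,
              ppv = ppv, npv = npv, balanced_accuracy = bal)
  attr(out, "undefined") <- names(out)[vapply(out, is.nan, logical(1))]
  out
}

#' Exact one-tailed binomial test for above-chance agreement
#'
#' Each case where algorithm and panel agree counts as a successful
#' Bernoulli trial with null success probability 0.5; the p-value is the
#' exact upper tail `P(X >= matches)` under `H1: P(success) > P(failure)`.
#'
#' @param matches number of agreeing cases.
#' @param N total number of cases.
#' @return exact p-value.
#' @export
binomial_onetailed <- function(matches, N) {
  stopifnot(matches >= 0, matches <= N, N >= 1)
  stats::pbinom(matches - 1, size = N, prob = 0.5, lower.tail = FALSE)
}

#' Phi correlation of two binary vectors
#'
#' The Pearson correlation of 0/1 vectors, identical to the phi coefficient
#' of their 2x2 contingency table. Undefined (NA, with a warning) when
#' either vector is constant.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return correlation in \code{[-1, 1]}, or NA.
#' @export
phi_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant vector: phi correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Average correlations through the Fisher z-transform
#'
#' Correlations are not additive; the standard average is
#' `tanh(mean(atanh(r)))`.
#'
#' @param r numeric vector of correlations with `|r| < 1`.
#' @return averaged correlation.
#' @export
fisher_mean <- function(r) {
  if (length(r) == 0L) stop("need at least one correlation", call. = FALSE)
  if (any(abs(r) >= 1))
    stop("|r| = 1 cannot be Fisher-averaged", call. = FALSE)
  tanh(mean(atanh(r)))
}

#' Full evaluation of an algorithm's decisions against a rater panel
#'
#' Screens the panel, aggregates it to majority decisions, and computes the
#' confusion table, the six classifier metrics, the exact binomial p-value
#' and the phi correlation.
#'
#' @param judgments rater x case binary matrix.
#' @param pred 0/1 algorithm decisions, one per case (column order).
#' @param variant balanced-accuracy variant, see [confusion_metrics()].
#' @return list with `screening`, `majority`, `P_E`, `confusion`, `metrics`,
#'   `binomial_p`, `phi`.
#' @export
evaluate_against_panel <- function(judgments, pred,
                                   variant = c("ppv_npv", "sens_spec")) {
  judgments <- as.matrix(judgments)
  if (is.null(rownames(judgments)))
    rownames(judgments) <- as.character(seq_len(nrow(judgments)))
  scr <- screen_raters(judgments)
  kept <- judgments[scr$retained, , drop = FALSE]
  agg <- aggregate_panel(kept)
  ct <- confusion_table(agg$majority, pred)
  list(screening = scr,
       majority = agg$majority,
       P_E = agg$P_E,
       confusion = ct,
       metrics = confusion_metrics(ct, variant),
       binomial_p = binomial_onetailed(ct$N00 + ct$N11,
                                       length(agg$majority)),
       phi = phi_correlation(agg$majority, pred))
}
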