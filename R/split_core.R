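#' Assemble a split-procedure dataset
#'
#' The split procedure presents every action as a reference ("target") and
#' asks, for each other action, whether the two are directly associated
#' during task execution. One participant therefore produces `n * (n - 1)`
#' directed judgments (each unordered pair is asked twice, once per target).
#'
#' @param judgments data.frame with columns `participant_id`, `target_id`,
#'   `compared_id` and `verdict` (+1 associated, -1 not associated).
#' @param task an [sdam_task()]; used to check completeness.
#' @return object of class `sdam_splits` (the validated data.frame).
#' @export
sdam_splits <- function(judgments, task) {
  judgments <- as.data.frame(judgments)
  need <- c("participant_id", "target_id", "compared_id", "verdict")
  miss <- setdiff(need, names(judgments))
  if (length(miss))
    stop("judgments missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(judgments$verdict %in% c(-1L, 1L)))
    stop("verdict must be +1 or -1", call. = FALSE)
  judgments$target_id <- as.integer(judgments$target_id)
  judgments$compared_id <- as.integer(judgments$compared_id)
  judgments$verdict <- as.integer(judgments$verdict)
  if (any(judgments$target_id == judgments$compared_id))
    stop("an action cannot be compared to itself", call. = FALSE)
  ids <- task_action_ids(task)
  bad <- setdiff(c(judgments$target_id, judgments$compared_id), ids)
  if (length(bad))
    stop("judgment references unknown action id: ", bad[1L], call. = FALSE)
  for (p in unique(judgments$participant_id)) {
    sub <- judgments[judgments$participant_id == p, ]
    key <- paste(sub$target_id, sub$compared_id)
    if (anyDuplicated(key))
      stop("participant ", p, ": duplicate judgment for pair (",
           sub$target_id[duplicated(key)][1L], ", ",
           sub$compared_id[duplicated(key)][1L], ")", call. = FALSE)
    want <- expand.grid(target_id = ids, compared_id = ids)
    want <- want[want$target_id != want$compared_id, ]
    missing_pairs <- setdiff(paste(want$target_id, want$compared_id), key)
    if (length(missing_pairs))
      stop("participant ", p, ": incomplete dataset; missing pair(s): ",
           paste(utils::head(missing_pairs, 5L), collapse = "; "),
           if (length(missing_pairs) > 5L) " ...", call. = FALSE)
  }
  class(judgments) <- c("sdam_splits", "data.frame")
  judgments
}

#' Node scores for one split-procedure target
#'
#' Each judgment sorts an action into the target's "associated" node or its
#' "not associated" node; an action in a node of size `|N|` scores
#' `s * |N|`, with `s = +1` for the associated node and `s = -1` otherwise.
#' So if `k` of the `n - 1` compared actions are judged associated, these
#' score `+k` each and the remaining ones score `-(n - 1 - k)` each.
#'
#' How the target scores against itself is a convention the scaling method
#' leaves open:
#' \describe{
#'   \item{`self_max` (default)}{the target is counted into its own
#'     associated node and scores `+(k + 1)`.}
#'   \item{`pairwise_exclude`}{the self entry is left missing (`NA`) and the
#'     affected columns are dropped pairwise when correlating rows.}
#' }
#'
#' @param target_id the reference action.
#' @param judgments data.frame with columns `compared_id`, `verdict`
#'   (exactly one row per non-target action).
#' @param action_ids all action ids of the task, defining the vector layout.
#' @param self_column `"self_max"` or `"pairwise_exclude"`.
#' @return named numeric x-vector over all `action_ids`.
#' @export
node_scores <- function(target_id, judgments, action_ids,
                        self_column = c("self_max", "pairwise_exclude")) {
  self_column <- match.arg(self_column)
  target_id <- as.integer(target_id)
  others <- setdiff(action_ids, target_id)
  j <- judgments
  if (!setequal(j$compared_id, others) || nrow(j) != length(others))
    stop("need exactly one judgment per non-target action for target ",
         target_id, call. = FALSE)
  verdict <- j$verdict[match(others, j$compared_id)]
  if (!all(verdict %in% c(-1L, 1L)))
    stop("verdict must be +1 or -1", call. = FALSE)
  k <- sum(verdict == 1L)
  x <- stats::setNames(numeric(length(action_ids)), action_ids)
  x[as.character(others[verdict == 1L])] <- k
  x[as.character(others[verdict == -1L])] <- -(length(others) - k)
  x[as.character(target_id)] <-
    if (self_column == "self_max") k + 1 else NA_real_
  x
}

#' Standardize a score vector to z-scores
#'
#' Centers to mean zero and scales to unit standard deviation. The `sd`
#' convention chooses the denominator: `"population"` (divide by n; the
#' default, under which the closed-form relation between the correlation and
#' distance matrices holds exactly) or `"sample"` (divide by n - 1).
#' A constant input has no scale; it maps to the all-zero vector, marked
#' with attribute `degenerate = TRUE`.
#'
#' Missing entries (the `pairwise_exclude` self column) are ignored when
#' computing the mean and sd and stay missing in the output.
#'
#' @param x numeric vector, length >= 2.
#' @param sd `"population"` or `"sample"`.
#' @return z-scored vector, possibly with attribute `degenerate`.
#' @export
z_standardize <- function(x, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  if (length(x) < 2L)
    stop("need at least 2 values to standardize", call. = FALSE)
  ok <- !is.na(x)
  m <- mean(x[ok])
  v <- sum((x[ok] - m)^2) / (if (sd == "population") sum(ok) else sum(ok) - 1L)
  if (v == 0) {
    z <- x
    z[ok] <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (x - m) / sqrt(v)
}

#' Build the Z, R and D matrices from a split dataset
#'
#' Row `t` of the Z matrix is the z-standardized node-score vector of target
#' `t`. The R matrix holds Pearson correlations between all row pairs, the D
#' matrix their Euclidean distances. Under the default conventions
#' (`self_max`, `population`) the identity `D_ij = sqrt(2 n (1 - R_ij))`
#' holds exactly, so R and D carry the same information on different scales.
#'
#' Under `pairwise_exclude` the self entries are missing, and columns `i`
#' and `j` are dropped pairwise before computing `R_ij` and `D_ij`.
#'
#' A degenerate row (the participant gave the same verdict for every action
#' against some target, leaving no variance once the self entry is excluded
#' under `pairwise_exclude`; under `self_max` the self entry always differs,
#' so rows cannot degenerate) has its correlations defined as 0 and its
#' distances as `sqrt(2 n)` — the values a perfectly uncorrelated row would
#' produce — and a warning names the target. A constant pair-specific column
#' subset likewise gets correlation 0, but keeps its true Euclidean
#' distance.
#'
#' @param dataset an [sdam_splits()] (single participant), or a data.frame
#'   with one participant's complete judgments.
#' @param task an [sdam_task()].
#' @param self_column,sd matrix-building conventions; see [node_scores()]
#'   and [z_standardize()].
#' @return object of class `sdam_matrices`: list with `action_ids`, `Z`,
#'   `R`, `D`, `conventions`, `degenerate` (ids of degenerate targets) and
#'   `participant_id`.
#' @export
build_matrices <- function(dataset, task,
                           self_column = c("self_max", "pairwise_exclude"),
                           sd = c("population", "sample")) {
  self_column <- match.arg(self_column)
  sd <- match.arg(sd)
  if (!inherits(dataset, "sdam_splits"))
    dataset <- sdam_splits(dataset, task)
  pid <- unique(dataset$participant_id)
  if (length(pid) != 1L)
    stop("`build_matrices` expects a single participant; got ",
         length(pid), call. = FALSE)

  ids <- task_action_ids(task)
  n <- length(ids)
  Z <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  degenerate <- integer(0)
  for (t in ids) {
    x <- node_scores(t, dataset[dataset$target_id == t, , drop = FALSE],
                     ids, self_column)
    z <- z_standardize(x, sd)
    if (isTRUE(attr(z, "degenerate"))) degenerate <- c(degenerate, t)
    Z[as.character(t), ] <- as.numeric(z)
  }
  if (length(degenerate))
    warning("degenerate (constant) judgment row(s) for target(s) ",
            paste(degenerate, collapse = ", "),
            "; correlations set to 0, distances to sqrt(2n)", call. = FALSE)

  R <- matrix(1, n, n, dimnames = list(ids, ids))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      zi <- Z[i, ]; zj <- Z[j, ]
      if (self_column == "pairwise_exclude") {
        keep <- setdiff(seq_len(n), c(i, j))
        zi <- zi[keep]; zj <- zj[keep]
      }
      deg_i <- ids[i] %in% degenerate
      deg_j <- ids[j] %in% degenerate
      if (deg_i || deg_j) {
        # a fully constant judgment row carries no signal: uncorrelated by
        # definition, at the distance an exactly uncorrelated row would have
        r <- 0
        d <- sqrt(2 * n)
      } else if (stats::sd(zi) == 0 || stats::sd(zj) == 0) {
        # pairwise column drop left a constant sub-row: the correlation is
        # undefined (set to 0) but the Euclidean distance is still real
        r <- 0
        d <- sqrt(sum((zi - zj)^2))
      } else {
        r <- stats::cor(zi, zj)
        d <- sqrt(sum((zi - zj)^2))
      }
      R[i, j] <- R[j, i] <- r
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(action_ids = ids, Z = Z, R = R, D = D,
                 conventions = list(self_column = self_column, sd = sd),
                 degenerate = degenerate, participant_id = pid),
            class = "sdam_matrices")
}

#' @export
print.sdam_matrices <- function(x, ...) {
  cat("SDA-M matrix bundle (participant ", x$participant_id, "): ",
      length(x$action_ids), " actions\n", sep = "")
  cat("  conventions: self_column =", x$conventions$self_column,
      ", sd =", x$conventions$sd, "\n")
  off <- x$R[upper.tri(x$R)]
  cat(sprintf("  R off-diagonal range: [%.3f, %.3f]\n", min(off), max(off)))
  if (length(x$degenerate))
    cat("  degenerate targets:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
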