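# Independent oracles and fixture builders. Each oracle recomputes a
# quantity by the most naive route available so the implementation under
# test never checks itself.

# Naive UPGMA: at every step recompute every cross-cluster mean distance
# from the original matrix and merge the minimum, ties broken by the
# smallest (min id of first cluster, min id of second cluster) pair.
naive_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        a <- clusters[[i]]; b <- clusters[[j]]
        if (min(a) > min(b)) { tmp <- a; a <- b; b <- tmp }
        key <- c(d, min(a), min(b))
        if (is.null(best) ||
            isTRUE(key[1] < best$key[1]) ||
            (key[1] == best$key[1] &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3]))))
          best <- list(key = key, i = i, j = j)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$key[1])
    members <- c(members, list(merged))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, members = members)
}

# Naive CASPA: direct summation of (r/(1-r))^(1/s) weights.
naive_caspa <- function(R, sit, s = 0.4, r_clip = 1e-12) {
  r <- R[as.character(sit$a_j), as.character(sit$candidates)]
  keep <- r > 0
  if (!any(keep)) return(0)
  r <- pmin(r[keep], 1 - r_clip)
  w <- (r / (1 - r))^(1 / s)
  correct <- sit$candidates[keep] %in% sit$C_S
  if (!any(correct)) return(0)
  sum(w[correct]) / sum(w)
}

# Phi coefficient straight from the 2x2 table counts.
phi_from_table <- function(N00, N01, N10, N11) {
  (N00 * N11 - N01 * N10) /
    sqrt((N00 + N01) * (N10 + N11) * (N00 + N10) * (N01 + N11))
}

# Exact upper binomial tail by explicit summation.
binom_tail_sum <- function(matches, N) {
  if (matches == 0) return(1)
  sum(choose(N, matches:N)) * 0.5^N
}

# Per-pair reimplementation of the R/D construction (default conventions):
# score, standardize and correlate each pair from first principles.
naive_matrices <- function(dataset, task) {
  ids <- task$actions$id
  n <- length(ids)
  Z <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (t in ids) {
    sub <- dataset[dataset$target_id == t, ]
    others <- setdiff(ids, t)
    v <- sub$verdict[match(others, sub$compared_id)]
    k <- sum(v == 1)
    x <- numeric(n)
    names(x) <- ids
    x[as.character(others)] <- ifelse(v == 1, k, -(n - 1 - k))
    x[as.character(t)] <- k + 1
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    Z[as.character(t), ] <- if (s == 0) 0 else (x - m) / s
  }
  R <- matrix(1, n, n, dimnames = list(ids, ids))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      zi <- Z[i, ]; zj <- Z[j, ]
      if (sd(zi) == 0 || sd(zj) == 0) {
        r <- 0; d <- sqrt(2 * n)
      } else {
        r <- sum((zi - mean(zi)) * (zj - mean(zj))) /
          sqrt(sum((zi - mean(zi))^2) * sum((zj - mean(zj))^2))
        d <- sqrt(sum((zi - zj)^2))
      }
      R[i, j] <- R[j, i] <- r
      D[i, j] <- D[j, i] <- d
    }
  }
  list(Z = Z, R = R, D = D)
}

# Brute-force enumeration of correct sequences for small tasks.
enumerate_prefixes <- function(task) {
  seqs <- enumerate_sequences(task)
  out <- list()
  for (s in seqs)
    for (k in seq_along(s))
      out[[paste(s[seq_len(k)], collapse = " ")]] <- s[seq_len(k)]
  out
}

# A small task with one ordered and one unordered activity.
toy_task <- function() {
  sdam_task(
    actions = data.frame(id = 1:6, label = paste("action", 1:6)),
    activities = list(
      list(id = 1L, name = "ordered", ordered = TRUE, action_ids = 1:3),
      list(id = 2L, name = "unordered", ordered = FALSE, action_ids = 4:6)
    )
  )
}

# Task with explicit branching sequences: (1,2,3,4,7) and (1,2,3,5,6).
branching_task <- function() {
  sdam_task(
    actions = data.frame(id = 1:7, label = paste("action", 1:7)),
    activities = list(
      list(id = 1L, name = "all", ordered = FALSE, action_ids = 1:7)
    ),
    sequences = list(c(1L, 2L, 3L, 4L, 7L), c(1L, 2L, 3L, 5L, 6L))
  )
}

# A single-ordered-activity task of n actions, for hand-built R/D matrices.
chain_task <- function(n) {
  sdam_task(
    actions = data.frame(id = seq_len(n), label = paste("a", seq_len(n))),
    activities = list(
      list(id = 1L, name = "chain", ordered = TRUE, action_ids = seq_len(n))
    )
  )
}

# Symmetric correlation matrix from a named upper-triangle spec,
# e.g. sym_R(4, "1,2" = .6, "1,3" = .2, "1,4" = -.1); unspecified pairs 0.
sym_R <- function(n, ...) {
  R <- diag(n)
  dimnames(R) <- list(seq_len(n), seq_len(n))
  spec <- list(...)
  for (key in names(spec)) {
    ij <- as.integer(strsplit(key, ",")[[1]])
    R[ij[1], ij[2]] <- R[ij[2], ij[1]] <- spec[[key]]
  }
  R
}

# Random symmetric distance matrix with zero diagonal.
random_D <- function(n) {
  M <- matrix(runif(n * n, 0.1, 10), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(seq_len(n), seq_len(n))
  M
}
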