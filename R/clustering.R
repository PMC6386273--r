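#' Hierarchical agglomerative average-linkage (UPGMA) clustering
#'
#' Clusters the actions on the distance matrix D. The distance between two
#' clusters is the unweighted mean of all cross-pair distances; at every
#' step the closest pair of clusters merges. Ties at the minimum are broken
#' deterministically by the smallest (min id of first cluster, min id of
#' second cluster) pair, so results are reproducible across platforms.
#'
#' @param D symmetric numeric matrix with zero diagonal and non-negative
#'   entries; dimnames give the action ids (defaults to 1..n).
#' @return object of class `sdam_dendrogram`: list with `labels` (action
#'   ids as character), `merge` (hclust-style merge matrix: negative =
#'   leaf, positive = earlier merge row), `height` (merge heights,
#'   non-decreasing), `size` (cluster size after each merge), and `members`
#'   (list of leaf-label sets per merge).
#' @seealso [cut_dendrogram()], [to_newick()], [as.hclust.sdam_dendrogram()]
#' @export
average_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (ncol(D) != n || max(abs(D - t(D))) > 1e-12)
    stop("D must be a symmetric matrix", call. = FALSE)
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  if (any(diag(D) != 0)) stop("D must have a zero diagonal", call. = FALSE)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters: row in working matrix, size, min original index, merge code
  W <- D
  size <- rep(1L, n)
  minid <- seq_len(n)            # smallest original leaf index in the cluster
  code <- -seq_len(n)            # hclust coding
  members <- lapply(seq_len(n), identity)  # original leaf indices
  active <- rep(TRUE, n)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  mmembers <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        a <- idx[ii]; b <- idx[jj]
        d <- W[a, b]
        # order the pair by smallest min original id
        lo <- if (minid[a] <= minid[b]) a else b
        hi <- if (minid[a] <= minid[b]) b else a
        key <- c(d, minid[lo], minid[hi])
        if (is.null(best) || lexicographic_less(key, best$key))
          best <- list(key = key, a = lo, b = hi)
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort_merge_codes(code[a], code[b])
    height[step] <- W[a, b]
    msize[step] <- size[a] + size[b]
    mmembers[[step]] <- sort(c(members[[a]], members[[b]]))  # leaf indices

    # Lance-Williams update for average linkage, merged cluster stored in a
    for (k in which(active)) {
      if (k == a || k == b) next
      W[a, k] <- W[k, a] <-
        (size[a] * W[a, k] + size[b] * W[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    minid[a] <- min(minid[a], minid[b])
    members[[a]] <- mmembers[[step]]
    code[a] <- step
    active[b] <- FALSE
  }

  structure(list(labels = labels, merge = merge, height = height,
                 size = msize,
                 members = lapply(mmembers, function(m) labels[m])),
            class = "sdam_dendrogram")
}

lexicographic_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  FALSE
}

# order a merge row for display: smaller leaf first among singletons,
# sub-clusters before singletons, earlier merges first among sub-clusters
sort_merge_codes <- function(a, b) {
  if ((a < 0 && b < 0 && a < b) || (a > 0 && b > 0 && a > b) ||
      (a < 0 && b > 0))
    c(b, a)
  else
    c(a, b)
}

#' @export
print.sdam_dendrogram <- function(x, ...) {
  cat("Average-linkage dendrogram:", length(x$labels), "leaves,",
      length(x$height), "merges\n")
  cat(sprintf("  merge heights: %.4g .. %.4g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a dendrogram to a stats::hclust object
#'
#' Enables plotting with [stats::plot.hclust()] and cutting with
#' [stats::cutree()].
#'
#' @param x an `sdam_dendrogram`.
#' @param ... unused.
#' @export
as.hclust.sdam_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendrogram_leaf_order(x$merge),
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

dendrogram_leaf_order <- function(merge) {
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(merge[code, 1L]), expand(merge[code, 2L]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram at a critical distance
#'
#' Removes all merges with height above `d_crit`; the resulting connected
#' components are the clusters.
#'
#' @param dendro an `sdam_dendrogram`.
#' @param d_crit non-negative distance threshold.
#' @return list of character vectors of leaf labels, one per cluster,
#'   ordered by smallest member label.
#' @export
cut_dendrogram <- function(dendro, d_crit) {
  stopifnot(d_crit >= 0)
  h <- as.hclust.sdam_dendrogram(dendro)
  grp <- stats::cutree(h, h = d_crit)
  cl <- split(names(grp), grp)
  names(cl) <- NULL
  ord <- order(vapply(cl, function(m) min(suppressWarnings(as.numeric(m)),
                                          na.rm = TRUE), numeric(1)))
  cl[ord]
}

#' Export a dendrogram as a Newick tree string
#'
#' Branch lengths follow the standard dendrogram-to-tree convention: each
#' child branch has length (parent merge height - child height) / 2, so the
#' cophenetic (tip-to-tip path) distance of the tree equals the original
#' merge heights and every leaf sits at depth (root height) / 2.
#'
#' @param dendro an `sdam_dendrogram`.
#' @param digits significant digits for branch lengths.
#' @return single Newick string, semicolon-terminated.
#' @export
to_newick <- function(dendro, digits = 10) {
  merge <- dendro$merge
  height <- dendro$height
  node_str <- function(code, parent_h) {
    if (code < 0) {
      len <- parent_h / 2
      return(sprintf("%s:%s", dendro$labels[-code],
                     format(len, digits = digits)))
    }
    h <- height[code]
    kids <- paste(node_str(merge[code, 1L], h),
                  node_str(merge[code, 2L], h), sep = ",")
    sprintf("(%s):%s", kids, format((parent_h - h) / 2, digits = digits))
  }
  root <- nrow(merge)
  h <- height[root]
  paste0("(", node_str(merge[root, 1L], h), ",",
         node_str(merge[root, 2L], h), ");")
}

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance of two leaves is the height of the lowest merge
#' joining them. If the input distance matrix was exactly ultrametric,
#' these reproduce it.
#'
#' @param dendro an `sdam_dendrogram`.
#' @return symmetric matrix with the dendrogram's leaf labels.
#' @export
cophenetic_distances <- function(dendro) {
  n <- length(dendro$labels)
  M <- matrix(0, n, n, dimnames = list(dendro$labels, dendro$labels))
  for (s in seq_along(dendro$height)) {
    left <- merge_leaves(dendro$merge, dendro$merge[s, 1L])
    right <- merge_leaves(dendro$merge, dendro$merge[s, 2L])
    M[left, right] <- dendro$height[s]
    M[right, left] <- dendro$height[s]
  }
  M
}

merge_leaves <- function(merge, code) {
  if (code < 0) return(-code)
  c(merge_leaves(merge, merge[code, 1L]),
    merge_leaves(merge, merge[code, 2L]))
}

#' Plot a dendrogram
#'
#' Draws the merge tree with action ids as labels and, optionally, a
#' horizontal line at the critical distance used for cutting.
#'
#' @param x an `sdam_dendrogram`.
#' @param d_crit optional critical distance to draw.
#' @param ... passed to [stats::plot.hclust()].
#' @export
plot.sdam_dendrogram <- function(x, d_crit = NULL, ...) {
  graphics::plot(as.hclust.sdam_dendrogram(x), ...)
  if (!is.null(d_crit))
    graphics::abline(h = d_crit, lty = 2, col = "red")
  invisible(x)
}
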