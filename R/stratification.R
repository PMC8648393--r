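#' Average-linkage hierarchical clustering on Euclidean distances
#'
#' UPGMA on the rows of a feature matrix (e.g. per-cancer-type mean SR or
#' mean LSR vectors). Deterministic; distance ties are resolved by the
#' agglomeration order of `stats::hclust`, which is by lowest item index.
#'
#' @param mat Items x features numeric matrix, no missing values.
#' @param k Optional number of clusters to cut the tree at.
#' @return List with `tree` (an `hclust`) and, when `k` is given,
#'   `assignments` (a `cluster_assignment`).
#' @export
hierarchical <- function(mat, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 items to cluster")
  if (anyNA(mat)) stop("missing values not allowed in the feature matrix")
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "average")
  out <- list(tree = tree)
  if (!is.null(k)) {
    lab <- stats::cutree(tree, k = k)
    out$assignments <- new_cluster_assignment(
      lab, method = "hierarchical-UPGMA", k = k,
      distance = "euclidean", linkage = "average")
  }
  out
}

#' k-means clustering with multiple random starts
#'
#' Lloyd/Hartigan-Wong k-means as in `stats::kmeans`, taking the best of
#' `n_starts` random initializations by within-cluster sum of squares;
#' fully reproducible given `seed`.
#'
#' @param mat Items x features numeric matrix.
#' @param k Number of clusters (k <= number of items).
#' @param n_starts Number of random initializations (default 25).
#' @param seed Integer seed for the initialization stream.
#' @return A `cluster_assignment` with the fitted `stats::kmeans` object
#'   in `attr(, "fit")`.
#' @export
kmeans_cluster <- function(mat, k, n_starts = 25L, seed = 1L) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values not allowed in the feature matrix")
  if (k > nrow(mat)) stop("k = ", k, " exceeds the number of items")
  set.seed(seed)
  fit <- if (k == nrow(mat)) {
    # every item its own cluster; stats::kmeans rejects this edge case
    list(cluster = seq_len(nrow(mat)), centers = mat,
         totss = sum(scale(mat, scale = FALSE)^2),
         withinss = rep(0, k), tot.withinss = 0)
  } else {
    stats::kmeans(mat, centers = k, nstart = n_starts, iter.max = 100L)
  }
  out <- new_cluster_assignment(stats::setNames(fit$cluster,
                                                rownames(mat)),
                                method = "kmeans", k = k,
                                n_starts = n_starts, seed = seed)
  attr(out, "fit") <- fit
  out
}

new_cluster_assignment <- function(labels, ...) {
  labels <- as.integer(labels) |> stats::setNames(names(labels))
  stopifnot(all(labels >= 1L))
  structure(labels, meta = list(...), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  m <- attr(x, "meta")
  cat("cluster_assignment (", m$method, "): ", length(x), " items in ",
      length(unique(unclass(x))), " clusters\n", sep = "")
  print(table(unclass(x)))
  invisible(x)
}

#' Chi-square association between cluster labels and a clinical factor
#'
#' Pearson chi-square (no continuity correction) on the labels x factor
#' contingency table, df = (r - 1)(c - 1).
#'
#' @param labels A `cluster_assignment` (or any vector of labels).
#' @param factor A categorical vector over the same items, at least 2
#'   levels.
#' @return List with `statistic`, `df`, `p` and the contingency `table`.
#' @export
chi_square_association <- function(labels, factor) {
  labels <- unclass(labels)
  if (length(labels) != length(factor)) {
    stop("labels and factor must cover the same items")
  }
  tab <- table(labels, factor)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 levels in both labels and factor")
  }
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cnt == 0)) {
    stop("contingency table has a zero expected count; ",
         "merge sparse levels before testing")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter), p = res$p.value, table = tab)
}

#' Per-type mean entropy features for type-level clustering
#'
#' Collapses a per-sample entropy matrix to one mean SR value and one mean
#' LSR vector per group (e.g. cancer type), the representation used for
#' clustering tumor types.
#'
#' @param em An `entropy_matrix`.
#' @param groups Factor/character vector assigning each sample to a type.
#' @return List with `mean_sr` (named numeric) and `mean_lsr` (types x
#'   genes matrix).
#' @export
type_means <- function(em, groups) {
  stopifnot(inherits(em, "entropy_matrix"),
            length(groups) == ncol(em$lsr))
  groups <- as.factor(groups)
  mean_sr <- tapply(em$summary$SR, groups, mean)
  mean_lsr <- t(apply(em$lsr, 1L, function(v) tapply(v, groups, mean)))
  list(mean_sr = c(mean_sr), mean_lsr = t(mean_lsr))
}
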