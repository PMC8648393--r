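#' Cohen's d effect size (pooled SD)
#'
#' (mean(a) - mean(b)) / s_pooled, with s_pooled from the two unbiased
#' variances weighted by their degrees of freedom. By the convention used
#' throughout the differential analysis, `a` is the tumor group, so d > 0
#' means higher in tumor.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return The effect size d; 0 with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero; returning d = 0")
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Two-sided two-sample Student's t-test
#'
#' Classic pooled-variance test with df = n_a + n_b - 2 (a Welch option is
#' provided but off by default, matching the classical name). Degenerate
#' zero-variance input is handled explicitly: equal means give t = 0,
#' p = 1; unequal means give an infinite statistic and p = 0.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param welch Use the Welch unequal-variance test instead.
#' @return List with `t` and `p`.
#' @export
ttest_two_sided <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg false discovery rate
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential local signaling entropy between two groups
#'
#' Per-gene tumor-vs-normal comparison of LSR: Student's t (two-sided),
#' BH FDR across genes, Cohen's d (tumor minus normal). Genes are classed
#' `up` (q < q_max and d > d_min), `down` (q < q_max and d < -d_min), or
#' `none`.
#'
#' @param lsr_tumor,lsr_normal Gene x sample LSR matrices sharing the same
#'   gene order; at least 2 samples per group.
#' @param q_max FDR threshold (default 0.05).
#' @param d_min Effect-size threshold on |d| (default 1).
#' @param welch Use Welch's t instead of the pooled test.
#' @return A `data.frame` of class `dlsr_table`: gene, mean_tumor,
#'   mean_normal, t, p, q, d, class.
#' @export
dlsr <- function(lsr_tumor, lsr_normal, q_max = 0.05, d_min = 1,
                 welch = FALSE) {
  if (!identical(rownames(lsr_tumor), rownames(lsr_normal))) {
    stop("tumor and normal matrices must share the same gene order")
  }
  if (ncol(lsr_tumor) < 2L || ncol(lsr_normal) < 2L) {
    stop("need at least 2 samples per group")
  }
  genes <- rownames(lsr_tumor)
  n_g <- length(genes)
  t_stat <- p <- d <- numeric(n_g)
  for (i in seq_len(n_g)) {
    a <- lsr_tumor[i, ]; b <- lsr_normal[i, ]
    tt <- ttest_two_sided(a, b, welch = welch)
    t_stat[i] <- tt$t
    p[i] <- tt$p
    d[i] <- suppressWarnings(cohens_d(a, b))
  }
  q <- bh_fdr(p)
  cls <- rep("none", n_g)
  cls[q < q_max & d > d_min] <- "up"
  cls[q < q_max & d < -d_min] <- "down"
  out <- data.frame(gene = genes,
                    mean_tumor = rowMeans(lsr_tumor),
                    mean_normal = rowMeans(lsr_normal),
                    t = t_stat, p = p, q = q, d = d, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  message("dlsr: ", sum(cls == "up"), " up / ", sum(cls == "down"),
          " down / ", sum(cls == "none"), " unchanged")
  class(out) <- c("dlsr_table", "data.frame")
  out
}

#' Consensus differential features across cancer types
#'
#' Genes classed `up` (resp. `down`) in at least `min_types` of the
#' supplied per-type differential tables, mirroring the selection of a
#' shared prognostic feature panel across tumor types.
#'
#' @param tables A list of `dlsr_table` objects (one per cancer type).
#' @param min_types Minimum number of tables in which a gene must carry
#'   the same class.
#' @return List with character vectors `up` and `down` and a `membership`
#'   data.frame counting per-gene up/down calls across tables.
#' @export
consensus_features <- function(tables, min_types) {
  stopifnot(length(tables) >= 1L, min_types >= 1L)
  genes <- unique(unlist(lapply(tables, function(t) t$gene)))
  up_n <- down_n <- setNames(integer(length(genes)), genes)
  for (t in tables) {
    up_n[t$gene[t$class == "up"]] <- up_n[t$gene[t$class == "up"]] + 1L
    down_n[t$gene[t$class == "down"]] <-
      down_n[t$gene[t$class == "down"]] + 1L
  }
  up <- names(up_n)[up_n >= min_types]
  down <- names(down_n)[down_n >= min_types]
  if (!length(up) && !length(down)) {
    message("consensus_features: no gene reaches ", min_types, " types")
  }
  list(up = up, down = down,
       membership = data.frame(gene = genes, n_up = unname(up_n),
                               n_down = unname(down_n),
                               stringsAsFactors = FALSE))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a
#' selected gene list, against a stated universe (by default the signaling
#' network's node set in the drivers). Set membership is intersected with
#' the universe before testing; BH correction is applied across sets.
#'
#' @param selected Character vector of selected genes (must lie in
#'   `universe`).
#' @param universe Character vector: the background gene universe.
#' @param sets A `gene_set_collection` (named list of character vectors).
#' @return A `data.frame`: set, overlap, set_size, selected_size,
#'   universe_size, p, q, ordered by p.
#' @export
ora <- function(selected, universe, sets) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (length(selected) == 0L) stop("empty selected gene list")
  out_u <- setdiff(selected, universe)
  if (length(out_u)) stop("selected gene(s) outside the universe: ",
                          paste(utils::head(out_u, 5L), collapse = ", "))
  N <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    # P(X >= k) for X ~ Hypergeom(N, K, n_sel)
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n_sel,
                                           lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K,
               selected_size = n_sel, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res[order(res$p), , drop = FALSE]
}
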