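#' Binarize a drug's ln-IC50 values into sensitive/resistant
#'
#' Default method fits a two-component Gaussian mixture to the ln-IC50
#' vector (natural log of the uM half-maximal inhibitory concentration)
#' and places the threshold at the equal-posterior crossing between the
#' component means. When model selection prefers a single component, or
#' the two-component fit degenerates (a vanishing component, or no
#' posterior crossing between the means), the threshold falls back to the
#' median and the record is flagged. Sensitive = ln-IC50 strictly below
#' the threshold.
#'
#' @param ic50 Numeric vector of ln-IC50 values for one drug (missing
#'   values dropped); at least 10 non-missing values required.
#' @param min_weight Smallest admissible mixture weight before the fit is
#'   deemed degenerate (default 0.05).
#' @return List with `threshold`, `labels` (character, `"sensitive"` /
#'   `"resistant"`, aligned to the non-missing input, names kept), and
#'   `method` (`"mixture"` or `"median"`).
#' @export
binarize_ic50 <- function(ic50, min_weight = 0.05) {
  keep <- !is.na(ic50)
  v <- ic50[keep]
  if (length(v) < 10L) stop("need >= 10 non-missing ln-IC50 values, got ",
                            length(v))
  if (stats::sd(v) == 0) stop("degenerate IC50 vector: all values identical")
  thr <- NA_real_
  method <- "median"
  # Mclust resolves its helper functions in the caller's frame, so the
  # call is evaluated inside the mclust namespace
  fit <- tryCatch(
    eval(call("Mclust", data = v, G = 1:2,
              modelNames = c("E", "V"), verbose = FALSE),
         envir = asNamespace("mclust")),
    error = function(e) NULL)
  if (!is.null(fit) && fit$G == 2L) {
    pars <- fit$parameters
    mu <- pars$mean
    sig <- sqrt(if (length(pars$variance$sigmasq) == 1L)
      rep(pars$variance$sigmasq, 2L) else pars$variance$sigmasq)
    w <- pars$pro
    if (min(w) >= min_weight && abs(diff(mu)) > 1e-8) {
      lo <- min(mu); hi <- max(mu)
      post_diff <- function(t) {
        d1 <- w[1] * stats::dnorm(t, mu[1], sig[1])
        d2 <- w[2] * stats::dnorm(t, mu[2], sig[2])
        if (mu[1] < mu[2]) d1 - d2 else d2 - d1
      }
      if (sign(post_diff(lo)) != sign(post_diff(hi))) {
        thr <- stats::uniroot(post_diff, c(lo, hi))$root
        method <- "mixture"
      }
    }
  }
  if (method == "median") thr <- stats::median(v)
  labels <- ifelse(v < thr, "sensitive", "resistant")
  names(labels) <- names(v)
  if (method == "median") {
    message("binarize_ic50: mixture fit unimodal/degenerate; ",
            "median fallback used")
  }
  list(threshold = thr, labels = labels, method = method)
}

#' SR effect size between resistant and sensitive cell lines
#'
#' Cohen's d of global signaling entropy, resistant minus sensitive (so a
#' positive effect size means SR is higher in resistant lines), with a
#' two-sided Student's t p-value.
#'
#' @param sr Named numeric vector of SR per cell line.
#' @param labels Character vector (`"sensitive"` / `"resistant"`) aligned
#'   to `sr` (matched by name when both are named).
#' @return List with `d`, `t`, `p`, and per-class counts.
#' @export
sr_drug_effect <- function(sr, labels) {
  if (!is.null(names(sr)) && !is.null(names(labels))) {
    common <- intersect(names(sr), names(labels))
    sr <- sr[common]; labels <- labels[common]
  }
  stopifnot(length(sr) == length(labels))
  res <- sr[labels == "resistant"]
  sen <- sr[labels == "sensitive"]
  if (length(res) < 2L || length(sen) < 2L) {
    stop("need >= 2 cell lines per class (resistant: ", length(res),
         ", sensitive: ", length(sen), ")")
  }
  tt <- ttest_two_sided(res, sen)
  list(d = suppressWarnings(cohens_d(res, sen)), t = tt$t, p = tt$p,
       n_resistant = length(res), n_sensitive = length(sen))
}

#' Per-drug SR effect sizes across a drug panel
#'
#' Runs [binarize_ic50()] and [sr_drug_effect()] for every drug of an
#' ln-IC50 matrix; drugs whose binarization leaves a class with fewer than
#' 2 lines are skipped with a warning. P-values are BH-adjusted across
#' drugs.
#'
#' @param sr Named SR vector per cell line.
#' @param ic50 Cell line x drug matrix of ln-IC50.
#' @return `data.frame`: drug, threshold, method, d, t, p, q, class
#'   counts.
#' @export
sr_drug_effects <- function(sr, ic50) {
  rows <- lapply(colnames(ic50), function(dr) {
    v <- ic50[, dr]
    names(v) <- rownames(ic50)
    out <- tryCatch({
      b <- suppressMessages(binarize_ic50(v))
      e <- sr_drug_effect(sr, b$labels)
      data.frame(drug = dr, threshold = b$threshold, method = b$method,
                 d = e$d, t = e$t, p = e$p,
                 n_sensitive = e$n_sensitive,
                 n_resistant = e$n_resistant, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("drug ", dr, " skipped: ", conditionMessage(e))
      NULL
    })
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no drug could be analysed")
  res$q <- bh_fdr(res$p)
  res
}

#' LSR ratio of drug targets
#'
#' For each (cell line, drug, target) triple, the target gene's local
#' signaling entropy divided by the cell line's total SR. Because the
#' LSRs sum to SR, the ratio is a proportion in `[0, 1]` that isolates
#' the target's share of the signaling entropy from the influence of all
#' other genes; it is identical whether computed from normalized or raw
#' LSR, since both carry the same normalization.
#'
#' @param em An `entropy_matrix` over the cell lines.
#' @param targets `data.frame` with columns `drug` and `target` (one row
#'   per target; multi-target drugs contribute one row per target).
#' @param mutations Optional cell line x gene 0/1 matrix of target
#'   mutation status.
#' @return `data.frame` of class `drug_target_scores`: cell_line, drug,
#'   target, ratio (and `mutated` when mutations are given). Targets
#'   absent from the network are listed in `attr(, "unmapped")`.
#' @export
lsr_ratio <- function(em, targets, mutations = NULL) {
  stopifnot(inherits(em, "entropy_matrix"),
            all(c("drug", "target") %in% names(targets)))
  sr_tot <- stats::setNames(em$summary$SR, em$summary$sample)
  if (any(sr_tot <= 0)) stop("non-positive SR encountered")
  mapped <- targets$target %in% rownames(em$lsr)
  unmapped <- unique(targets$target[!mapped])
  if (length(unmapped)) {
    message("lsr_ratio: ", length(unmapped),
            " target(s) absent from the network: ",
            paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  tg <- targets[mapped, , drop = FALSE]
  cells <- colnames(em$lsr)
  out <- do.call(rbind, lapply(seq_len(nrow(tg)), function(i) {
    g <- tg$target[i]
    data.frame(cell_line = cells, drug = tg$drug[i], target = g,
               ratio = em$lsr[g, ] / sr_tot[cells],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(mutations)) {
    out$mutated <- mapply(function(cl, g) {
      if (cl %in% rownames(mutations) && g %in% colnames(mutations)) {
        as.integer(mutations[cl, g])
      } else NA_integer_
    }, out$cell_line, out$target)
  }
  attr(out, "unmapped") <- unmapped
  class(out) <- c("drug_target_scores", "data.frame")
  out
}

#' Correlation between LSR ratio and ln-IC50
#'
#' Pearson correlation (two-sided test) between each drug target's LSR
#' ratio and the drug's ln-IC50 across cell lines, optionally stratified
#' by the target's mutation status. A negative correlation means cell
#' lines in which the target carries a larger share of the signaling
#' entropy are more sensitive to the drug.
#'
#' @param scores A `drug_target_scores` table.
#' @param ic50 Cell line x drug matrix of ln-IC50.
#' @param stratify_by_mutation Split each (drug, target) by the `mutated`
#'   column (requires `lsr_ratio(..., mutations = )`).
#' @return `data.frame`: drug, target (, mutated), n, r, p, plus a
#'   `summary` attribute counting significant negative/positive
#'   correlations at p < 0.05.
#' @export
ratio_ic50_correlation <- function(scores, ic50,
                                   stratify_by_mutation = FALSE) {
  stopifnot(inherits(scores, "drug_target_scores"))
  if (stratify_by_mutation && is.null(scores$mutated)) {
    stop("scores carry no mutation status; rerun lsr_ratio with mutations")
  }
  key <- if (stratify_by_mutation) {
    interaction(scores$drug, scores$target, scores$mutated, drop = TRUE)
  } else interaction(scores$drug, scores$target, drop = TRUE)
  rows <- lapply(split(scores, key), function(s) {
    dr <- s$drug[1L]
    if (!dr %in% colnames(ic50)) return(NULL)
    y <- ic50[s$cell_line, dr]
    ok <- !is.na(y)
    if (sum(ok) < 3L) return(NULL)
    x <- s$ratio[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance for drug ", dr, " / target ", s$target[1L],
              "; record skipped")
      return(NULL)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    base <- data.frame(drug = dr, target = s$target[1L], n = sum(ok),
                       r = unname(ct$estimate), p = ct$p.value,
                       stringsAsFactors = FALSE)
    if (stratify_by_mutation) base$mutated <- s$mutated[1L]
    base
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no (drug, target) stratum had enough data")
  rownames(res) <- NULL
  attr(res, "summary") <- c(
    sig_negative = sum(res$r < 0 & res$p < 0.05),
    sig_positive = sum(res$r > 0 & res$p < 0.05),
    nonsig = sum(res$p >= 0.05))
  res
}
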