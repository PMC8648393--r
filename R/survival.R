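#' Multivariate Cox proportional-hazards model on entropy features
#'
#' Fits one pan-feature Cox model (partial likelihood, Breslow tie
#' handling by default) of survival on a samples x features matrix, e.g.
#' the consensus LSR features. All supplied features are kept: no variable
#' selection is performed, so features weakly related to survival in one
#' cohort can still contribute in another. Cohorts with fewer samples than
#' features are rejected, matching the exclusion of such tumor types from
#' the original analysis.
#'
#' @param features Samples x features numeric matrix, rownames = sample
#'   ids.
#' @param clinical A `clinical_table` covering those samples.
#' @param efron Use Efron instead of Breslow tie handling.
#' @param ridge Non-negative ridge penalty (0 = none); a small penalty
#'   stabilizes near-separated fits.
#' @return An object of class `cox_fit`: coefficients, hazard ratios,
#'   per-sample linear predictor, Harrell's C-index, convergence info and
#'   the underlying `survival::coxph` fit.
#' @export
fit_cox <- function(features, clinical, efron = FALSE, ridge = 0) {
  features <- as.matrix(features)
  clinical <- validate_clinical(as.data.frame(clinical))
  idx <- match(rownames(features), clinical$sample)
  if (anyNA(idx)) stop("clinical data missing for sample(s): ",
                       paste(utils::head(rownames(features)[is.na(idx)], 5L),
                             collapse = ", "))
  clinical <- clinical[idx, ]
  n <- nrow(features); p <- ncol(features)
  if (p >= n) {
    stop("p = ", p, " features with only n = ", n, " samples; ",
         "cohorts with n <= p are excluded from Cox fitting")
  }
  dat <- data.frame(time = clinical$time, event = clinical$event,
                    features, check.names = FALSE)
  ties <- if (efron) "efron" else "breslow"
  fml <- if (ridge > 0) {
    stats::as.formula(paste0(
      "Surv(time, event) ~ ridge(",
      paste(sprintf("`%s`", colnames(features)), collapse = ", "),
      ", theta = ", ridge, ", scale = TRUE)"))
  } else {
    stats::as.formula(paste(
      "Surv(time, event) ~",
      paste(sprintf("`%s`", colnames(features)), collapse = " + ")))
  }
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (ridge == 0 && !is.null(fit$info) ) fit$info <- NULL
  if (anyNA(stats::coef(fit))) {
    stop("Cox fit did not converge to finite coefficients; ",
         "consider the ridge argument")
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(features)
  lp <- as.numeric(features %*% beta)
  names(lp) <- rownames(features)
  structure(list(features = colnames(features),
                 coefficients = beta,
                 hazard_ratios = exp(beta),
                 linear_predictor = lp,
                 cindex = concordance_index(lp, clinical),
                 iterations = fit$iter,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit: ", length(x$coefficients), " feature(s), C-index = ",
      format(x$cindex, digits = 4), "\n", sep = "")
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios))
  invisible(x)
}

#' Apply a fitted Cox model to new samples
#'
#' Computes the linear predictor (log relative hazard) only; no refit.
#' This is how a model trained on cohorts with matched controls is carried
#' over to cohorts without them.
#'
#' @param fit A `cox_fit`.
#' @param features Samples x features matrix containing the fit's
#'   features.
#' @return Named numeric vector of linear predictors.
#' @export
apply_cox <- function(fit, features) {
  stopifnot(inherits(fit, "cox_fit"))
  miss <- setdiff(fit$features, colnames(features))
  if (length(miss)) stop("new data missing feature(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  lp <- as.numeric(as.matrix(features[, fit$features, drop = FALSE]) %*%
                     fit$coefficients)
  stats::setNames(lp, rownames(features))
}

#' Harrell's concordance index
#'
#' Probability that, over comparable pairs (one sample's event observed
#' before the other's event or censoring), the model ranks the earlier
#' event as higher risk. Ties in the predictor count 1/2. Higher linear
#' predictor = higher risk.
#'
#' @param lp Linear predictor (risk score), one value per sample.
#' @param clinical A `clinical_table` aligned to `lp` (matched by sample
#'   id when `lp` is named).
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(lp, clinical) {
  clinical <- validate_clinical(as.data.frame(clinical))
  if (!is.null(names(lp))) {
    idx <- match(names(lp), clinical$sample)
    if (anyNA(idx)) stop("clinical data missing for some lp samples")
    clinical <- clinical[idx, ]
  } else stopifnot(length(lp) == nrow(clinical))
  cf <- survival::concordance(
    survival::Surv(clinical$time, clinical$event) ~ lp, reverse = TRUE)
  if (sum(cf$count[c("concordant", "discordant", "tied.x")]) == 0) {
    stop("no comparable pairs (no events, or all times tied)")
  }
  unname(cf$concordance)
}

#' Median split of samples into risk groups
#'
#' High risk = linear predictor strictly greater than the cohort median of
#' the linear predictor; everything else (including an all-equal
#' degenerate cohort) is low risk.
#'
#' @param fit A `cox_fit`, or a numeric linear-predictor vector.
#' @return An object of class `risk_groups`: named character vector in
#'   `{"high", "low"}` with the split value in `attr(, "split")`.
#' @export
median_split <- function(fit) {
  lp <- if (inherits(fit, "cox_fit")) fit$linear_predictor else fit
  med <- stats::median(lp)
  grp <- ifelse(lp > med, "high", "low")
  structure(stats::setNames(grp, names(lp)), split = med,
            class = "risk_groups")
}

#' Kaplan-Meier survival curves per risk group
#'
#' @param groups A `risk_groups` (or any grouping vector).
#' @param clinical A `clinical_table` aligned (by sample id when `groups`
#'   is named).
#' @return A `survival::survfit` object.
#' @export
km_curve <- function(groups, clinical) {
  al <- align_groups(groups, clinical)
  if (any(table(al$group) == 0L)) stop("empty group")
  survival::survfit(survival::Surv(time, event) ~ group, data = al)
}

#' Two-group log-rank test
#'
#' @inheritParams km_curve
#' @return List with `statistic` (chi-square, 1 df for two groups) and
#'   `p`.
#' @export
logrank <- function(groups, clinical) {
  al <- align_groups(groups, clinical)
  tab <- table(al$group)
  if (any(tab == 0L) || length(tab) < 2L) {
    stop("log-rank needs at least two non-empty groups")
  }
  if (sum(al$event) == 0) stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = al)
  df <- length(tab) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

align_groups <- function(groups, clinical) {
  clinical <- validate_clinical(as.data.frame(clinical))
  g <- as.character(unclass(groups))
  names(g) <- names(groups)
  if (!is.null(names(g))) {
    idx <- match(names(g), clinical$sample)
    if (anyNA(idx)) stop("clinical data missing for some grouped samples")
    clinical <- clinical[idx, ]
  } else stopifnot(length(g) == nrow(clinical))
  data.frame(time = clinical$time, event = clinical$event,
             group = factor(g), stringsAsFactors = FALSE)
}
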