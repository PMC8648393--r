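make_clin <- function(time, event, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%03d", seq_along(time))
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("concordance matches a brute-force pair count", {
  clin <- make_clin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 2, 1), clin), 1)
  expect_equal(concordance_index(c(1, 2, 3), clin), 0)
  expect_equal(concordance_index(c(3, 1, 2), clin), 2 / 3)
  # random draws against the O(n^2) oracle, censoring included
  set.seed(61)
  for (rep in 1:5) {
    n <- 40
    time <- rexp(n); event <- rbinom(n, 1, 0.7); lp <- rnorm(n)
    expect_equal(concordance_index(lp, make_clin(time, event)),
                 concordance_oracle(lp, time, event))
  }
  expect_error(concordance_index(c(1, 2), make_clin(c(1, 2), c(0, 0))),
               "no comparable pairs")
})

test_that("Cox fitting recovers planted coefficients and rejects p >= n", {
  set.seed(62)
  n <- 500
  z <- matrix(rnorm(n), ncol = 1, dimnames = list(sprintf("s%03d", 1:n),
                                                  "f1"))
  times <- rexp(n, rate = 0.01 * exp(0.8 * z[, 1]))
  clin <- make_clin(times, rep(1, n), rownames(z))
  fit <- fit_cox(z, clin)
  expect_equal(unname(fit$coefficients), 0.8, tolerance = 0.15 / 0.8)
  expect_gt(fit$cindex, 0.65)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))

  # feature independent of survival: C-index near 1/2
  z0 <- matrix(rnorm(n), ncol = 1, dimnames = dimnames(z))
  fit0 <- fit_cox(z0, clin)
  expect_equal(fit0$cindex, 0.5, tolerance = 0.1)

  # a binary feature separating early from late events: positive risk
  # coefficient; C-index equals the tie-aware brute-force value (within-
  # group pairs are predictor ties, counted 1/2)
  zb <- matrix(rep(c(1, 0), each = 10), ncol = 1,
               dimnames = list(sprintf("s%03d", 1:20), "f1"))
  clinb <- make_clin(c(1:10, 101:110), rep(1, 20), rownames(zb))
  fitb <- suppressWarnings(fit_cox(zb, clinb))
  expect_gt(unname(fitb$coefficients), 0)
  expect_equal(fitb$cindex,
               concordance_oracle(zb[, 1], clinb$time, clinb$event))
  # a continuous feature that perfectly ranks event times: C = 1
  zc <- matrix(20:1, ncol = 1, dimnames = dimnames(zb))
  expect_equal(concordance_index(zc[, 1], clinb), 1)

  wide <- matrix(rnorm(5 * 6), nrow = 5,
                 dimnames = list(sprintf("s%03d", 1:5), paste0("f", 1:6)))
  expect_error(fit_cox(wide, make_clin(1:5, rep(1, 5), rownames(wide))),
               "excluded")
})

test_that("coefficients rescale inversely under feature scaling", {
  set.seed(63)
  n <- 200
  z <- matrix(rnorm(n), ncol = 1, dimnames = list(sprintf("s%03d", 1:n),
                                                  "f1"))
  clin <- make_clin(rexp(n, 0.01 * exp(0.5 * z[, 1])), rep(1, n),
                    rownames(z))
  f1 <- fit_cox(z, clin)
  f10 <- fit_cox(z * 10, clin)
  expect_equal(unname(f10$coefficients), unname(f1$coefficients) / 10,
               tolerance = 1e-6)
  expect_equal(order(f10$linear_predictor), order(f1$linear_predictor))
  expect_equal(f10$cindex, f1$cindex)
})

test_that("a fitted model can be re-applied to new cohorts without refit", {
  set.seed(64)
  z <- matrix(rnorm(100), ncol = 2,
              dimnames = list(sprintf("s%03d", 1:50), c("f1", "f2")))
  clin <- make_clin(rexp(50, 0.01 * exp(0.7 * z[, 1])), rep(1, 50),
                    rownames(z))
  fit <- fit_cox(z, clin)
  znew <- matrix(rnorm(20), ncol = 2,
                 dimnames = list(sprintf("t%02d", 1:10), c("f1", "f2")))
  lp <- apply_cox(fit, znew)
  expect_equal(unname(lp), as.numeric(znew %*% fit$coefficients))
  expect_error(apply_cox(fit, znew[, 1, drop = FALSE]), "missing feature")
})

test_that("median split puts strictly-above-median samples in the high arm", {
  g <- median_split(stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4)))
  expect_equal(as.character(unclass(g)), c("low", "low", "high", "high"))
  expect_equal(attr(g, "split"), 2.5)
  g3 <- median_split(c(1, 2, 3))
  expect_equal(as.character(unclass(g3)), c("low", "low", "high"))
  expect_true(all(unclass(median_split(rep(1, 5))) == "low"))
})

test_that("KM and log-rank reproduce hand results and detect planted hazard", {
  # product-limit with no censoring: drops to 2/3, 1/3, 0
  clin <- make_clin(c(1, 2, 3), c(1, 1, 1))
  grp <- structure(stats::setNames(rep("all", 3), clin$sample),
                   class = "risk_groups")
  km <- km_curve(stats::setNames(rep(c("a", "b"), c(2, 1)), clin$sample),
                 clin)
  expect_s3_class(km, "survfit")
  km1 <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = clin)
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))

  # identical groups: statistic near zero
  set.seed(65)
  t2 <- rexp(100, 0.01)
  clin2 <- make_clin(c(t2, t2), rep(1, 200))
  g2 <- stats::setNames(rep(c("a", "b"), each = 100), clin2$sample)
  lr <- logrank(g2, clin2)
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)

  # planted hazard ratio 3 at n = 200: power across seeded replicates
  hits <- vapply(1:40, function(i) {
    set.seed(6500 + i)
    g <- rep(c("high", "low"), each = 100)
    times <- rexp(200, ifelse(g == "high", 0.03, 0.01))
    cl <- make_clin(times, rep(1, 200))
    logrank(stats::setNames(g, cl$sample), cl)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  expect_error(logrank(stats::setNames(rep("a", 3), clin$sample), clin),
               "two non-empty groups")
})
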