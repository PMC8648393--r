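test_that("IC50 binarization separates a bimodal panel and falls back when unimodal", {
  set.seed(71)
  v <- c(rnorm(100, -2, 0.5), rnorm(100, 2, 0.5))
  names(v) <- sprintf("c%03d", 1:200)
  b <- binarize_ic50(v)
  expect_identical(b$method, "mixture")
  expect_gt(b$threshold, -1)
  expect_lt(b$threshold, 1)
  truth <- rep(c("sensitive", "resistant"), each = 100)
  expect_gte(mean(b$labels == truth), 0.95)
  # label semantics: sensitive iff strictly below the threshold
  expect_identical(unname(b$labels == "sensitive"), unname(v < b$threshold))

  set.seed(72)
  expect_message(bu <- binarize_ic50(rnorm(120)), "fallback")
  expect_identical(bu$method, "median")
  expect_equal(sum(bu$labels == "sensitive"), 60)

  expect_error(binarize_ic50(rep(3, 50)), "degenerate IC50")
  expect_error(binarize_ic50(rnorm(5)), ">= 10")
})

test_that("median-fallback labels never flip when sensitive lines get more sensitive", {
  set.seed(73)
  v <- rnorm(40)
  b <- suppressMessages(binarize_ic50(v))
  sens <- b$labels == "sensitive"
  v2 <- v
  v2[sens] <- v2[sens] - 2   # push sensitive lines further down
  b2 <- suppressMessages(binarize_ic50(v2))
  expect_identical(b2$labels[sens], b$labels[sens])
  expect_identical(b2$labels[!sens], b$labels[!sens])
})

test_that("SR effect size follows the resistant-minus-sensitive convention", {
  sr <- c(rep(0.9, 5), rep(0.9, 5))
  lab <- rep(c("resistant", "sensitive"), each = 5)
  e0 <- suppressWarnings(sr_drug_effect(sr, lab))
  expect_equal(e0$d, 0)
  expect_equal(e0$p, 1)

  set.seed(74)
  sens <- rnorm(50, 0.91, 0.01)
  res <- rnorm(50, 0.89, 0.01)
  e <- sr_drug_effect(c(res, sens),
                      rep(c("resistant", "sensitive"), each = 50))
  expect_lt(e$d, 0)     # SR lower in resistant lines here
  expect_lt(e$p, 0.01)
  # swapping the labels flips the sign
  e_sw <- sr_drug_effect(c(res, sens),
                         rep(c("sensitive", "resistant"), each = 50))
  expect_equal(e_sw$d, -e$d)
  expect_error(sr_drug_effect(sr, c("resistant", rep("sensitive", 9))),
               ">= 2 cell lines")
})

test_that("LSR ratios are shares of SR that sum to one per cell line", {
  net <- net_k3()
  m <- cbind(c1 = c(1, 1, 1), c2 = c(1, 2, 3))
  rownames(m) <- net$genes
  em <- entropy_matrix(m, net)
  targets <- data.frame(drug = c("d1", "d1", "d2"),
                        target = c("A", "C", "ZZZ"),
                        stringsAsFactors = FALSE)
  sc <- suppressMessages(lsr_ratio(em, targets))
  expect_identical(attr(sc, "unmapped"), "ZZZ")
  # uniform expression on K3: every gene carries a third of the entropy
  expect_equal(sc$ratio[sc$cell_line == "c1" & sc$target == "A"], 1 / 3)
  # worked example: node-3 share under x = (1, 2, 3)
  expect_equal(sc$ratio[sc$cell_line == "c2" & sc$target == "C"],
               0.3756665 / 0.8913473, tolerance = 1e-6)
  # shares over all genes sum to 1 for every cell line
  all_t <- data.frame(drug = "dx", target = net$genes)
  sall <- lsr_ratio(em, all_t)
  sums <- tapply(sall$ratio, sall$cell_line, sum)
  expect_equal(unname(c(sums)), c(1, 1), tolerance = 1e-10)
  expect_true(all(sc$ratio >= 0 & sc$ratio <= 1))
})

test_that("ratio-IC50 correlation recovers planted couplings", {
  set.seed(75)
  ratio <- runif(100, 0.1, 0.6)
  cells <- sprintf("c%03d", 1:100)
  sc <- structure(data.frame(cell_line = cells, drug = "d1",
                             target = "g1", ratio = ratio,
                             stringsAsFactors = FALSE),
                  class = c("drug_target_scores", "data.frame"))
  # exact linear decrease: r = -1
  ic50 <- matrix(5 - 2 * ratio, ncol = 1, dimnames = list(cells, "d1"))
  res <- ratio_ic50_correlation(sc, ic50)
  expect_equal(res$r, -1)

  # planted noisy coupling
  ic50n <- matrix(2 - 5 * ratio + rnorm(100, 0, 0.5), ncol = 1,
                  dimnames = list(cells, "d1"))
  resn <- ratio_ic50_correlation(sc, ic50n)
  expect_lt(resn$r, -0.5)
  expect_lt(resn$p, 1e-6)
  expect_equal(unname(attr(resn, "summary")["sig_negative"]), 1L)

  # constant ratio: skipped with a warning
  sc0 <- sc; sc0$ratio <- 0.3
  expect_warning(expect_error(ratio_ic50_correlation(sc0, ic50n),
                              "enough data"), "zero variance")
})

test_that("mutation strata each preserve the planted negative coupling", {
  set.seed(76)
  n <- 120
  cells <- sprintf("c%03d", 1:n)
  ratio <- runif(n, 0.1, 0.6)
  mut <- matrix(rbinom(n, 1, 0.4), ncol = 1,
                dimnames = list(cells, "g1"))
  net <- NULL  # scores constructed directly; mutation join is the point
  sc <- structure(data.frame(cell_line = cells, drug = "d1",
                             target = "g1", ratio = ratio,
                             mutated = mut[, 1],
                             stringsAsFactors = FALSE),
                  class = c("drug_target_scores", "data.frame"))
  ic50 <- matrix(2 - 5 * ratio + rnorm(n, 0, 0.4), ncol = 1,
                 dimnames = list(cells, "d1"))
  res <- ratio_ic50_correlation(sc, ic50, stratify_by_mutation = TRUE)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$r < -0.5))
  expect_true(all(res$p < 1e-4))
})

test_that("the per-drug driver skips unusable drugs but reports the rest", {
  set.seed(77)
  cells <- sprintf("c%03d", 1:60)
  sr <- stats::setNames(runif(60, 0.85, 0.95), cells)
  ic50 <- cbind(dA = c(rnorm(30, -2, 0.4), rnorm(30, 2, 0.4)),
                dB = rep(1, 60))   # dB is degenerate
  rownames(ic50) <- cells
  expect_warning(res <- sr_drug_effects(sr, ic50), "dB skipped")
  expect_identical(res$drug, "dA")
  expect_true(is.finite(res$d))
  expect_equal(res$q, bh_fdr(res$p))
})
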