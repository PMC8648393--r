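#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators with defaults that
#' emulate the scale and signal structure the analyses assume: a
#' scale-free interaction graph, log-normal expression with planted
#' multiplicative tumor effects, exponential survival driven linearly by
#' chosen entropy features, and a drug panel whose ln-IC50 is linearly
#' coupled to the target's LSR ratio.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_genes Number of network genes.
#' @param pa_m Attachment parameter: edges added per new node.
#' @param n_tumor,n_normal Per-group sample counts.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes.
#' @param effect Multiplicative expression effect in tumor (up genes x
#'   effect, down genes / effect).
#' @param sigma Log-normal expression noise SD (log scale).
#' @param beta Survival coefficients over the chosen features.
#' @param h0 Baseline hazard rate.
#' @param censoring Target censoring fraction in `[0, 1)`.
#' @param ic50_intercept,ic50_slope,ic50_noise ln-IC50 generator:
#'   intercept - slope x ratio + Normal(0, noise).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, pa_m = 2L,
                       n_tumor = 50L, n_normal = 50L,
                       n_up = 20L, n_down = 0L, effect = 4,
                       sigma = 0.5,
                       beta = 0.8, h0 = 0.01, censoring = 0.2,
                       ic50_intercept = 2, ic50_slope = 5,
                       ic50_noise = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              pa_m = as.integer(pa_m), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), n_up = as.integer(n_up),
              n_down = as.integer(n_down), effect = effect,
              sigma = sigma, beta = beta, h0 = h0,
              censoring = censoring, ic50_intercept = ic50_intercept,
              ic50_slope = ic50_slope, ic50_noise = ic50_noise)
  stopifnot(cfg$n_genes >= 10L, cfg$pa_m >= 1L, cfg$n_tumor > 0L,
            cfg$n_normal > 0L, cfg$effect > 0, cfg$sigma >= 0,
            cfg$censoring >= 0, cfg$censoring < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a scale-free interaction network
#'
#' Preferential attachment: the graph starts from a single edge between
#' the first two genes; each subsequent gene attaches to `m` distinct
#' existing genes sampled with probability proportional to their current
#' degree. The result is connected by construction with
#' 1 + m (n - 2) edges when m existing genes are always available (fewer
#' in the first steps when m exceeds the number of existing genes), and
#' degree-heterogeneous like curated PPI networks.
#'
#' @param config A `sim_config` (uses `n_genes`, `pa_m`, `seed`).
#' @return An `edge_list` over genes `g0001 ...`.
#' @export
simulate_ppi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes; m <- config$pa_m
  set.seed(config$seed)
  deg <- integer(n)
  from <- integer(0); to <- integer(0)
  deg[1:2] <- 1L
  from <- 1L; to <- 2L
  for (v in 3:n) {
    k <- min(m, v - 1L)
    nb <- sample.int(v - 1L, k, prob = deg[seq_len(v - 1L)])
    from <- c(from, nb); to <- c(to, rep(v, k))
    deg[nb] <- deg[nb] + 1L
    deg[v] <- k
  }
  width <- max(4L, nchar(as.character(n)))
  gene <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  el <- data.frame(from = gene[from], to = gene[to],
                   stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  el
}

#' Simulate two-group expression with planted differential genes
#'
#' Baseline expression is log-normal per gene (gene-specific log-means
#' drawn once, Normal(log 10, 1)); every sample adds Normal(0, sigma)
#' noise on the log scale. Tumor samples multiply the planted up genes by
#' `effect` and divide the planted down genes by it. Planted genes are
#' drawn at random among the network genes; a truth table records the
#' planted class of every gene.
#'
#' @param net A `signaling_network` (genes define the rows).
#' @param config A `sim_config`.
#' @return List with `expr` (an `expr_matrix`, genes x samples), `groups`
#'   (character vector `"tumor"` / `"normal"` per sample) and `truth`
#'   (`data.frame` gene/class).
#' @export
simulate_expression <- function(net, config) {
  stopifnot(inherits(net, "signaling_network"),
            inherits(config, "sim_config"))
  genes <- net$genes
  n_g <- length(genes)
  if (config$n_up + config$n_down > n_g) {
    stop("more planted genes than network genes")
  }
  set.seed(config$seed + 1L)
  planted <- sample(genes, config$n_up + config$n_down)
  up <- planted[seq_len(config$n_up)]
  down <- setdiff(planted, up)
  mu <- stats::rnorm(n_g, mean = log(10), sd = 1)
  n_s <- config$n_tumor + config$n_normal
  m <- exp(mu + matrix(stats::rnorm(n_g * n_s, sd = config$sigma),
                       n_g, n_s))
  dimnames(m) <- list(genes,
                      c(sprintf("tumor_%03d", seq_len(config$n_tumor)),
                        sprintf("normal_%03d", seq_len(config$n_normal))))
  tum <- seq_len(config$n_tumor)
  m[up, tum] <- m[up, tum] * config$effect
  m[down, tum] <- m[down, tum] / config$effect
  truth <- data.frame(gene = genes,
                      class = ifelse(genes %in% up, "up",
                                     ifelse(genes %in% down, "down",
                                            "none")),
                      stringsAsFactors = FALSE)
  list(expr = as_expr_matrix(m, "linear-nonnegative"),
       groups = rep(c("tumor", "normal"),
                    c(config$n_tumor, config$n_normal)),
       truth = truth)
}

#' Simulate survival outcomes from entropy features
#'
#' Event times are exponential with rate h0 * exp(beta' z), where z are
#' the internally standardized feature columns. Censoring is independent
#' uniform on (0, U), with U chosen numerically so the realized censoring
#' fraction approximates the configured rate.
#'
#' @param features Samples x features numeric matrix (e.g. LSR features).
#' @param config A `sim_config`; `beta` is recycled/truncated to the
#'   number of feature columns.
#' @return List with `clinical` (a `clinical_table`) and `beta` (the true
#'   coefficients on the standardized scale).
#' @export
simulate_survival <- function(features, config) {
  stopifnot(inherits(config, "sim_config"))
  features <- as.matrix(features)
  n <- nrow(features)
  beta <- rep_len(config$beta, ncol(features))
  z <- scale(features)
  z[is.nan(z)] <- 0   # constant feature: no effect
  lp <- as.numeric(z %*% beta)
  set.seed(config$seed + 2L)
  times <- stats::rexp(n, rate = config$h0 * exp(lp))
  u <- stats::runif(n)
  if (config$censoring == 0) {
    event <- rep(1L, n)
  } else {
    cens_frac <- function(U) mean(U * u < times) - config$censoring
    U <- stats::uniroot(cens_frac, lower = min(times) * 1e-6,
                        upper = max(times) * 1e6)$root
    ct <- U * u
    event <- as.integer(times <= ct)
    times <- pmin(times, ct)
  }
  samples <- rownames(features)
  if (is.null(samples)) samples <- sprintf("s%04d", seq_len(n))
  clin <- validate_clinical(data.frame(sample = samples,
                                       time = times, event = event,
                                       stringsAsFactors = FALSE))
  list(clinical = clin, beta = stats::setNames(beta, colnames(features)))
}

#' Simulate a drug-response panel coupled to the LSR ratio
#'
#' ln-IC50 = intercept - slope x ratio + Normal(0, noise) per cell line,
#' optionally shifted by a two-component mixture over cell lines to
#' induce the bimodality that the threshold binarization expects.
#'
#' @param ratio Named numeric vector: the target's LSR ratio per cell
#'   line (>= 10 cell lines).
#' @param config A `sim_config`.
#' @param bimodal_shift Optional size of an additive shift applied to a
#'   random half of the cell lines (0 = none).
#' @return List with `ic50` (named vector), `truth` (the noiseless
#'   linear part) and, when shifted, `component` (1/2 per cell line).
#' @export
simulate_drug_panel <- function(ratio, config, bimodal_shift = 0) {
  stopifnot(inherits(config, "sim_config"), length(ratio) >= 10L)
  set.seed(config$seed + 3L)
  lin <- config$ic50_intercept - config$ic50_slope * ratio
  ic50 <- lin + stats::rnorm(length(ratio), sd = config$ic50_noise)
  comp <- NULL
  if (bimodal_shift != 0) {
    comp <- sample(rep(1:2, length.out = length(ratio)))
    ic50 <- ic50 + (comp - 1L) * bimodal_shift
  }
  names(ic50) <- names(ratio)
  out <- list(ic50 = ic50, truth = lin)
  if (!is.null(comp)) out$component <- stats::setNames(comp, names(ratio))
  out
}
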