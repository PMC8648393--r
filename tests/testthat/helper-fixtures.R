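# Small graph fixtures and independent oracles shared across tests.

make_edge_list <- function(from, to) {
  el <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  class(el) <- c("edge_list", "data.frame")
  el
}

uniform_expr <- function(genes, samples = "s1") {
  matrix(1, length(genes), length(samples),
         dimnames = list(genes, samples))
}

net_k3 <- function() {
  suppressMessages(build_network(
    make_edge_list(c("A", "A", "B"), c("B", "C", "C")),
    uniform_expr(c("A", "B", "C"))))
}

net_path3 <- function() {
  suppressMessages(build_network(
    make_edge_list(c("A", "B"), c("B", "C")),
    uniform_expr(c("A", "B", "C"))))
}

net_star3 <- function() {
  suppressMessages(build_network(
    make_edge_list(c("H", "H", "H"), c("L1", "L2", "L3")),
    uniform_expr(c("H", "L1", "L2", "L3"))))
}

# "kite": triangle A-B-C with pendant D on C
net_kite <- function() {
  suppressMessages(build_network(
    make_edge_list(c("A", "A", "B", "C"), c("B", "C", "C", "D")),
    uniform_expr(c("A", "B", "C", "D"))))
}

# random connected graph: spanning tree + extra random edges
random_connected_net <- function(n, extra = n) {
  stopifnot(n >= 3L)
  genes <- sprintf("n%03d", seq_len(n))
  from <- genes[vapply(2:n, function(v) sample.int(v - 1L, 1L), 1L)]
  to <- genes[2:n]
  for (k in seq_len(extra)) {
    pair <- sample.int(n, 2L)
    from <- c(from, genes[pair[1L]])
    to <- c(to, genes[pair[2L]])
  }
  keep <- from != to
  suppressMessages(build_network(make_edge_list(from[keep], to[keep]),
                                 uniform_expr(genes)))
}

# Empirical per-step entropy of a simulated stationary walk: an oracle for
# the analytic entropy rate that never touches the entropy code path.
walk_entropy_oracle <- function(P, lambda, steps = 1e6L, seed = 1L) {
  set.seed(seed)
  P <- as.matrix(P)
  n <- nrow(P)
  cum <- t(apply(P, 1L, cumsum))
  state <- sample.int(n, 1L, prob = lambda)
  u <- stats::runif(steps)
  acc <- 0
  for (t in seq_len(steps)) {
    nxt <- findInterval(u[t], cum[state, ]) + 1L
    acc <- acc - log(P[state, nxt])
    state <- nxt
  }
  acc / steps
}

# Brute-force Harrell's C over all pairs (ties in predictor count 1/2).
concordance_oracle <- function(lp, time, event) {
  conc <- comp <- 0
  n <- length(lp)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else 0L
    if (first == 0L || event[first] == 0L) next
    comp <- comp + 1
    other <- if (first == i) j else i
    if (lp[first] > lp[other]) conc <- conc + 1
    else if (lp[first] == lp[other]) conc <- conc + 0.5
  }
  conc / comp
}

# Simulated two-group synthetic pipeline used by several tests.
sim_pipeline <- function(cfg) {
  edges <- simulate_ppi(cfg)
  probe <- uniform_expr(unique(c(edges$from, edges$to)))
  net <- suppressMessages(build_network(edges, probe))
  sim <- simulate_expression(net, cfg)
  em <- suppressMessages(entropy_matrix(sim$expr, net))
  list(net = net, sim = sim, em = em)
}
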