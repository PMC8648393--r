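#' Expression-weighted transition model on the signaling network
#'
#' Builds the per-sample random-walk model from one expression vector x.
#' Edge weights follow mass action, w_ij proportional to x_i * x_j; row
#' normalization gives the stochastic matrix with entries
#' p_ij = x_j / (Ax)_i over the neighbours N(i). The invariant measure has
#' the closed form lambda_i = x_i (Ax)_i / (x' A x), which satisfies
#' lambda P = lambda exactly because the walk obeys detailed balance
#' (lambda_i p_ij = lambda_j p_ji = A_ij x_i x_j / (x' A x)).
#'
#' @param x Strictly positive expression vector. Either unnamed and aligned
#'   to `net$genes`, or named, in which case it is reordered by name.
#' @param net A `signaling_network`.
#' @return An object of class `transition_model`: list with sparse
#'   row-stochastic `P`, invariant measure `lambda`, and the aligned `x`.
#' @examples
#' el <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"))
#' class(el) <- c("edge_list", "data.frame")
#' expr <- matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
#' net <- build_network(el, expr)
#' tm <- transition_model(c(1, 2, 3), net)
#' tm$lambda  # 5/22, 8/22, 9/22
#' @export
transition_model <- function(x, net) {
  stopifnot(inherits(net, "signaling_network"))
  x <- align_to_nodes(x, net)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("expression vector must be strictly positive; ",
         "apply add_pseudocount() first")
  }
  A <- net$adjacency
  ax <- as.numeric(A %*% x)
  if (any(ax == 0)) stop("(Ax)_i = 0 at node ", which(ax == 0)[1L],
                         "; transition row undefined")
  # P = D(1/Ax) A D(x): sparse, nonzero exactly on the edges of A
  P <- Matrix::Diagonal(x = 1 / ax) %*% A %*% Matrix::Diagonal(x = x)
  dimnames(P) <- list(net$genes, net$genes)
  lambda <- x * ax / sum(x * ax)
  names(lambda) <- net$genes
  structure(list(P = P, lambda = lambda, x = x),
            class = "transition_model")
}

align_to_nodes <- function(x, net) {
  n <- length(net$genes)
  if (!is.null(names(x))) {
    miss <- setdiff(net$genes, names(x))
    if (length(miss)) stop("expression missing for network gene(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    x <- x[net$genes]
  } else if (length(x) != n) {
    stop("unnamed expression vector of length ", length(x),
         " cannot be aligned to ", n, " network genes")
  }
  as.numeric(x)
}

#' Maximum attainable entropy rate of the network
#'
#' The entropy rate of any walk on the graph is bounded by the maximal-
#' entropy random walk, whose rate is the natural log of the dominant
#' adjacency eigenvalue. The eigenvalue is found by power iteration on
#' A + I (the shift keeps the iteration convergent on bipartite graphs,
#' where +/- eigenvalue pairs would otherwise cycle), started from the
#' all-ones vector.
#'
#' @param net A `signaling_network`.
#' @param tol Relative convergence tolerance on the eigenvalue (default
#'   1e-10).
#' @param max_iter Iteration cap.
#' @return The maximum entropy rate in nats, with the dominant eigenvalue
#'   and its eigenvector in attributes `eigenvalue` and `eigenvector`.
#' @export
max_entropy_rate <- function(net, tol = 1e-10, max_iter = 100000L) {
  A <- net$adjacency
  n <- nrow(A)
  v <- rep(1, n)
  v <- v / sqrt(sum(v^2))
  ev_old <- 0
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v       # (A + I) v
    nrm <- sqrt(sum(w^2))
    v <- w / nrm
    ev <- sum(v * (as.numeric(A %*% v) + v))
    if (abs(ev - ev_old) <= tol * abs(ev)) {
      lam <- ev - 1
      out <- log(lam)
      attr(out, "eigenvalue") <- lam
      attr(out, "eigenvector") <- v / sum(v)
      return(out)
    }
    ev_old <- ev
  }
  stop("power iteration did not converge in ", max_iter,
       " iterations; increase max_iter or loosen tol")
}

#' Signaling-entropy profile of one sample
#'
#' Computes the unnormalized entropy rate
#' Sr = -sum_i lambda_i sum_j p_ij log p_ij (nats), the normalized global
#' signaling entropy SR = Sr / maxSr in `[0, 1]`, and the per-gene local
#' signaling entropy LSR_i = -lambda_i sum_j p_ij log p_ij. LSR is
#' reported after division by maxSr so that the LSRs sum exactly to SR;
#' the unnormalized values are kept in `lsr_raw`.
#'
#' @param x Strictly positive expression vector (see
#'   [transition_model()]).
#' @param net A `signaling_network`.
#' @param max_sr Optionally a precomputed [max_entropy_rate()] value, to
#'   avoid re-solving the eigenproblem per sample.
#' @return An object of class `entropy_profile`: list with `sr` (nats),
#'   `max_sr` (nats), `SR` (dimensionless), `lsr` (named, sums to SR) and
#'   `lsr_raw` (named, sums to `sr`).
#' @export
entropy_profile <- function(x, net, max_sr = NULL) {
  tm <- transition_model(x, net)
  if (is.null(max_sr)) max_sr <- max_entropy_rate(net)
  # -p log p summed per row; P's stored entries are all positive, so the
  # 0 log 0 := 0 convention is honoured by the sparsity pattern itself
  Plogp <- tm$P
  Plogp@x <- Plogp@x * log(Plogp@x)
  h <- -as.numeric(Matrix::rowSums(Plogp))
  lsr_raw <- tm$lambda * h
  sr <- sum(lsr_raw)
  structure(list(sr = sr,
                 max_sr = as.numeric(max_sr),
                 SR = sr / as.numeric(max_sr),
                 lsr = lsr_raw / as.numeric(max_sr),
                 lsr_raw = lsr_raw),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat("entropy_profile: Sr = ", format(x$sr, digits = 6), " nats, maxSr = ",
      format(x$max_sr, digits = 6), " nats, SR = ",
      format(x$SR, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Entropy profiles for every sample of an expression matrix
#'
#' Vectorized driver: solves the eigenproblem once, then computes one
#' [entropy_profile()] per column. Zeros are pseudocounted per matrix
#' before the walk is built.
#'
#' @param m Non-negative gene x sample matrix; rownames must cover
#'   `net$genes`.
#' @param net A `signaling_network`.
#' @param pseudocount Passed to [add_pseudocount()].
#' @param progress_every Emit a progress message every this many samples
#'   (0 = silent).
#' @return An object of class `entropy_matrix`: list with `summary` (a
#'   `data.frame` with columns sample, sr, max_sr, SR), `lsr` (genes x
#'   samples, normalized so columns sum to the sample's SR), and
#'   `lsr_raw`.
#' @export
entropy_matrix <- function(m, net, pseudocount = "auto",
                           progress_every = 0L) {
  miss <- setdiff(net$genes, rownames(m))
  if (length(miss)) stop("expression matrix missing network gene(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  m <- add_pseudocount(unclass(m)[net$genes, , drop = FALSE], pseudocount)
  max_sr <- max_entropy_rate(net)
  n_s <- ncol(m)
  failures <- character(0)
  lsr <- matrix(NA_real_, length(net$genes), n_s,
                dimnames = list(net$genes, colnames(m)))
  lsr_raw <- lsr
  sr <- numeric(n_s)
  for (j in seq_len(n_s)) {
    prof <- tryCatch(entropy_profile(m[, j], net, max_sr = max_sr),
                     error = function(e) e)
    if (inherits(prof, "error")) {
      failures <- c(failures, paste0(colnames(m)[j], ": ",
                                     conditionMessage(prof)))
      next
    }
    sr[j] <- prof$sr
    lsr[, j] <- prof$lsr
    lsr_raw[, j] <- prof$lsr_raw
    if (progress_every > 0L && j %% progress_every == 0L) {
      message("entropy_matrix: ", j, "/", n_s, " samples done")
    }
  }
  if (length(failures)) {
    stop("entropy computation failed for ", length(failures),
         " sample(s):\n", paste(failures, collapse = "\n"))
  }
  structure(list(summary = data.frame(sample = colnames(m), sr = sr,
                                      max_sr = as.numeric(max_sr),
                                      SR = sr / as.numeric(max_sr),
                                      stringsAsFactors = FALSE),
                 lsr = lsr, lsr_raw = lsr_raw),
            class = "entropy_matrix")
}

#' @export
print.entropy_matrix <- function(x, ...) {
  cat("entropy_matrix: ", nrow(x$lsr), " genes x ", ncol(x$lsr),
      " samples; SR in [", format(min(x$summary$SR), digits = 4), ", ",
      format(max(x$summary$SR), digits = 4), "]\n", sep = "")
  invisible(x)
}
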