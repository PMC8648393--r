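#' Read a protein-protein interaction edge list
#'
#' Reads a two-column (SIF-like) file of undirected interactions. A third
#' column, if present, is treated as an interaction-type annotation and
#' ignored. Self-loops are dropped and duplicate unordered pairs (in either
#' order) are collapsed; counts of dropped records are reported via message.
#'
#' @param path Path to the edge-list file. Lines starting with `#` are
#'   skipped.
#' @param delimiter Field separator (default tab; any run of the delimiter
#'   is treated as one separator when it is whitespace).
#' @return An object of class `edge_list`: a `data.frame` with character
#'   columns `from` and `to`, one row per unique undirected interaction.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC", "B\tC"), tf)
#' e <- read_edge_list(tf)
#' nrow(e)  # 2: the A-B duplicate collapses, the C-C self-loop is dropped
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no edges parsed from '", path, "'")
  split_re <- if (grepl("^\\s+$", delimiter)) "\\s+" else delimiter
  parts <- strsplit(lines, split_re, fixed = FALSE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge line ", bad[1L], ": '", lines[bad[1L]],
         "' (need >= 2 fields)")
  }
  from <- trimws(vapply(parts, `[[`, "", 1L))
  to   <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("empty gene identifier at line ",
         which(!nzchar(from) | !nzchar(to))[1L])
  }
  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]; to <- to[!loops]
  key <- ifelse(from < to, paste0(from, "\r", to), paste0(to, "\r", from))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  el <- data.frame(from = from[!dup], to = to[!dup],
                   stringsAsFactors = FALSE)
  if (n_loops || n_dup) {
    message("read_edge_list: dropped ", n_loops, " self-loop(s) and ",
            n_dup, " duplicate pair(s); ", nrow(el), " edges kept")
  }
  class(el) <- c("edge_list", "data.frame")
  el
}

#' Write an edge list as two-column TSV
#'
#' @param edges An `edge_list` (or two-column data frame).
#' @param path Output path. A `#`-prefixed provenance header is written
#'   first.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header("edge_list"), con)
  utils::write.table(edges[, c("from", "to")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

provenance_header <- function(what, params = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("sigentropy")),
                  error = function(e) "dev")
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=",
                      collapse = " "))
  } else ""
  paste0("# sigentropy ", ver, " ", what, extra)
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a TSV with a header row of sample identifiers and gene
#' identifiers in the first column. Duplicate gene rows are resolved by
#' keeping the row with the highest mean. The declared scale is attached to
#' the result and checked: `"linear-nonnegative"` matrices must not contain
#' negative values.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the values: `"linear-nonnegative"` (e.g.
#'   RSEM abundance estimates) or `"log-ratio"` (e.g. TMT proteome ratios,
#'   which may contain missing values).
#' @return A numeric matrix (genes x samples) of class `expr_matrix` with
#'   attribute `scale`.
#' @export
read_expression <- function(path,
                            scale = c("linear-nonnegative", "log-ratio")) {
  scale <- match.arg(scale)
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no genes parsed from '", path, "'")
  genes <- trimws(as.character(df[[1L]]))
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, TRUE)
  if (any(non_num)) {
    stop("non-numeric expression value(s) in column(s): ",
         paste(names(vals)[non_num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    means <- rowMeans(m, na.rm = TRUE)
    ord <- order(genes, -means)
    m <- m[ord, , drop = FALSE]
    keep <- !duplicated(rownames(m))
    message("read_expression: collapsed ", sum(!keep),
            " duplicate gene row(s), keeping the highest-mean row")
    m <- m[keep, , drop = FALSE]
  }
  if (scale == "linear-nonnegative") {
    if (anyNA(m)) stop("missing values not allowed on linear-nonnegative scale")
    if (any(m < 0)) stop("negative value found but scale declared linear-nonnegative")
  }
  as_expr_matrix(m, scale)
}

as_expr_matrix <- function(m, scale) {
  attr(m, "scale") <- scale
  class(m) <- c("expr_matrix", class(m))
  m
}

#' Write an expression-like matrix as TSV with provenance header
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param what Label recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, what = "matrix") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(what), con)
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}

#' Preprocess a log-ratio proteome matrix to positive masses
#'
#' TMT-style proteome log-ratios are made comparable across samples by
#' per-column centering and scaling (population standard deviation, so a
#' two-value column (-1, 1) maps to (-1, 1)); remaining missing entries in
#' each protein row are filled with that row's median; rows that are
#' entirely missing are dropped with a warning. Finally values are mapped
#' to a strictly positive linear scale by base-2 exponentiation so they can
#' serve as mass-action weights.
#'
#' @param m An `expr_matrix` declared `"log-ratio"` (missing values
#'   allowed).
#' @return An `expr_matrix` on the `"linear-nonnegative"` scale, strictly
#'   positive, with no missing values.
#' @export
preprocess_proteome <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!identical(attr(m, "scale"), "log-ratio")) {
    stop("preprocess_proteome expects a matrix declared 'log-ratio'")
  }
  x <- unclass(m)
  attr(x, "scale") <- NULL
  all_na <- rowSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing protein row(s): ",
            paste(utils::head(rownames(x)[all_na], 5L), collapse = ", "))
    x <- x[!all_na, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no proteins left after dropping all-missing rows")
  # column z-score with population (1/n) SD; constant columns are centered only
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    mu <- mean(v[ok])
    sd_pop <- sqrt(mean((v[ok] - mu)^2))
    x[, j] <- if (sd_pop > 0) (v - mu) / sd_pop else v - mu
  }
  for (i in seq_len(nrow(x))) {
    miss <- is.na(x[i, ])
    if (any(miss)) x[i, miss] <- stats::median(x[i, ], na.rm = TRUE)
  }
  as_expr_matrix(2 ^ x, "linear-nonnegative")
}

#' Replace zeros with a small pseudocount
#'
#' The transition model needs strictly positive expression: a node whose
#' neighbours all have zero expression has an undefined transition row.
#' Zeros are replaced by half the smallest positive value in the matrix (or
#' an explicit pseudocount).
#'
#' @param m Numeric matrix, non-negative.
#' @param pseudocount `"auto"` (default: 0.5 x smallest positive entry) or
#'   a positive number.
#' @return The matrix with all entries strictly positive.
#' @export
add_pseudocount <- function(m, pseudocount = "auto") {
  if (!any(m == 0)) return(m)
  eps <- if (identical(pseudocount, "auto")) {
    pos <- m[m > 0]
    if (!length(pos)) stop("matrix is all zero; cannot derive a pseudocount")
    min(pos) * 0.5
  } else {
    stopifnot(is.numeric(pseudocount), pseudocount > 0)
    pseudocount
  }
  m[m == 0] <- eps
  m
}

#' Build the signaling network from an edge list and expression data
#'
#' Restricts the interaction graph to genes present in both the edge list
#' and the expression matrix, keeps the largest connected component, and
#' fixes the node order used by all entropy computations.
#'
#' @param edges An `edge_list`.
#' @param expr An `expr_matrix` (or any matrix with gene rownames).
#' @return An object of class `signaling_network`: a list with `genes`
#'   (node order), `adjacency` (sparse symmetric 0/1 `Matrix`), `graph`
#'   (the igraph object), and `degree`.
#' @export
build_network <- function(edges, expr) {
  genes_expr <- rownames(expr)
  keep <- edges$from %in% genes_expr & edges$to %in% genes_expr
  if (!any(keep)) stop("no overlap between edge-list genes and expression genes")
  g <- igraph::graph_from_data_frame(edges[keep, c("from", "to")],
                                     directed = FALSE)
  g <- igraph::simplify(g)   # enforce simple 0/1 adjacency
  comp <- igraph::components(g)
  lcc <- which.max(comp$csize)
  g <- igraph::induced_subgraph(g, which(comp$membership == lcc))
  if (igraph::vcount(g) < 3L) {
    stop("largest connected component has ", igraph::vcount(g),
         " node(s); need at least 3 for a useful entropy")
  }
  nodes <- sort(igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  message("build_network: ", length(nodes), " nodes / ",
          igraph::ecount(g), " edges in the largest connected component (",
          comp$no, " component(s) before restriction)")
  structure(list(genes = nodes, adjacency = A, graph = g,
                 degree = Matrix::rowSums(A)),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("signaling_network: ", length(x$genes), " genes, ",
      sum(x$degree) / 2, " interactions\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics: tab-separated lines of set name, description,
#' then member genes.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class `gene_set_collection`;
#'   descriptions are kept in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) stop("GMT line ", which(short)[1L],
                       " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L)) {
    stop("gene set(s) with no members: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  }
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  class(sets) <- "gene_set_collection"
  sets
}

#' Read a clinical table with survival outcome
#'
#' Expects a TSV with columns `sample`, `time` (days, positive), `event`
#' (1 = event, 0 = censored); any further columns are kept as categorical
#' covariates.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  bad_t <- !is.finite(df$time) | df$time <= 0
  if (any(bad_t)) stop("non-positive survival time for sample(s): ",
                       paste(df$sample[bad_t], collapse = ", "))
  if (!all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}
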