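#' Partial-correlation matrix from ROI time series
#'
#' Estimates the unique pairwise associations between network nodes from the
#' inverse of the sample covariance matrix: with `Omega = solve(cov(X))`,
#' the partial correlation is `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`
#' — the correlation between nodes i and j after filtering out the linear
#' contributions of all other nodes. The diagonal is fixed at 0
#' (self-connections never enter the analysis).
#'
#' The estimate requires more scans than nodes and a well-conditioned
#' covariance. A ridge term (`ridge` added to the covariance diagonal) is
#' available as an opt-in for near-singular inputs and is recorded in the
#' result; it is off by default because the reference analysis used none.
#'
#' @param series ROI x scan numeric matrix (rows are nodes), or a
#'   `subject_condition_series`.
#' @param ridge Non-negative ridge added to the covariance diagonal
#'   (default 0).
#' @param max_condition Largest admissible covariance condition number
#'   before an error asks for the ridge option (default 1e12).
#' @return A `pcor_matrix`: list with `values` (symmetric N x N, zero
#'   diagonal), `n_samples`, `nodes` (labels), `ridge`.
#' @examples
#' x <- matrix(rnorm(300), 3, 100)
#' partial_correlation(x)$values
#' @export
partial_correlation <- function(series, ridge = 0, max_condition = 1e12) {
  x <- as.matrix(series)
  n_nodes <- nrow(x)
  n_samples <- ncol(x)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  if (n_samples <= n_nodes) {
    stop(sprintf("need more scans (%d) than nodes (%d)", n_samples, n_nodes),
         call. = FALSE)
  }
  stopifnot(ridge >= 0)
  C <- stats::cov(t(x))
  if (ridge > 0) C <- C + diag(ridge, n_nodes)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop(paste0("sample covariance is singular or ill-conditioned ",
                "(condition number above cap); consider the `ridge` option"),
         call. = FALSE)
  }
  Omega <- solve(C)
  d <- sqrt(diag(Omega))
  rho <- -Omega / outer(d, d)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 0
  nodes <- rownames(x) %||% sprintf("node%02d", seq_len(n_nodes))
  dimnames(rho) <- list(nodes, nodes)
  structure(list(values = rho, n_samples = n_samples, nodes = nodes,
                 ridge = ridge),
            class = "pcor_matrix")
}

#' Two-sided significance of partial correlations
#'
#' Tests each off-diagonal partial correlation against zero with the t
#' transform `t = rho * sqrt(df / (1 - rho^2))`, where
#' `df = n_samples - N` — the usual degrees of freedom for a correlation
#' (`n - 2`) reduced by the `N - 2` nodes partialled out. P-values are
#' two-sided and symmetric; `rho = 0` gives p = 1, and the diagonal is set
#' to 1 so it can never form an edge.
#'
#' @param pcm A `pcor_matrix`.
#' @return Symmetric N x N matrix of p-values.
#' @export
edge_significance <- function(pcm) {
  stopifnot(inherits(pcm, "pcor_matrix"))
  n_nodes <- nrow(pcm$values)
  df <- pcm$n_samples - n_nodes
  if (df <= 0) stop("non-positive degrees of freedom (n_samples - N)",
                    call. = FALSE)
  rho <- pcm$values
  rho2 <- pmin(rho^2, 1 - 1e-15)
  tval <- abs(rho) * sqrt(df / (1 - rho2))
  p <- 2 * stats::pt(tval, df, lower.tail = FALSE)
  diag(p) <- 1
  dimnames(p) <- dimnames(rho)
  p
}

#' Supported significance thresholds
#'
#' The five alpha levels at which networks are constructed, spanning sparse
#' to dense graphs so conclusions can be checked for robustness to network
#' density.
#' @export
GTNA_ALPHAS <- c(0.0001, 0.0005, 0.001, 0.005, 0.01)

#' Threshold a partial-correlation matrix into a network graph
#'
#' Declares an edge between nodes i and j when the two-sided p-value of
#' their partial correlation is below `alpha`, producing the binary
#' adjacency matrix, plus a weighted companion in which each valid edge
#' carries its (signed, by default) partial correlation. Because the p-value
#' is monotone in `|rho|` at fixed sample size, edge sets are nested across
#' increasing alphas.
#'
#' @param pcm A `pcor_matrix`.
#' @param alpha Significance level in (0, 1). The five preset levels in
#'   [GTNA_ALPHAS] are the standard choices; other values are accepted with
#'   a message.
#' @param signed Keep the sign of negative partial correlations in the
#'   weights (default `TRUE`); if `FALSE`, absolute values are stored.
#' @return A `network_graph`: list with `alpha`, `binary` (0/1 N x N,
#'   zero diagonal), `weights`, `nodes`, `signed`.
#' @export
threshold_network <- function(pcm, alpha, signed = TRUE) {
  stopifnot(inherits(pcm, "pcor_matrix"), is.numeric(alpha),
            length(alpha) == 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  if (!any(abs(alpha - GTNA_ALPHAS) < 1e-12)) {
    message(sprintf("note: alpha %g is not one of the standard levels (%s)",
                    alpha, paste(GTNA_ALPHAS, collapse = ", ")))
  }
  p <- edge_significance(pcm)
  binary <- (p < alpha) * 1
  diag(binary) <- 0
  w <- if (signed) pcm$values else abs(pcm$values)
  weights <- w * binary
  structure(list(alpha = alpha, binary = binary, weights = weights,
                 nodes = pcm$nodes, signed = signed),
            class = "network_graph")
}

#' Construct a network graph directly from an adjacency matrix
#'
#' Mainly for tests and for importing externally thresholded networks.
#'
#' @param binary Symmetric 0/1 adjacency matrix, zero diagonal.
#' @param weights Optional weight matrix (defaults to `binary`); zeroed
#'   wherever `binary` is 0.
#' @param alpha Nominal alpha recorded on the graph (default `NA`).
#' @return A `network_graph`.
#' @export
network_graph <- function(binary, weights = NULL, alpha = NA_real_) {
  binary <- as.matrix(binary)
  assert_symmetric(binary, name = "binary")
  if (!all(binary %in% c(0, 1))) stop("binary must be 0/1", call. = FALSE)
  if (any(diag(binary) != 0)) stop("self-connections are not allowed",
                                   call. = FALSE)
  if (is.null(weights)) weights <- binary
  weights <- as.matrix(weights) * binary
  nodes <- rownames(binary) %||% sprintf("node%02d", seq_len(nrow(binary)))
  structure(list(alpha = alpha, binary = binary, weights = weights,
                 nodes = nodes, signed = TRUE),
            class = "network_graph")
}

#' Number of edges of a network graph
#' @param graph A `network_graph`.
#' @return Integer count of unordered edges.
#' @export
edge_count <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  as.integer(sum(graph$binary) / 2)
}

#' Export a graph as an edge-list TSV
#'
#' One row per unordered valid edge: node labels, partial correlation,
#' p-value and the alpha at which the graph was built.
#'
#' @param graph A `network_graph`.
#' @param pcm The `pcor_matrix` it came from (for p-values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, pcm, path) {
  stopifnot(inherits(graph, "network_graph"), inherits(pcm, "pcor_matrix"))
  p <- edge_significance(pcm)
  idx <- which(upper.tri(graph$binary) & graph$binary == 1, arr.ind = TRUE)
  df <- data.frame(
    node_i = graph$nodes[idx[, 1]], node_j = graph$nodes[idx[, 2]],
    partial_r = graph$weights[idx], p = p[idx], alpha = graph$alpha,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a graph as GraphML
#'
#' Minimal GraphML (undirected, with a `weight` edge attribute) for
#' visualization tools.
#'
#' @param graph A `network_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "network_graph"))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  idx <- which(upper.tri(graph$binary) & graph$binary == 1, arr.ind = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    paste0("  <key id=\"w\" for=\"edge\" attr.name=\"weight\" ",
           "attr.type=\"double\"/>"),
    paste0("  <key id=\"label\" for=\"node\" attr.name=\"label\" ",
           "attr.type=\"string\"/>"),
    "  <graph edgedefault=\"undirected\">",
    sprintf("    <node id=\"n%d\"><data key=\"label\">%s</data></node>",
            seq_along(graph$nodes), esc(graph$nodes)),
    if (nrow(idx)) {
      sprintf(paste0("    <edge source=\"n%d\" target=\"n%d\">",
                     "<data key=\"w\">%.10g</data></edge>"),
              idx[, 1], idx[, 2], graph$weights[idx])
    },
    "  </graph>",
    "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
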