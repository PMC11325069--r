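#' Node-by-node Pearson correlation matrix
#'
#' @param timeseries `n_nodes x T` matrix with at least 3 frames and no
#'   constant rows.
#' @return Symmetric `n_nodes x n_nodes` correlation matrix.
#' @export
correlation_matrix <- function(timeseries) {
  timeseries <- assert_matrix(timeseries, "timeseries")
  if (ncol(timeseries) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  centered <- timeseries - rowMeans(timeseries)
  ss <- sqrt(rowSums(centered^2))
  if (any(ss == 0)) {
    stop(sprintf("constant time-series for node(s): %s",
                 paste(which(ss == 0), collapse = ", ")), call. = FALSE)
  }
  cm <- tcrossprod(centered / ss)
  diag(cm) <- 1
  pmin(pmax(cm, -1), 1)
}

#' Mean degree implied by a density exponent
#'
#' Inverts `S = log(N) / log(K)`: given the number of nodes `N` and the
#' exponent `S`, returns the average number of connections per node
#' `K = N^(1/S)`. Fixing `S` across subjects fixes the edge density.
#'
#' @param n_nodes Number of nodes `N` (at least 2).
#' @param s_value Density exponent `S` (positive).
#' @return Target mean degree `K`.
#' @export
degree_for_s <- function(n_nodes, s_value) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  s_value <- assert_number(s_value, "s_value", 0, lower_open = TRUE)
  n_nodes^(1 / s_value)
}

#' Binarize a correlation matrix at a target density
#'
#' Keeps exactly the `floor(N * K / 2)` largest off-diagonal correlations as
#' edges, so any two networks with the same `N` and `K` have identical edge
#' counts. Ranking is on signed correlation (largest `r`, not `|r|`); ties
#' are broken by lexicographic node-pair order. The result depends only on
#' the rank order of the correlations, so it is invariant to strictly
#' monotone transforms.
#'
#' @param corr_matrix Symmetric `N x N` correlation (or similarity) matrix.
#' @param k_target Target mean degree `K`, in `(0, N - 1)`.
#' @param s_value Optional exponent recorded on the network for provenance.
#' @return An object of class `binary_network`: `n_nodes`, `edges` (an
#'   `m x 2` matrix of node pairs with `i < j`), `k_target`, `s_value`, and
#'   the realized `mean_degree`.
#' @export
threshold_to_density <- function(corr_matrix, k_target, s_value = NA_real_) {
  corr_matrix <- assert_matrix(corr_matrix, "corr_matrix")
  n <- nrow(corr_matrix)
  if (n != ncol(corr_matrix) || n < 2L) {
    stop("`corr_matrix` must be square with at least 2 nodes", call. = FALSE)
  }
  if (!is.numeric(k_target) || k_target <= 0 || k_target >= n - 1) {
    stop("`k_target` must lie in (0, N - 1)", call. = FALSE)
  }
  m_edges <- floor(n * k_target / 2)
  if (m_edges < 1L) stop("`k_target` too small: no edges would be kept", call. = FALSE)
  ut <- which(upper.tri(corr_matrix))
  vals <- corr_matrix[ut]
  # restrict the full (value, i, j) ordering to the candidate set at or
  # above the m-th largest value; ties at the boundary stay in and are
  # resolved lexicographically below
  cutoff <- -sort(-vals, partial = m_edges)[m_edges]
  cand <- which(vals >= cutoff)
  pos <- arrayInd(ut[cand], dim(corr_matrix))
  ord <- order(-vals[cand], pos[, 1L], pos[, 2L], method = "radix")
  sel <- ord[seq_len(m_edges)]
  edges <- cbind(i = pos[sel, 1L], j = pos[sel, 2L])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  binary_network(n, edges, k_target = k_target, s_value = s_value)
}

binary_network <- function(n_nodes, edges, k_target = NA_real_, s_value = NA_real_) {
  structure(list(
    n_nodes = as.integer(n_nodes),
    edges = edges,
    k_target = k_target,
    s_value = s_value,
    mean_degree = 2 * nrow(edges) / n_nodes
  ), class = "binary_network")
}

#' Build a binary network from a cleaned time-series
#'
#' Convenience wrapper: correlation matrix, implied mean degree from the
#' density exponent, then density thresholding.
#'
#' @param timeseries `n_nodes x T` matrix.
#' @param s_value Density exponent `S` (default 2.5).
#' @return A `binary_network` (see [threshold_to_density()]).
#' @export
network_from_timeseries <- function(timeseries, s_value = 2.5) {
  cm <- correlation_matrix(timeseries)
  threshold_to_density(cm, degree_for_s(nrow(cm), s_value), s_value = s_value)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("Binary network: %d nodes, %d edges (mean degree %.2f, target K %.2f)\n",
              x$n_nodes, nrow(x$edges), x$mean_degree, x$k_target))
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::make_empty_graph(network$n_nodes, directed = FALSE)
  igraph::add_edges(g, t(network$edges))
}

node_degrees <- function(network) {
  tabulate(network$edges, nbins = network$n_nodes)
}
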