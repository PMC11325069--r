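#' Community partition
#'
#' A labeling of every node with exactly one community, optionally carrying
#' the modularity of the labeling and the provenance of the search that
#' produced it.
#'
#' @param labels Integer vector of positive community labels, one per node.
#' @param q Modularity of the labeling (NA if not computed).
#' @param n_runs Number of optimizer restarts that produced it (NA if planted).
#' @param seed Seed of the search (NA if planted).
#' @return An object of class `community_partition`.
#' @export
community_partition <- function(labels, q = NA_real_, n_runs = NA_integer_,
                                seed = NA_integer_) {
  if (length(labels) == 0L || anyNA(labels) ||
      any(labels < 1) || any(labels != floor(labels))) {
    stop("`labels` must be positive integers with no missing values", call. = FALSE)
  }
  structure(list(labels = as.integer(labels), q = q,
                 n_runs = n_runs, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d nodes, %d communities, Q = %s\n",
              length(x$labels), length(unique(x$labels)),
              if (is.na(x$q)) "NA" else sprintf("%.4f", x$q)))
  invisible(x)
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]`, where `m` is the edge count,
#' `e_c` the number of edges internal to community `c`, and `d_c` the summed
#' degree of its members. `Q` always lies in `[-0.5, 1)`.
#'
#' @param network A `binary_network`.
#' @param partition A [community_partition()] (or a bare label vector)
#'   covering all nodes.
#' @return Modularity `Q`.
#' @export
modularity_q <- function(network, partition) {
  labels <- if (inherits(partition, "community_partition")) partition$labels else partition
  if (length(labels) != network$n_nodes) {
    stop("partition must label every node of the network", call. = FALSE)
  }
  m <- nrow(network$edges)
  if (m == 0L) stop("modularity is undefined for an empty edge set", call. = FALSE)
  within <- labels[network$edges[, 1L]] == labels[network$edges[, 2L]]
  e_c <- tapply(within, labels[network$edges[, 1L]], sum)
  deg <- node_degrees(network)
  d_c <- tapply(deg, labels, sum)
  sum(e_c[!is.na(e_c)]) / m - sum((d_c / (2 * m))^2)
}

#' Discrete-time Markov stability of a partition
#'
#' Autocovariance of community indicators under a `t`-step unbiased random
#' walk at stationarity:
#' `R(t) = sum_{c(i)=c(j)} [ pi_i (P^t)_{ij} - pi_i pi_j ]` with
#' `P = D^{-1} A` and `pi = d / 2m`. At `t = 1` this equals Newman
#' modularity exactly, which is why maximizing "stability" with default
#' (unit Markov time) parameters and maximizing `Q` coincide; the test
#' suite checks the identity numerically.
#'
#' @param network A `binary_network` with no isolated nodes.
#' @param partition A [community_partition()] or label vector.
#' @param t Positive integer Markov time.
#' @return Stability `R(t)`.
#' @export
markov_stability <- function(network, partition, t = 1L) {
  labels <- if (inherits(partition, "community_partition")) partition$labels else partition
  t <- assert_count(t, "t")
  n <- network$n_nodes
  deg <- node_degrees(network)
  if (any(deg == 0)) {
    stop("Markov stability requires every node to have positive degree", call. = FALSE)
  }
  adj <- matrix(0, n, n)
  adj[network$edges] <- 1
  adj <- adj + t(adj)
  m <- nrow(network$edges)
  p_step <- adj / deg
  p_t <- diag(n)
  for (k in seq_len(t)) p_t <- p_t %*% p_step
  pi_v <- deg / (2 * m)
  same <- outer(labels, labels, "==")
  sum((pi_v * p_t - outer(pi_v, pi_v))[same])
}

#' Detect communities by repeated modularity maximization
#'
#' Runs a stochastic greedy (Louvain-type, multilevel) modularity maximizer
#' `n_runs` times, each restart visiting the nodes in a fresh random order,
#' and returns the partition with the highest recomputed modularity. The
#' result is deterministic given `(network, n_runs, seed)`, and the best `Q`
#' over a nested seed sequence is non-decreasing in `n_runs`.
#'
#' @param network A `binary_network` with at least one edge.
#' @param n_runs Number of restarts (the source analysis used 100).
#' @param seed Integer seed.
#' @return A [community_partition()] with `q`, `n_runs` and `seed` filled in.
#' @export
detect_communities <- function(network, n_runs = 100L, seed = 1L) {
  n_runs <- assert_count(n_runs, "n_runs")
  if (nrow(network$edges) == 0L) {
    stop("cannot detect communities in a network with no edges", call. = FALSE)
  }
  g <- as_igraph(network)
  n <- network$n_nodes
  with_seed(seed, {
    best_q <- -Inf
    best_labels <- NULL
    for (run in seq_len(n_runs)) {
      perm <- sample.int(n)
      memb <- igraph::membership(igraph::cluster_louvain(igraph::permute(g, perm)))
      labels <- as.integer(memb[perm])
      q <- modularity_q(network, labels)
      if (q > best_q) {
        best_q <- q
        best_labels <- labels
      }
    }
    community_partition(best_labels, q = best_q,
                        n_runs = n_runs, seed = as.integer(seed))
  })
}
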