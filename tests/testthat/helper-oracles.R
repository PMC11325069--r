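# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, enumeration, dense algebra) and share no code
# with the package internals they check.

# All set partitions of n items as restricted-growth label vectors.
set_partitions <- function(n) {
  out <- vector("list", 0L)
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (lab in seq_len(maxlab + 1L)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Modularity from the pairwise definition on a dense adjacency matrix.
brute_modularity <- function(n, edges, labels) {
  A <- matrix(0, n, n)
  A[edges] <- 1
  A <- A + t(A)
  m <- nrow(edges)
  d <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) q <- q + A[i, j] - d[i] * d[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Uniform random graph on n nodes as a sinet binary_network (min 1 edge).
random_network <- function(n, p = 0.4) {
  pairs <- t(combn(n, 2))
  repeat {
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  sinet:::binary_network(n, pairs[keep, , drop = FALSE])
}

# Node-wise scaled inclusivity by direct double loop.
si_ref <- function(labels, template) {
  values <- numeric(length(labels))
  for (n in template) {
    C <- which(labels == labels[n])
    overlap <- length(intersect(C, template))
    values[n] <- overlap^2 / (length(C) * length(template))
  }
  values
}

ruzicka_ref <- function(x, y) {
  smin <- 0
  smax <- 0
  for (i in seq_along(x)) {
    smin <- smin + min(x[i], y[i])
    smax <- smax + max(x[i], y[i])
  }
  smin / smax
}

dvars_ref <- function(ts) {
  gm <- mean(ts)
  out <- numeric(ncol(ts))
  for (t in 2:ncol(ts)) {
    acc <- 0
    for (i in seq_len(nrow(ts))) acc <- acc + (ts[i, t] - ts[i, t - 1])^2
    out[t] <- sqrt(acc / nrow(ts)) / gm * 100
  }
  out
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Random symmetric nonnegative zero-diagonal matrix as a pair_distance.
random_pair_distance <- function(m, ids = sprintf("S%03d", seq_len(m))) {
  v <- matrix(0, m, m)
  v[upper.tri(v)] <- runif(m * (m - 1) / 2)
  v <- v + t(v)
  pair_distance(v, subject_ids = ids, kind = "brain_jaccard")
}

# Random si_map list over n nodes for m subjects.
random_si_maps <- function(m, n) {
  lapply(seq_len(m), function(i) {
    structure(list(subject_id = sprintf("S%03d", i), template_name = "T",
                   values = runif(n)), class = "si_map")
  })
}

# Reference fixed-effects fit via lm() with an explicit dummy matrix.
lm_dummy_fit <- function(y, xs, drop_subject = NULL) {
  m <- length(y$subject_ids)
  if (is.null(drop_subject)) drop_subject <- m
  ut <- which(upper.tri(y$values))
  pos <- arrayInd(ut, dim(y$values))
  yv <- y$values[ut]
  D <- matrix(0, length(yv), m)
  D[cbind(seq_along(yv), pos[, 1])] <- 1
  D[cbind(seq_along(yv), pos[, 2])] <- 1
  D <- D[, -drop_subject, drop = FALSE]
  X <- do.call(cbind, lapply(xs, function(x) x$values[ut]))
  fit <- lm(yv ~ X + D)
  cf <- summary(fit)$coefficients
  rows <- 1 + seq_along(xs)
  data.frame(estimate = cf[rows, 1], se = cf[rows, 2], t = cf[rows, 3],
             p = 2 * pnorm(-abs(cf[rows, 3])), row.names = NULL)
}
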