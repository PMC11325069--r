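#' Pairwise distance matrix over subjects
#'
#' @param values Symmetric nonnegative `M x M` matrix with zero diagonal.
#' @param subject_ids Ordered subject identifiers.
#' @param kind One of `"brain_jaccard"`, `"abs_numeric"`, `"binary_mismatch"`.
#' @return An object of class `pair_distance`.
#' @export
pair_distance <- function(values, subject_ids = rownames(values),
                          kind = c("brain_jaccard", "abs_numeric", "binary_mismatch")) {
  kind <- match.arg(kind)
  values <- assert_matrix(values, "values")
  m <- nrow(values)
  if (m != ncol(values)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12 || any(diag(values) != 0) ||
      any(values < 0)) {
    stop("distance matrix must be symmetric, nonnegative, zero-diagonal",
         call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(m))
  structure(list(subject_ids = as.character(subject_ids), values = values,
                 kind = kind), class = "pair_distance")
}

#' Ruzicka (weighted-Jaccard) similarity
#'
#' `sum_i min(x_i, y_i) / sum_i max(x_i, y_i)` for nonnegative vectors; also
#' known as the Jaccardized Czekanowski index. Equal nonzero vectors score
#' 1, vectors with disjoint support score 0.
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
ruzicka_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0)) {
    stop("inputs must be nonnegative with no missing values", call. = FALSE)
  }
  denom <- sum(pmax(x, y))
  if (denom == 0) {
    stop("both vectors are all-zero; similarity is 0/0", call. = FALSE)
  }
  sum(pmin(x, y)) / denom
}

#' Pairwise Jaccard distances between subject SI maps
#'
#' Entry `(i, j)` is `1 - ruzicka_similarity(map_i, map_j)`: a semimetric
#' that is 0 exactly when the two maps are identical.
#'
#' @param maps List of `si_map`s over a common node space.
#' @return A [pair_distance()] of kind `"brain_jaccard"`.
#' @export
brain_distance_matrix <- function(maps) {
  vals <- si_values_matrix(maps)
  m <- nrow(vals)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      d[i, j] <- d[j, i] <- 1 - ruzicka_similarity(vals[i, ], vals[j, ])
    }
  }
  ids <- vapply(maps, function(x) as.character(x$subject_id), character(1))
  if (anyNA(ids)) ids <- sprintf("S%03d", seq_len(m))
  pair_distance(d, subject_ids = ids, kind = "brain_jaccard")
}

#' Pairwise covariate distances
#'
#' Numeric covariates use the absolute difference; binary covariates (e.g.
#' sex) use mismatch coding (0 if equal, 1 otherwise).
#'
#' @param values Numeric vector, one value per subject (binary kind requires
#'   values in `{0, 1}`).
#' @param kind `"abs_numeric"` or `"binary_mismatch"`.
#' @param subject_ids Optional identifiers.
#' @return A [pair_distance()].
#' @export
covariate_distance_matrix <- function(values,
                                      kind = c("abs_numeric", "binary_mismatch"),
                                      subject_ids = names(values)) {
  kind <- match.arg(kind)
  if (anyNA(values) || !is.numeric(values)) {
    stop("covariate must be numeric with no missing values", call. = FALSE)
  }
  d <- if (kind == "abs_numeric") {
    abs(outer(values, values, "-"))
  } else {
    if (!all(values %in% c(0, 1))) {
      stop("binary covariate must be coded 0/1", call. = FALSE)
    }
    (outer(values, values, "!=")) * 1
  }
  dimnames(d) <- NULL
  pair_distance(d, subject_ids = subject_ids, kind = kind)
}

#' Distance regression with subject fixed effects
#'
#' Unrolls the `M(M-1)/2` unordered subject pairs and regresses the pairwise
#' outcome distances on the pairwise covariate distances plus an intercept
#' and subject indicator columns (pair `(i, j)` carries a 1 in columns `i`
#' and `j`; one column is dropped for identifiability — covariate estimates
#' are invariant to which). Parametric two-sided p-values use the
#' standard-normal reference on `T = estimate / SE`, matching the published
#' convention at printed precision; because the pairs sharing a subject are
#' not independent, a subject-relabeling permutation p-value for a focal
#' term is available and is the recommended inference.
#'
#' The permutation scheme relabels subjects: a permuted covariate distance
#' matrix is the original with rows and columns jointly permuted, which is
#' exactly the matrix rebuilt from permuted subject covariate values. The
#' permuted fits reuse the Frisch-Waugh-Lovell identity (residualize the
#' outcome and the focal column on everything else once), which reproduces
#' the full-refit T statistic exactly.
#'
#' @param y A [pair_distance()] outcome (e.g. from [brain_distance_matrix()]).
#' @param xs List of [pair_distance()] predictors sharing `y`'s subject order.
#' @param term_names Names for the predictor terms.
#' @param permutations Number of permutations for the focal term (0 = none).
#' @param perm_term Index into `xs` of the focal term (default 1).
#' @param seed Integer seed for the permutations.
#' @param drop_subject Index of the subject indicator to drop (default `M`).
#' @return An object of class `distance_model`: `terms` (data frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `p_perm` (or `NA`), `n_subjects`,
#'   `n_pairs`, `permutations`, `seed`.
#' @export
fit_distance_regression <- function(y, xs, term_names = NULL, permutations = 0L,
                                    perm_term = 1L, seed = 1L,
                                    drop_subject = NULL) {
  stopifnot(inherits(y, "pair_distance"))
  if (!is.list(xs) || length(xs) == 0L) stop("`xs` must be a non-empty list", call. = FALSE)
  m <- length(y$subject_ids)
  if (m < 4L) stop("need at least 4 subjects", call. = FALSE)
  for (x in xs) {
    stopifnot(inherits(x, "pair_distance"))
    if (!identical(x$subject_ids, y$subject_ids)) {
      stop("mismatched subject order between distance matrices", call. = FALSE)
    }
  }
  if (is.null(term_names)) term_names <- names(xs)
  if (is.null(term_names)) term_names <- paste0("x", seq_along(xs))
  if (is.null(drop_subject)) drop_subject <- m
  drop_subject <- assert_count(drop_subject, "drop_subject")

  ut <- which(upper.tri(y$values))
  pos <- arrayInd(ut, dim(y$values))
  yv <- y$values[ut]
  n_pairs <- length(yv)
  xcols <- vapply(xs, function(x) x$values[ut], numeric(n_pairs))
  dummies <- matrix(0, n_pairs, m)
  dummies[cbind(seq_len(n_pairs), pos[, 1L])] <- 1
  dummies[cbind(seq_len(n_pairs), pos[, 2L])] <- 1
  dummies <- dummies[, -drop_subject, drop = FALSE]
  design <- cbind(`(Intercept)` = 1, xcols, dummies)
  colnames(design) <- c("(Intercept)", term_names,
                        paste0("subj_", y$subject_ids[-drop_subject]))
  p_all <- ncol(design)
  if (qr(design)$rank < p_all) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  xtx <- crossprod(design)
  xtx_inv <- chol2inv(chol(xtx))
  beta <- drop(xtx_inv %*% crossprod(design, yv))
  resid <- yv - drop(design %*% beta)
  sigma2 <- sum(resid^2) / (n_pairs - p_all)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * pnorm(-abs(tval))
  keep <- seq_along(term_names) + 1L  # covariate terms (skip intercept)
  terms <- data.frame(term = term_names, estimate = beta[keep], se = se[keep],
                      t = tval[keep], p = pval[keep], row.names = NULL)

  p_perm <- NA_real_
  t_perm_obs <- NA_real_
  if (permutations > 0L) {
    perm_term <- assert_count(perm_term, "perm_term")
    focal <- xcols[, perm_term]
    z <- design[, -(perm_term + 1L), drop = FALSE]
    qz <- qr(z)
    ry <- qr.resid(qz, yv)
    t_for <- function(xcol) {
      rx <- qr.resid(qz, xcol)
      sxx <- sum(rx^2)
      b <- sum(rx * ry) / sxx
      s2 <- (sum(ry^2) - b^2 * sxx) / (n_pairs - p_all)
      b / sqrt(s2 / sxx)
    }
    t_obs <- t_perm_obs <- t_for(focal)
    xmat <- xs[[perm_term]]$values
    t_null <- with_seed(seed, vapply(seq_len(permutations), function(b) {
      pm <- sample.int(m)
      t_for(xmat[pm, pm][ut])
    }, numeric(1)))
    p_perm <- (1 + sum(abs(t_null) >= abs(t_obs))) / (permutations + 1)
  }
  structure(list(terms = terms, p_perm = p_perm, t_perm_obs = t_perm_obs,
                 n_subjects = m,
                 n_pairs = n_pairs, permutations = as.integer(permutations),
                 seed = as.integer(seed)),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("Distance regression: %d subjects, %d pairs\n",
              x$n_subjects, x$n_pairs))
  print(x$terms, digits = 4)
  if (!is.na(x$p_perm)) {
    cat(sprintf("Permutation p (focal term, B = %d): %.4f\n",
                x$permutations, x$p_perm))
  }
  invisible(x)
}

#' Step-up false-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values:
#' `q_(k) = min over j >= k of min(1, m * p_(j) / j)`, mapped back to input
#' order. Outputs are monotone in the inputs and never smaller than them.
#' A two-stage adaptive variant (estimating the null proportion from a
#' first-pass rejection count) is available via `method = "two-stage"`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"two-stage"`.
#' @param alpha Level used by the two-stage null-proportion estimate.
#' @return Adjusted p-values in input order.
#' @export
adapted_fdr <- function(p_values, method = c("bh", "two-stage"), alpha = 0.05) {
  method <- match.arg(method)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  step_up <- function(p, m_eff) {
    ord <- order(p, decreasing = TRUE)
    ranks <- m:1L
    adj <- pmin(1, cummin(m_eff / ranks * p[ord]))
    adj[order(ord)]
  }
  if (method == "bh") return(step_up(p_values, m))
  # two-stage: first pass at alpha / (1 + alpha) estimates the null count
  first <- step_up(p_values, m)
  r1 <- sum(first <= alpha / (1 + alpha))
  m0 <- m - r1
  if (m0 == 0L) return(first)
  step_up(p_values, m0)
}

#' Bundled reference table of distance-regression results
#'
#' A published multivariable distance-regression summary for eight brain
#' subnetworks under two scan conditions (rest and a motor-imagery task),
#' with the contrast-sensitivity term's estimate, standard error, T-score,
#' raw p-value and FDR-adjusted p-value. Used as the worked example for
#' [adapted_fdr()] and the T-to-p mapping; estimates printed as `<0.0001`
#' in the source table are stored as `NA`.
#'
#' @return Data frame with columns `network`, `condition`, `term`,
#'   `estimate`, `se`, `t`, `p`, `p_fdr`.
#' @export
reference_model_table <- function() {
  path <- system.file("extdata", "reference_model_table.tsv", package = "sinet")
  read.delim(path, stringsAsFactors = FALSE)
}
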