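#' Canonical template subnetwork names
#'
#' Eight disjoint reference communities commonly used for whole-brain
#' community-consistency scoring: visual (VN), default mode (DMN),
#' sensorimotor (SMN), basal ganglia (BGN), central executive (CEN),
#' dorsal attention (DAN), frontotemporal (FTN) and salience (SN).
#' @export
TEMPLATE_NAMES <- c("VN", "DMN", "SMN", "BGN", "CEN", "DAN", "FTN", "SN")

#' Template set from a node labeling
#'
#' @param membership Vector with one entry per node: a template name, or
#'   `NA`/`"none"` for nodes outside every template.
#' @return A named list of node-index vectors (class `template_set`);
#'   templates are pairwise disjoint by construction.
#' @export
template_set <- function(membership) {
  membership[membership %in% "none"] <- NA
  labs <- unique(membership[!is.na(membership)])
  if (length(labs) == 0L) stop("no template labels found", call. = FALSE)
  out <- lapply(labs, function(l) which(membership == l))
  names(out) <- labs
  structure(out, n_nodes = length(membership), class = "template_set")
}

#' Templates from a planted partition
#'
#' In synthetic mode the planted communities themselves serve as the
#' reference templates; they are named with the canonical subnetwork names
#' (in order) when there are at most eight.
#'
#' @param partition A [community_partition()].
#' @param names Optional character names, one per community.
#' @return A `template_set`.
#' @export
templates_from_partition <- function(partition, names = NULL) {
  labs <- sort(unique(partition$labels))
  if (is.null(names)) {
    names <- if (length(labs) <= length(TEMPLATE_NAMES)) {
      TEMPLATE_NAMES[seq_along(labs)]
    } else {
      paste0("C", labs)
    }
  }
  membership <- rep(NA_character_, length(partition$labels))
  for (k in seq_along(labs)) membership[partition$labels == labs[k]] <- names[k]
  template_set(membership)
}

#' Scaled inclusivity of one subject against one template
#'
#' For each node `n` in the template `T`, let `C` be the subject community
#' containing `n`. The node's scaled inclusivity is
#' `SI(n) = |C intersect T|^2 / (|C| * |T|)`,
#' which is 1 only when `C` and `T` coincide and is penalized both for
#' template nodes missing from `C` and for extra nodes `C` drags in.
#' Nodes outside `T` score 0. SI is invariant to community relabeling.
#'
#' @param partition A [community_partition()] covering all nodes.
#' @param template Integer vector of template node indices (non-empty), or a
#'   single `template_set` element.
#' @param subject_id,template_name Optional identifiers carried on the map.
#' @return An object of class `si_map`: list with `subject_id`,
#'   `template_name` and `values` (length `n_nodes`, in `[0, 1]`).
#' @export
subject_si_map <- function(partition, template, subject_id = NA_character_,
                           template_name = NA_character_) {
  stopifnot(inherits(partition, "community_partition"))
  template <- as.integer(template)
  if (length(template) == 0L) stop("template is empty", call. = FALSE)
  labels <- partition$labels
  if (any(template < 1L | template > length(labels))) {
    stop("template refers to nodes outside the partition", call. = FALSE)
  }
  values <- numeric(length(labels))
  t_size <- length(template)
  labs_in_t <- labels[template]
  comm_sizes <- tabulate(labels)
  for (lab in unique(labs_in_t)) {
    overlap <- sum(labs_in_t == lab)
    si <- overlap^2 / (comm_sizes[lab] * t_size)
    values[template[labs_in_t == lab]] <- si
  }
  structure(list(subject_id = subject_id, template_name = template_name,
                 values = values), class = "si_map")
}

#' Group-average scaled-inclusivity map
#'
#' Node-wise arithmetic mean of per-subject SI maps; equals 1 on the
#' template only under perfect alignment of every subject.
#'
#' @param maps Non-empty list of `si_map`s over the same node space.
#' @return Numeric vector of node-wise means in `[0, 1]`.
#' @export
group_si_map <- function(maps) {
  vals <- si_values_matrix(maps)
  colMeans(vals)
}

# subjects x nodes matrix of SI values, with shape checks
si_values_matrix <- function(maps) {
  if (length(maps) == 0L) stop("no SI maps supplied", call. = FALSE)
  lens <- vapply(maps, function(m) length(m$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("SI maps do not share a node space", call. = FALSE)
  }
  do.call(rbind, lapply(maps, `[[`, "values"))
}

#' Split subjects into covariate tertiles
#'
#' Subjects are ordered by the covariate (stable order, so tied values fall
#' to the lower tertile first) and split into three near-equal groups; when
#' the count is not divisible by 3 the extra members go to the lower
#' tertile(s) first, e.g. 10 subjects split 4/3/3.
#'
#' @param covariate Numeric vector, one value per subject, with at least
#'   three distinct values.
#' @return List of index vectors `lower`, `middle`, `upper`.
#' @export
tertile_split <- function(covariate) {
  n <- length(covariate)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (length(unique(covariate)) < 3L) {
    stop("covariate must take at least 3 distinct values", call. = FALSE)
  }
  ord <- order(covariate)
  f <- n %/% 3L
  r <- n %% 3L
  sizes <- c(lower = f + (r >= 1L), middle = f + (r >= 2L), upper = f)
  bounds <- cumsum(sizes)
  list(lower = ord[seq_len(bounds[1L])],
       middle = ord[(bounds[1L] + 1L):bounds[2L]],
       upper = ord[(bounds[2L] + 1L):bounds[3L]])
}

#' Upper- and lower-tertile group SI maps
#'
#' Visualization aid for the direction of a covariate effect: group-average
#' SI maps for the subjects in the upper and lower covariate tertiles.
#' These maps are descriptive only and feed no statistics.
#'
#' @param maps List of `si_map`s, one per subject, aligned with `covariate`.
#' @param covariate Numeric vector, one value per subject.
#' @return List with `upper` and `lower` node-wise mean maps and the
#'   `split` used.
#' @export
tertile_maps <- function(maps, covariate) {
  if (length(maps) != length(covariate)) {
    stop("one covariate value per SI map is required", call. = FALSE)
  }
  split <- tertile_split(covariate)
  list(upper = group_si_map(maps[split$upper]),
       lower = group_si_map(maps[split$lower]),
       split = split)
}
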