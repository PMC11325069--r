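#' Configuration for a synthetic cohort
#'
#' Describes a cohort of subjects whose node time-series carry planted
#' community structure. The spatial fidelity of one target community is
#' degraded subject-by-subject at a "jitter" rate that depends linearly on a
#' continuous covariate (log contrast sensitivity, CS): subjects with lower
#' CS have more of the target community's nodes reassigned to other
#' communities before their signals are simulated. Defaults follow the
#' published cohort where one exists (CS mean 1.71, SD 0.14) and otherwise
#' use desk-scale values documented in the methods vignette.
#'
#' The jitter rate for a subject with covariate value `c` is
#' `g(c) = clamp(jitter_intercept - jitter_slope * (c - covariate_mean), 0, 1)`,
#' so a positive slope makes low-CS subjects noisier, the direction of the
#' effect the downstream distance regression is designed to detect.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of network nodes; must equal `sum(community_sizes)`.
#' @param n_timepoints Frames per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param community_sizes Integer vector of community sizes (sums to `n_nodes`).
#' @param target_community Index of the community whose membership is jittered.
#' @param within_corr Expected within-community Pearson correlation, in `[0, 1)`.
#' @param covariate_mean,covariate_sd Mean and SD of the CS covariate
#'   (log contrast sensitivity units). Draws are truncated to `[0, 2.4]`,
#'   the physical range of a 48-letter Pelli-Robson chart.
#' @param jitter_slope Link between CS and jitter rate (per log-CS unit).
#' @param jitter_intercept Jitter rate at the covariate mean, in `[0, 1]`.
#' @param sex_fraction Probability that `sex == 1`.
#' @param motion_spike_rate Per-frame probability of a 1 mm head-motion spike.
#' @param baseline Mean signal level added to all series (arbitrary units);
#'   gives DVARS a well-defined percent-signal-change scale.
#' @param signal_amplitude SD of the simulated fluctuations, in the same
#'   units as `baseline` (default 0.25, i.e. 0.25% of a baseline of 100).
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40, n_nodes = 600, n_timepoints = 200,
                          tr_seconds = 2, community_sizes = rep(150L, 4),
                          target_community = 1L, within_corr = 0.4,
                          covariate_mean = 1.71, covariate_sd = 0.14,
                          jitter_slope = 1.2, jitter_intercept = 0.35,
                          sex_fraction = 0.5, motion_spike_rate = 0.02,
                          baseline = 100, signal_amplitude = 0.25,
                          seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 3L)
  tr_seconds <- assert_number(tr_seconds, "tr_seconds", lower = 0, lower_open = TRUE)
  community_sizes <- vapply(community_sizes, assert_count, integer(1),
                            name = "community_sizes")
  if (sum(community_sizes) != n_nodes) {
    stop("`community_sizes` must sum to `n_nodes`", call. = FALSE)
  }
  target_community <- assert_count(target_community, "target_community")
  if (target_community > length(community_sizes)) {
    stop("`target_community` is not an index into `community_sizes`", call. = FALSE)
  }
  within_corr <- assert_number(within_corr, "within_corr", 0, 1, upper_open = TRUE)
  covariate_sd <- assert_number(covariate_sd, "covariate_sd", lower = 0)
  jitter_intercept <- assert_number(jitter_intercept, "jitter_intercept", 0, 1)
  sex_fraction <- assert_number(sex_fraction, "sex_fraction", 0, 1)
  motion_spike_rate <- assert_number(motion_spike_rate, "motion_spike_rate", 0, 1)
  structure(list(
    n_subjects = n_subjects, n_nodes = n_nodes, n_timepoints = n_timepoints,
    tr_seconds = tr_seconds, community_sizes = community_sizes,
    target_community = target_community, within_corr = within_corr,
    covariate_mean = as.numeric(covariate_mean), covariate_sd = covariate_sd,
    jitter_slope = as.numeric(jitter_slope), jitter_intercept = jitter_intercept,
    sex_fraction = sex_fraction, motion_spike_rate = motion_spike_rate,
    baseline = as.numeric(baseline),
    signal_amplitude = as.numeric(signal_amplitude),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Covariate-dependent jitter rate
#'
#' @param config A [cohort_config()].
#' @param cs Covariate values.
#' @return Jitter rates clamped to `[0, 1]`.
#' @export
jitter_rate <- function(config, cs) {
  pmin(pmax(config$jitter_intercept -
              config$jitter_slope * (cs - config$covariate_mean), 0), 1)
}

#' Plant a community partition
#'
#' Assigns each of `sum(community_sizes)` nodes to exactly one community so
#' that community `c` has `community_sizes[c]` members. Node order is
#' randomized so that planted communities are not contiguous index blocks.
#'
#' @param community_sizes Positive integer community sizes.
#' @param seed Integer seed.
#' @return A [community_partition()].
#' @export
plant_partition <- function(community_sizes, seed = 1L) {
  if (length(community_sizes) == 0L) {
    stop("`community_sizes` must be non-empty", call. = FALSE)
  }
  sizes <- vapply(community_sizes, assert_count, integer(1), name = "community_sizes")
  labels <- rep.int(seq_along(sizes), sizes)
  labels <- with_seed(seed, sample(labels))
  community_partition(labels, seed = as.integer(seed))
}

#' Jitter the membership of one community
#'
#' Each node of the target community is independently reassigned, with the
#' given probability, to a community chosen uniformly among the others.
#' Non-target nodes are untouched. This is the generative analogue of the
#' between-subject spatial variability that scaled inclusivity measures.
#'
#' @param partition A [community_partition()].
#' @param target Community label to perturb.
#' @param rate Reassignment probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A new [community_partition()] (modularity not carried over).
#' @export
jitter_membership <- function(partition, target, rate, seed = 1L) {
  stopifnot(inherits(partition, "community_partition"))
  rate <- assert_number(rate, "rate", 0, 1)
  with_seed(seed, jitter_membership_impl(partition, target, rate))
}

jitter_membership_impl <- function(partition, target, rate) {
  labels <- partition$labels
  comms <- sort(unique(labels))
  if (!target %in% comms) stop("`target` is not a community label", call. = FALSE)
  idx <- which(labels == target)
  flip <- runif(length(idx)) < rate
  if (any(flip)) {
    others <- setdiff(comms, target)
    if (length(others) == 0L) {
      stop("cannot jitter: the partition has a single community", call. = FALSE)
    }
    labels[idx[flip]] <- others[sample.int(length(others), sum(flip), replace = TRUE)]
  }
  community_partition(labels)
}

#' Simulate community-structured signals
#'
#' One latent unit-variance series per community plus independent per-node
#' noise: node `i` is `sqrt(rho) * latent[c(i)] + sqrt(1 - rho) * noise_i`,
#' giving expected within-community Pearson correlation `rho` and
#' cross-community correlation 0.
#'
#' @param partition A [community_partition()].
#' @param n_timepoints Number of frames (at least 3).
#' @param within_corr Expected within-community correlation `rho` in `[0, 1)`.
#' @param seed Integer seed.
#' @return `n_nodes x n_timepoints` numeric matrix.
#' @export
simulate_bold <- function(partition, n_timepoints, within_corr, seed = 1L) {
  stopifnot(inherits(partition, "community_partition"))
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 3L)
  within_corr <- assert_number(within_corr, "within_corr", 0, 1, upper_open = TRUE)
  with_seed(seed, simulate_bold_impl(partition, n_timepoints, within_corr))
}

simulate_bold_impl <- function(partition, n_timepoints, rho) {
  labels <- partition$labels
  n <- length(labels)
  k <- max(labels)
  latent <- matrix(rnorm(k * n_timepoints), k, n_timepoints)
  noise <- matrix(rnorm(n * n_timepoints), n, n_timepoints)
  sqrt(rho) * latent[labels, , drop = FALSE] + sqrt(1 - rho) * noise
}

#' Convert a Pelli-Robson letter count to log contrast sensitivity
#'
#' Letter-by-letter scoring at 0.05 log units per letter over the 48-letter
#' chart, so scores span 0 to 2.40.
#'
#' @param n_letters_correct Number of letters read correctly (0-48).
#' @return Log contrast sensitivity.
#' @export
pelli_robson_to_logcs <- function(n_letters_correct) {
  if (any(!is.finite(n_letters_correct)) ||
      any(n_letters_correct < 0 | n_letters_correct > 48) ||
      any(n_letters_correct != floor(n_letters_correct))) {
    stop("`n_letters_correct` must be integers in [0, 48]", call. = FALSE)
  }
  0.05 * n_letters_correct
}

#' Generate a synthetic cohort
#'
#' Draws per-subject covariates, jitters the target community at the
#' covariate-linked rate, simulates signals from the jittered partition, and
#' simulates motion traces with occasional 1 mm spikes. The planted
#' (unjittered) partition is shared across subjects and returned as
#' `$base_partition`; it doubles as the template set in synthetic mode.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list with `subjects` (a list of
#'   `subject_record`s), `base_partition`, and `config`. Each subject record
#'   holds `subject_id`, `covariates` (`cs`, `sex`, `volumes_removed`),
#'   `timeseries` (`n_nodes x n_timepoints`), `motion_params`
#'   (`n_timepoints x 6`; translations in mm, rotations in radians), and
#'   `true_partition` (the subject's jittered partition).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  base <- plant_partition(config$community_sizes, seed = config$seed)
  subjects <- with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      cs <- draw_truncnorm(config$covariate_mean, config$covariate_sd, 0, 2.4)
      sex <- rbinom(1L, 1L, config$sex_fraction)
      rate <- jitter_rate(config, cs)
      part <- jitter_membership_impl(base, config$target_community, rate)
      ts <- config$baseline + config$signal_amplitude *
        simulate_bold_impl(part, config$n_timepoints, config$within_corr)
      mp <- simulate_motion(config$n_timepoints, config$motion_spike_rate)
      fd <- framewise_displacement(mp)
      structure(list(
        subject_id = sprintf("S%03d", i),
        covariates = list(cs = cs, sex = sex,
                          volumes_removed = sum(fd > 0.5)),
        timeseries = ts,
        motion_params = mp,
        true_partition = part
      ), class = "subject_record")
    })
  })
  structure(list(subjects = subjects, base_partition = base, config = config),
            class = "cohort")
}

# Rejection sampler for a Normal truncated to [lo, hi]; draws one value.
draw_truncnorm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# Gaussian jitter around zero (0.02 mm translations, 4e-4 rad rotations)
# plus Bernoulli 1 mm translation spikes lasting a single frame, which a
# 0.5 mm framewise-displacement threshold flags on entry and exit.
simulate_motion <- function(n_timepoints, spike_rate) {
  mp <- cbind(matrix(rnorm(n_timepoints * 3, sd = 0.02), ncol = 3),
              matrix(rnorm(n_timepoints * 3, sd = 4e-4), ncol = 3))
  if (spike_rate > 0 && n_timepoints > 2) {
    spikes <- which(runif(n_timepoints - 2) < spike_rate) + 1L
    mp[spikes, 1] <- mp[spikes, 1] + 1.0
  }
  colnames(mp) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  mp
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d nodes x %d frames, %d communities\n",
              length(x$subjects), x$config$n_nodes, x$config$n_timepoints,
              length(x$config$community_sizes)))
  invisible(x)
}
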