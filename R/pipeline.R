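#' Pipeline configuration
#'
#' One object driving the full synthetic-mode analysis: cohort generation,
#' optional signal cleaning, network construction, community detection,
#' scaled inclusivity against the planted templates, and one distance
#' regression per (template network, condition), pooled only for the FDR
#' step. Conditions are emulated by separate jitter parameters per
#' condition (the analysis fits conditions separately rather than
#' contrasting them).
#'
#' @param cohort A [cohort_config()] shared by all conditions.
#' @param conditions Character vector of condition labels.
#' @param condition_jitter Optional named list (per condition) of lists with
#'   `jitter_slope` / `jitter_intercept` overrides.
#' @param s_value Density exponent for network construction.
#' @param n_community_runs Restarts for [detect_communities()] (source
#'   analysis: 100).
#' @param cleaning A [cleaning_config()], or `NULL` to skip the cleaning
#'   stage (the synthetic generator's signals are already confound-free).
#' @param permutations Permutations for the CS term (0 = parametric only).
#' @param seed Integer seed (mandatory; every stage derives from it).
#' @param output_dir Directory for stage artifacts, or `NULL` for none.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            conditions = c("rest", "task"),
                            condition_jitter = NULL,
                            s_value = 2.5, n_community_runs = 100L,
                            cleaning = NULL, permutations = 0L,
                            seed = 1L, output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (!is.null(cleaning)) stopifnot(inherits(cleaning, "cleaning_config"))
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(cohort = cohort, conditions = as.character(conditions),
                 condition_jitter = condition_jitter, s_value = s_value,
                 n_community_runs = assert_count(n_community_runs, "n_community_runs"),
                 cleaning = cleaning,
                 permutations = assert_count(permutations, "permutations", min = 0L),
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

# cohort -> partitions for every subject (optionally after cleaning)
detect_cohort_partitions <- function(cohort, s_value, n_runs, seed,
                                     cleaning = NULL) {
  with_seed(seed, {
    lapply(cohort$subjects, function(s) {
      ts <- s$timeseries
      if (!is.null(cleaning)) {
        cleaned <- tryCatch(
          clean_series(ts, s$motion_params, cohort$config$tr_seconds, cleaning),
          error = function(e) stop(sprintf("cleaning failed for subject %s: %s",
                                           s$subject_id, conditionMessage(e)),
                                   call. = FALSE))
        ts <- cleaned$timeseries
      }
      net <- network_from_timeseries(ts, s_value)
      detect_communities(net, n_runs = n_runs, seed = sample.int(2^30, 1L))
    })
  })
}

# SI maps of every subject against one template
cohort_si_maps <- function(partitions, template_nodes, template_name, ids) {
  Map(function(p, id) subject_si_map(p, template_nodes, subject_id = id,
                                     template_name = template_name),
      partitions, ids)
}

#' Run the full synthetic-mode pipeline
#'
#' Executes cohort generation, (optional) cleaning, network construction,
#' community detection, scaled inclusivity, distance regressions and the
#' FDR step, one model per (template network, condition). The CS term's
#' parametric p-values across the whole family form the FDR family.
#'
#' @param config A [pipeline_config()].
#' @return A list with `results` (data frame: network, condition, term,
#'   estimate, se, t, p, p_perm, p_fdr — `p_fdr` filled for the CS term),
#'   `si_maps` (nested list by condition then network), `tertiles`
#'   (tertile maps per network/condition), and `provenance`. With an
#'   `output_dir`, also writes `results.tsv`, group/tertile SI map TSVs and
#'   `provenance.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list()
  si_store <- list()
  tert_store <- list()
  counts <- list()
  for (k in seq_along(config$conditions)) {
    cond <- config$conditions[k]
    cfg_c <- config$cohort
    over <- config$condition_jitter[[cond]]
    if (!is.null(over)) {
      for (fld in names(over)) cfg_c[[fld]] <- over[[fld]]
    }
    cfg_c$seed <- config$seed + k
    cohort <- generate_cohort(cfg_c)
    templates <- templates_from_partition(cohort$base_partition)
    ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
    partitions <- detect_cohort_partitions(cohort, config$s_value,
                                           config$n_community_runs,
                                           seed = config$seed + 100L + k,
                                           cleaning = config$cleaning)
    cs <- vapply(cohort$subjects, function(s) s$covariates$cs, numeric(1))
    sex <- vapply(cohort$subjects, function(s) s$covariates$sex, numeric(1))
    motion <- vapply(cohort$subjects, function(s) s$covariates$volumes_removed,
                     numeric(1))
    xs <- list(
      binocular_cs = covariate_distance_matrix(cs, "abs_numeric", ids),
      motion = covariate_distance_matrix(motion, "abs_numeric", ids),
      sex = covariate_distance_matrix(sex, "binary_mismatch", ids)
    )
    si_store[[cond]] <- list()
    tert_store[[cond]] <- list()
    for (tname in names(templates)) {
      maps <- cohort_si_maps(partitions, templates[[tname]], tname, ids)
      si_store[[cond]][[tname]] <- maps
      tert_store[[cond]][[tname]] <- tertile_maps(maps, cs)
      y <- brain_distance_matrix(maps)
      fit <- fit_distance_regression(y, xs, names(xs),
                                     permutations = config$permutations,
                                     perm_term = 1L,
                                     seed = config$seed + 1000L + k)
      res <- fit$terms
      res$p_perm <- c(fit$p_perm, rep(NA_real_, nrow(res) - 1L))
      res <- cbind(network = tname, condition = cond, res)
      results[[paste(tname, cond, sep = "/")]] <- res
    }
    counts[[cond]] <- list(subjects = length(ids),
                           nodes = cfg_c$n_nodes,
                           templates = length(templates))
  }
  results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
  cs_rows <- results$term == "binocular_cs"
  results$p_fdr <- NA_real_
  results$p_fdr[cs_rows] <- adapted_fdr(results$p[cs_rows])
  provenance <- list(
    package_version = as.character(utils::packageVersion("sinet")),
    seed = config$seed,
    config_hash = config_hash(config),
    stage_counts = counts
  )
  out <- list(results = results, si_maps = si_store, tertiles = tert_store,
              provenance = provenance)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(results, file.path(config$output_dir, "results.tsv"))
    for (cond in names(si_store)) {
      for (tname in names(si_store[[cond]])) {
        grp <- group_si_map(si_store[[cond]][[tname]])
        tert <- tert_store[[cond]][[tname]]
        write_tsv(data.frame(node = seq_along(grp), group_si = grp,
                             upper_tertile = tert$upper,
                             lower_tertile = tert$lower),
                  file.path(config$output_dir,
                            sprintf("si_%s_%s.tsv", tname, cond)))
      }
    }
    jsonlite::write_json(provenance,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # hash the scientific configuration only
  json <- jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  tmp <- tempfile()
  writeLines(json, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' One synthetic replicate of the target-network analysis
#'
#' Generates a cohort, detects communities, scores scaled inclusivity
#' against the planted target community, and fits the distance regression
#' of the brain distances on CS, motion and sex distances. Used by the
#' calibration and power checks.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param s_value Density exponent.
#' @param n_runs Community-detection restarts.
#' @param permutations Permutations for the CS term.
#' @param seed Integer seed (overrides the one in `cohort_cfg`).
#' @return The CS row of the fit: list with `estimate`, `t`, `p`, `p_perm`.
#' @export
run_synthetic_replicate <- function(cohort_cfg, s_value = 2.5, n_runs = 3L,
                                    permutations = 1000L, seed = 1L) {
  cohort_cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cohort_cfg)
  templates <- templates_from_partition(cohort$base_partition)
  target <- templates[[cohort_cfg$target_community]]
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  partitions <- detect_cohort_partitions(cohort, s_value, n_runs,
                                         seed = seed + 7L)
  maps <- cohort_si_maps(partitions, target,
                         names(templates)[cohort_cfg$target_community], ids)
  cs <- vapply(cohort$subjects, function(s) s$covariates$cs, numeric(1))
  sex <- vapply(cohort$subjects, function(s) s$covariates$sex, numeric(1))
  motion <- vapply(cohort$subjects, function(s) s$covariates$volumes_removed,
                   numeric(1))
  xs <- list(binocular_cs = covariate_distance_matrix(cs, "abs_numeric", ids),
             motion = covariate_distance_matrix(motion, "abs_numeric", ids),
             sex = covariate_distance_matrix(sex, "binary_mismatch", ids))
  fit <- fit_distance_regression(brain_distance_matrix(maps), xs, names(xs),
                                 permutations = permutations, perm_term = 1L,
                                 seed = seed + 13L)
  list(estimate = fit$terms$estimate[1L], t = fit$terms$t[1L],
       p = fit$terms$p[1L], p_perm = fit$p_perm)
}
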