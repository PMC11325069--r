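# Plain-text serialization of stage artifacts. Every writer is
# deterministic (fixed column order, fixed numeric formatting), so a cohort
# generated twice from the same config serializes byte-identically.

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) if (is.double(col)) fmt_num(col) else col)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a numeric matrix as TSV
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(matrix(fmt_num(m), nrow(m), ncol(m)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a numeric matrix from TSV
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Write a community partition as TSV (node, community) with a JSON sidecar
#' @param partition A [community_partition()].
#' @param path TSV path; the sidecar is written next to it as `<path>.json`.
#' @export
write_partition <- function(partition, path) {
  write_tsv(data.frame(node = seq_along(partition$labels),
                       community = partition$labels), path)
  jsonlite::write_json(
    list(q = partition$q, n_runs = partition$n_runs, seed = partition$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
}

#' Read a community partition written by [write_partition()]
#' @param path TSV path.
#' @return A [community_partition()].
#' @export
read_partition <- function(path) {
  df <- read.delim(path)
  meta_path <- paste0(path, ".json")
  q <- NA_real_; n_runs <- NA_integer_; seed <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$q)) q <- as.numeric(meta$q)
    if (!is.null(meta$n_runs)) n_runs <- as.integer(meta$n_runs)
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
  }
  community_partition(df$community[order(df$node)], q = q,
                      n_runs = n_runs, seed = seed)
}

#' Write a binary network as an edge-list TSV with a JSON sidecar
#' @param network A `binary_network`.
#' @param path TSV path; sidecar written as `<path>.json`.
#' @export
write_network <- function(network, path) {
  write_tsv(data.frame(node_i = network$edges[, 1L],
                       node_j = network$edges[, 2L]), path)
  jsonlite::write_json(
    list(n_nodes = network$n_nodes, k_target = network$k_target,
         s_value = network$s_value,
         density = 2 * nrow(network$edges) / (network$n_nodes * (network$n_nodes - 1))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
}

#' Read a binary network written by [write_network()]
#' @param path TSV path.
#' @return A `binary_network`.
#' @export
read_network <- function(path) {
  df <- read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  binary_network(as.integer(meta$n_nodes),
                 cbind(i = df$node_i, j = df$node_j),
                 k_target = as.numeric(meta$k_target),
                 s_value = if (is.null(meta$s_value)) NA_real_ else as.numeric(meta$s_value))
}

#' Serialize a synthetic cohort to a directory
#'
#' Writes `covariates.tsv` (subject_id, cs, sex, volumes_removed),
#' `true_partition.tsv` for the planted template partition, `config.json`,
#' and per subject `timeseries_<id>.tsv` / `motion_<id>.tsv` /
#' `partition_<id>.tsv` (the subject's jittered partition).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    cs = vapply(cohort$subjects, function(s) s$covariates$cs, numeric(1)),
    sex = vapply(cohort$subjects, function(s) s$covariates$sex, numeric(1)),
    volumes_removed = vapply(cohort$subjects,
                             function(s) s$covariates$volumes_removed, numeric(1))
  )
  write_tsv(cov, file.path(dir, "covariates.tsv"))
  write_partition(cohort$base_partition, file.path(dir, "true_partition.tsv"))
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in cohort$subjects) {
    write_matrix_tsv(s$timeseries, file.path(dir, sprintf("timeseries_%s.tsv", s$subject_id)))
    write_matrix_tsv(s$motion_params, file.path(dir, sprintf("motion_%s.tsv", s$subject_id)))
    write_partition(s$true_partition, file.path(dir, sprintf("partition_%s.tsv", s$subject_id)))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  cov <- read.delim(file.path(dir, "covariates.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(cohort_config, cfg[setdiff(names(cfg), character(0))])
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    id <- cov$subject_id[i]
    structure(list(
      subject_id = id,
      covariates = list(cs = cov$cs[i], sex = cov$sex[i],
                        volumes_removed = cov$volumes_removed[i]),
      timeseries = read_matrix_tsv(file.path(dir, sprintf("timeseries_%s.tsv", id))),
      motion_params = read_matrix_tsv(file.path(dir, sprintf("motion_%s.tsv", id))),
      true_partition = read_partition(file.path(dir, sprintf("partition_%s.tsv", id)))
    ), class = "subject_record")
  })
  structure(list(subjects = subjects,
                 base_partition = read_partition(file.path(dir, "true_partition.tsv")),
                 config = config),
            class = "cohort")
}

#' Write SI maps for a set of subjects as a wide TSV (node x subject)
#' @param maps List of `si_map`s.
#' @param path Output path.
#' @export
write_si_maps <- function(maps, path) {
  vals <- t(si_values_matrix(maps))
  ids <- vapply(maps, function(m) as.character(m$subject_id), character(1))
  df <- cbind(data.frame(node = seq_len(nrow(vals))),
              as.data.frame(vals))
  names(df) <- c("node", ids)
  write_tsv(df, path)
}
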