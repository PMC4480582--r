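#' Read a cells-by-species observation table
#'
#' CSV or TSV with a header row of variable names, one row per cell.
#' Delimiter is inferred from the extension (`.tsv`/`.txt` = tab).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_observations <- function(path) {
  if (!file.exists(path))
    stop("observation file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- tibble::as_tibble(read.csv(path, sep = sep, check.names = FALSE))
  if (nrow(out) == 0 || ncol(out) == 0)
    stop("observation file ", path, " is empty", call. = FALSE)
  out
}

#' Serialise a trace to JSON lines
#'
#' One JSON record per retained sample (iteration, number of components,
#' allocation, per-component adjacencies), human-readable and
#' diff-friendly.
#'
#' @param fit An `unpbn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in fit$samples) {
    rec <- list(iteration = s$iteration, n_components = s$n_components,
                allocation = s$allocation,
                dags = lapply(s$dags, function(a) unname(as.matrix(a))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Run manifest for bit-identical reproduction
#'
#' Records the configuration, seed, package version and a checksum of the
#' input data; two runs with identical manifests produce identical outputs.
#'
#' @param config An [mcmc_config()] (or any list of settings).
#' @param data The input data.
#' @param extra Optional named list of additional settings.
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(config, data, extra = list()) {
  cfg <- unclass(config)
  cfg$move_probabilities <- as.list(cfg$move_probabilities)
  c(list(package_version = as.character(utils::packageVersion("unpbn")),
         data_checksum = digest::digest(as_data_matrix(data)),
         config = cfg),
    extra)
}
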