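#' Write spike trains as a tab-separated table
#'
#' One row per spike: `cell_id<TAB>time_s`. A JSON sidecar (same path with
#' `.json` appended) records the run configuration and seed.
#'
#' @param result A `simulation_result` or `session_dataset`.
#' @param path Output TSV path.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spike_tsv <- function(result, path, sidecar = TRUE) {
  st <- result$spike_times
  df <- data.frame(
    cell_id = rep(seq_along(st), lengths(st)),
    time_s = unlist(st, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- result$config
    if (is.null(meta))
      meta <- result[setdiff(names(result), "spike_times")]
    meta <- unclass(meta)
    meta$cell <- unclass(meta$cell)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read spike trains from a tab-separated table
#'
#' @param path TSV with columns `cell_id`, `time_s`.
#' @param n_cells Total cell count (defaults to the largest id present).
#' @return List of per-cell spike-time vectors.
#' @export
read_spike_tsv <- function(path, n_cells = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_cells)) n_cells <- max(df$cell_id)
  lapply(seq_len(n_cells), function(i) sort(df$time_s[df$cell_id == i]))
}

#' Write a feature table as CSV
#' @param features Feature data frame from [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feature_csv <- function(path) utils::read.csv(path)
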