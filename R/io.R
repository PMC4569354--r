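#' Read an event-marker list from TSV
#'
#' Two-column TSV (`time_s`, `label`); times must be ascending.
#'
#' @param path TSV file.
#' @return A tibble with `time_s` (numeric) and `label`.
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("marker TSV must have columns 'time_s' and 'label'")
  if (is.unsorted(df$time_s)) stop("marker times must be sorted ascending")
  tibble::as_tibble(df)
}

#' Save / load an epoched recording
#'
#' The container is the in-memory `epoched_recording` object serialized
#' with R's native format; the geometry, sampling rate and epoch structure
#' travel with the data.
#'
#' @param rec An `epoched_recording`.
#' @param path File path.
#' @return `write_recording` returns the path invisibly; `read_recording`
#'   the recording.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "epoched_recording")) stop("not an epoched_recording file")
  rec
}

#' Write a graph-measures table as TSV
#' @param measures Tibble from [graph_measures()] / [run_pipeline()].
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_measures <- function(measures, path) {
  utils::write.table(measures, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a stat/cluster result as JSON
#' @param result A `stat_result` or `cluster_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_stat_result <- function(result, path) {
  df <- as.data.frame(tidy_result(result))
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

tidy_result <- function(x) {
  out <- tibble::as_tibble(x)
  list_cols <- vapply(out, is.list, logical(1))
  for (nm in names(out)[list_cols])
    out[[nm]] <- vapply(out[[nm]], function(v)
      paste(if (is.matrix(v)) apply(v, 1, paste, collapse = "-")
            else as.character(v), collapse = ","), character(1))
  out
}
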