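# Plain-text interchange: tracks and scores as TSV, planted truth as JSON.

#' Write / read marker tracks as TSV
#'
#' Dialect: tab-separated with header
#' `trial_id  marker_id  time_s  x  y`.
#'
#' @param tracks named list of marker-track data frames (one trial), or a
#'   single data frame.
#' @param file path.
#' @param trial_id trial identifier stored in the first column.
#' @export
write_tracks <- function(tracks, file, trial_id = "t1") {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(trial_id = trial_id, marker_id = tr$marker_id,
               time_s = tr$time_s, x = tr$x, y = tr$y,
               stringsAsFactors = FALSE)))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_tracks
#' @return `read_tracks` returns a named list of marker-track data frames
#'   per trial.
#' @export
read_tracks <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("trial_id", "marker_id", "time_s", "x", "y")
  if (!all(need %in% names(df)))
    stop("tracks file must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$trial_id), function(tr)
    lapply(split(tr, tr$marker_id), function(m)
      m[order(m$time_s), c("marker_id", "time_s", "x", "y")]))
}

#' Write planted ground truth as a JSON sidecar
#'
#' @param truth the `truth` component of a [simulate_trace()] result.
#' @param file path.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Write a per-trial score table as TSV
#'
#' @param scores score table.
#' @param file path.
#' @export
write_scores <- function(scores, file) {
  utils::write.table(scores, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
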