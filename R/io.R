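#' Write / read a history matrix as wide CSV
#'
#' One row per cell: `cell_id`, then one column per timepoint named
#' `t=<hours>`.
#'
#' @param histories cells x timepoints matrix with time colnames.
#' @param path output CSV path.
#' @export
write_histories_csv <- function(histories, path) {
  df <- data.frame(cell_id = rownames(histories), histories,
                   check.names = FALSE)
  names(df)[-1] <- paste0("t=", colnames(histories))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histories_csv
#' @return For the reader, a list with `histories` and `time`.
#' @export
read_histories_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  time <- as.numeric(sub("^t=", "", colnames(m)))
  colnames(m) <- signif(time, 10)
  list(histories = m, time = time)
}

#' Write / read a detection table as TSV
#' @param detections data.frame (frame, detection_id, x, y, division_class).
#' @param path file path.
#' @export
write_detections_tsv <- function(detections, path) {
  utils::write.table(detections, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_tsv
#' @export
read_detections_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a lineage (track table) as JSON
#' @param trackset a `track_set`.
#' @param path file path.
#' @export
write_lineage_json <- function(trackset, path) {
  jsonlite::write_json(list(tracks = trackset$tracks,
                            assignments = trackset$assignments),
                       path, dataframe = "columns", na = "null")
  invisible(path)
}
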