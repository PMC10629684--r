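# delimited-text interchange: header row, optional '#' comment metadata

#' Read and write delimited data streams
#'
#' Beat series, point series and observation tables are interchanged as
#' UTF-8 tab-separated text with a header row; lines starting with `#`
#' carry free-form metadata (run id, parameters) and are skipped on read.
#'
#' @param x Object to write.
#' @param path File path.
#' @param comment Character vector of metadata lines (written prefixed with
#'   `"# "`).
#' @return `path` invisibly for writers; a tibble for readers.
#' @export
write_beats <- function(x, path, comment = character()) {
  stopifnot(is.data.frame(x), "beat_ms" %in% names(x))
  write_tsv_commented(tibble(time_ms = x$beat_ms), path, comment)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  out <- tibble(beat_ms = d$time_ms)
  class(out) <- c("vt_beats", class(out))
  out
}

#' @rdname write_beats
#' @export
write_observation_table <- function(x, path, comment = character()) {
  write_tsv_commented(x, path, comment)
}

#' @rdname write_beats
#' @export
read_observation_table <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  class(out) <- c("vt_obs", class(out))
  out
}

write_tsv_commented <- function(x, path, comment) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
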