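## Trial-table I/O.  One canonical CSV schema is shared by the synthetic
## generator and (via a column mapping documented in the README) externally
## recorded data: participant, task, location_cm, trial, raw_response,
## response_units.

trials_columns <- c("participant", "task", "location_cm", "trial",
                    "raw_response", "response_units")

#' Read a trial table from CSV
#'
#' Validates the canonical schema; malformed rows are reported by number.
#'
#' @param path CSV file path.
#' @return data frame of trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trials_columns, names(df))
  if (length(missing))
    stop(sprintf("trial file lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) {
    warning("empty trial file")
    return(df)
  }
  bad_task <- which(!df$task %in% c("image", "space"))
  if (length(bad_task))
    stop(sprintf("unknown task label in row(s): %s",
                 paste(utils::head(bad_task, 10), collapse = ", ")))
  for (col in c("location_cm", "trial", "raw_response")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric '%s' in row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write a trial table to CSV
#'
#' @param trials data frame of trial records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  missing <- setdiff(trials_columns, names(trials))
  if (length(missing))
    stop(sprintf("trial table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  utils::write.csv(trials[trials_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a results object as JSON
#'
#' @param object a list or data frame of results.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary <- function(object, path) {
  jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
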