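# Small plain-text I/O helpers for the tabular interfaces.

#' Read a confound table (TSV, one column per regressor, header row)
#'
#' @param path File path.
#' @return Numeric matrix with one row per time point.
#' @export
read_confounds <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write / read a cohort table as CSV
#'
#' @param table Cohort data frame (e.g. \code{gen_bold_cohort(...)$table}).
#' @param path File path.
#' @return \code{write_cohort_table} returns \code{path} invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a sliding HRV track as TSV
#'
#' @param track A \code{sliding_hrv}.
#' @param path File path.
#' @export
write_sliding_hrv <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
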