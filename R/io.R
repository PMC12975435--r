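#' Read and write feature / outcome tables as CSV
#'
#' Plain CSV with a header row; feature tables carry `patient_id` and
#' `batch` columns ahead of the feature columns.
#'
#' @param table data.frame; @param path file path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_feature_table
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_outcome_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
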