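# FeatureTable convention: a numeric matrix, patients in rows (row names =
# patient IDs), features in columns, with an optional "family" attribute
# (named character vector, one family tag per feature).

#' Write a patient-by-feature table as CSV
#'
#' Patient IDs go in the first column (`patient_id`), one feature per
#' remaining column, header row included.
#'
#' @param features numeric matrix with row names (patient IDs).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  df <- data.frame(patient_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a patient-by-feature CSV written by [write_feature_table()]
#'
#' @param path CSV path; first column must hold patient IDs.
#' @return numeric matrix with patient-ID row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

feature_family <- function(features) {
  fam <- attr(features, "family")
  if (is.null(fam)) fam <- stats::setNames(rep(NA_character_,
                                               ncol(features)),
                                           colnames(features))
  fam
}
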