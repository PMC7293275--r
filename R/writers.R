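## Plain-text writers for the remaining synthetic-cohort artifacts.

#' Write cohort metadata as CSV
#' @param metadata Metadata data.frame from [simulateVariantCohort()].
#' @param path Output path.
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Write genotyping-array calls as CSV
#' @param arrayCalls data.frame from [simulateArrayGenotypes()].
#' @param path Output path.
#' @export
writeArrayCalls <- function(arrayCalls, path) {
  requireColumns(arrayCalls, c("sample", "chrom", "pos", "ref", "alt",
                               "arrayAf"), "array call table")
  utils::write.csv(arrayCalls, path, row.names = FALSE)
  invisible(path)
}

#' Write a mutation catalog as CSV
#' @param catalog A [MutationCatalog-class].
#' @param path Output path.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "MutationCatalog"))
  utils::write.csv(data.frame(sample = rownames(catalogCounts(catalog)),
                              catalogCounts(catalog), check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a mutation catalog from CSV
#' @param path CSV with a `sample` column and 96 channel columns.
#' @return A [MutationCatalog-class].
#' @export
readCatalog <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  MutationCatalog(m)
}

#' Write simulation ground truth as JSON
#' @param truth The `truth` element of [simulateVariantCohort()].
#' @param path Output path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", matrix = "rowmajor",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
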