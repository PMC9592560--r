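# Plain-text readers and writers for the formats the pipeline exchanges.

#' Read a dense gene x sample expression table
#'
#' Expects a TSV/CSV with a header of sample ids and gene ids in the first
#' column.
#'
#' @param path File path; the separator is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param platform Platform tag for the resulting `expr_matrix`.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, platform = "rnaseq-counts") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expr_matrix(as.matrix(df), platform = platform)
}

#' Write a stem cell index result table with a JSON parameter sidecar
#'
#' @param results Data frame from [stem_cell_index()].
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_index <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- paste0(path, ".params.json")
  jsonlite::write_json(list(params = unclass(attr(results, "params")),
                            cohort = attr(results, "cohort")),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a single-cell count matrix from MatrixMarket triplet files
#'
#' @param mtx,features,barcodes Paths to the `.mtx` count file and the
#'   one-column (or first-column) feature and barcode TSVs.
#' @return A sparse `dgCMatrix` with feature rownames and barcode
#'   colnames.
#' @export
read_cell_counts <- function(mtx, features, barcodes) {
  m <- Matrix::readMM(mtx)
  feat <- utils::read.table(features, sep = "\t",
                            stringsAsFactors = FALSE)[[1]]
  bc <- utils::read.table(barcodes, sep = "\t",
                          stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feat) || ncol(m) != length(bc))
    stop("matrix dimensions do not match features/barcodes")
  dimnames(m) <- list(feat, bc)
  methods::as(m, "CsparseMatrix")
}

#' Write a single-cell count matrix as MatrixMarket triplet files
#'
#' @param counts Gene x cell matrix.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_counts <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
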