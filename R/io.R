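#' Write a count matrix as MatrixMarket with sidecar gene/cell tables
#'
#' Writes `matrix.mtx` (1-based coordinate triplets), `genes.tsv` and
#' `cells.tsv` into `dir`. The sidecars are one identifier per line; cell
#' metadata columns, if supplied, are written alongside the cell IDs.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @param cell_meta optional data.frame with one row per cell.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir, cell_meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  if (is.null(cell_meta)) {
    writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  } else {
    stopifnot(nrow(cell_meta) == ncol(counts))
    write.table(cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return list with `counts` (dense genes x cells matrix) and `cell_meta`
#'   (data.frame, or NULL when the cells sidecar is a bare ID list).
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells_path <- file.path(dir, "cells.tsv")
  first <- readLines(cells_path, n = 1)
  cell_meta <- NULL
  if (grepl("\t", first)) {
    cell_meta <- read.table(cells_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    cells <- cell_meta[[1]]
  } else {
    cells <- readLines(cells_path)
  }
  dimnames(m) <- list(genes, cells)
  storage.mode(m) <- "integer"
  list(counts = m, cell_meta = cell_meta)
}

#' Write a count matrix as a dense TSV (genes in rows, header = cell IDs)
#' @param counts genes x cells matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a dense TSV count matrix written by [write_counts_tsv()]
#' @param path input file.
#' @return genes x cells integer matrix.
#' @export
read_counts_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' Serialize a ground-truth list to JSON
#' @param truth the `truth` element of a `synthetic_counts` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$spec <- unclass(truth$spec)
  truth$mean_matrix <- if (!is.null(truth$mean_matrix)) {
    list(genes = rownames(truth$mean_matrix),
         types = colnames(truth$mean_matrix),
         values = unname(apply(truth$mean_matrix, 2, as.vector, simplify = FALSE)))
  }
  # named atomic vectors must become lists, or jsonlite drops their names
  for (nm in names(truth)) {
    v <- truth[[nm]]
    if (is.atomic(v) && !is.null(names(v))) truth[[nm]] <- as.list(v)
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
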