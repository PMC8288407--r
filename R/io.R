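#' Write / read a count matrix as MatrixMarket + TSV sidecars
#'
#' Counts are stored genes x cells in `\<prefix\>matrix.mtx` (sparse
#' MatrixMarket) with `\<prefix\>genes.tsv` and `\<prefix\>cells.tsv`
#' sidecars, the common exchange layout for single-cell matrices.  The
#' in-memory orientation of this package (cells as rows) is restored on
#' read.
#'
#' @param counts Cells x genes matrix.
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return `write_count_matrix()`: the directory, invisibly;
#'   `read_count_matrix()`: a cells x genes base matrix.
#' @export
write_count_matrix <- function(counts, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, paste0(prefix, "matrix.mtx")))
  writeLines(colnames(counts), file.path(dir, paste0(prefix, "genes.tsv")))
  writeLines(rownames(counts), file.path(dir, paste0(prefix, "cells.tsv")))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir, prefix = "") {
  m <- Matrix::readMM(file.path(dir, paste0(prefix, "matrix.mtx")))
  genes <- readLines(file.path(dir, paste0(prefix, "genes.tsv")))
  cells <- readLines(file.path(dir, paste0(prefix, "cells.tsv")))
  out <- t(as.matrix(m))
  dimnames(out) <- list(cells, genes)
  out
}

#' Write a simulated atlas to plain-text files
#'
#' Emits the full input bundle of the pipeline: MTX counts with sidecars,
#' cell metadata TSV, BED-like annotation, conservation TSV, GMT-like
#' regulons and a JSON ground-truth record.
#'
#' @param sim `abc_sim` object from [simulate_atlas()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_atlas <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$counts, dir)
  utils::write.table(sim$cells, file.path(dir, "cells_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_annotation_bed(sim$annotation, file.path(dir, "annotation.bed"))
  utils::write.table(
    data.frame(gene_id = names(sim$conservation),
               score = unname(sim$conservation)),
    file.path(dir, "conservation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$regulons$regulons, file.path(dir, "regulons.gmt"))
  writeLines(sim$regulons$canonical_tfs, file.path(dir, "canonical_tfs.txt"))
  jsonlite::write_json(sim$truth[c("annotation", "signature_plan")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
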