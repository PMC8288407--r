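#' Construct a gene-model table
#'
#' A gene-model set is a plain `data.frame` describing gene bodies as
#' genomic intervals in 0-based half-open coordinates, with a `biotype`
#' column separating protein-coding genes from lncRNAs.  It is the
#' substrate of the <5 kb adjacency scan ([adjacency_scan()]).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param start,end Integer interval bounds, 0-based half-open
#'   (`0 <= start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @param biotype `"coding"` or `"lncRNA"` per gene.
#' @return A validated `data.frame` with one row per gene.
#' @export
gene_model_set <- function(gene_id, chrom, start, end, strand, biotype) {
  ann <- data.frame(
    gene_id = as.character(gene_id),
    chrom   = as.character(chrom),
    start   = as.integer(start),
    end     = as.integer(end),
    strand  = as.character(strand),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  validate_gene_models(ann)
  ann
}

#' Validate a gene-model table
#'
#' @param ann A gene-model `data.frame` as built by [gene_model_set()].
#' @return `ann`, invisibly, after checking interval sanity, unique ids,
#'   strand and biotype domains.
#' @export
validate_gene_models <- function(ann) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (any(ann$start < 0L) || any(ann$start >= ann$end))
    stop("invalid interval(s): require 0 <= start < end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(ann$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'")
  invisible(ann)
}

#' Write / read gene models as BED-like text
#'
#' BED6 columns (chrom, start, end, name, score, strand) plus the biotype
#' in a 7th column; coordinates stay 0-based half-open as in BED.
#'
#' @param ann Gene-model `data.frame`.
#' @param path Output (or input) file path.
#' @return `write_annotation_bed()` returns `path` invisibly;
#'   `read_annotation_bed()` returns a validated gene-model `data.frame`.
#' @export
write_annotation_bed <- function(ann, path) {
  validate_gene_models(ann)
  out <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id,
                    0L, ann$strand, ann$biotype)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 7L) stop("expected 7 columns (BED6 + biotype) in ", path)
  gene_model_set(gene_id = raw[[4]], chrom = raw[[1]], start = raw[[2]],
                 end = raw[[3]], strand = raw[[6]], biotype = raw[[7]])
}
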