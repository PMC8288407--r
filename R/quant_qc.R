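#' Collapse UMI-level reads to a distinct-UMI count matrix
#'
#' The count of a gene in a cell is the number of *distinct* UMI strings
#' observed for that (cell, gene) pair; duplicate rows carrying the same
#' UMI collapse to one molecule.
#'
#' @param reads A `data.frame`/`data.table` with columns `cell_id`,
#'   `gene_id`, `umi`.
#' @param strict If `TRUE` (default) malformed rows (empty or missing
#'   fields) are a fatal error naming the offending row indices; otherwise
#'   they are dropped with a warning.
#' @return Integer cells x genes matrix (rows = cells, columns = genes),
#'   both axes sorted; empty input gives a 0 x 0 matrix.
#' @export
count_umis <- function(reads, strict = TRUE) {
  reads <- data.table::as.data.table(reads)
  need <- c("cell_id", "gene_id", "umi")
  if (!all(need %in% names(reads)))
    stop("reads must have columns cell_id, gene_id, umi")
  if (nrow(reads) == 0L)
    return(matrix(0L, 0L, 0L))
  bad <- which(is.na(reads$cell_id) | is.na(reads$gene_id) | is.na(reads$umi) |
               reads$cell_id == "" | reads$gene_id == "" | reads$umi == "")
  if (length(bad)) {
    msg <- paste0("malformed read row(s): ",
                  paste(utils::head(bad, 10L), collapse = ", "),
                  if (length(bad) > 10L) " ...")
    if (strict) stop(msg)
    warning(msg, "; dropped")
    reads <- reads[-bad]
  }
  cell_id <- gene_id <- umi <- NULL # appease R CMD check
  cnt <- unique(reads, by = need)[, list(n = .N), by = list(cell_id, gene_id)]
  cells <- sort(unique(cnt$cell_id))
  genes <- sort(unique(cnt$gene_id))
  m <- matrix(0L, length(cells), length(genes),
              dimnames = list(cells, genes))
  m[cbind(match(cnt$cell_id, cells), match(cnt$gene_id, genes))] <-
    as.integer(cnt$n)
  m
}

#' Lineage-aware cell quality filter
#'
#' Retains a cell when (i) its mapping rate is not below its lineage
#' family's threshold (strict "discard under X%": 10% HSPC/monocyte, 5%
#' B/NK/neutrophil/erythrocyte, 2.5% T) and (ii) strictly more than
#' `min_coding` protein-coding genes (for the coding matrix) or strictly
#' more than `min_lnc` lncRNAs (for the lncRNA matrix) are detected
#' (count > 0).  The coding-retained and lncRNA-retained cell sets are
#' computed and reported separately; they generally differ.
#'
#' @param counts Cells x genes integer matrix covering both biotypes.
#' @param cells Cell metadata with `cell_id`, `cell_type`, `mapping_rate`.
#' @param biotype Character vector (`"coding"`/`"lncRNA"`) per column of
#'   `counts`.
#' @param min_coding,min_lnc Strict detection cut-offs (defaults 1000 and
#'   500 detected genes).
#' @param thresholds Named mapping-rate thresholds per family (default
#'   [family_mapping_thresholds()]).
#' @param type_table Cell-type/family lookup (default [abc_cell_types()]).
#' @return List of class `abc_qc`: `coding` and `lncrna` (filtered
#'   biotype-specific count matrices), `report` (per-cell `data.frame`
#'   with the individual rule outcomes) and `summary` (counts removed per
#'   rule and retained per biotype).
#' @export
qc_filter <- function(counts, cells, biotype, min_coding = 1000L,
                      min_lnc = 500L, thresholds = family_mapping_thresholds(),
                      type_table = abc_cell_types()) {
  stopifnot(nrow(counts) == nrow(cells),
            ncol(counts) == length(biotype))
  fam <- cell_family(cells$cell_type, type_table)
  if (anyNA(thresholds[fam]))
    stop("no mapping-rate threshold for family: ",
         paste(unique(fam[is.na(thresholds[fam])]), collapse = ", "))
  map_pass <- cells$mapping_rate >= thresholds[fam]
  cod <- counts[, biotype == "coding", drop = FALSE]
  lnc <- counts[, biotype == "lncRNA", drop = FALSE]
  det_cod <- rowSums(cod > 0)
  det_lnc <- rowSums(lnc > 0)
  cod_pass <- map_pass & det_cod > min_coding
  lnc_pass <- map_pass & det_lnc > min_lnc
  report <- data.frame(
    cell_id = cells$cell_id, cell_type = cells$cell_type, family = fam,
    mapping_rate = cells$mapping_rate, mapping_pass = map_pass,
    detected_coding = det_cod, detected_lncrna = det_lnc,
    coding_retained = cod_pass, lncrna_retained = lnc_pass,
    stringsAsFactors = FALSE
  )
  structure(list(
    coding = cod[cod_pass, , drop = FALSE],
    lncrna = lnc[lnc_pass, , drop = FALSE],
    report = report,
    summary = list(
      n_cells = nrow(cells),
      removed_mapping = sum(!map_pass),
      removed_coding_detection = sum(map_pass & det_cod <= min_coding),
      removed_lncrna_detection = sum(map_pass & det_lnc <= min_lnc),
      retained_coding = sum(cod_pass),
      retained_lncrna = sum(lnc_pass)
    )
  ), class = "abc_qc")
}

#' log2(TPM/10 + 1) normalization
#'
#' Counts are converted per cell to transcripts-per-million over the gene
#' set of the supplied matrix (so coding and lncRNA matrices are
#' normalized within their own biotype when analyzed separately), divided
#' by 10 and log2(x + 1)-transformed.  A zero count maps exactly to 0.
#'
#' @param counts Cells x genes count matrix; every cell must have total
#'   count > 0 (zero-total cells should have been removed by
#'   [qc_filter()] and are a fatal error here).
#' @return Numeric matrix of the same shape.
#' @export
normalize_log2tpm10 <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(rownames(counts)[tot <= 0], 5L), collapse = ", "))
  log2(counts / tot * 1e6 / 10 + 1)
}

#' Per-cell-type detected-gene statistics
#'
#' A gene is detected in a cell when its count is > 0.  Summaries are the
#' per-type distribution of the per-cell detected-gene numbers.
#'
#' @param counts Cells x genes count matrix.
#' @param cells Cell metadata aligned with the rows of `counts`.
#' @return `data.frame` with one row per cell type: `n`, `mean`, `median`,
#'   `q25`, `q75` of detected genes, ordered by decreasing mean.
#' @export
detection_stats <- function(counts, cells) {
  stopifnot(nrow(counts) == nrow(cells), nrow(counts) > 0L)
  det <- rowSums(counts > 0)
  sp <- split(det, cells$cell_type)
  out <- data.frame(
    cell_type = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    median = vapply(sp, stats::median, numeric(1)),
    q25 = vapply(sp, function(x) unname(stats::quantile(x, 0.25)), numeric(1)),
    q75 = vapply(sp, function(x) unname(stats::quantile(x, 0.75)), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  out
}
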