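#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2` with Shannon entropy in
#' bits, so the result lies in \[0, 1\], is symmetric, and is 0 iff
#' `p == q`.
#'
#' @param p,q Non-negative probability vectors of equal length, each
#'   summing to 1 within 1e-9.
#' @return The divergence, a scalar in \[0, 1\].
#' @export
#' @examples
#' jsd(c(0.5, 0.5), c(1, 0))  # 0.311278
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("probability vectors must sum to 1")
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  H((p + q) / 2) - (H(p) + H(q)) / 2
}

#' Cell-specificity scores from Jensen-Shannon divergence
#'
#' For every gene, the per-type mean expression profile is normalized to
#' a probability vector `e` and scored against the one-hot "ideal"
#' profile of each type `t`: `score(g, t) = 1 - sqrt(JSD(e, onehot_t))`.
#' A gene expressed in exactly one type scores 1 there; a flat gene
#' scores low everywhere.  Genes with zero mean expression in every type
#' are flagged `NA`.
#'
#' @param norm Normalized cells x genes matrix.
#' @param cells Cell metadata aligned with the rows of `norm` (>= 2 types
#'   required).
#' @return List of class `specificity_table`: `scores` (genes x types),
#'   `max_score`, `argmax_type` (both per gene).
#' @export
specificity_scores <- function(norm, cells) {
  types <- sort(unique(cells$cell_type))
  if (length(types) < 2L) stop("need >= 2 cell types")
  grp <- factor(cells$cell_type, levels = types)
  M <- rowsum(norm, grp) / as.vector(table(grp))   # types x genes means
  tot <- colSums(M)
  ok <- tot > 0
  E <- sweep(M, 2, ifelse(ok, tot, 1), "/")        # per-gene profile, sums 1
  h <- function(x) ifelse(x > 0, -x * log2(x), 0)
  He <- colSums(h(E))                              # entropy of profile
  A <- colSums(h(E / 2))                           # sum of h(e_s / 2)
  # JSD(e, onehot_t) = [A - h(e_t/2) + h((e_t+1)/2)] - He/2
  Jt <- sweep(-h(E / 2) + h((E + 1) / 2), 2, A, "+")
  Jt <- sweep(Jt, 2, He / 2, "-")
  S <- t(1 - sqrt(pmax(Jt, 0)))                    # genes x types
  S[!ok, ] <- NA_real_
  ms <- apply(S, 1, function(r) if (all(is.na(r))) NA_real_ else max(r))
  am <- apply(S, 1, function(r) if (all(is.na(r))) NA_character_
              else types[which.max(r)])
  structure(list(scores = S, max_score = ms, argmax_type = am),
            class = "specificity_table")
}

#' Scan lncRNA-coding adjacency within a distance cut-off
#'
#' For every lncRNA, finds the protein-coding genes on the same
#' chromosome whose gene-body interval lies strictly less than `max_dist`
#' bp away (overlap counts as gap 0; strand is ignored).  Gaps are
#' measured between interval hulls under the annotation's 0-based
#' half-open coordinates.
#'
#' @param ann Gene-model `data.frame` containing both biotypes.
#' @param max_dist Strict distance cut-off in bp (default 5000).
#' @return `data.frame` of class `adjacency_map` with columns `lnc_id`,
#'   `coding_id`, `gap_bp`; zero rows when nothing is adjacent.
#' @export
adjacency_scan <- function(ann, max_dist = 5000L) {
  validate_gene_models(ann)
  lnc <- ann[ann$biotype == "lncRNA", , drop = FALSE]
  cod <- ann[ann$biotype == "coding", , drop = FALSE]
  empty <- data.frame(lnc_id = character(0), coding_id = character(0),
                      gap_bp = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("adjacency_map", "data.frame")
  if (!nrow(lnc) || !nrow(cod)) return(empty)
  gr <- function(d) GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(start = d$start + 1L, end = d$end))
  gl <- gr(lnc); gc <- gr(cod)
  hits <- GenomicRanges::findOverlaps(gl, gc, maxgap = max_dist - 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(gl[i], gc[j], ignore.strand = TRUE)
  out <- data.frame(lnc_id = lnc$gene_id[i], coding_id = cod$gene_id[j],
                    gap_bp = as.integer(gap), stringsAsFactors = FALSE)
  out <- out[order(out$lnc_id, out$gap_bp, out$coding_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("adjacency_map", "data.frame")
  out
}

#' Proportion of signature lncRNAs adjacent to same-type coding signatures
#'
#' For each cell type, the fraction of its signature lncRNAs that have at
#' least one adjacent protein-coding gene which is itself a coding
#' signature of the same type.  Types without signature lncRNAs are
#' reported `NA`.
#'
#' @param sig_lnc,sig_coding `signature_set` tables ([find_signatures()])
#'   for the lncRNA and coding views; both must use the same type labels.
#' @param adj `adjacency_map` from [adjacency_scan()].
#' @param cell_types Optional explicit type ordering (default: types
#'   present in `sig_lnc`).
#' @return `data.frame` with `cell_type`, `n_signature_lnc`,
#'   `n_adjacent`, `proportion`.
#' @export
signature_adjacency_proportion <- function(sig_lnc, sig_coding, adj,
                                           cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- unique(sig_lnc$cell_type)
  out <- lapply(cell_types, function(ct) {
    lncs <- sig_lnc$gene_id[sig_lnc$cell_type == ct]
    cods <- sig_coding$gene_id[sig_coding$cell_type == ct]
    n <- length(lncs)
    hit <- sum(vapply(lncs, function(l)
      any(adj$coding_id[adj$lnc_id == l] %in% cods), logical(1)))
    data.frame(cell_type = ct, n_signature_lnc = n, n_adjacent = hit,
               proportion = if (n > 0) hit / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare conservation of signature vs background genes
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that signature
#' genes have higher conservation scores than the background set.
#'
#' @param scores Named numeric vector of per-gene conservation scores.
#' @param signature_ids,background_ids Disjoint, non-empty gene-id sets
#'   resolvable in `scores` (overlap is an error).
#' @return List with `median_signature`, `median_background`,
#'   `delta_median`, `U`, `p`.
#' @export
conservation_compare <- function(scores, signature_ids, background_ids) {
  if (!length(signature_ids) || !length(background_ids))
    stop("both gene sets must be non-empty")
  if (length(intersect(signature_ids, background_ids)))
    stop("signature and background sets overlap")
  s <- scores[signature_ids]; b <- scores[background_ids]
  if (anyNA(s) || anyNA(b)) stop("gene id(s) missing from the score table")
  ht <- rank_sum_test(s, b, alternative = "greater")
  list(median_signature = stats::median(s),
       median_background = stats::median(b),
       delta_median = stats::median(s) - stats::median(b),
       U = ht$U, p = ht$p)
}

#' Overlap of coding neighbors of signature lncRNAs with a reference set
#'
#' Hypergeometric upper-tail test for the overlap between the set of
#' protein-coding genes adjacent to signature lncRNAs and a reference
#' gene set (e.g. published hematopoietic signature genes), in a universe
#' of `universe_size` coding genes.
#'
#' @param adj `adjacency_map` from [adjacency_scan()].
#' @param sig_lnc_ids Signature lncRNA ids.
#' @param reference_ids Reference coding gene-id set.
#' @param universe_size Number of coding genes in the universe (must be
#'   at least as large as either set).
#' @return List with `neighbors` (the neighbor gene set), `overlap`, `p`.
#' @export
neighbor_signature_overlap <- function(adj, sig_lnc_ids, reference_ids,
                                       universe_size) {
  nb <- unique(adj$coding_id[adj$lnc_id %in% sig_lnc_ids])
  if (universe_size < length(nb) || universe_size < length(reference_ids))
    stop("universe smaller than one of the gene sets")
  ov <- length(intersect(nb, reference_ids))
  p <- stats::phyper(ov - 1, length(reference_ids),
                     universe_size - length(reference_ids),
                     length(nb), lower.tail = FALSE)
  list(neighbors = nb, overlap = ov, p = p)
}
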