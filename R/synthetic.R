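#' Generate a synthetic gene annotation with planted lncRNA-coding adjacency
#'
#' Lays out `n_coding` protein-coding genes and `n_lnc` lncRNAs along a
#' synthetic chromosome so that exactly `round(coupling_fraction * n_lnc)`
#' lncRNAs sit within `max_dist` (default 5 kb) of a coding gene while every
#' remaining lncRNA is at least `max_dist` away from every coding gene.
#' The genome is organised in blocks anchored on coding genes: each block
#' holds the coding gene, a near zone for coupled lncRNAs (gap drawn
#' uniformly from `0 .. max_dist - 1`) and a far zone for uncoupled
#' lncRNAs, with buffers sized so the far-zone guarantee holds against both
#' flanking coding genes.  Every placement is recorded in the returned
#' truth object so downstream adjacency estimates have an exact target.
#'
#' @param n_coding,n_lnc Number of coding genes / lncRNAs (each >= 1).
#' @param coupling_fraction Fraction of lncRNAs planted adjacent to a
#'   coding gene, in \[0, 1\].
#' @param genome_length Optional total chromosome length; when `NULL` the
#'   minimal feasible length is used.  Too small a value is a sizing error.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param coding_len,lnc_len Length ranges (bp) for coding genes / lncRNAs.
#' @param max_dist Adjacency radius in bp (strict `<` when scanned).
#' @return A list with elements `annotation` (gene-model `data.frame`, see
#'   [gene_model_set()]) and `truth` (list: `coupled_pairs` data.frame with
#'   `lnc_id`, `coding_id`, `gap_bp`; `uncoupled_lnc`; `coupling_fraction`;
#'   `max_dist`; `seed`).
#' @export
gen_annotation <- function(n_coding, n_lnc, coupling_fraction = 0.6,
                           genome_length = NULL, seed = 1L,
                           coding_len = c(500L, 5000L),
                           lnc_len = c(200L, 2000L),
                           max_dist = 5000L) {
  stopifnot(n_coding >= 1L, n_lnc >= 1L,
            coupling_fraction >= 0, coupling_fraction <= 1)
  withr::local_seed(seed)

  n_cpl <- round(coupling_fraction * n_lnc)
  lc <- sample(coding_len[1]:coding_len[2], n_coding, replace = TRUE)
  ll <- sample(lnc_len[1]:lnc_len[2], n_lnc, replace = TRUE)
  max_ll <- lnc_len[2]

  # block anchored at coding gene i:
  #   [coding][near zone: max_dist-1 + max_ll][pad max_dist]
  #   [far zone: jitter 1000 + max_ll][pad max_dist]
  near_w <- (max_dist - 1L) + max_ll
  far_w  <- 1000L + max_ll
  block_w <- lc + near_w + max_dist + far_w + max_dist
  need <- sum(block_w)
  if (is.null(genome_length)) genome_length <- need + 1000L
  if (genome_length < need)
    stop("genome_length ", genome_length, " too small: need at least ", need,
         " bp to place ", n_coding, " coding genes and ", n_lnc,
         " lncRNAs without forced overlap")
  slack <- (genome_length - need) %/% max(n_coding, 1L)
  coding_start <- cumsum(c(0L, (block_w + slack)[-n_coding]))
  coding_end <- coding_start + lc

  lnc_start <- integer(n_lnc)
  gap_bp <- rep(NA_integer_, n_lnc)
  anchor <- (seq_len(n_lnc) - 1L) %% n_coding + 1L
  is_cpl <- seq_len(n_lnc) <= n_cpl
  if (n_cpl > 0L) {
    g <- sample(0:(max_dist - 1L), n_cpl, replace = TRUE)
    lnc_start[is_cpl] <- coding_end[anchor[is_cpl]] + g
    gap_bp[is_cpl] <- g
  }
  if (n_cpl < n_lnc) {
    j <- which(!is_cpl)
    far0 <- coding_end[anchor[j]] + near_w + max_dist
    lnc_start[j] <- far0 + sample(0:1000L, length(j), replace = TRUE)
  }
  lnc_end <- lnc_start + ll

  ids_c <- sprintf("PC%05d", seq_len(n_coding))
  ids_l <- sprintf("LNC%05d", seq_len(n_lnc))
  ann <- gene_model_set(
    gene_id = c(ids_c, ids_l),
    chrom   = "chrS",
    start   = c(coding_start, lnc_start),
    end     = c(coding_end, lnc_end),
    strand  = sample(c("+", "-"), n_coding + n_lnc, replace = TRUE),
    biotype = rep(c("coding", "lncRNA"), c(n_coding, n_lnc))
  )
  truth <- list(
    coupled_pairs = data.frame(
      lnc_id = ids_l[is_cpl],
      coding_id = ids_c[anchor[is_cpl]],
      gap_bp = gap_bp[is_cpl],
      stringsAsFactors = FALSE
    ),
    uncoupled_lnc = ids_l[!is_cpl],
    coupling_fraction = coupling_fraction,
    max_dist = max_dist,
    seed = seed
  )
  list(annotation = ann, truth = truth)
}

#' Plant per-cell-type signature genes into an annotation
#'
#' Chooses disjoint sets of coding and lncRNA signature genes for every
#' cell type.  A fraction `coupling` of each type's signature lncRNAs is
#' drawn from the annotation's coupled pairs, and the coding partner of
#' each such pair is promoted to a coding signature of the same type, so
#' the planted adjacency proportion of [signature_adjacency_proportion()]
#' equals `coupling` up to per-type rounding.  The remaining signature
#' lncRNAs come from the uncoupled pool and therefore have no coding gene
#' within the adjacency radius.
#'
#' @param ann_truth Result of [gen_annotation()] (annotation + truth).
#' @param cell_types Character vector of type labels (default the 32-label
#'   table of [abc_cell_types()]).
#' @param fold_change Planted up-regulation fold for signature genes.
#' @param n_coding_sig Range (length-2 integer) of coding signatures per
#'   type; the per-type count is drawn uniformly from it (default 20-40).
#' @param lnc_ratio Signature lncRNAs per type as a fraction of the type's
#'   coding signature count (floored at 2).
#' @param coupling Fraction of each type's signature lncRNAs planted
#'   adjacent to one of its coding signatures; defaults to the
#'   annotation's global coupling fraction.
#' @param seed Integer seed.
#' @return `signature_plan`: named list (one element per cell type) of
#'   lists with `coding`, `lnc` (gene ids) and `fold_change`.
#' @export
plan_signatures <- function(ann_truth, cell_types = abc_cell_types()$cell_type,
                            fold_change = 5, n_coding_sig = c(20L, 40L),
                            lnc_ratio = 0.5,
                            coupling = ann_truth$truth$coupling_fraction,
                            seed = 1L) {
  withr::local_seed(seed)
  ann <- ann_truth$annotation
  pairs <- ann_truth$truth$coupled_pairs
  # pairs with a unique coding partner, usable as planted couples
  pairs <- pairs[!duplicated(pairs$coding_id), , drop = FALSE]
  free_unc <- ann_truth$truth$uncoupled_lnc
  paired_coding <- pairs$coding_id
  free_coding <- setdiff(ann$gene_id[ann$biotype == "coding"], paired_coding)

  plan <- stats::setNames(vector("list", length(cell_types)), cell_types)
  pair_ptr <- 1L
  sig_range <- n_coding_sig[1]:n_coding_sig[2]
  for (ct in cell_types) {
    m_c <- sig_range[sample.int(length(sig_range), 1L)]
    m_l <- max(2L, round(lnc_ratio * m_c))
    k_cpl <- round(coupling * m_l)
    k_cpl <- min(k_cpl, nrow(pairs) - pair_ptr + 1L, m_c)
    take <- if (k_cpl > 0L) seq.int(pair_ptr, length.out = k_cpl) else integer(0)
    pair_ptr <- pair_ptr + k_cpl

    cod <- pairs$coding_id[take]
    if (length(cod) < m_c) {
      extra <- sample(free_coding, m_c - length(cod))
      free_coding <- setdiff(free_coding, extra)
      cod <- c(cod, extra)
    }
    lnc <- pairs$lnc_id[take]
    if (length(lnc) < m_l) {
      extra <- sample(free_unc, m_l - length(lnc))
      free_unc <- setdiff(free_unc, extra)
      lnc <- c(lnc, extra)
    }
    plan[[ct]] <- list(coding = cod, lnc = lnc, fold_change = fold_change)
  }
  plan
}

#' Generate synthetic cell metadata with planted QC failures
#'
#' @param cell_types Character vector of labels, or a table with columns
#'   `cell_type`/`family` as in [abc_cell_types()].
#' @param n_per_type Cells per type (>= 1).
#' @param n_donors Number of donors labels to draw from (default 21).
#' @param qc_fail_fraction Fraction of cells planted with a mapping rate
#'   strictly below their family threshold (`0 <= f < 1`); exactly
#'   `round(f * n_cells)` cells fail, and the assignment is recorded in
#'   the `planted_qc_fail` column.
#' @param seed Integer seed.
#' @param type_table Family lookup used for thresholds and tissue origin.
#' @return `data.frame` with columns `cell_id`, `donor`, `cell_type`,
#'   `family`, `tissue`, `mapping_rate`, `planted_qc_fail`.
#' @export
gen_cells <- function(cell_types = abc_cell_types(), n_per_type = 50L,
                      n_donors = 21L, qc_fail_fraction = 0,
                      seed = 1L, type_table = abc_cell_types()) {
  stopifnot(n_per_type >= 1L, qc_fail_fraction >= 0, qc_fail_fraction < 1)
  withr::local_seed(seed)
  if (is.data.frame(cell_types)) {
    type_table <- cell_types
    cell_types <- cell_types$cell_type
  }
  n <- length(cell_types) * n_per_type
  ct <- rep(cell_types, each = n_per_type)
  fam <- cell_family(ct, type_table)
  # mature lymphoid populations are peripheral-blood derived, the rest
  # bone-marrow derived
  pb <- c("naive_B", "memory_B", "regulatory_B", "cytotoxic_NK", "cytokine_NK",
          "CD4_naive_T", "CD4_memory_T", "CD4_effector_T",
          "CD8_naive_T", "CD8_memory_T", "CD8_effector_T")
  thr <- family_mapping_thresholds()[fam]
  n_fail <- round(qc_fail_fraction * n)
  fail <- rep(FALSE, n)
  if (n_fail > 0L) fail[sample.int(n, n_fail)] <- TRUE
  rate <- stats::runif(n, 0.2, 0.9)
  rate[fail] <- thr[fail] * stats::runif(sum(fail), 0, 0.95)
  data.frame(
    cell_id = sprintf("cell%05d", seq_len(n)),
    donor = sample(sprintf("D%02d", seq_len(n_donors)), n, replace = TRUE),
    cell_type = ct,
    family = fam,
    tissue = ifelse(ct %in% pb, "peripheral_blood", "bone_marrow"),
    mapping_rate = rate,
    planted_qc_fail = fail,
    stringsAsFactors = FALSE
  )
}

# Negative-binomial distinct-UMI counts: per-gene baseline mean, shared
# dispersion, per-cell capture factor, planted fold change for signature
# genes in their own type.  Cells are rows, genes are columns.
.gen_counts <- function(ann, cells, signature_plan, nb_dispersion = 2,
                        base_meanlog = log(1.3), base_sdlog = 0.3,
                        capture_sdlog = 0.2, seed = 1L) {
  withr::local_seed(seed)
  genes <- ann$gene_id
  n_g <- length(genes)
  n_c <- nrow(cells)
  mu_g <- stats::rlnorm(n_g, base_meanlog, base_sdlog)
  capt <- stats::rlnorm(n_c, 0, capture_sdlog)
  mu <- outer(capt, mu_g)
  for (ct in names(signature_plan)) {
    rows <- which(cells$cell_type == ct)
    if (!length(rows)) next
    pl <- signature_plan[[ct]]
    cols <- match(c(pl$coding, pl$lnc), genes)
    cols <- cols[!is.na(cols)]
    mu[rows, cols] <- mu[rows, cols] * pl$fold_change
  }
  counts <- matrix(stats::rnbinom(n_c * n_g, mu = as.vector(mu),
                                  size = nb_dispersion),
                   nrow = n_c, ncol = n_g,
                   dimnames = list(cells$cell_id, genes))
  counts
}

#' Generate UMI-level synthetic reads
#'
#' Emits one row per sequenced read as `(cell_id, gene_id, umi)`.  The
#' number of distinct UMIs per (cell, gene) follows the same negative
#' binomial model used by [simulate_atlas()]; a configurable fraction of
#' molecules additionally emits duplicate rows carrying the same UMI
#' string, so that distinct-UMI collapsing ([count_umis()]) is exercised.
#'
#' @param ann Gene-model `data.frame`.
#' @param cells Cell metadata from [gen_cells()].
#' @param signature_plan Planted signatures from [plan_signatures()]
#'   (may be an empty list).
#' @param dup_rate Probability that a molecule emits one duplicate read.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @param ... Passed to the internal count sampler (baseline mean etc.).
#' @return `data.table` with columns `cell_id`, `gene_id`, `umi`.
#' @export
gen_reads <- function(ann, cells, signature_plan = list(), dup_rate = 0.1,
                      nb_dispersion = 2, seed = 1L, ...) {
  counts <- .gen_counts(ann, cells, signature_plan,
                        nb_dispersion = nb_dispersion, seed = seed, ...)
  withr::local_seed(seed + 1L)
  nz <- which(counts > 0L, arr.ind = TRUE)
  k <- counts[nz]
  reads <- data.table::data.table(
    cell_id = rep(rownames(counts)[nz[, 1]], k),
    gene_id = rep(colnames(counts)[nz[, 2]], k),
    umi = sprintf("U%06d", unlist(lapply(k, seq_len), use.names = FALSE))
  )
  if (dup_rate > 0) {
    dup <- which(stats::runif(nrow(reads)) < dup_rate)
    if (length(dup)) reads <- rbind(reads, reads[dup])
  }
  data.table::setorder(reads, cell_id, gene_id, umi)
  reads[]
}

#' Generate per-gene conservation scores
#'
#' Scores live in \[0, 1\] (per-gene aggregates of a base-wise conservation
#' track).  Background genes draw from Beta(2, 8); lncRNAs planted as
#' signatures get an additive mean shift of `conservation_shift`, clipped
#' to 1.
#'
#' @param ann Gene-model `data.frame`.
#' @param signature_plan Planted signatures from [plan_signatures()].
#' @param conservation_shift Additive shift (>= 0) for signature lncRNAs.
#' @param seed Integer seed.
#' @return Named numeric vector over all genes in `ann`.
#' @export
gen_conservation <- function(ann, signature_plan, conservation_shift = 0.3,
                             seed = 1L) {
  stopifnot(conservation_shift >= 0)
  withr::local_seed(seed)
  sc <- stats::rbeta(nrow(ann), 2, 8)
  names(sc) <- ann$gene_id
  sig_lnc <- unique(unlist(lapply(signature_plan, `[[`, "lnc")))
  sc[sig_lnc] <- pmin(1, sc[sig_lnc] + conservation_shift)
  sc
}

#' Generate lineage regulons with a recorded novelty truth
#'
#' Builds one regulon per lineage family: the transcription factor is one
#' of the family's planted coding signature genes and the target set is
#' the union of the coding signatures of the family's cell types (TF
#' included), so the regulon's targets are co-ordinately up-regulated in
#' exactly that family's cells.  `n_novel` of the family TFs are withheld
#' from the canonical list, planting a known set of novel regulons.
#'
#' @param signature_plan Planted signatures from [plan_signatures()].
#' @param type_table Cell-type/family table (default [abc_cell_types()]).
#' @param n_novel Number of family TFs excluded from the canonical list.
#' @param seed Integer seed.
#' @return List with `regulons` (named list TF -> target gene ids),
#'   `canonical_tfs`, `novel_tfs` and `regulon_family` (named character:
#'   TF -> lineage family).
#' @export
gen_regulons <- function(signature_plan, type_table = abc_cell_types(),
                         n_novel = 2L, seed = 1L) {
  withr::local_seed(seed)
  fams <- unique(type_table$family)
  regs <- list(); reg_fam <- character(0)
  for (f in fams) {
    types <- intersect(type_table$cell_type[type_table$family == f],
                       names(signature_plan))
    if (!length(types)) next
    targets <- unique(unlist(lapply(signature_plan[types], `[[`, "coding")))
    tf <- targets[1L]
    regs[[tf]] <- targets
    reg_fam[tf] <- f
  }
  tfs <- names(regs)
  n_novel <- min(n_novel, length(tfs))
  novel <- sort(sample(tfs, n_novel))
  list(regulons = regs,
       canonical_tfs = setdiff(tfs, novel),
       novel_tfs = novel,
       regulon_family = reg_fam)
}

#' Default configuration of the synthetic atlas
#'
#' The study conditions the generator emulates: 32 immunophenotypic cell
#' types in 7 lineage families from 21 donors, 2000 protein-coding genes
#' and 1000 lncRNAs (of which 60% are planted within 5 kb of a coding
#' gene), 5-fold planted cell-type signatures (20-40 coding genes per
#' type, about half as many lncRNAs — tens per type, mirroring the
#' hundreds of DEGs that separate real immunophenotypic types once scaled
#' to a 2000-gene genome), conservation scores shifted +0.3 for signature
#' lncRNAs, negative-binomial counts with dispersion (size) 2, and 5% of
#' cells planted as mapping-rate QC failures.
#'
#' @param ... Named overrides of any default element.
#' @return A named list of generator parameters.
#' @export
atlas_sim_config <- function(...) {
  cfg <- list(
    n_coding = 2000L, n_lnc = 1000L, coupling_fraction = 0.6,
    genome_length = NULL, max_dist = 5000L,
    cell_types = abc_cell_types(), n_per_type = 50L, n_donors = 21L,
    qc_fail_fraction = 0.05,
    fold_change = 5, n_coding_sig = c(20L, 40L), lnc_ratio = 0.5,
    nb_dispersion = 2, conservation_shift = 0.3, n_novel_regulons = 2L,
    seed = 1L
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Simulate a complete synthetic blood-cell atlas
#'
#' Runs every generator ([gen_annotation()], [plan_signatures()],
#' [gen_cells()], count sampling, [gen_conservation()], [gen_regulons()])
#' under a single seed and returns the inputs of the analysis pipeline
#' together with the full ground truth.  The distinct-UMI count matrix is
#' drawn directly from the negative-binomial model (the read-level route
#' of [gen_reads()] collapses to the same counts in expectation and is
#' exercised separately at small scale).
#'
#' @param config Parameter list from [atlas_sim_config()].
#' @return List of class `abc_sim`: `annotation`, `cells`, `counts`
#'   (cells x genes integer matrix), `biotype` (per column of `counts`),
#'   `conservation`, `regulons`, `truth` (annotation truth, signature
#'   plan, regulon truth, config).
#' @export
simulate_atlas <- function(config = atlas_sim_config()) {
  seed <- config$seed
  ga <- gen_annotation(config$n_coding, config$n_lnc,
                       coupling_fraction = config$coupling_fraction,
                       genome_length = config$genome_length,
                       seed = seed, max_dist = config$max_dist)
  plan <- plan_signatures(ga, cell_types = config$cell_types$cell_type,
                          fold_change = config$fold_change,
                          n_coding_sig = config$n_coding_sig,
                          lnc_ratio = config$lnc_ratio,
                          coupling = config$coupling_fraction,
                          seed = seed + 1L)
  cells <- gen_cells(config$cell_types, n_per_type = config$n_per_type,
                     n_donors = config$n_donors,
                     qc_fail_fraction = config$qc_fail_fraction,
                     seed = seed + 2L)
  counts <- .gen_counts(ga$annotation, cells, plan,
                        nb_dispersion = config$nb_dispersion,
                        seed = seed + 3L)
  cons <- gen_conservation(ga$annotation, plan,
                           conservation_shift = config$conservation_shift,
                           seed = seed + 4L)
  regs <- gen_regulons(plan, type_table = config$cell_types,
                       n_novel = config$n_novel_regulons, seed = seed + 5L)
  structure(list(
    annotation = ga$annotation,
    cells = cells,
    counts = counts,
    biotype = ga$annotation$biotype[match(colnames(counts),
                                          ga$annotation$gene_id)],
    conservation = cons,
    regulons = regs,
    truth = list(annotation = ga$truth, signature_plan = plan,
                 regulons = regs, config = config)
  ), class = "abc_sim")
}
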