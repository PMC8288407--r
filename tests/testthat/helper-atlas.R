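# Shared fixtures, built once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Compact atlas for module-level tests: 8 types spanning all 7 families.
small_types <- function() {
  tt <- abc_cell_types()
  tt[tt$cell_type %in% c("HSC", "MPP", "naive_B", "cytotoxic_NK",
                         "CD4_naive_T", "classical_monocyte",
                         "mature_neutrophil", "nucleated_erythrocyte"), ]
}

small_atlas <- function() {
  .memo("small_atlas", function() {
    cfg <- atlas_sim_config(
      cell_types = small_types(), n_per_type = 15L,
      n_coding = 400L, n_lnc = 200L, n_coding_sig = c(6L, 10L),
      qc_fail_fraction = 0.1, seed = 101L
    )
    sim <- simulate_atlas(cfg)
    qc <- qc_filter(sim$counts, sim$cells, sim$biotype,
                    min_coding = 100L, min_lnc = 50L)
    cells_cod <- sim$cells[match(rownames(qc$coding), sim$cells$cell_id), ]
    cells_lnc <- sim$cells[match(rownames(qc$lncrna), sim$cells$cell_id), ]
    list(sim = sim, qc = qc,
         cells_cod = cells_cod, cells_lnc = cells_lnc,
         norm_cod = normalize_log2tpm10(qc$coding),
         norm_lnc = normalize_log2tpm10(qc$lncrna))
  })
}

# The default synthetic atlas (the package's stated study conditions:
# 32 types x 50 cells, 2000 coding + 1000 lncRNA genes, 5-fold planted
# signatures), processed through QC, normalization and signature calling.
default_atlas <- function() {
  .memo("default_atlas", function() {
    sim <- simulate_atlas(atlas_sim_config(seed = 20L))
    qc <- qc_filter(sim$counts, sim$cells, sim$biotype)
    cells_cod <- sim$cells[match(rownames(qc$coding), sim$cells$cell_id), ]
    cells_lnc <- sim$cells[match(rownames(qc$lncrna), sim$cells$cell_id), ]
    norm_cod <- normalize_log2tpm10(qc$coding)
    norm_lnc <- normalize_log2tpm10(qc$lncrna)
    list(sim = sim, qc = qc,
         cells_cod = cells_cod, cells_lnc = cells_lnc,
         norm_cod = norm_cod, norm_lnc = norm_lnc,
         sig_cod = find_signatures(norm_cod, cells_cod),
         sig_lnc = find_signatures(norm_lnc, cells_lnc))
  })
}

# Precision/recall of a called signature set against the planted plan.
sig_precision_recall <- function(sig, plan, key) {
  tp <- sum(vapply(names(plan), function(ct)
    sum(sig$gene_id[sig$cell_type == ct] %in% plan[[ct]][[key]]),
    numeric(1)))
  c(precision = tp / nrow(sig),
    recall = tp / sum(vapply(plan, function(x) length(x[[key]]), numeric(1))))
}

# O(n^2) all-pairs brute force for lncRNA-coding adjacency (independent
# oracle for adjacency_scan).
brute_force_adjacency <- function(ann, max_dist = 5000L) {
  l <- ann[ann$biotype == "lncRNA", , drop = FALSE]
  cd <- ann[ann$biotype == "coding", , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(l))) {
    for (j in seq_len(nrow(cd))) {
      if (l$chrom[i] != cd$chrom[j]) next
      gap <- max(0L, max(l$start[i], cd$start[j]) - min(l$end[i], cd$end[j]))
      if (gap < max_dist) {
        res[[length(res) + 1L]] <- data.frame(
          lnc_id = l$gene_id[i], coding_id = cd$gene_id[j], gap_bp = gap,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(lnc_id = character(0), coding_id = character(0),
                      gap_bp = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$lnc_id, out$gap_bp, out$coding_id), , drop = FALSE]
}

# Random multi-chromosome annotation (no structure guarantees; used to
# exercise adjacency_scan against the brute force).
random_annotation <- function(n_genes, seed, n_chrom = 3L,
                              span = 200000L) {
  withr::with_seed(seed, {
    n_cod <- ceiling(n_genes / 2)
    n_lnc <- n_genes - n_cod
    start <- sample.int(span, n_genes, replace = TRUE)
    gene_model_set(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE),
      start = start,
      end = start + sample(200:5000, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = rep(c("coding", "lncRNA"), c(n_cod, n_lnc))
    )
  })
}

# Hand-built 12-cell QC fixture exercising all three mapping-rate
# thresholds and both detection cut-offs.  Detection counts are planted
# as runs of 1s; expected retained sets are hand-computed.
qc_toy_fixture <- function() {
  n_cod <- 1100L; n_lnc <- 600L
  spec <- data.frame(
    cell_id = sprintf("t%02d", 1:12),
    cell_type = c("HSC", "HSC", "classical_monocyte", "naive_B", "naive_B",
                  "cytotoxic_NK", "CD4_naive_T", "CD8_naive_T",
                  "mature_neutrophil", "nucleated_erythrocyte",
                  "erythroid_progenitor", "MPP"),
    mapping_rate = c(0.12, 0.09, 0.10, 0.049, 0.05, 0.30,
                     0.024, 0.025, 0.06, 0.90, 0.04, 0.11),
    det_cod = c(1050L, 1050L, 1001L, 1050L, 1000L, 1001L,
                1100L, 1100L, 999L, 1001L, 1050L, 1001L),
    det_lnc = c(550L, 550L, 501L, 550L, 501L, 500L,
                600L, 600L, 499L, 0L, 550L, 501L),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, 12L, n_cod + n_lnc,
                   dimnames = list(spec$cell_id,
                                   c(sprintf("PC%04d", 1:n_cod),
                                     sprintf("LNC%04d", 1:n_lnc))))
  for (i in 1:12) {
    if (spec$det_cod[i] > 0) counts[i, seq_len(spec$det_cod[i])] <- 1L
    if (spec$det_lnc[i] > 0) counts[i, n_cod + seq_len(spec$det_lnc[i])] <- 1L
  }
  list(counts = counts,
       cells = spec[, c("cell_id", "cell_type", "mapping_rate")],
       biotype = rep(c("coding", "lncRNA"), c(n_cod, n_lnc)),
       # mapping pass: t01 (.12>=.10), t03 (.10>=.10), t05 (.05>=.05),
       # t06, t08 (.025>=.025), t09, t10, t12; fail: t02, t04, t07, t11.
       expect_coding = c("t01", "t03", "t06", "t08", "t10", "t12"),
       expect_lncrna = c("t01", "t03", "t05", "t08", "t12"))
}
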