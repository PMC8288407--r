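# bloodatlas

Tools for building and validating single-cell transcriptional references
of the human blood system from UMI-based scRNA-seq — for computational
biologists assembling a hematopoietic atlas (tens of immunophenotypic,
FACS-sorted cell types from many donors) and for anyone who needs its
downstream machinery: per-cell-type signature genes for protein-coding
genes *and* lncRNAs, lncRNA cell-specificity and conservation contrasts,
regulon on/off states, and reference-based cell-type prediction.

## What it computes

* **Quantification & QC** — gene counts are distinct-UMI counts; cells
  are retained per lineage family (mapping rate ≥ 10% for
  HSPCs/monocytes, ≥ 5% for B/NK/neutrophils/erythrocytes, ≥ 2.5% for T
  cells) and must detect > 1000 coding genes / > 500 lncRNAs, the coding
  and lncRNA cell sets being kept separately.  Normalization is
  `log2(TPM/10 + 1)`.
* **Signatures** — one-vs-rest Wilcoxon rank-sum per gene per type (the
  test is implemented in the package, exact for small untied samples),
  BH-corrected, thresholded at `q ≤ 0.05`, `log2FC ≥ 1`, detection ≥
  25%.  Pairwise DEG counts between all type pairs, and the Spearman
  concordance ρ between the coding and lncRNA DEG matrices.
* **lncRNA characterization** — cell specificity
  `1 − √JSD(e, onehot_t)` from the Jensen–Shannon divergence of a
  gene's per-type expression profile; conservation contrasts of
  signature vs background lncRNAs; a genomic scan for protein-coding
  neighbors strictly within 5 kb, and the per-type proportion of
  signature lncRNAs adjacent to same-type coding signatures;
  hypergeometric overlap of those neighbors with reference gene sets.
* **Regulons** — per-cell activity as the rank-recovery AUC of a
  regulon's targets among the cell's top 5% expressed genes; on/off
  binarization by deterministic 1-D two-means; cluster-level states and
  novelty flags against a canonical TF list.
* **Projection** — per-type mean centroids over signature-ranked
  features, cosine assignment with an unassignment threshold of 0.7, and
  stratified k-fold self-projection accuracy.
* **Synthetic atlas** — `simulate_atlas()` generates annotation, cells,
  counts, conservation scores and regulons with a recorded ground truth
  (planted signatures, planted <5 kb lncRNA–coding couples, planted QC
  failures, planted novel regulons), so every claim above is testable
  without the original sequencing data.

## Worked example

```r
library(bloodatlas)

# simulate a compact atlas: 8 cell types, 15 cells each, 600 genes
types <- abc_cell_types()
types <- types[types$cell_type %in% c("HSC", "MPP", "naive_B",
  "cytotoxic_NK", "CD4_naive_T", "classical_monocyte",
  "mature_neutrophil", "nucleated_erythrocyte"), ]
sim <- simulate_atlas(atlas_sim_config(
  cell_types = types, n_per_type = 15L, n_coding = 400L, n_lnc = 200L,
  n_coding_sig = c(8L, 12L), seed = 1L))

qc <- qc_filter(sim$counts, sim$cells, sim$biotype,
                min_coding = 100L, min_lnc = 50L)
unlist(qc$summary)
#>                  n_cells          removed_mapping removed_coding_detection
#>                      120                        6                        0
#> removed_lncrna_detection          retained_coding          retained_lncrna
#>                        0                      114                      114
```

Six cells fall below their family's mapping-rate threshold (the
generator planted 5% failures); everything else clears both detection
cut-offs at this small scale.

```r
cells <- sim$cells[match(rownames(qc$coding), sim$cells$cell_id), ]
norm <- normalize_log2tpm10(qc$coding)
sig <- find_signatures(norm, cells)
head(sig[, c("cell_type", "gene_id", "log2fc", "q", "pct_in")], 3)
#>     cell_type gene_id   log2fc            q pct_in
#> 1 CD4_naive_T PC00138 2.622403 4.847739e-07      1
#> 2 CD4_naive_T PC00136 2.818064 1.315051e-06      1
#> 3 CD4_naive_T PC00333 2.836106 2.409157e-06      1
table(sig$cell_type)
#>           CD4_naive_T    classical_monocyte          cytotoxic_NK
#>                    10                     7                     9
#>                   HSC     mature_neutrophil                   MPP
#>                    10                     9                     8
#>               naive_B nucleated_erythrocyte
#>                    12                     7
```

Each type recovers roughly its planted 8–12 signature genes, at
log2 fold changes near the planted 5-fold (`log2 5 ≈ 2.3`) and q-values
far below the 0.05 cut-off.

```r
adj <- adjacency_scan(sim$annotation)
nrow(adj)          # lncRNA-coding pairs closer than 5 kb
#> [1] 120

acc <- self_projection_accuracy(norm, cells, seed = 1, n_features = 100L)
round(acc$overall, 3)
#> [1] 0.746
```

120 of the 200 simulated lncRNAs sit within 5 kb of a coding gene — the
generator's planted coupling fraction of 0.6 exactly.  Self-projection
on this deliberately small atlas (12 training cells per type per fold)
reaches 0.746 against a chance level of 0.125; at the default atlas
scale (50 cells per type) it exceeds 0.99.

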