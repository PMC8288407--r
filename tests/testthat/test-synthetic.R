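test_that("gen_annotation plants exactly the requested coupling and is reproducible", {
  ga <- gen_annotation(n_coding = 150, n_lnc = 100, coupling_fraction = 0.6,
                       seed = 1)
  expect_equal(nrow(ga$truth$coupled_pairs), 60)
  expect_equal(length(ga$truth$uncoupled_lnc), 40)
  expect_true(all(ga$truth$coupled_pairs$gap_bp < 5000))
  validate_gene_models(ga$annotation)
  expect_equal(sum(ga$annotation$biotype == "coding"), 150)
  expect_equal(sum(ga$annotation$biotype == "lncRNA"), 100)

  ga2 <- gen_annotation(n_coding = 150, n_lnc = 100, coupling_fraction = 0.6,
                        seed = 1)
  expect_identical(ga, ga2)

  # full coupling: every lncRNA has a <5 kb coding neighbor
  full <- gen_annotation(n_coding = 20, n_lnc = 10, coupling_fraction = 1,
                         seed = 2)
  adj <- adjacency_scan(full$annotation)
  expect_setequal(unique(adj$lnc_id),
                  full$annotation$gene_id[full$annotation$biotype == "lncRNA"])

  # zero coupling: the neighbor map is empty
  none <- gen_annotation(n_coding = 20, n_lnc = 10, coupling_fraction = 0,
                         seed = 3)
  expect_equal(nrow(adjacency_scan(none$annotation)), 0L)
})

test_that("gen_annotation refuses an infeasible genome length", {
  expect_error(gen_annotation(50, 20, genome_length = 10000, seed = 1),
               "too small")
})

test_that("planted adjacency truth matches the scanner's gap arithmetic", {
  ga <- gen_annotation(80, 60, coupling_fraction = 0.5, seed = 7)
  adj <- adjacency_scan(ga$annotation)
  truth <- ga$truth$coupled_pairs
  m <- merge(adj, truth, by = c("lnc_id", "coding_id"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$gap_bp.x, m$gap_bp.y)
  expect_false(any(ga$truth$uncoupled_lnc %in% adj$lnc_id))
})

test_that("gen_cells plants the exact number of QC failures and metadata cardinalities", {
  tt <- small_types()
  cells <- gen_cells(tt, n_per_type = 20, n_donors = 21,
                     qc_fail_fraction = 0.2, seed = 4)
  expect_equal(nrow(cells), 20 * nrow(tt))
  expect_equal(sum(cells$planted_qc_fail), round(0.2 * nrow(cells)))
  thr <- family_mapping_thresholds()[cells$family]
  expect_true(all(cells$mapping_rate[cells$planted_qc_fail] < thr[cells$planted_qc_fail]))
  expect_true(all(cells$mapping_rate[!cells$planted_qc_fail] >= thr[!cells$planted_qc_fail]))
  expect_false(anyDuplicated(cells$cell_id) > 0)
  expect_lte(length(unique(cells$donor)), 21)
  expect_setequal(unique(cells$cell_type), tt$cell_type)

  clean <- gen_cells(tt, n_per_type = 10, qc_fail_fraction = 0, seed = 5)
  expect_equal(sum(clean$planted_qc_fail), 0)
})

test_that("gen_reads realises the planted fold change and exercises duplicates", {
  tt <- small_types()[1:2, ]
  cells <- gen_cells(tt, n_per_type = 60, qc_fail_fraction = 0, seed = 6)
  ga <- gen_annotation(50, 10, coupling_fraction = 0, seed = 6)
  plan <- plan_signatures(ga, cell_types = tt$cell_type,
                          n_coding_sig = c(5L, 5L), fold_change = 5, seed = 6)
  reads <- gen_reads(ga$annotation, cells, plan, dup_rate = 0, seed = 6)
  # no duplicates: every row is a distinct molecule
  expect_equal(nrow(unique(reads)), nrow(reads))
  cm <- count_umis(reads)
  ct1 <- plan[[tt$cell_type[1]]]$coding
  in1 <- intersect(rownames(cm), cells$cell_id[cells$cell_type == tt$cell_type[1]])
  out1 <- intersect(rownames(cm), cells$cell_id[cells$cell_type == tt$cell_type[2]])
  ratio <- mean(cm[in1, ct1]) / mean(cm[out1, ct1])
  expect_gt(ratio, 4); expect_lt(ratio, 6)

  withdup <- gen_reads(ga$annotation, cells[1:20, ], plan, dup_rate = 0.3,
                       seed = 6)
  expect_gt(nrow(withdup), nrow(unique(withdup)))
  # collapsing removes all planted duplicates
  expect_equal(sum(count_umis(withdup)), nrow(unique(withdup)))
})

test_that("conservation generator shifts signature lncRNAs and is null-calibrated", {
  ga <- gen_annotation(100, 80, coupling_fraction = 0.5, seed = 8)
  plan <- plan_signatures(ga, cell_types = c("a", "b", "c"),
                          n_coding_sig = c(10L, 10L), lnc_ratio = 1,
                          seed = 8)
  sig_lnc <- unique(unlist(lapply(plan, `[[`, "lnc")))
  bg <- setdiff(ga$annotation$gene_id[ga$annotation$biotype == "lncRNA"],
                sig_lnc)

  # planted shift of 0.3 is detected decisively
  sc <- gen_conservation(ga$annotation, plan, conservation_shift = 0.3,
                         seed = 8)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_lt(conservation_compare(sc, sig_lnc, bg)$p, 0.001)

  # zero shift: the one-sided test stays non-significant in >= 90% of seeds
  p0 <- vapply(1:100, function(s) {
    sc0 <- gen_conservation(ga$annotation, plan, conservation_shift = 0,
                            seed = s)
    conservation_compare(sc0, sig_lnc, bg)$p
  }, numeric(1))
  expect_gte(mean(p0 > 0.05), 0.9)
})

test_that("simulate_atlas is seed-reproducible with consistent truth bookkeeping", {
  cfg <- atlas_sim_config(cell_types = small_types(), n_per_type = 5L,
                          n_coding = 200L, n_lnc = 100L,
                          n_coding_sig = c(4L, 6L), seed = 9L)
  s1 <- simulate_atlas(cfg)
  s2 <- simulate_atlas(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == round(s1$counts)))
  # every planted id exists in the annotation
  planted <- unlist(lapply(s1$truth$signature_plan,
                           function(x) c(x$coding, x$lnc)))
  expect_true(all(planted %in% s1$annotation$gene_id))
})
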