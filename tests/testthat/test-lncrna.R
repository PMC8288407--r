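test_that("jsd matches hand-derived values and basic divergence properties", {
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd(c(0.5, 0.5), c(1, 0)), 0.311278, tolerance = 1e-6)
  # symmetric, non-negative, bounded, zero iff equal
  withr::with_seed(18, {
    for (i in 1:25) {
      p <- runif(6); p <- p / sum(p)
      q <- runif(6); q <- q / sum(q)
      expect_equal(jsd(p, q), jsd(q, p))
      expect_gte(jsd(p, q), 0)
      expect_lte(jsd(p, q), 1)
      expect_equal(jsd(p, p), 0)
    }
  })
  expect_error(jsd(c(0.5, 0.5), c(0.7, 0.7)), "sum to 1")
  expect_error(jsd(c(1.5, -0.5), c(0.5, 0.5)), "negative")
  expect_error(jsd(c(1, 0), c(0.5, 0.25, 0.25)), "length")
})

test_that("specificity scores follow the 1 - sqrt(JSD) construction", {
  # 3 types x 2 cells; one gene one-hot, one uniform over two types, one silent
  m <- matrix(0, 6, 3, dimnames = list(sprintf("c%d", 1:6),
                                       c("onehot", "uni2", "silent")))
  m[1:2, "onehot"] <- 5
  m[1:4, "uni2"] <- 3
  cells <- data.frame(cell_id = rownames(m),
                      cell_type = rep(c("a", "b", "d"), each = 2))
  sp <- specificity_scores(m, cells)
  expect_equal(sp$scores["onehot", "a"], 1)
  expect_equal(sp$max_score[["onehot"]], 1)
  expect_identical(sp$argmax_type[["onehot"]], "a")
  # uniform across 2 of the types: 1 - sqrt(0.311278) at either
  expect_lt(abs(sp$scores["uni2", "a"] - 0.44207), 1e-5)
  expect_lt(abs(sp$scores["uni2", "b"] - 0.44207), 1e-5)
  expect_true(is.na(sp$max_score[["silent"]]))
})

test_that("planted signature lncRNAs score higher specificity than background", {
  at <- small_atlas()
  sp <- specificity_scores(at$norm_lnc, at$cells_lnc)
  sig_ids <- intersect(
    unique(unlist(lapply(at$sim$truth$signature_plan, `[[`, "lnc"))),
    colnames(at$norm_lnc))
  bg_ids <- setdiff(names(sp$max_score)[!is.na(sp$max_score)], sig_ids)
  expect_gt(stats::median(sp$max_score[sig_ids]),
            stats::median(sp$max_score[bg_ids]))
  p <- rank_sum_test(sp$max_score[sig_ids], sp$max_score[bg_ids],
                     "greater")$p
  expect_lt(p, 0.01)

  # label permutation stochastically decreases specificity of planted genes
  withr::with_seed(19, {
    cp <- at$cells_lnc
    cp$cell_type <- sample(cp$cell_type)
  })
  sp_perm <- specificity_scores(at$norm_lnc, cp)
  expect_gt(mean(sp$max_score[sig_ids]), mean(sp_perm$max_score[sig_ids]))
})

test_that("adjacency_scan equals the all-pairs brute force on random annotations", {
  for (s in 1:20) {
    ann <- random_annotation(500, seed = 100 + s)
    got <- adjacency_scan(ann)
    want <- brute_force_adjacency(ann)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(as.data.frame(got), want)
  }
})

test_that("adjacency boundaries: gap 4999 is adjacent, 5000 is not, overlap is gap 0", {
  ann <- gene_model_set(
    gene_id = c("lnc_in", "lnc_out", "lnc_ovl", "pc"),
    chrom = "chr1",
    start = c(20000L + 4999L, 20000L + 5000L, 19500L, 10000L),
    end = c(26000L, 26100L, 20200L, 20000L),
    strand = "+",
    biotype = c("lncRNA", "lncRNA", "lncRNA", "coding")
  )
  adj <- adjacency_scan(ann)
  expect_setequal(adj$lnc_id, c("lnc_in", "lnc_ovl"))
  expect_equal(adj$gap_bp[adj$lnc_id == "lnc_in"], 4999L)
  expect_equal(adj$gap_bp[adj$lnc_id == "lnc_ovl"], 0L)
})

test_that("signature adjacency proportion matches the planted coupling across seeds", {
  pooled <- vapply(1:20, function(s) {
    ga <- gen_annotation(250, 200, coupling_fraction = 0.6, seed = 300 + s)
    plan <- plan_signatures(ga, cell_types = sprintf("T%02d", 1:10),
                            n_coding_sig = c(16L, 16L), lnc_ratio = 0.625,
                            seed = 300 + s)
    sig_of <- function(key) do.call(rbind, lapply(names(plan), function(ct)
      data.frame(cell_type = ct, gene_id = plan[[ct]][[key]],
                 stringsAsFactors = FALSE)))
    adj <- adjacency_scan(ga$annotation)
    pr <- signature_adjacency_proportion(sig_of("lnc"), sig_of("coding"), adj)
    sum(pr$n_adjacent) / sum(pr$n_signature_lnc)
  }, numeric(1))
  expect_true(all(abs(pooled - 0.6) <= 0.05))

  # trivial cases
  ga <- gen_annotation(50, 30, coupling_fraction = 0, seed = 21)
  plan <- plan_signatures(ga, cell_types = c("x", "y"), coupling = 0,
                          n_coding_sig = c(5L, 5L), seed = 21)
  sig_of <- function(key) do.call(rbind, lapply(names(plan), function(ct)
    data.frame(cell_type = ct, gene_id = plan[[ct]][[key]],
               stringsAsFactors = FALSE)))
  adj0 <- adjacency_scan(ga$annotation)
  pr0 <- signature_adjacency_proportion(sig_of("lnc"), sig_of("coding"), adj0)
  expect_true(all(pr0$proportion == 0))
})

test_that("conservation comparison is calibrated under the null and errors on overlap", {
  withr::with_seed(22, {
    rej <- vapply(1:200, function(i) {
      s <- rbeta(30, 2, 8); b <- rbeta(100, 2, 8)
      names(s) <- paste0("s", 1:30); names(b) <- paste0("b", 1:100)
      conservation_compare(c(s, b), names(s), names(b))$p <= 0.05
    }, logical(1))
  })
  expect_lte(mean(rej), 0.07)

  sc <- c(a = 1, b = 0.9, d = 0.1, e = 0)
  expect_error(conservation_compare(sc, c("a", "b"), c("b", "d")), "overlap")
  # fully separated groups attain the minimal p for the group sizes
  res <- conservation_compare(sc, c("a", "b"), c("d", "e"))
  expect_equal(res$p, 1 / choose(4, 2))
  expect_equal(res$delta_median, 0.9)
})

test_that("neighbor overlap test equals the exact hypergeometric tail", {
  # universe 100, |ref| = 10, |neighbors| = 10, overlap 5
  adj <- data.frame(lnc_id = rep("l1", 10),
                    coding_id = sprintf("pc%02d", 1:10))
  ref <- c(sprintf("pc%02d", 6:10), sprintf("rf%02d", 1:5))
  got <- neighbor_signature_overlap(adj, "l1", ref, universe_size = 100)
  expect_equal(got$overlap, 5)
  exact <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k), numeric(1))) / choose(100, 10)
  expect_equal(got$p, exact)

  # complete overlap is the minimal attainable tail
  full <- neighbor_signature_overlap(adj, "l1", sprintf("pc%02d", 1:10), 1000)
  expect_equal(full$p, 1 / choose(1000, 10) * choose(990, 0) * choose(10, 10))
  # disjoint small sets in a large universe: p near 1
  none <- neighbor_signature_overlap(adj, "l1", sprintf("zz%02d", 1:5), 5000)
  expect_gt(none$p, 0.98)
  expect_error(neighbor_signature_overlap(adj, "l1", ref, universe_size = 5),
               "universe")
})
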