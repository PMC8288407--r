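test_that("ras_auc equals explicit step-curve integration on small instances", {
  withr::with_seed(23, {
    for (i in 1:10) {
      G <- sample(20:50, 1)
      n <- sample(5:15, 1)
      m <- matrix(sample(0:6, n * G, replace = TRUE), n, G,
                  dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:G)))
      targets <- sample(colnames(m), sample(3:8, 1))
      tf <- 0.2
      got <- ras_auc(m, targets, top_fraction = tf)
      oracle <- apply(m, 1, function(x) {
        ord <- order(-x, seq_along(x))
        X <- floor(tf * G)
        r <- cumsum(colnames(m)[ord] %in% targets)[seq_len(X)] / length(targets)
        sum(r) / X
      })
      expect_equal(got, oracle)
    }
  })
})

test_that("ras_auc hits its extremes and is rank-invariant", {
  m <- matrix(c(9, 4, 3, 2, 1, 0, 0, 0, 0, 0), 2, 5, byrow = TRUE,
              dimnames = list(c("hi", "lo"), sprintf("g%d", 1:5)))
  # single-target regulon whose target is the top-ranked gene: score 1
  expect_equal(unname(ras_auc(m, "g1", top_fraction = 0.4)["hi"]), 1)
  # targets entirely outside the top window: score 0
  expect_equal(unname(ras_auc(m, "g5", top_fraction = 0.4)["hi"]), 0)
  expect_error(ras_auc(m, "nope", top_fraction = 0.2), "resolvable")

  # invariant under any monotone transform of a cell's expression
  withr::with_seed(24, {
    big <- matrix(runif(30 * 100), 30, 100,
                  dimnames = list(NULL, sprintf("g%d", 1:100)))
  })
  tg <- sprintf("g%d", c(3, 14, 15, 60, 90))
  expect_equal(ras_auc(big, tg), ras_auc(2^big + 5, tg))
})

test_that("ras_scores agrees with ras_auc and enforces the target floor", {
  at <- small_atlas()
  regs <- at$sim$regulons$regulons
  ras <- ras_scores(at$norm_cod, regs)
  one <- ras_auc(at$norm_cod, regs[[1]])
  expect_equal(unname(ras[, names(regs)[1]]), unname(one))
  expect_true(all(ras >= 0 & ras <= 1))
  expect_warning(
    ras_scores(at$norm_cod, c(regs, list(tiny = colnames(at$norm_cod)[1:2]))),
    "tiny")
})

test_that("two-means binarization separates planted clusters exactly", {
  withr::with_seed(25, {
    lo <- 0.1 + rnorm(60, sd = 0.02)
    hi <- 0.9 + rnorm(40, sd = 0.02)
  })
  ras <- cbind(bimodal = c(lo, hi))
  rownames(ras) <- sprintf("c%03d", 1:100)
  bin <- binarize_ras(ras)
  expect_gt(bin$thresholds[["bimodal"]], 0.2)
  expect_lt(bin$thresholds[["bimodal"]], 0.8)
  expect_equal(unname(bin$state[, "bimodal"]), rep(c(0L, 1L), c(60, 40)))

  # a single active cell is the only one on
  single <- cbind(r = c(rep(0, 19), 1))
  rownames(single) <- sprintf("s%02d", 1:20)
  b2 <- binarize_ras(single)
  expect_equal(sum(b2$state), 1L)
  expect_equal(unname(which(b2$state[, 1] == 1L)), 20L)

  # invariant to cell order
  withr::with_seed(26, perm <- sample(100))
  b3 <- binarize_ras(ras[perm, , drop = FALSE])
  expect_equal(b3$state[rownames(ras), ], bin$state[, 1])
})

test_that("constant regulons are dropped with a warning during binarization", {
  withr::with_seed(27, x <- runif(30))
  ras <- cbind(ok = x, flat = rep(0.4, 30))
  rownames(ras) <- sprintf("c%02d", 1:30)
  expect_warning(bin <- binarize_ras(ras), "flat")
  expect_equal(colnames(bin$state), "ok")
})

test_that("cluster states and specificity flags behave on planted and degenerate designs", {
  # block design: regulon A on in cluster 1 only, regulon B on everywhere
  state <- cbind(A = rep(c(1L, 0L), c(20, 40)), B = rep(1L, 60))
  labs <- rep(c("c1", "c2", "c3"), each = 20)
  st <- cluster_regulon_states(state, labs)
  expect_equal(unname(st$state[, "A"]), c(1L, 0L, 0L))
  expect_equal(unname(st$state[, "B"]), c(1L, 1L, 1L))
  expect_identical(st$specific$c1, "A")  # B is on in 2 other clusters
  expect_false("B" %in% unlist(st$specific))

  # min_on_fraction = 1 with one off-cell per cluster: all states off
  state2 <- cbind(A = rep(1L, 30)); state2[c(1, 11, 21), 1] <- 0L
  st2 <- cluster_regulon_states(state2, rep(c("x", "y", "z"), each = 10),
                                min_on_fraction = 1)
  expect_true(all(st2$state == 0L))

  expect_error(cluster_regulon_states(state, c(labs[-1], NA)), "label")
})

test_that("novel-regulon flagging reduces to set logic over activated regulons", {
  state <- cbind(A = c(1L, 0L), B = c(0L, 1L), C = c(0L, 0L))
  rownames(state) <- c("c1", "c2")
  st <- list(state = state)
  class(st) <- "regulon_states"
  # canonical list covers everything: nothing novel
  expect_equal(flag_novel_regulons(st, c("A", "B", "C")), character(0))
  # empty canonical list: all activated regulons are novel (C is inactive)
  expect_equal(flag_novel_regulons(st, character(0)), c("A", "B"))
})

test_that("generator-planted lineage regulons are recovered end to end", {
  at <- default_atlas()
  sim <- at$sim
  ras <- ras_scores(at$norm_cod, sim$regulons$regulons)
  bin <- binarize_ras(ras)
  st <- cluster_regulon_states(bin, at$cells_cod$family)
  # each family regulon is on exactly in its own lineage family cluster
  fam_of <- sim$regulons$regulon_family
  for (tf in colnames(st$state)) {
    on_in <- rownames(st$state)[st$state[, tf] == 1L]
    expect_identical(on_in, unname(fam_of[tf]))
    expect_true(tf %in% st$specific[[fam_of[tf]]])
  }
  # exactly the planted non-canonical activated TFs are flagged novel
  expect_identical(flag_novel_regulons(st, sim$regulons$canonical_tfs),
                   sim$regulons$novel_tfs)
})
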