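test_that("consensus_rank aggregates by geometric mean with competition ties", {
  cons <- consensus_rank(list(
    genorm = c(a = 1, b = 2, c = 3),
    normfinder = c(a = 1, b = 3, c = 2),
    bestkeeper = c(a = 1, b = 2, c = 3)))
  expect_equal(cons$geomean[cons$gene == "a"], 1)
  expect_equal(cons$com_rank[cons$gene == "a"], 1L)
  expect_identical(attr(cons, "best_gene"), "a")

  # (5,1,1) -> 5^(1/3)
  cons2 <- consensus_rank(list(m1 = c(x = 5, y = 1), m2 = c(x = 1, y = 2),
                               m3 = c(x = 1, y = 2)))
  expect_equal(cons2$geomean[cons2$gene == "x"], 5^(1 / 3))

  # ties share a rank; next rank skips (competition ranking)
  cons3 <- consensus_rank(list(m1 = c(a = 1, b = 1, c = 3),
                               m2 = c(a = 2, b = 2, c = 3),
                               m3 = c(a = 1, b = 1, c = 3)))
  expect_equal(cons3$com_rank, c(1L, 1L, 3L))
})

test_that("consensus_rank is method-order invariant and validates input", {
  rv <- list(g = c(a = 1, b = 2, c = 3), n = c(a = 3, b = 1, c = 2),
             b = c(a = 2, b = 3, c = 1))
  c1 <- consensus_rank(rv)
  c2 <- consensus_rank(rev(rv))
  expect_equal(c1$geomean, c2$geomean)
  expect_identical(c1$gene, c2$gene)
  expect_error(consensus_rank(list(m1 = c(a = 1), m2 = c(b = 1))),
               "same gene set")
  expect_error(consensus_rank(rv[1]), ">= 2 methods")
})

test_that("random rank permutations sort exactly like the brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    genes <- paste0("g", 1:10)
    rv <- lapply(1:3, function(i) setNames(sample(10), genes))
    names(rv) <- c("g", "n", "b")
    cons <- consensus_rank(rv)
    gm <- sapply(genes, function(gn)
      prod(sapply(rv, `[[`, gn))^(1 / 3))
    expect_equal(setNames(cons$geomean, cons$gene)[genes], gm)
    # output is sorted ascending and com_rank is the competition rank
    expect_true(!is.unsorted(cons$geomean))
    expect_identical(cons$com_rank,
                     as.integer(rank(cons$geomean, ties.method = "min")))
  }
})

test_that("ddct self-normalization and one-cycle doubling", {
  ct <- rbind(target = c(24, 23, 24), ref = c(24, 24, 24))
  colnames(ct) <- c("ctrl", "trt", "other")
  m <- ct_matrix(ct)
  rel <- ddct(m, "target", "ref", calibrator = "ctrl")
  expect_equal(rel$fold[rel$sample == "ctrl"], 1)
  expect_equal(rel$fold[rel$sample == "trt"], 2)

  # target == reference everywhere -> fold 1 in every sample
  rel2 <- ddct(m, "ref", "ref", calibrator = "ctrl")
  expect_equal(rel2$fold, rep(1, 3))
})

test_that("multi-reference ddct averages reference Ct; group calibrator", {
  ct <- rbind(t = c(24, 22), r1 = c(20, 20.4), r2 = c(22, 21.6))
  colnames(ct) <- c("w1", "r1s")
  meta <- data.frame(sample_id = colnames(ct), set = "v", group = c("W", "R"),
                     tissue = NA, time = NA, replicate = NA)
  m <- ct_matrix(ct, meta)
  rel <- ddct(m, "t", c("r1", "r2"), calibrator = "W",
              calibrator_is_group = TRUE)
  # ref ct: (20+22)/2 = 21 then (20.4+21.6)/2 = 21; dct 3 -> 1; fold 4
  expect_equal(rel$fold, c(1, 4))
  expect_error(ddct(m, "t", "r1", calibrator = "nope"), "not found")
  expect_error(ddct(m, "z", "r1", calibrator = "w1"), "unknown gene")
})

test_that("ddct is invariant to per-sample loading shifts", {
  m <- fixture_t1()
  rel1 <- ddct(m, "gA", c("gB", "gC"), calibrator = "s1")
  ct2 <- m$ct + matrix(rep(c(1, -2, 0.5, 3), each = 3), 3, 4)
  rel2 <- ddct(ct_matrix(ct2, m$meta), "gA", c("gB", "gC"), calibrator = "s1")
  expect_equal(rel1$fold, rel2$fold, tolerance = 1e-12)
})

test_that("fold recovery is unbiased as replicates grow", {
  err <- vapply(c(3, 30), function(nrep) {
    folds <- vapply(1:50, function(seed) {
      set.seed(seed)
      ref <- 20 + rnorm(2 * nrep, 0, 0.1)
      tgt <- c(24 + rnorm(nrep, 0, 0.1), 22 + rnorm(nrep, 0, 0.1))
      ct <- rbind(t = tgt, r = ref)
      colnames(ct) <- paste0("s", seq_len(2 * nrep))
      meta <- data.frame(sample_id = colnames(ct), set = "v",
                         group = rep(c("W", "R"), each = nrep),
                         tissue = NA, time = NA, replicate = NA)
      rel <- ddct(ct_matrix(ct, meta), "t", "r", "W",
                  calibrator_is_group = TRUE)
      mean(rel$fold[meta$group == "R"])
    }, numeric(1))
    abs(mean(log2(folds)) - 2)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("reference_choice_sensitivity flags unstable references", {
  # two Ct-shifted copies -> zero divergence; self vs self -> zero
  m <- fixture_t1()
  ct <- rbind(m$ct, gB2 = m$ct["gB", ] + 1.5)
  m2 <- ct_matrix(ct, m$meta)
  sens <- reference_choice_sensitivity(m2, "gA", c("gB", "gB2"), "s1")
  expect_equal(sens$max_divergence, 0, tolerance = 1e-12)
  expect_false(sens$direction_flip)

  # a reference with a group effect flips direction of a small true change
  ct <- rbind(t = c(24, 23.5), good = c(20, 20), bad = c(20, 18.5))
  colnames(ct) <- c("ctrl", "trt")
  m3 <- ct_matrix(ct)
  sens <- reference_choice_sensitivity(m3, "t", c("good", "bad"), "ctrl")
  expect_true(sens$direction_flip)
  expect_equal(sens$max_divergence, 1.5, tolerance = 1e-12)
})

test_that("stability_suite wires the three methods into one consensus", {
  sim <- simulate_ct(default_sim_config(seed = 2))
  m <- collapse_replicates(sim$ct)
  sets <- default_sample_sets(m)
  res <- stability_suite(m, sets$stress_leaf)
  expect_setequal(res$consensus$gene, m$genes)
  expect_identical(res$normfinder$mode, "grouped")
  expect_equal(res$consensus$geomean,
               apply(as.matrix(as.data.frame(res$consensus)[,
                 c("rank_genorm", "rank_normfinder", "rank_bestkeeper")]),
                 1, function(r) prod(r)^(1 / 3)))
  # cultivar set has singleton groups after collapse -> ungrouped fallback
  res_c <- stability_suite(m, sets$cultivars)
  expect_identical(res_c$normfinder$mode, "ungrouped")
})
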