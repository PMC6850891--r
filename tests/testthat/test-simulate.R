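test_that("noiseless limit yields perfect-stability outputs everywhere", {
  cfg <- default_sim_config(seed = 4)
  cfg$genes$sigma[] <- 0
  cfg$effects <- NULL
  cfg$tau <- 0
  sim <- simulate_ct(sim_config(cfg$genes, cfg$design, NULL, tau = 0, seed = 4))
  expect_equal(apply(sim$ct$ct, 1, sd), setNames(rep(0, 10), sim$ct$genes))
  g <- genorm(sim$ct)
  expect_equal(g$table$m_single, rep(0, 10))
  nf <- normfinder(sim$ct)
  expect_equal(nf$table$stability, rep(0, 10))
  suppressWarnings(bk <- bestkeeper(sim$ct))
  expect_equal(bk$table$sd, rep(0, 10))
})

test_that("same config + seed reproduces the matrix exactly", {
  s1 <- simulate_ct(default_sim_config(seed = 77))
  s2 <- simulate_ct(default_sim_config(seed = 77))
  s3 <- simulate_ct(default_sim_config(seed = 78))
  expect_identical(s1$ct$ct, s2$ct$ct)
  expect_false(identical(s1$ct$ct, s3$ct$ct))
  expect_identical(s1$truth, s2$truth)
})

test_that("empirical gene noise matches sigma after removing loading", {
  sds <- seq(0.1, 1.0, by = 0.1)
  genes <- data.frame(gene = paste0("g", 1:10), baseline = 25, sigma = sds)
  design <- expand.grid(group = paste0("grp", 1:6),
                        replicate = 1:167, stringsAsFactors = FALSE)
  design$set <- "x"; design$tissue <- NA; design$time <- NA
  design$sample_id <- paste0("s", seq_len(nrow(design)))
  sim <- simulate_ct(sim_config(genes, design, NULL, tau = 1, seed = 12))
  # centering on the per-sample gene mean removes the shared loading
  centered <- sweep(sim$ct$ct, 2, colMeans(sim$ct$ct))
  emp <- apply(centered, 1, sd)
  # centering leaves sd_i' = sqrt(sig_i^2 (1-2/k) + mean(sig^2)/k)
  k <- 10
  expected <- sqrt(sds^2 * (1 - 2 / k) + mean(sds^2) / k)
  expect_true(all(abs(emp - expected) / expected < 0.15))
})

test_that("truth scores combine noise and regulation variance", {
  genes <- data.frame(gene = c("a", "b"), baseline = 25, sigma = c(0.1, 0.2))
  design <- data.frame(sample_id = paste0("s", 1:4), set = "x",
                       group = rep(c("g1", "g2"), each = 2),
                       tissue = NA, time = NA, replicate = c(1, 2, 1, 2))
  eff <- data.frame(gene = "a", group = "g2", delta = 1)
  sim <- simulate_ct(sim_config(genes, design, eff, tau = 0, seed = 5))
  # gene a: delta (0, 1) over two conditions -> population var 0.25
  expect_equal(unname(sim$truth$score["a"]), sqrt(0.1^2 + 0.25))
  expect_equal(unname(sim$truth$score["b"]), 0.2)
  expect_identical(sim$truth$order, c("b", "a"))
})

test_that("invalid configs are rejected", {
  genes <- data.frame(gene = "a", baseline = 25, sigma = -1)
  design <- data.frame(sample_id = "s1", set = "x", group = "g",
                       tissue = NA, time = NA, replicate = 1)
  expect_error(sim_config(genes, design), "sigma")
  genes$sigma <- 1
  expect_error(sim_config(genes, design, tau = -0.1), "tau")
  design$group <- ""
  expect_error(sim_config(genes, design), "group label")
})

test_that("dilution series hits the analytic line when noiseless", {
  tab <- simulate_dilution_series(true_e = 1.0, sigma_ct = 0, seed = 1)
  cv <- fit_standard_curve(tab$dilution, tab$ct)
  expect_equal(cv$efficiency, 1.0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # minimal valid design still fits
  tab <- simulate_dilution_series(replicates = 1, n_dilutions = 3, seed = 2)
  expect_s3_class(fit_standard_curve(tab$dilution, tab$ct), "standard_curve")
  expect_error(simulate_dilution_series(true_e = 2), "0.5")
})

test_that("screening generator encodes its own truth", {
  sim <- simulate_screening_table(n_families = 6, per_family = 8, seed = 31)
  res <- select_candidates(sim$table)
  got <- sapply(split(res, res$family), function(d)
    if (any(d$selected)) d$gene_id[d$selected] else NA_character_)
  expect_identical(unname(got[sim$truth$family]),
                   sim$truth$expected_gene)
})

test_that("loading shifts cancel in geNorm/NormFinder but not BestKeeper", {
  cfg <- default_sim_config(seed = 21, tau = 0)
  cfg0 <- sim_config(cfg$genes, cfg$design[cfg$design$set == "stress" &
                                             cfg$design$tissue == "leaf", ],
                     cfg$effects, tau = 0, seed = 21)
  sim <- simulate_ct(cfg0)
  shifts <- seq(-1, 1, length.out = length(sim$ct$samples))
  ct_shift <- sim$ct$ct + matrix(rep(shifts, each = 10), 10)
  m0 <- sim$ct
  m1 <- ct_matrix(ct_shift, sim$ct$meta)
  expect_equal(genorm(m1)$table$m_single, genorm(m0)$table$m_single,
               tolerance = 1e-10)
  expect_equal(normfinder(m1, m1$meta$group)$table$stability,
               normfinder(m0, m0$meta$group)$table$stability,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(bestkeeper(m1)$table$sd,
                                bestkeeper(m0)$table$sd)))
})

test_that("stability methods converge to truth order as separation grows", {
  sds <- c(0.05, 0.05, 0.1, 0.3, 0.8, 1.4)
  genes <- data.frame(gene = paste0("g", 1:6), baseline = 25, sigma = sds)
  design <- data.frame(sample_id = paste0("s", 1:40), set = "x",
                       group = rep(paste0("grp", 1:4), each = 10),
                       tissue = NA, time = NA, replicate = 1:40)
  rhos <- sapply(1:10, function(seed) {
    sim <- simulate_ct(sim_config(genes, design, NULL, tau = 0.5, seed = seed))
    truth <- sim$truth$score
    g <- genorm(sim$ct)
    nf <- normfinder(sim$ct)
    bk <- bestkeeper(sim$ct)
    c(cor(g$table$m_single, truth[g$table$gene], method = "spearman"),
      cor(setNames(nf$table$stability, nf$table$gene)[names(truth)], truth,
          method = "spearman"),
      cor(setNames(bk$table$sd, bk$table$gene)[names(truth)], truth,
          method = "spearman"))
  })
  expect_true(all(rowMeans(rhos) >= 0.9))
})
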