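# Fixed toy fixtures and independent, loop-style oracle implementations.
# The oracles deliberately avoid the package's code paths: everything is
# written as explicit per-element arithmetic, the way one would lay the
# computation out in a spreadsheet.

# T1: 3 genes x 4 samples, values chosen by hand (no structure intended)
fixture_t1 <- function() {
  ct <- matrix(c(20.1, 21.3, 19.8, 20.9,
                 25.0, 26.4, 24.6, 25.8,
                 30.2, 30.9, 31.8, 29.7),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  ct_matrix(ct)
}

# T2: 3 genes x 2 groups x 3 samples for the model-based (NormFinder) oracle
fixture_t2 <- function() {
  ct <- matrix(c(20.0, 20.3, 19.8, 21.1, 21.4, 20.9,
                 24.9, 25.2, 25.4, 25.0, 24.7, 25.3,
                 30.5, 30.1, 30.6, 32.2, 32.6, 31.9),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6), set = "all",
                     group = rep(c("G1", "G2"), each = 3),
                     tissue = NA, time = NA, replicate = NA)
  ct_matrix(ct, meta)
}

sample_sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# relative quantities, one element at a time
oracle_q <- function(ct, base = 2) {
  q <- ct
  for (i in seq_len(nrow(ct))) {
    mn <- min(ct[i, ])
    for (j in seq_len(ncol(ct))) q[i, j] <- base^(mn - ct[i, j])
  }
  q
}

# full pairwise-variation matrix V_jk = sd over samples of log2(Qj/Qk)
oracle_v_matrix <- function(q) {
  G <- nrow(q)
  V <- matrix(0, G, G, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(G)) for (k in seq_len(G)) if (j != k) {
    ratios <- numeric(ncol(q))
    for (s in seq_len(ncol(q))) ratios[s] <- log2(q[j, s] / q[k, s])
    V[j, k] <- sample_sd_oracle(ratios)
  }
  V
}

oracle_m <- function(q, subset = rownames(q)) {
  V <- oracle_v_matrix(q[subset, , drop = FALSE])
  out <- numeric(length(subset))
  for (j in seq_along(subset))
    out[j] <- mean(V[j, -j])
  names(out) <- subset
  out
}

# stepwise exclusion by brute force; tie on max M removes the later gene
oracle_genorm_stepwise <- function(q) {
  current <- rownames(q)
  removed <- character(0)
  while (length(current) > 2) {
    mv <- oracle_m(q, current)
    worst <- current[max(which(mv == max(mv)))]
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
  }
  list(removed = removed, final_pair = current,
       order = c(current, rev(removed)))
}

oracle_v_series <- function(q, stability_order) {
  G <- length(stability_order)
  nf <- function(n) {
    sapply(seq_len(ncol(q)), function(s) {
      vals <- q[stability_order[1:n], s]
      exp(sum(log(vals)) / n)
    })
  }
  v <- numeric(G - 2)
  for (n in 2:(G - 1))
    v[n - 1] <- sample_sd_oracle(log2(nf(n) / nf(n + 1)))
  v
}

# spreadsheet-style BestKeeper: per-gene stats + correlation with the
# geometric-mean index
oracle_bestkeeper <- function(ct) {
  idx <- sapply(seq_len(ncol(ct)), function(s)
    exp(mean(log(ct[, s]))))
  out <- data.frame(gene = rownames(ct), sd = NA_real_, cv = NA_real_,
                    r = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ct))) {
    x <- ct[i, ]
    out$sd[i] <- sample_sd_oracle(x)
    out$cv[i] <- 100 * out$sd[i] / mean(x)
    out$r[i] <- suppressWarnings(cor(x, idx))
  }
  out
}

# straight-line transcription of the model-based stability estimators:
# sample centering, centering-bias-corrected group variances, moment
# estimate of the inter-group variance, shrinkage, S = |d~| + posterior SD
oracle_normfinder_grouped <- function(ct, groups) {
  k <- nrow(ct)
  y <- -ct
  z <- y
  for (j in seq_len(ncol(y))) z[, j] <- y[, j] - mean(y[, j])
  glev <- unique(groups)
  G <- length(glev)
  zbar <- v <- sig2 <- u <- d <- matrix(0, k, G,
                                        dimnames = list(rownames(ct), glev))
  for (gi in seq_len(G)) {
    cols <- which(groups == glev[gi])
    for (i in seq_len(k)) {
      zbar[i, gi] <- mean(z[i, cols])
      v[i, gi] <- sum((z[i, cols] - zbar[i, gi])^2) / (length(cols) - 1)
    }
    for (i in seq_len(k)) {
      est <- (v[i, gi] - mean(v[, gi]) / (k - 1)) * k / (k - 2)
      sig2[i, gi] <- max(0, est)
      u[i, gi] <- sig2[i, gi] / length(cols)
    }
  }
  for (i in seq_len(k)) d[i, ] <- zbar[i, ] - mean(zbar[i, ])
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(u))
  S <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) {
      w <- if (gamma2 + u[i, gi] > 0) gamma2 / (gamma2 + u[i, gi]) else 0
      acc <- acc + abs(d[i, gi] * w) + sqrt(u[i, gi] * w)
    }
    S[i] <- acc / G
  }
  names(S) <- rownames(ct)
  S
}

# brute-force per-family scan for the screening filter
oracle_select <- function(tab) {
  out <- character(0)
  for (fam in unique(tab$family)) {
    rows <- tab[tab$family == fam, ]
    l2r <- abs(log2(rows$r_fpkm / rows$w_fpkm))
    ok <- which(l2r < 1)
    out[fam] <- if (length(ok)) {
      cand <- rows$gene_id[ok]
      cand[order(l2r[ok], cand)][1]
    } else NA_character_
  }
  out
}

# small random ct_matrix generator for property tests
random_ct <- function(genes = 5, samples = 8, seed = 1, sd = 0.5, base_ct = 25) {
  set.seed(seed)
  ct <- matrix(base_ct + rnorm(genes * samples, 0, sd), genes, samples,
               dimnames = list(paste0("g", seq_len(genes)),
                               paste0("s", seq_len(samples))))
  ct_matrix(ct)
}
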