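#' Simulation configuration for synthetic Ct data
#'
#' Describes the generative model
#' `Ct_igr = B_i + L_s + delta_ig + eps_igr` with per-gene baseline Ct
#' `B_i`, a per-sample (per-reaction) loading shift `L_s ~ N(0, tau^2)`
#' shared by all genes of that sample, a deterministic group regulation
#' effect `delta_ig` in cycles, and gene-specific Gaussian noise
#' `eps ~ N(0, sigma_i^2)` (optionally t-distributed for robustness
#' checks). Normal noise on the Ct scale is multiplicative on the quantity
#' scale, the standard qPCR error model.
#'
#' @param genes `data.frame` with columns `gene`, `baseline` (cycles),
#'   `sigma` (cycles, >= 0)
#' @param design `data.frame` with columns `sample_id`, `set`, `group`,
#'   `tissue`, `time`, `replicate` — one row per reaction
#' @param effects optional `data.frame` with columns `gene`, `group`,
#'   `delta` and optionally `tissue` (`NA` = any tissue); rows give the
#'   regulation shift of a gene in a group
#' @param tau per-sample loading SD in cycles (>= 0)
#' @param seed integer seed fixing all randomness
#' @param noise `"normal"` (default) or `"t"` (df = 3, scaled to SD sigma)
#' @return object of class `sim_config`
#' @export
sim_config <- function(genes, design, effects = NULL, tau = 0.5, seed = 1,
                       noise = c("normal", "t")) {
  noise <- match.arg(noise)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "baseline", "sigma") %in% names(genes)),
            all(c("sample_id", "set", "group", "replicate") %in% names(design)))
  if (any(genes$sigma < 0)) stopf("sigma must be >= 0")
  if (tau < 0) stopf("tau must be >= 0")
  if (any(design$replicate < 1)) stopf("replicates must be >= 1")
  if (any(is.na(design$group) | !nzchar(design$group)))
    stopf("every design row needs a group label")
  for (col in c("tissue", "time")) if (!col %in% names(design)) design[[col]] <- NA
  if (!is.null(effects)) {
    effects <- as.data.frame(effects, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "group", "delta") %in% names(effects)))
    if (!"tissue" %in% names(effects)) effects$tissue <- NA
  }
  structure(list(genes = genes, design = design, effects = effects,
                 tau = tau, seed = as.integer(seed), noise = noise),
            class = "sim_config")
}

#' Default configuration mirroring a full reference-gene study
#'
#' Ten candidate genes across the classic five-way design: 6 cultivars, 7
#' organs and 3 abiotic stresses x 5 time points x 2 tissues, each with 3
#' biological replicates. Baseline Ct values follow typical mean Ct of
#' the usual candidate families; noise SDs and regulation effects encode a
#' ground truth in which PP2A/SAND/RH 8 are stable and TUBB/GAPDH/F-box
#' carry both higher noise and condition-specific regulation.
#'
#' @param seed integer seed
#' @param tau per-sample loading SD (cycles)
#' @return a [sim_config()]
#' @export
default_sim_config <- function(seed = 1, tau = 0.5) {
  genes <- data.frame(
    gene = c("ACTIN", "CYP2", "EF1a", "Fbox", "GAPDH",
             "18S", "PP2A", "RH8", "SAND", "TUBB"),
    baseline = c(25.89, 20.84, 24.76, 30.56, 28.96,
                 27.20, 26.37, 27.13, 28.42, 26.84),
    sigma = c(0.30, 0.20, 0.30, 0.35, 0.40,
              0.20, 0.15, 0.18, 0.15, 0.45),
    stringsAsFactors = FALSE)

  cultivars <- c("Brewer", "BainFav1", "Bain11", "HollisterRed", "Bain6",
                 "Washington")
  organs <- c("root", "stem", "leaf", "flower", "white_fruit", "red_fruit",
              "seed")
  stresses <- c("salt", "alkali", "drought")
  times <- c(0, 3, 6, 9, 12)
  reps <- 1:3

  design <- rbind(
    expand.grid(set = "cultivars", group = cultivars, tissue = "leaf",
                time = NA_real_, replicate = reps, stringsAsFactors = FALSE),
    expand.grid(set = "organs", group = organs, tissue = NA_character_,
                time = NA_real_, replicate = reps, stringsAsFactors = FALSE),
    expand.grid(set = "stress", group = stresses, tissue = c("leaf", "root"),
                time = times, replicate = reps, stringsAsFactors = FALSE))
  design$sample_id <- paste0(design$set, ".", design$group,
                             ifelse(is.na(design$tissue), "",
                                    paste0(".", design$tissue)),
                             ifelse(is.na(design$time), "",
                                    paste0(".t", design$time)),
                             ".r", design$replicate)

  effects <- data.frame(
    gene   = c("TUBB", "TUBB", "TUBB", "GAPDH", "GAPDH", "GAPDH",
               "EF1a", "Fbox", "ACTIN", "ACTIN", "Fbox"),
    group  = c("salt", "alkali", "drought", "flower", "red_fruit", "seed",
               "drought", "salt", "Brewer", "Washington", "alkali"),
    tissue = c(NA, NA, NA, NA, NA, NA, "leaf", "root", NA, NA, NA),
    delta  = c(1.0, -0.8, 0.6, 0.8, -0.6, 0.7,
               0.8, -0.7, 0.3, -0.3, 0.5),
    stringsAsFactors = FALSE)

  sim_config(genes, design, effects, tau = tau, seed = seed)
}

#' Simulate a Ct matrix with known ground truth
#'
#' Draws Ct values under the generative model of [sim_config()] and
#' returns both the data and the implied true stability structure: per
#' gene, the instability score `sqrt(sigma_i^2 + var_g(delta_ig))` (the
#' population variance of its regulation effect over all distinct
#' group/tissue conditions in the design, zero where no effect is
#' declared) and the resulting true stability order.
#'
#' @param config a [sim_config()]
#' @return list with `ct` (a [ct_matrix()], one column per design row) and
#'   `truth` (list: `score` named vector, `order` gene labels most to
#'   least stable)
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  design <- config$design
  k <- nrow(genes)
  ns <- nrow(design)
  if (!ns) stopf("empty design")

  delta <- matrix(0, k, ns, dimnames = list(genes$gene, design$sample_id))
  if (!is.null(config$effects)) {
    for (r in seq_len(nrow(config$effects))) {
      e <- config$effects[r, ]
      if (!e$gene %in% genes$gene) stopf("effect for unknown gene '%s'", e$gene)
      hit <- design$group == e$group &
        (is.na(e$tissue) | (!is.na(design$tissue) & design$tissue == e$tissue))
      delta[e$gene, hit] <- delta[e$gene, hit] + e$delta
    }
  }

  loading <- rnorm(ns, 0, config$tau)
  eps <- matrix(0, k, ns)
  for (i in seq_len(k)) {
    eps[i, ] <- if (config$noise == "normal")
      rnorm(ns, 0, genes$sigma[i])
    else genes$sigma[i] * stats::rt(ns, df = 3) / sqrt(3)
  }
  ct <- genes$baseline + delta + rep(loading, each = k) + eps
  dimnames(ct) <- list(genes$gene, design$sample_id)

  meta <- design[, c("sample_id", "set", "group", "tissue", "time", "replicate")]

  # ground truth: population variance of delta over the distinct conditions
  cond <- unique(paste(design$set, design$group, design$tissue, sep = "\r"))
  cond_idx <- match(cond, paste(design$set, design$group, design$tissue, sep = "\r"))
  dmat <- delta[, cond_idx, drop = FALSE]
  pop_var <- apply(dmat, 1, function(x) mean((x - mean(x))^2))
  score <- sqrt(genes$sigma^2 + pop_var)
  names(score) <- genes$gene
  ord <- names(sort(score))

  list(ct = ct_matrix(ct, meta), truth = list(score = score, order = ord))
}

#' Simulate a serial-dilution Ct series for standard-curve QC
#'
#' Ct at relative template amount d is
#' `intercept - log(d) / log(1 + true_e)` plus Gaussian noise: each
#' dilution step of a `fold`-fold series adds `log(fold)/log(1 + E)`
#' cycles.
#'
#' @param true_e true amplification efficiency as a fraction (0.5-1.5)
#' @param sigma_ct replicate noise SD in cycles
#' @param n_dilutions number of dilution points (>= 3 for a fit)
#' @param replicates reactions per dilution
#' @param fold dilution factor between steps (default 5)
#' @param intercept Ct of the undiluted sample
#' @param gene gene label for the output table
#' @param seed optional integer seed
#' @return `data.frame` with columns `gene`, `dilution`, `ct`
#' @export
simulate_dilution_series <- function(true_e = 1.0, sigma_ct = 0.05,
                                     n_dilutions = 5, replicates = 3,
                                     fold = 5, intercept = 20, gene = "sim",
                                     seed = NULL) {
  if (true_e < 0.5 || true_e > 1.5) stopf("true_e must be in [0.5, 1.5]")
  if (!is.null(seed)) set.seed(seed)
  d <- rep(fold^-(seq_len(n_dilutions) - 1), each = replicates)
  ct <- intercept - log(d) / log(1 + true_e) +
    rnorm(length(d), 0, sigma_ct)
  data.frame(gene = gene, dilution = d, ct = ct, stringsAsFactors = FALSE)
}

#' Simulate a two-library screening table with known family minima
#'
#' Generates gene families with log-normal FPKM in the first library and
#' log2 ratios drawn uniformly from (-2, 2), so members fall on both sides
#' of the |log2Ratio| = 1 significance filter. The sidecar truth records,
#' per family, the member a brute-force scan would select (smallest
#' |log2Ratio| among those < 1) or `NA` when the whole family fails the
#' filter.
#'
#' @param n_families number of gene families (>= 1)
#' @param per_family members per family
#' @param seed optional integer seed
#' @return list with `table` (`family`, `gene_id`, `length`, `w_fpkm`,
#'   `r_fpkm`) and `truth` (`family`, `expected_gene`)
#' @export
simulate_screening_table <- function(n_families = 10, per_family = 5,
                                     seed = NULL) {
  if (n_families < 1) stopf("need >= 1 family")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("FAM%02d", f)
    ids <- sprintf("%s.g%02d", fam, seq_len(per_family))
    w <- exp(rnorm(per_family, log(20), 1))
    l2r <- runif(per_family, -2, 2)
    r <- w * 2^l2r
    rows[[f]] <- data.frame(family = fam, gene_id = ids,
                            length = sample(300:2500, per_family, replace = TRUE),
                            w_fpkm = w, r_fpkm = r, stringsAsFactors = FALSE)
    ok <- abs(l2r) < 1
    truth[[f]] <- data.frame(
      family = fam,
      expected_gene = if (any(ok)) ids[ok][which.min(abs(l2r)[ok])] else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), truth = do.call(rbind, truth))
}
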