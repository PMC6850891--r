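#' Relative quantities from Ct values
#'
#' Converts each gene's Ct row to relative quantities
#' `Q = base^(Ctmin - Ct)`, so the sample with the lowest Ct (highest
#' expression) gets Q = 1 and every other sample a value in (0, 1]. The
#' default base 2 assumes perfect doubling; an efficiency-corrected base
#' `1 + E` per gene may be supplied instead.
#'
#' @param m a [ct_matrix()]
#' @param base scalar or per-gene vector of amplification bases (> 1)
#' @return genes x samples numeric matrix of relative quantities
#' @export
relative_quantities <- function(m, base = 2) {
  stopifnot(inherits(m, "ct_matrix"))
  if (any(base <= 1)) stopf("base must be > 1 (use 1 + efficiency)")
  base <- rep_len(base, length(m$genes))
  q <- m$ct
  for (i in seq_along(m$genes))
    q[i, ] <- base[i]^(min(m$ct[i, ]) - m$ct[i, ])
  q
}

#' Pairwise variation between two genes
#'
#' The geNorm pairwise variation `V_jk`: the standard deviation (n-1
#' denominator) over samples of the log2 ratio of the two genes' relative
#' quantities. Two perfectly co-regulated genes have V = 0 regardless of
#' their expression levels.
#'
#' @param qj,qk relative-quantity rows of equal length (>= 2 samples)
#' @return the pairwise variation (log2 units)
#' @export
gene_pair_variation <- function(qj, qk) {
  if (length(qj) != length(qk)) stopf("rows differ in length")
  if (length(qj) < 2) stopf("need >= 2 samples")
  stats::sd(log2(qj / qk))
}

#' geNorm M values for a gene subset
#'
#' `M_j` is the arithmetic mean of `V_jk` over all other genes k in the
#' subset; lower M = more stable.
#'
#' @param q relative-quantity matrix from [relative_quantities()]
#' @param subset gene labels to evaluate (default: all rows of `q`)
#' @return named numeric vector of M values
#' @export
m_values <- function(q, subset = rownames(q)) {
  if (length(subset) < 2) stopf("M undefined for fewer than 2 genes")
  lq <- log2(q[subset, , drop = FALSE])
  vapply(seq_along(subset), function(j) {
    others <- setdiff(seq_along(subset), j)
    mean(vapply(others, function(k) stats::sd(lq[j, ] - lq[k, ]), numeric(1)))
  }, numeric(1)) |> setNames(subset)
}

#' geNorm stability analysis with stepwise exclusion
#'
#' Runs the full geNorm procedure on a Ct matrix: relative quantities,
#' single-pass M values on the whole panel, stepwise removal of the least
#' stable gene (highest M, recomputing M at each step) down to the final
#' untied pair, and the pairwise-variation series `V_n/n+1` of
#' normalization factors that recommends how many reference genes are
#' needed.
#'
#' Two rankings are reported: `rank_stepwise` from the exclusion order
#' (final two genes tied at rank 1) and `rank_single` from the single-pass
#' M values (distinct ranks). The single-pass ranking is the default input
#' to [consensus_rank()].
#'
#' @param m a [ct_matrix()] with >= 3 genes
#' @param base amplification base passed to [relative_quantities()]
#' @param v_threshold pairwise-variation cutoff below which n genes are
#'   deemed sufficient (default 0.15)
#' @param m_cutoff M value above which a gene is flagged unsuitable as a
#'   reference (default 1.5)
#' @return object of class `genorm_result`: list with `table` (per-gene
#'   `m_single`, `rank_single`, `m_at_removal`, `exclusion_rank`,
#'   `rank_stepwise`, `flagged`), `best_pair` (the tied final two and their
#'   shared M), `stability_order` (most to least stable, stepwise),
#'   `v_series` (`data.frame` of n, `v`, `below_threshold`),
#'   `recommended_n`, and `nf` (normalization factors per n)
#' @export
genorm <- function(m, base = 2, v_threshold = 0.15, m_cutoff = 1.5) {
  stopifnot(inherits(m, "ct_matrix"))
  genes <- m$genes
  if (length(genes) < 3) stopf("geNorm needs >= 3 genes")
  if (length(m$samples) < 2) stopf("geNorm needs >= 2 samples")
  q <- relative_quantities(m, base = base)

  m_single <- m_values(q)

  # stepwise exclusion: drop the highest-M gene until two remain;
  # tie on highest M -> remove the later gene in input order
  current <- genes
  removal <- character(0)
  m_at_removal <- numeric(0)
  while (length(current) > 2) {
    mv <- m_values(q, current)
    worst_i <- max(which(mv == max(mv)))
    removal <- c(removal, current[worst_i])
    m_at_removal <- c(m_at_removal, mv[worst_i])
    current <- current[-worst_i]
  }
  final_pair <- current
  pair_m <- m_values(q, final_pair)[1]  # both equal V of the pair

  stability_order <- c(final_pair, rev(removal))  # most stable first
  exclusion_rank <- setNames(rep(NA_integer_, length(genes)), genes)
  exclusion_rank[removal] <- seq_along(removal)
  rank_stepwise <- setNames(integer(length(genes)), genes)
  rank_stepwise[final_pair] <- 1L
  rank_stepwise[rev(removal)] <- 2L + seq_along(removal)

  m_rem <- setNames(rep(NA_real_, length(genes)), genes)
  m_rem[removal] <- m_at_removal
  m_rem[final_pair] <- pair_m

  tab <- data.frame(gene = genes,
                    m_single = unname(m_single[genes]),
                    rank_single = competition_rank(m_single[genes]),
                    m_at_removal = unname(m_rem[genes]),
                    exclusion_rank = unname(exclusion_rank[genes]),
                    rank_stepwise = unname(rank_stepwise[genes]),
                    flagged = unname(m_single[genes] > m_cutoff),
                    stringsAsFactors = FALSE)

  pv <- pairwise_variation_nf(q, stability_order, threshold = v_threshold)

  structure(list(table = tab,
                 best_pair = list(genes = final_pair, m = unname(pair_m)),
                 stability_order = stability_order,
                 v_series = pv$v_series, recommended_n = pv$recommended_n,
                 nf = pv$nf, base = base,
                 v_threshold = v_threshold, m_cutoff = m_cutoff),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm analysis\n")
  cat("  best pair:", paste(x$best_pair$genes, collapse = " & "),
      sprintf("(M = %.3f)\n", x$best_pair$m))
  cat("  recommended n:",
      if (is.na(x$recommended_n)) "none below threshold (use 2-3 most stable)"
      else x$recommended_n, "\n")
  invisible(x)
}

#' Pairwise variation of normalization factors (V_n/n+1)
#'
#' `NF_n` for a sample is the geometric mean of the relative quantities of
#' the n most stable genes; `V_n/n+1` is the SD over samples of
#' `log2(NF_n / NF_n+1)`, computed for n = 2 .. G-1. The recommended number
#' of reference genes is the smallest n with `V_n/n+1` below the threshold;
#' if no V falls below it, `recommended_n` is `NA` and the 2-3 most stable
#' genes should be chosen from the V-value trend.
#'
#' @param q relative-quantity matrix
#' @param ranking gene labels ordered most to least stable (e.g.
#'   `stability_order` from [genorm()])
#' @param threshold V cutoff (default 0.15)
#' @return list with `v_series` (`data.frame`: `n`, `v`,
#'   `below_threshold`), `recommended_n`, and `nf` (list of per-sample
#'   normalization factors for each n)
#' @export
pairwise_variation_nf <- function(q, ranking, threshold = 0.15) {
  G <- length(ranking)
  if (G < 3) stopf("V_n/n+1 needs >= 3 genes")
  if (!all(ranking %in% rownames(q))) stopf("ranking names genes absent from q")
  nf <- lapply(2:G, function(n)
    apply(q[ranking[1:n], , drop = FALSE], 2, geo_mean))
  names(nf) <- paste0("NF", 2:G)
  v <- vapply(seq_len(G - 2), function(i)
    stats::sd(log2(nf[[i]] / nf[[i + 1]])), numeric(1))
  v_series <- data.frame(n = 2:(G - 1), v = v, below_threshold = v < threshold)
  rec <- if (any(v_series$below_threshold))
    v_series$n[which(v_series$below_threshold)[1]] else NA_integer_
  list(v_series = v_series, recommended_n = rec, nf = nf)
}
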