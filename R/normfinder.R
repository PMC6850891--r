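#' NormFinder model-based stability analysis
#'
#' Estimates a per-gene stability value S from a variance decomposition of
#' log-scale expression. Ct values are taken to the log2 expression scale
#' (`y = -Ct`; per-gene constants cancel), each sample is centered by its
#' across-gene mean to remove loading differences, and the centered values
#' `z` are decomposed into intra-group variance and inter-group expression
#' differences.
#'
#' Grouped mode (a partition of the samples is supplied): per gene i and
#' group g the within-group variance of z is bias-corrected for the
#' centering step,
#' `sigma2_ig = (v_ig - mean_l(v_lg)/(k-1)) * k/(k-2)` (k = number of
#' genes, clamped at 0), the inter-group difference
#' `d_ig = mean_j(z_igj) - mean_g(...)` is shrunk toward 0 by the
#' empirical-Bayes factor `gamma2 / (gamma2 + sigma2_ig/n_g)` where
#' `gamma2` is a method-of-moments estimate of the variance of the true
#' group differences, and
#' `S_i = mean_g(|shrunk d_ig| + sqrt(posterior variance of d_ig))`.
#' Ungrouped mode: `S_i` is the bias-corrected SD of the gene's centered
#' values. Lower S = more stable. The best two-gene combination minimises
#' the stability of the averaged pair.
#'
#' @param m a [ct_matrix()] with >= 3 genes
#' @param groups `NULL` (ungrouped), a character vector assigning each
#'   sample of `m` to a group, or a [sample_set()] (the matrix is then
#'   subset to its members and its group partition used)
#' @param simplified logical; `TRUE` skips the shrinkage and uses
#'   `S_i = mean_g(|d_ig| + sqrt(sigma2_ig/n_g))` (transparent but noisier)
#' @return object of class `normfinder_result`: list with `table` (per-gene
#'   `stability` and `rank`), `d` and `sigma2` (gene x group matrices,
#'   grouped mode), `gamma2`, `best_pair` (genes + combined stability),
#'   `mode`
#' @export
normfinder <- function(m, groups = NULL, simplified = FALSE) {
  stopifnot(inherits(m, "ct_matrix"))
  if (inherits(groups, "sample_set")) {
    m <- ct_subset(m, samples = groups$samples)
    groups <- groups$groups
  }
  genes <- m$genes
  k <- length(genes)
  if (k < 3) stopf("NormFinder needs >= 3 genes (sample-centering degenerate)")

  y <- -m$ct                       # log2 expression up to per-gene constants
  z <- sweep(y, 2, colMeans(y))    # remove per-sample loading

  if (is.null(groups)) {
    v <- apply(z, 1, var)
    sigma2 <- correct_centered_var(v, k)
    S <- sqrt(sigma2)
    tab <- data.frame(gene = genes, stability = unname(S),
                      rank = competition_rank(S), stringsAsFactors = FALSE)
    pair <- best_pair_ungrouped(sigma2, genes)
    res <- list(table = tab[order(tab$stability, tab$gene), ],
                d = NULL, sigma2 = matrix(sigma2, ncol = 1,
                                          dimnames = list(genes, "all")),
                gamma2 = NA_real_, best_pair = pair, mode = "ungrouped")
    return(structure(res, class = "normfinder_result"))
  }

  groups <- as.character(groups)
  if (length(groups) != length(m$samples))
    stopf("groups must assign every sample")
  glev <- unique(groups)
  G <- length(glev)
  ng <- table(factor(groups, levels = glev))
  if (any(ng < 2)) stopf("every group needs >= 2 samples")

  zbar <- sapply(glev, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  vraw <- sapply(glev, function(g) apply(z[, groups == g, drop = FALSE], 1, var))
  sigma2 <- apply(vraw, 2, correct_centered_var, k = k)
  dimnames(sigma2) <- dimnames(zbar) <- list(genes, glev)

  u <- sweep(sigma2, 2, as.numeric(ng), "/")   # sampling var of group means
  d <- zbar - rowMeans(zbar)

  if (G < 2) stopf("grouped mode needs >= 2 groups")
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(u))

  if (simplified) {
    S_ig <- abs(d) + sqrt(u)
  } else {
    shrink <- gamma2 / (gamma2 + u)
    shrink[gamma2 + u == 0] <- 0
    d_tilde <- d * shrink
    post_var <- u * shrink
    S_ig <- abs(d_tilde) + sqrt(post_var)
    d <- d_tilde
  }
  S <- rowMeans(S_ig)

  tab <- data.frame(gene = genes, stability = unname(S),
                    rank = competition_rank(S), stringsAsFactors = FALSE)
  pair <- best_pair_grouped(d, u, gamma2, genes, simplified)
  structure(list(table = tab[order(tab$stability, tab$gene), ],
                 d = d, sigma2 = sigma2, gamma2 = gamma2,
                 best_pair = pair, mode = "grouped"),
            class = "normfinder_result")
}

# Unbiased recovery of the per-gene noise variance after the across-gene
# sample centering: with k genes, E[v_i] = sigma2_i (1 - 2/k) + mean(sigma2)/k,
# which inverts to the expression below. Negative estimates are clamped to 0.
correct_centered_var <- function(v, k) {
  if (k < 3) stopf("variance correction needs >= 3 genes")
  est <- (v - mean(v) / (k - 1)) * k / (k - 2)
  bad <- est < 0
  if (any(bad)) est[bad] <- 0
  est
}

best_pair_ungrouped <- function(sigma2, genes) {
  best <- list(genes = NULL, stability = Inf)
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in seq((i + 1), length(genes))) {
      s <- sqrt(sigma2[i] + sigma2[j]) / 2   # SD of the two-gene average
      if (s < best$stability)
        best <- list(genes = genes[c(i, j)], stability = unname(s))
    }
  }
  best
}

best_pair_grouped <- function(d, u, gamma2, genes, simplified) {
  shrinkv <- if (simplified) u else u * gamma2 / (gamma2 + u)
  shrinkv[!is.finite(shrinkv)] <- 0
  best <- list(genes = NULL, stability = Inf)
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in seq((i + 1), length(genes))) {
      s <- mean(abs(d[i, ] + d[j, ]) / 2 + sqrt((shrinkv[i, ] + shrinkv[j, ]) / 4))
      if (s < best$stability)
        best <- list(genes = genes[c(i, j)], stability = s)
    }
  }
  best
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder (%s mode)\n", x$mode))
  cat("  most stable:", x$table$gene[1],
      sprintf("(S = %.3f)\n", x$table$stability[1]))
  if (!is.null(x$best_pair$genes))
    cat("  best pair:", paste(x$best_pair$genes, collapse = " & "),
        sprintf("(%.3f)\n", x$best_pair$stability))
  invisible(x)
}
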