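#' BestKeeper descriptive stability analysis
#'
#' Works directly on raw Ct values. Per gene it reports the geometric and
#' arithmetic mean Ct, min/max, the dispersion (classical sample SD by
#' default, or the original spreadsheet's mean absolute deviation around
#' the arithmetic mean with `mad = TRUE`), the CV as a percentage of the
#' mean Ct, and the Pearson correlation (with two-sided p value) between
#' the gene's Ct profile and the BestKeeper index — the per-sample
#' geometric mean of all candidate genes' Ct. Genes are ranked ascending by
#' dispersion and a gene with SD < 1 cycle is flagged as stably expressed.
#'
#' Because BestKeeper operates on raw Ct, it is deliberately sensitive to
#' sample-loading shifts that geNorm and NormFinder cancel out.
#'
#' @param m a [ct_matrix()] with >= 2 genes and >= 3 samples
#' @param cv_mean `"arithmetic"` (default) or `"geometric"`: which mean Ct
#'   forms the CV denominator
#' @param mad logical; `TRUE` replaces the sample SD with the mean absolute
#'   deviation around the arithmetic mean Ct (the original tool's variant)
#' @param exclude_self logical; `TRUE` correlates each gene against the
#'   index computed from the *other* genes only
#' @param sd_threshold stability cutoff in cycles (default 1)
#' @return object of class `bestkeeper_result`: list with `table`
#'   (per-gene `geo_mean`, `ar_mean`, `min_ct`, `max_ct`, `sd`, `cv_pct`,
#'   `r`, `p`, `rank`, `stable`) and `index` (per-sample geometric mean Ct)
#' @export
bestkeeper <- function(m, cv_mean = c("arithmetic", "geometric"), mad = FALSE,
                       exclude_self = FALSE, sd_threshold = 1) {
  stopifnot(inherits(m, "ct_matrix"))
  cv_mean <- match.arg(cv_mean)
  if (length(m$genes) < 2) stopf("BestKeeper needs >= 2 genes")
  if (length(m$samples) < 3) stopf("BestKeeper needs >= 3 samples")
  ct <- m$ct
  index <- apply(ct, 2, geo_mean)

  rows <- lapply(m$genes, function(g) {
    x <- ct[g, ]
    am <- mean(x)
    disp <- if (mad) mean(abs(x - am)) else stats::sd(x)
    denom <- if (cv_mean == "arithmetic") am else geo_mean(x)
    idx <- if (exclude_self)
      apply(ct[setdiff(m$genes, g), , drop = FALSE], 2, geo_mean) else index
    if (stats::sd(x) == 0 || stats::sd(idx) == 0) {
      warnf("gene '%s': zero variance, index correlation undefined", g)
      r <- p <- NA_real_
    } else {
      h <- cor.test(x, idx, method = "pearson")
      r <- unname(h$estimate)
      p <- h$p.value
    }
    data.frame(gene = g, geo_mean = geo_mean(x), ar_mean = am,
               min_ct = min(x), max_ct = max(x), sd = disp,
               cv_pct = 100 * disp / denom, r = r, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$rank <- competition_rank(tab$sd)
  tab$stable <- tab$sd < sd_threshold
  rownames(tab) <- NULL
  structure(list(table = tab, index = index, mad = mad,
                 sd_threshold = sd_threshold),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  best <- x$table$gene[x$table$rank == 1]
  cat("BestKeeper analysis\n")
  cat("  most stable:", paste(best, collapse = ", "),
      sprintf("(SD = %.3f)\n", min(x$table$sd)))
  cat(sprintf("  %d/%d genes with SD < %g\n", sum(x$table$stable),
              nrow(x$table), x$sd_threshold))
  invisible(x)
}
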