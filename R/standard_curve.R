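#' Fit a qPCR standard curve from a serial dilution series
#'
#' Ordinary least squares of mean Ct against log10(relative template
#' amount). The undiluted sample defines relative amount 1 (x = 0); because
#' the fit is linear, the slope `k` and hence the amplification efficiency
#' `E = 10^(-1/k) - 1` are invariant to the choice of reference amount.
#' Replicate Ct measurements at the same dilution are averaged before
#' fitting.
#'
#' @param dilutions dilution factors (e.g. `c(1, 1/5, 1/25, 1/125, 1/625)`
#'   for a 5-fold series); replicate entries allowed
#' @param ct matched Ct values (cycles)
#' @return object of class `standard_curve`: list with `slope` (cycles per
#'   log10 unit, negative for a valid curve), `intercept`, `r_squared`,
#'   `efficiency` (fraction, e.g. 1.0 = 100%), `points` (the averaged
#'   dilution/Ct pairs)
#' @examples
#' fit_standard_curve(c(1, 0.2, 0.04), c(20, 22.322, 24.644))
#' @export
fit_standard_curve <- function(dilutions, ct) {
  if (length(dilutions) != length(ct)) stopf("dilutions and ct lengths differ")
  if (any(!is.finite(ct))) stopf("non-finite Ct in dilution series")
  if (any(dilutions <= 0)) stopf("dilution factors must be > 0")
  # average replicates per dilution
  agg <- tapply(ct, dilutions, mean)
  d <- as.numeric(names(agg))
  y <- as.numeric(agg)
  if (length(d) < 3) stopf("need >= 3 distinct dilutions to fit a curve")
  x <- log10(d / max(d))
  if (var(x) == 0) stopf("zero variance in log10 dilution")
  fit <- lm(y ~ x)
  k <- unname(coef(fit)[2])
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(list(slope = k, intercept = unname(coef(fit)[1]),
                 r_squared = r2, efficiency = efficiency_from_slope(k),
                 points = data.frame(dilution = d, ct = y)),
            class = "standard_curve")
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/k) - 1`; a slope of `-1/log10(2) = -3.3219` corresponds to
#' perfect doubling (E = 1, i.e. 100%).
#'
#' @param k slope in cycles per log10 unit (negative for valid curves)
#' @return efficiency as a fraction
#' @export
efficiency_from_slope <- function(k) {
  if (any(k == 0)) stopf("slope of 0 has undefined efficiency")
  10^(-1 / k) - 1
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, R^2 %.4f, E %.1f%%\n",
              x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Primer QC table over a batch of standard curves
#'
#' Flags genes whose amplification efficiency falls outside an acceptance
#' band or whose regression coefficient is too low. The default band
#' (90-110% efficiency, R^2 >= 0.99) is lab policy, not a property of the
#' fitting; adjust to taste.
#'
#' @param curves named list of [fit_standard_curve()] results (names = genes)
#' @param e_band length-2 numeric, efficiency acceptance band as fractions
#' @param r2_min minimum acceptable R^2
#' @return `data.frame` with columns `gene`, `slope`, `r_squared`,
#'   `efficiency_pct`, `pass`
#' @export
efficiency_report <- function(curves, e_band = c(0.90, 1.10), r2_min = 0.99) {
  stopifnot(length(e_band) == 2, e_band[1] < e_band[2])
  rows <- lapply(names(curves), function(g) {
    cv <- curves[[g]]
    data.frame(gene = g, slope = cv$slope, r_squared = cv$r_squared,
               efficiency_pct = 100 * cv$efficiency,
               pass = cv$efficiency >= e_band[1] & cv$efficiency <= e_band[2] &
                 !is.na(cv$r_squared) & cv$r_squared >= r2_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit standard curves for every gene in a dilution-series table
#'
#' @param df `data.frame` with columns `gene`, `dilution`, `ct` (replicate
#'   rows allowed)
#' @return named list of `standard_curve` objects
#' @export
fit_standard_curves <- function(df) {
  need <- c("gene", "dilution", "ct")
  if (!all(need %in% names(df))) stopf("need columns gene, dilution, ct")
  out <- lapply(split(df, df$gene), function(d)
    fit_standard_curve(d$dilution, d$ct))
  out[unique(df$gene)]
}
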