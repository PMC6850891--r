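#' RPKM expression level
#'
#' Reads per kilobase of transcript per million aligned reads:
#' `10^9 * C / (N * L)` where `C` is the number of reads aligned to the
#' transcript, `N` the total number of aligned reads in the library and `L`
#' the transcript length in bases. Vectorised over all arguments.
#'
#' @param c aligned read count for the transcript (>= 0)
#' @param n total aligned reads in the library (> 0)
#' @param l transcript length in bases (> 0)
#' @return RPKM value(s)
#' @examples
#' rpkm(1000, 1e7, 1000) # 100
#' @export
rpkm <- function(c, n, l) {
  if (any(n <= 0)) stopf("total read count `n` must be > 0")
  if (any(l <= 0)) stopf("length `l` must be > 0")
  if (any(c < 0)) stopf("read count `c` must be >= 0")
  1e9 * as.numeric(c) / (as.numeric(n) * as.numeric(l))
}

#' Signed log2 expression ratio between two libraries
#'
#' `log2(r / w)`; positive values mean enrichment in the first (e.g. red
#' fruit) library, negative in the second (white fruit).
#'
#' @param r,w expression levels (RPKM/FPKM), both strictly positive
#' @param pseudo optional pseudo-count added to both values (default 0;
#'   use e.g. `1e-4` to tolerate zero-expression entries). Its use is logged
#'   with a warning.
#' @return the signed log2 ratio
#' @export
log2ratio <- function(r, w, pseudo = 0) {
  if (pseudo > 0) {
    warnf("log2ratio: applying pseudo-count %g to both libraries", pseudo)
    r <- r + pseudo
    w <- w + pseudo
  }
  if (any(r <= 0) || any(w <= 0))
    stopf("log2ratio undefined for non-positive expression (consider `pseudo`)")
  log2(r / w)
}

#' Screen candidate reference genes from a two-library expression table
#'
#' For each gene family, members whose expression differs significantly
#' between the two libraries (|log2Ratio| >= 1) are excluded; among the
#' survivors the member with the smallest |log2Ratio| is selected as the
#' family's candidate. Families whose members all fail the filter are
#' flagged rather than given a selection.
#'
#' @param records `data.frame` with columns `family`, `gene_id`, `length`,
#'   and either precomputed `w_fpkm`/`r_fpkm` columns or raw-count columns
#'   `w_reads`/`r_reads` plus `w_total`/`r_total` (library totals), from
#'   which RPKM is computed. Mixing both conventions for one library is an
#'   error.
#' @param pseudo passed to [log2ratio()]
#' @return the input with added columns `w_fpkm`/`r_fpkm` (if computed),
#'   `log2ratio`, `abs_log2ratio`, `selected` (logical) and
#'   `excluded_reason` (`NA`, `"significant_difference"` or
#'   `"not_minimum"`); attribute `"flagged_families"` lists families with no
#'   surviving member.
#' @export
select_candidates <- function(records, pseudo = 0) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("family", "gene_id")
  if (!all(need %in% names(records)))
    stopf("records need columns: %s", paste(need, collapse = ", "))
  if (!nrow(records)) stopf("empty screening table")

  has_fpkm <- all(c("w_fpkm", "r_fpkm") %in% names(records))
  has_counts <- all(c("w_reads", "r_reads", "w_total", "r_total") %in% names(records))
  if (has_fpkm && has_counts)
    stopf("provide either FPKM columns or read-count columns, not both")
  if (!has_fpkm && !has_counts)
    stopf("need w_fpkm/r_fpkm or w_reads/r_reads + w_total/r_total columns")
  if (has_counts) {
    if (!"length" %in% names(records))
      stopf("raw counts need a `length` column to compute RPKM")
    records$w_fpkm <- rpkm(records$w_reads, records$w_total, records$length)
    records$r_fpkm <- rpkm(records$r_reads, records$r_total, records$length)
  }

  records$log2ratio <- log2ratio(records$r_fpkm, records$w_fpkm, pseudo = pseudo)
  records$abs_log2ratio <- abs(records$log2ratio)
  records$selected <- FALSE
  records$excluded_reason <- NA_character_

  flagged <- character(0)
  for (fam in unique(records$family)) {
    idx <- which(records$family == fam)
    sig <- records$abs_log2ratio[idx] >= 1
    records$excluded_reason[idx[sig]] <- "significant_difference"
    surv <- idx[!sig]
    if (!length(surv)) {
      flagged <- c(flagged, fam)
      next
    }
    # minimum |log2ratio|; ties broken by lexicographically smallest gene_id
    o <- order(records$abs_log2ratio[surv], records$gene_id[surv])
    pick <- surv[o[1]]
    records$selected[pick] <- TRUE
    records$excluded_reason[setdiff(surv, pick)] <- "not_minimum"
  }
  attr(records, "flagged_families") <- flagged
  records
}

#' Read / write a screening table
#'
#' @param path TSV/CSV file mirroring the two-library screening layout:
#'   columns `family`, `gene_id`, `length`, then `w_fpkm`/`r_fpkm` or the
#'   raw-count quartet (see [select_candidates()]).
#' @return a `data.frame`
#' @export
read_screening_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read_delim_auto(path)
}

#' @rdname read_screening_table
#' @param records screening result from [select_candidates()]
#' @export
write_screening_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
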