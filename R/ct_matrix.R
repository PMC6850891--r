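#' Construct a Ct matrix
#'
#' The central container of the package: a genes x samples matrix of
#' quantification-cycle (Ct, also called Cq) values together with per-sample
#' metadata describing the experimental design (sample set, group, tissue,
#' time point and biological-replicate index).
#'
#' @param ct numeric matrix of Ct values (cycles), genes in rows, samples in
#'   columns; `rownames` are gene labels, `colnames` sample IDs. All values
#'   must be finite and strictly positive.
#' @param meta optional `data.frame` with one row per sample. Recognised
#'   columns: `sample_id`, `set`, `group`, `tissue`, `time`, `replicate`.
#'   Missing columns are filled with `NA`; a missing `meta` gets a minimal
#'   sheet with `set = "all"`.
#'
#' @return an object of class `ct_matrix`: a list with elements `ct` (the
#'   matrix), `meta` (the sample sheet, rows aligned with the columns of
#'   `ct`), `genes` and `samples`.
#' @examples
#' m <- ct_matrix(matrix(c(20, 21, 22, 25, 25.5, 26), nrow = 2, byrow = TRUE,
#'                       dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' summarize_ct(m)
#' @export
ct_matrix <- function(ct, meta = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stopf("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stopf("`ct` needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(ct)))
    stopf("duplicate gene label: %s", rownames(ct)[duplicated(rownames(ct))][1])
  if (anyDuplicated(colnames(ct)))
    stopf("duplicate sample ID: %s", colnames(ct)[duplicated(colnames(ct))][1])
  if (any(!is.finite(ct)))
    stopf("non-finite Ct value at gene '%s', sample '%s'",
          rownames(ct)[which(!is.finite(ct), arr.ind = TRUE)[1, 1]],
          colnames(ct)[which(!is.finite(ct), arr.ind = TRUE)[1, 2]])
  if (any(ct <= 0))
    stopf("Ct values must be > 0")

  meta <- normalize_meta(meta, colnames(ct))
  structure(list(ct = ct, meta = meta,
                 genes = rownames(ct), samples = colnames(ct)),
            class = "ct_matrix")
}

META_COLS <- c("sample_id", "set", "group", "tissue", "time", "replicate")

normalize_meta <- function(meta, samples) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = samples, set = "all", group = NA_character_,
                       tissue = NA_character_, time = NA_real_,
                       replicate = NA_integer_, stringsAsFactors = FALSE)
    return(meta)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stopf("sample sheet must have a 'sample_id' column")
  extra <- setdiff(meta$sample_id, samples)
  if (length(extra))
    stopf("sample sheet names unknown sample(s): %s",
          paste(head(extra, 3), collapse = ", "))
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    stopf("sample sheet does not cover sample(s): %s",
          paste(head(missing, 3), collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stopf("duplicate sample_id in sample sheet")
  for (col in setdiff(META_COLS, names(meta))) meta[[col]] <- NA
  meta <- meta[match(samples, meta$sample_id), META_COLS, drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  cat("sets:", paste(unique(x$meta$set), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a Ct matrix by samples and/or genes
#'
#' @param m a [ct_matrix()]
#' @param samples,genes character vectors of sample IDs / gene labels to keep
#'   (default: keep all)
#' @return a `ct_matrix` restricted to the requested rows/columns
#' @export
ct_subset <- function(m, samples = NULL, genes = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  samples <- samples %||% m$samples
  genes <- genes %||% m$genes
  bad <- setdiff(samples, m$samples)
  if (length(bad)) stopf("unknown sample(s): %s", paste(head(bad, 3), collapse = ", "))
  bad <- setdiff(genes, m$genes)
  if (length(bad)) stopf("unknown gene(s): %s", paste(head(bad, 3), collapse = ", "))
  ct_matrix(m$ct[genes, samples, drop = FALSE],
            m$meta[match(samples, m$meta$sample_id), , drop = FALSE])
}

#' Read a Ct table (wide or long) with its sample sheet
#'
#' Wide layout: first column the gene label, remaining columns one per
#' sample. Long layout: columns `gene`, `sample`, `ct`. Tab- or
#' comma-separated files are auto-detected from the extension (`.csv` =
#' comma, anything else tab). Decimal separator is ".".
#'
#' @param path path to the Ct table
#' @param layout `"wide"` or `"long"`
#' @param sample_sheet optional path to a sample sheet (TSV/CSV with columns
#'   `sample_id`, `set`, `group`, `tissue`, `time`, `replicate`). It must
#'   cover every sample in the table; unknown samples are an error.
#' @param na_action `"error"` (default) fails on missing/non-numeric Ct;
#'   `"drop"` removes the affected samples with a warning.
#' @return a [ct_matrix()]
#' @export
read_ct_table <- function(path, layout = c("wide", "long"), sample_sheet = NULL,
                          na_action = c("error", "drop")) {
  layout <- match.arg(layout)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read_delim_auto(path)

  if (layout == "wide") {
    genes <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(mat) <- "double")
    rownames(mat) <- genes
  } else {
    need <- c("gene", "sample", "ct")
    if (!all(need %in% names(df)))
      stopf("long layout needs columns gene, sample, ct")
    genes <- unique(as.character(df$gene))
    samples <- unique(as.character(df$sample))
    key <- paste(df$gene, df$sample, sep = "\r")
    if (anyDuplicated(key))
      stopf("duplicate (gene, sample) pair in long table")
    mat <- matrix(NA_real_, length(genes), length(samples),
                  dimnames = list(genes, samples))
    mat[cbind(match(df$gene, genes), match(df$sample, samples))] <-
      suppressWarnings(as.numeric(df$ct))
  }

  bad <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    if (na_action == "error")
      stopf("missing or non-numeric Ct at gene '%s', sample '%s'",
            rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]])
    drop_s <- unique(colnames(mat)[bad[, 2]])
    warnf("dropping %d sample(s) with missing Ct: %s", length(drop_s),
          paste(head(drop_s, 5), collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), drop_s), drop = FALSE]
  }

  meta <- if (!is.null(sample_sheet)) read_delim_auto(sample_sheet) else NULL
  ct_matrix(mat, meta)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a Ct matrix (and optionally its sample sheet) to TSV
#'
#' Numeric values are rendered at full double precision so a
#' write-then-read round trip reproduces the Ct values exactly.
#'
#' @param m a [ct_matrix()]
#' @param path output path for the Ct table
#' @param layout `"wide"` or `"long"`
#' @param sample_sheet optional path; when given the sample sheet is written
#'   there as TSV
#' @return `path`, invisibly
#' @export
write_ct_table <- function(m, path, layout = c("wide", "long"),
                           sample_sheet = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    out <- data.frame(gene = m$genes, stringsAsFactors = FALSE)
    for (s in m$samples) out[[s]] <- num_chr(m$ct[, s])
  } else {
    out <- data.frame(gene = rep(m$genes, times = length(m$samples)),
                      sample = rep(m$samples, each = length(m$genes)),
                      ct = num_chr(as.vector(m$ct)), stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet))
    write.table(m$meta, sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average technical/biological replicates into one column per unit
#'
#' A biological unit is defined by the metadata fields `set`, `group`,
#' `tissue` and `time`; every column sharing those fields is a replicate of
#' the same unit and is collapsed to its arithmetic mean Ct. Downstream
#' stability analysis is conventionally run on these per-unit means.
#'
#' @param m a [ct_matrix()]
#' @param policy `"mean"` (collapse) or `"none"` (return `m` unchanged)
#' @return a `ct_matrix` with one column per biological unit
#' @export
collapse_replicates <- function(m, policy = c("mean", "none")) {
  stopifnot(inherits(m, "ct_matrix"))
  policy <- match.arg(policy)
  if (policy == "none") return(m)
  if (all(is.na(m$meta$replicate)))
    stopf("policy 'mean' needs replicate indices in the sample sheet")
  key <- apply(m$meta[, c("set", "group", "tissue", "time")], 1, function(r)
    paste(r[!is.na(r) & r != "NA"], collapse = "."))
  if (any(!nzchar(key))) stopf("cannot form biological-unit keys: empty metadata")
  units <- unique(key)
  ctm <- sapply(units, function(u)
    rowMeans(m$ct[, key == u, drop = FALSE]))
  if (is.null(dim(ctm))) ctm <- matrix(ctm, nrow = length(m$genes),
                                       dimnames = list(m$genes, units))
  colnames(ctm) <- units
  meta <- m$meta[match(units, key), , drop = FALSE]
  meta$sample_id <- units
  meta$replicate <- NA_integer_
  ct_matrix(ctm, meta)
}

#' Per-gene Ct descriptive statistics
#'
#' Computes, per gene, the mean Ct, SD, CV% (= 100 * SD / mean Ct), the
#' min/max and their range delta Ct = Ctmax - Ctmin, and the quartiles used
#' for box plots (linear interpolation between order statistics).
#'
#' @param m a [ct_matrix()]
#' @param sd_denom `"n-1"` (sample SD, default) or `"n"`
#' @return a `data.frame` with one row per gene and columns `gene`, `n`,
#'   `mean_ct`, `sd`, `cv_pct`, `min_ct`, `q25`, `median`, `q75`, `max_ct`,
#'   `delta_ct`
#' @export
summarize_ct <- function(m, sd_denom = c("n-1", "n")) {
  stopifnot(inherits(m, "ct_matrix"))
  sd_denom <- match.arg(sd_denom)
  n <- length(m$samples)
  if (n < 2) stopf("need >= 2 samples for Ct summaries (SD undefined)")
  rows <- lapply(m$genes, function(g) {
    x <- m$ct[g, ]
    qs <- quantile(x, c(.25, .5, .75), names = FALSE, type = 7)
    s <- ct_sd(x, sd_denom)
    data.frame(gene = g, n = n, mean_ct = mean(x), sd = s,
               cv_pct = 100 * s / mean(x), min_ct = min(x), q25 = qs[1],
               median = qs[2], q75 = qs[3], max_ct = max(x),
               delta_ct = max(x) - min(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Define a sample set for stability analysis
#'
#' @param name label of the set (e.g. `"cultivars"`)
#' @param samples member sample IDs
#' @param groups optional character vector (same length) assigning each
#'   member to a group; used by the model-based (NormFinder) analysis.
#' @return an object of class `sample_set`
#' @export
sample_set <- function(name, samples, groups = NULL) {
  if (length(samples) < 2) stopf("a sample set needs >= 2 members")
  if (anyDuplicated(samples)) stopf("duplicate sample in set '%s'", name)
  if (!is.null(groups) && length(groups) != length(samples))
    stopf("groups must match samples in length")
  structure(list(name = name, samples = samples, groups = groups),
            class = "sample_set")
}

#' Derive the standard analysis sets from sample metadata
#'
#' Reproduces the usual five-way layout of a reference-gene study: one set
#' per value of `meta$set`, plus tissue-level subdivisions of any stress set
#' (leaf / root / combined) grouped by stress treatment (combined set:
#' stress x tissue).
#'
#' @param m a [ct_matrix()]
#' @return named list of [sample_set()] objects
#' @export
default_sample_sets <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  meta <- m$meta
  sets <- list()
  for (s in unique(meta$set)) {
    rows <- meta[meta$set == s, , drop = FALSE]
    tissues <- unique(rows$tissue[!is.na(rows$tissue)])
    if (s == "stress" && length(tissues) > 1) {
      for (tis in tissues) {
        sub <- rows[rows$tissue == tis, , drop = FALSE]
        sets[[paste0(s, "_", tis)]] <-
          sample_set(paste0(s, "_", tis), sub$sample_id, as.character(sub$group))
      }
      sets[[paste0(s, "_total")]] <-
        sample_set(paste0(s, "_total"), rows$sample_id,
                   paste(rows$group, rows$tissue, sep = ":"))
    } else {
      grp <- if (all(is.na(rows$group))) NULL else as.character(rows$group)
      sets[[s]] <- sample_set(s, rows$sample_id, grp)
    }
  }
  sets
}
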