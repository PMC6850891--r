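#' Comprehensive ranking across stability methods
#'
#' Aggregates the per-gene ranks of several stability algorithms (typically
#' geNorm, NormFinder and BestKeeper) by their geometric mean and assigns
#' the comprehensive rank by competition ranking (equal geometric means
#' share a rank).
#'
#' @param rank_vectors named list of named integer vectors (gene -> rank),
#'   one per method; every method must rank the same gene set
#' @return object of class `consensus_table`: `data.frame` with one rank
#'   column per method, `geomean` and `com_rank`, sorted ascending by
#'   `geomean`; attributes `best_gene` and `worst_gene`
#' @examples
#' consensus_rank(list(genorm = c(a = 1, b = 2, c = 3),
#'                     normfinder = c(a = 2, b = 1, c = 3),
#'                     bestkeeper = c(a = 1, b = 3, c = 2)))
#' @export
consensus_rank <- function(rank_vectors) {
  if (length(rank_vectors) < 2) stopf("need >= 2 methods to aggregate")
  if (is.null(names(rank_vectors)))
    names(rank_vectors) <- paste0("method", seq_along(rank_vectors))
  genes <- names(rank_vectors[[1]])
  for (mth in names(rank_vectors)) {
    v <- rank_vectors[[mth]]
    if (is.null(names(v)) || !setequal(names(v), genes))
      stopf("method '%s' does not rank the same gene set", mth)
    if (any(is.na(v))) stopf("method '%s' has missing ranks", mth)
  }
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (mth in names(rank_vectors))
    tab[[paste0("rank_", mth)]] <- as.integer(rank_vectors[[mth]][genes])
  rk <- as.matrix(tab[, -1, drop = FALSE])
  tab$geomean <- apply(rk, 1, geo_mean)
  tab$com_rank <- competition_rank(tab$geomean)
  tab <- tab[order(tab$geomean, tab$gene), ]
  rownames(tab) <- NULL
  attr(tab, "best_gene") <- tab$gene[tab$com_rank == 1]
  attr(tab, "worst_gene") <- tab$gene[tab$com_rank == max(tab$com_rank)]
  class(tab) <- c("consensus_table", "data.frame")
  tab
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes a target gene against one or more reference genes (the
#' per-sample reference Ct is the arithmetic mean of the references' Ct,
#' i.e. the geometric mean of their quantities) and expresses each sample
#' relative to a calibrator: `dCt_s = Ct_target,s - Ct_ref,s`,
#' `ddCt_s = dCt_s - dCt_calibrator`, fold change `= 2^-ddCt_s`. The
#' calibrator's fold change is 1 by construction.
#'
#' @param m a [ct_matrix()]
#' @param target target gene label
#' @param references character vector of reference gene labels
#' @param calibrator a sample ID, or (with `calibrator_is_group = TRUE`) a
#'   group label whose samples' mean dCt defines the baseline
#' @param calibrator_is_group logical (default `FALSE`)
#' @return object of class `relative_expression`: `data.frame` with
#'   columns `sample`, `dct`, `ddct`, `fold`; attributes `target`,
#'   `references`, `calibrator`
#' @export
ddct <- function(m, target, references, calibrator,
                 calibrator_is_group = FALSE) {
  stopifnot(inherits(m, "ct_matrix"))
  missing_g <- setdiff(c(target, references), m$genes)
  if (length(missing_g)) stopf("unknown gene(s): %s", paste(missing_g, collapse = ", "))
  ref_ct <- colMeans(m$ct[references, , drop = FALSE])
  dct <- m$ct[target, ] - ref_ct
  if (calibrator_is_group) {
    in_cal <- !is.na(m$meta$group) & m$meta$group == calibrator
    if (!any(in_cal)) stopf("no sample in calibrator group '%s'", calibrator)
    base <- mean(dct[in_cal])
  } else {
    if (!calibrator %in% m$samples)
      stopf("calibrator sample '%s' not found (did you mean calibrator_is_group?)",
            calibrator)
    base <- dct[calibrator]
  }
  out <- data.frame(sample = m$samples, dct = unname(dct),
                    ddct = unname(dct - base),
                    fold = unname(2^-(dct - base)), stringsAsFactors = FALSE)
  attr(out, "target") <- target
  attr(out, "references") <- references
  attr(out, "calibrator") <- calibrator
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Sensitivity of fold changes to the choice of reference gene
#'
#' Recomputes the target's 2^-ddCt profile under each candidate reference
#' separately and reports how much the profiles diverge: for every pair of
#' references the maximum over samples of |log2 fold_a - log2 fold_b|, and
#' whether any sample's direction of change (up vs down relative to the
#' calibrator) flips between references. Large divergence or direction
#' flips indicate that at least one candidate is not a safe reference.
#'
#' @param m a [ct_matrix()]
#' @param target target gene label
#' @param candidate_refs >= 2 reference gene labels to compare
#' @param calibrator,calibrator_is_group passed to [ddct()]
#' @return list with `profiles` (samples x references matrix of fold
#'   changes), `divergence` (references x references matrix of max |log2
#'   fold difference|), `max_divergence`, `direction_flip` (logical)
#' @export
reference_choice_sensitivity <- function(m, target, candidate_refs, calibrator,
                                         calibrator_is_group = FALSE) {
  if (length(candidate_refs) < 2) stopf("need >= 2 candidate references")
  folds <- sapply(candidate_refs, function(r)
    ddct(m, target, r, calibrator, calibrator_is_group)$fold)
  rownames(folds) <- m$samples
  nr <- length(candidate_refs)
  div <- matrix(0, nr, nr, dimnames = list(candidate_refs, candidate_refs))
  flip <- FALSE
  for (i in seq_len(nr - 1)) {
    for (j in seq((i + 1), nr)) {
      dv <- max(abs(log2(folds[, i]) - log2(folds[, j])))
      div[i, j] <- div[j, i] <- dv
      s_i <- sign(round(log2(folds[, i]), 10))
      s_j <- sign(round(log2(folds[, j]), 10))
      if (any(s_i * s_j < 0)) flip <- TRUE
    }
  }
  list(profiles = folds, divergence = div, max_divergence = max(div),
       direction_flip = flip)
}

#' Run all three stability methods and the consensus on one sample set
#'
#' Convenience wrapper: subsets the Ct matrix to the set, runs [genorm()],
#' [normfinder()] (grouped when the set carries a group partition with all
#' groups of size >= 2, ungrouped otherwise) and [bestkeeper()], and merges
#' their rankings through [consensus_rank()]. The geNorm rank fed to the
#' consensus is the single-pass M ranking (distinct ranks); pass
#' `genorm_ranking = "stepwise"` for the tied stepwise alternative.
#'
#' @param m a [ct_matrix()]
#' @param set a [sample_set()] (default: all samples, ungrouped)
#' @param genorm_ranking `"single"` or `"stepwise"`
#' @param ... passed through to [genorm()]
#' @return list with `genorm`, `normfinder`, `bestkeeper` result objects
#'   and `consensus` (a [consensus_rank()] table)
#' @export
stability_suite <- function(m, set = NULL, genorm_ranking = c("single", "stepwise"),
                            ...) {
  genorm_ranking <- match.arg(genorm_ranking)
  if (!is.null(set)) {
    sub <- ct_subset(m, samples = set$samples)
    groups <- set$groups
  } else {
    sub <- m
    groups <- NULL
  }
  if (!is.null(groups)) {
    sizes <- table(groups)
    if (length(sizes) < 2 || any(sizes < 2)) groups <- NULL
  }
  g <- genorm(sub, ...)
  nf <- normfinder(sub, groups = groups)
  bk <- bestkeeper(sub)

  g_rank <- if (genorm_ranking == "single")
    setNames(g$table$rank_single, g$table$gene)
  else setNames(g$table$rank_stepwise, g$table$gene)
  cons <- consensus_rank(list(
    genorm = g_rank,
    normfinder = setNames(nf$table$rank, nf$table$gene),
    bestkeeper = setNames(bk$table$rank, bk$table$gene)))
  list(genorm = g, normfinder = nf, bestkeeper = bk, consensus = cons)
}
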