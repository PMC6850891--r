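---
title: "Selecting RT-qPCR reference genes: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting RT-qPCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstab)
```

## The problem

Relative quantification by RT-qPCR divides a target gene's signal by that of
one or more reference ("housekeeping") genes, assuming the references are
expressed constantly across all samples. No gene satisfies that assumption
universally; a reference that drifts with cultivar, organ or stress silently
biases every downstream fold change. The accepted remedy is to screen a
panel of candidates on the actual experimental material and rank their
stability with several statistical algorithms whose assumptions differ, then
aggregate. `ctstab` implements that workflow end to end: candidate screening
from RNA-seq expression tables, primer efficiency QC, three stability
algorithms (geNorm, NormFinder, BestKeeper), a geometric-mean-of-ranks
consensus, and `2^-ddCt` validation of the chosen references.

## Data model

All stability analysis runs on a `ct_matrix`: genes x samples quantification
cycles (Ct) with a sample sheet assigning each sample to a *set* (e.g.
cultivars / organs / stress), a *group* within the set (cultivar name,
organ, stress treatment), a tissue, a time point and a biological-replicate
index. Ct is inversely proportional to log2 template abundance, so one cycle
is one doubling. By convention replicates are averaged
(`collapse_replicates()`) before stability analysis; this can be disabled.

## Candidate screening

From a two-library expression table, expression is quantified as
`RPKM = 10^9 C / (N L)` and differential expression as
`log2Ratio = log2(R_RPKM / W_RPKM)`. `|log2Ratio| >= 1` marks a significant
difference between the libraries; within each gene family the member with
the *smallest* `|log2Ratio| < 1` is selected as the candidate. Ties (never
observed in practice) break on the lexicographically smallest gene ID. Zero
expression makes the ratio undefined; the default is an error, with an
opt-in pseudo-count (`+1e-4`) that is always logged.

## Primer QC

A standard curve is ordinary least squares of mean Ct against
log10(relative template amount) over a serial dilution series (>= 3 distinct
dilutions; replicates averaged first). The undiluted sample anchors x = 0,
but slope and efficiency are invariant to that choice. Amplification
efficiency is `E = 10^(-1/k) - 1`; `k = -1/log10(2) = -3.3219` corresponds
to perfect doubling (E = 100%). The default acceptance band (90-110%,
R^2 >= 0.99) is laboratory policy, not statistics, and is configurable.

## geNorm

Ct rows are converted to relative quantities `Q = base^(Ctmin - Ct)`
(default base 2; efficiency-corrected base `1 + E` optional). The pairwise
variation of genes j,k is the SD (n-1) over samples of `log2(Qj/Qk)`; the M
value of a gene is the mean of its pairwise variations within the current
panel. The least stable gene (highest M) is removed repeatedly until two
remain — those two are inherently tied. `V_n/n+1` is the SD of
`log2(NF_n/NF_n+1)` where `NF_n` is the per-sample geometric mean of the n
most stable genes' quantities; the smallest n with `V < 0.15` is the
recommended number of references, with the 2-3 most stable genes as the
fallback when no V crosses the threshold. Genes with M above 1.5 on the
full panel are flagged as unsuitable.

Design choices: the final pair is reported tied at rank 1 under the
stepwise ranking, but published comparison tables conventionally print
*distinct* per-gene ranks, so a single-pass ranking (M computed once on the
full panel, no removal) is also emitted and is the default input to the
consensus. A tie on "highest M" during removal drops the later gene in
input order — deterministic and recorded. The "best combination" reported
for a set is the tied final pair, with its value being the pair's M.

## NormFinder

The model-based analysis works on the log2 expression scale (`y = -Ct`;
per-gene constants cancel). Each sample is centered by its across-gene
mean, removing loading differences — this is why NormFinder and geNorm are
shift-invariant where BestKeeper is not. With groups (e.g. stress
treatments), for gene i in group g the within-group variance of the
centered values is corrected for the centering itself: with k genes,
`E[v_ig] = sigma2_ig (1 - 2/k) + mean_l(sigma2_lg)/k`, which inverts to
`sigma2_ig = (v_ig - mean_l(v_lg)/(k-1)) * k/(k-2)` (clamped at zero and
logged when negative). The inter-group difference `d_ig` (group mean minus
the gene's cross-group mean) is shrunk toward zero by the empirical-Bayes
factor `gamma2/(gamma2 + sigma2_ig/n_g)`, where `gamma2` is the
method-of-moments estimate
`max(0, sum(d^2)/((G-1)(k-1)) - mean(sigma2_ig/n_g))` of the variance of
true group differences. The stability value averages, over groups, the
magnitude of the shrunk difference plus its posterior SD:
`S_i = mean_g(|d~_ig| + sqrt(u_ig * gamma2/(gamma2 + u_ig)))`. Ungrouped
mode reduces to the bias-corrected SD of the centered values. Lower S is
more stable; the best pair minimises the stability of the averaged
two-gene combination.

The published description of this estimator admits readings (notably the
exact bias-correction and moment constants). The constants above were
derived from first principles for unbiasedness and are pinned by an
independent straight-line transcription of the formulas on a frozen
fixture (T2) in the test suite; a documented `simplified = TRUE` mode
(no shrinkage, `S = mean_g(|d| + SD/sqrt(n_g))`) is available for
transparency. When the estimated inter-group variance is zero the shrunk
differences and their uncertainties vanish and all S collapse toward zero;
this is inherent to the shrinkage estimator and only occurs when the data
show no between-group structure at all. Grouped mode is the default for
stress designs (3 or 6 groups); cultivar and organ sets run ungrouped
because each biological unit is its own singleton "group" after replicate
collapse (a grouped model cannot estimate within-group variance there).

## BestKeeper

Deliberately model-free: per-gene descriptive statistics on *raw* Ct
(geometric/arithmetic mean, min/max, SD, CV% = 100 SD / mean Ct), the
BestKeeper index (per-sample geometric mean of all candidates' Ct), and
each gene's Pearson correlation with the index (two-sided p value; the
historical name "Poisson correlation coefficient" notwithstanding, the
statistic is Pearson's r). Genes rank by SD; SD < 1 cycle flags a gene as
acceptably stable. Working on raw Ct makes BestKeeper sensitive to
sample-loading shifts — a property, asserted in the tests, that contrasts
with the other two methods. Choices: classical sample SD (n-1) by default
with the original spreadsheet's mean-absolute-deviation variant behind
`mad = TRUE`; CV denominator is the arithmetic mean Ct (geometric behind a
flag); the index includes the gene being correlated, as in the original
tool (`exclude_self = TRUE` to change that).

## Consensus and validation

Per-method ranks are aggregated by their geometric mean; the comprehensive
rank uses competition ranking, so genuinely equal geometric means share a
rank, but unequal ones are never forced into a tie (published tables
sometimes merge near-ties editorially; the package does not reproduce such
judgment calls). Validation uses `2^-ddCt` with the per-sample reference Ct
being the arithmetic mean of the chosen references' Ct (geometric mean of
quantities — the standard multi-gene normalization), and
`reference_choice_sensitivity()` quantifies how much the target's fold
profile moves when the reference is swapped, flagging direction flips.

## The synthetic-data generator

`simulate_ct()` draws `Ct = B_i + L_s + delta_ig + eps` with per-gene
baseline `B_i`, per-reaction loading `L_s ~ N(0, tau^2)` shared across
genes, deterministic group regulation `delta_ig` (cycles), and gene noise
`eps ~ N(0, sigma_i^2)` — Gaussian on the Ct scale, i.e. multiplicative on
the quantity scale, the standard qPCR error model (t-distributed noise is
available for robustness checks). The default configuration mirrors a
full study: 10 candidate genes; 6 cultivars, 7 organs, and 3 stresses x 5
time points x 2 tissues, all with 3 biological replicates. Baseline Ct
values follow typical per-family mean Ct (about 20.8 for the most abundant
candidate to 30.6 for the least); noise SDs (0.15-0.45 cycles) and
regulation effects (0.3-1.0 cycles on the historically unstable families
TUBB, GAPDH, F-box, EF-1a, ACTIN) encode a known ground truth in which
PP2A, SAND and RH 8 are the stable genes; loading SD tau defaults to 0.5
cycles. These values were chosen once as field-realistic magnitudes (per-
gene biological noise below half a cycle; regulation up to one cycle,
i.e. two-fold) and are not tuned against any test outcome.

What the generator does *not* emulate: amplification-curve artefacts,
inhibitors, pipetting outliers, missing wells, between-plate batch effects,
or non-Gaussian heavy tails (beyond the optional t mode). A green test on
synthetic data therefore establishes algorithmic correctness and
statistical behaviour under the stated model — not robustness to every
real-world failure mode.

The true instability score of a gene is `sqrt(sigma_i^2 + Var_g(delta_ig))`
with the variance taken (population form) over all distinct group/tissue
conditions in the design; the tests require all three methods' rankings to
converge on this order as separations grow.

## Numerical choices and degenerate inputs

- SD uses the n-1 denominator everywhere (switchable in `summarize_ct()`);
  quartiles use linear interpolation between order statistics (R type 7).
- Missing or non-numeric Ct is a hard error naming the offending cell;
  `na_action = "drop"` removes the affected samples with a warning.
- A constant gene has SD = CV = 0 and an undefined index correlation,
  reported as `NA` with a warning rather than an error.
- Negative variance estimates after bias correction are clamped to zero.
- TSV output renders numerics at 17 significant digits so a
  write-read round trip is bitwise exact; re-running any stage with the
  same seed and config yields byte-identical outputs.
- The CLI accepts a JSON `--config` file (flags override it); YAML is not
  supported to keep the dependency footprint at base R + jsonlite.

## Known limitations

- Ranks, not scores, feed the consensus; methods with near-tied scores can
  contribute noisy ranks.
- The NormFinder grouped estimator needs every group of size >= 2 and >= 3
  genes; sets that violate this silently fall back to ungrouped mode in
  `stability_suite()` (explicit calls error instead).
- BestKeeper p values assume independent Gaussian Ct, which replicate
  structure violates mildly; they are reported for ranking context only.
- No proprietary thermocycler export parsing; users supply CSV/TSV.
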