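---
title: "Methods: the intestinal stem cell index and its cohort analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intestinal stem cell index and its cohort analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemindex)
```

## The phenotype axis and the index

Colorectal tumors mix two stem-cell programs: the homeostatic crypt-base
columnar (CBC) program marked by *LGR5*, and a regenerative/fetal (RSC)
program marked by *ANXA1*, *CLU* and *PLAUR*/*LY6A*. `stemindex` places a
bulk transcriptome on this axis with a single number,

$$\mathrm{index}_j \;=\; \mathrm{ES}_j(\mathrm{RSC}) - \mathrm{ES}_j(\mathrm{CBC}),$$

the difference of two single-sample enrichment scores. A positive index
means the regenerative program dominates sample $j$; a negative index means
the crypt-base program does. Everything else in the package exists to
compute this number well (normalization, the enrichment engine, signature
hygiene) or to use it at cohort scale (deciles, plasticity, reproducibility).

## The enrichment engine

`gsva_scores()` implements the kernel-CDF rank random-walk family of
single-sample enrichment scores:

1. **Kernel CDF per gene.** Expression of gene $i$ is converted to a
   within-cohort quantile $z_{ij}$ by a kernel estimate of its CDF across
   samples: a Gaussian kernel with per-gene bandwidth $s_i/4$ for
   continuous scales, a discrete Poisson-mixture kernel
   $z_{ij} = \tfrac1n\sum_k P(\mathrm{Pois}(x_{ik}+0.5) \le x_{ij})$ for raw
   counts, or the empirical CDF (`kernel = "none"`). The cohort is the
   reference population, so scores are only comparable within one
   normalized cohort; the result carries a cohort fingerprint to make
   accidental cross-cohort comparison visible.
2. **Symmetric rank statistic.** Per sample, genes are ranked by
   decreasing $z_{ij}$ (ties broken stably by input gene order, which makes
   the procedure deterministic) and the gene at rank $r$ receives the
   statistic $|p/2 - r|$, largest at both extremes of the ranking.
3. **Weighted KS-like walk.** Walking down the ranked list, in-set genes
   add their statistic to the power $\tau$ (default 1), normalized over the
   set; out-of-set genes subtract $1/(p-m)$. The score is either the
   maximum positive deviation plus the minimum negative deviation
   (`diff-of-extremes`, the default) or the single largest-magnitude
   deviation (`max-deviation`). Both normalizations bound scores in
   $[-1, 1]$.

A signature that covers the whole gene space leaves the out-of-set
decrement undefined and is rejected, as are overlaps outside
`[min_set_size, max_set_size]` (defaults 2 and 500).

**Expression scale.** For RNA-seq the package feeds the Gaussian kernel
with $\log_2(\mathrm{CPM}+1)$ after TMM normalization (`tmm_cpm(log =
TRUE)`); the Poisson kernel on raw counts is available via
`kernel = "poisson"`/`"auto"`. Running on the log scale keeps one kernel for
both RNA-seq and microarray inputs (microarray intensities are collapsed to
per-gene means by `collapse_probes()` first) and makes the
contamination-robustness behaviour easier to reason about, since the kernel
CDF is location-equivariant per gene.

**Normalization.** TMM scale factors are computed by edgeR (reference
sample = upper quartile closest to the cohort mean, log-ratio trim 0.30,
intensity trim 0.05, precision-weighted trimmed mean, factors rescaled to
geometric mean 1); the test suite pins the factors against an independent
literal transcription of the published formulas at $10^{-12}$.

## Signature refinement

Stem-cell signatures assembled from organoid or regeneration experiments
pick up genes that bulk tumor profiles express mainly through stroma or
through no cell type in particular. Two tools restrict a signature to genes
of predominantly epithelial origin in a reference single-cell dataset.

**Pseudobulk specificity (`classify_specificity`).** Raw counts are summed
into (cell type, patient) pseudobulk columns. A gene is specific to cell
type $c$ iff its total count in $c$ exceeds every other cell type's total
by at least one raw count (margin configurable) *and* every pairwise
comparison of $c$ against a rival is significant at $p < 0.01$. The test
behind the p-value is a design decision: a two-sided Welch t-test on
$\log(1+\mathrm{CPM})$ of the per-patient pseudobulk replicates, because
patients are the only replication unit the pseudobulk construction
provides; the margin is evaluated on totals summed over patients. At least
two patients per cell type are required, otherwise the test is undefined
and the function says so. The rule can crown at most one cell type per
gene, is deterministic, and is invariant to gene and column order.

**Cluster-based exclusion (`refine_signature`).** Each signature gene gets
a per-cell-type mean $\log_2$-CPM profile. Profiles are converted to a
*moderated* z-score, $(x - \bar x)/(s + s_0)$ with $s_0$ the median
per-gene profile sd across the signature, then clustered hierarchically
(Euclidean distance, average linkage, $k = \min(8, \lfloor n/5 \rfloor)$).
A cluster is dropped when its centroid is stromal-dominant, epithelial but
with stromal z above 0.5, or flat (maximum centroid z below 0.5). Two
numerical choices here deserve their rationale:

* *Moderated rather than plain z.* With only 4-6 cell types the per-gene sd
  is estimated from the same handful of points it standardizes. A gene with
  negligible absolute variation then gets inflated into a sharp random
  profile, and "no clear cell-type-specific expression" becomes
  undetectable. Adding the median sd to the denominator leaves strong
  profiles essentially intact while shrinking near-flat ones toward zero,
  where the flat rule can see them.
* *Euclidean rather than correlation distance.* Correlation distance is
  magnitude-blind: the correlation of two independent 4-point profiles is
  close to uniform on $[-1, 1]$, so flat genes routinely align with a sharp
  cluster's shape by chance and are absorbed into kept clusters. Euclidean
  distance on the moderated z keeps magnitude in play, gathering
  low-variation genes near the origin in their own (excluded) clusters.

Refinement preserves input gene order, returns a subset of its input, and
is idempotent on its own output against the same pseudobulk.

## The single-cell pipeline

* **QC gates** (`qc_filter`): more than 1000 UMIs (strict), mitochondrial
  fraction below 0.30 (strict), and 2000-6000 detected genes (both ends
  inclusive) — a literal reading of the usual epithelial scRNA-seq gates.
  Cells are flagged with reason codes, never silently dropped.
* **Logcounts** (`sc_logcounts`): $\log(1 + \mathrm{counts}\cdot 10^4 /
  \mathrm{depth})$. The target sum is configurable; $10^4$ is the common
  single-cell toolkit default.
* **Signature value** (`cell_signature_value`): arithmetic mean of
  logcounts over the signature genes present; absent genes shrink the
  denominator and are reported once.
* **Cutoffs** (`derive_cutoffs`): the 95th percentile of the per-cell
  values (linear interpolation between order statistics, the type-7
  default of this ecosystem), optionally rounded to the nearest 0.05
  logcounts with half-ties rounding up (a $10^{-9}$ guard keeps binary
  representation noise from flipping exact half ties). The 95th percentile
  encodes the prior that true *LGR5*+ CBC cells are about 5% of the
  epithelial population; with tie-free values it marks exactly 5% of cells
  positive, up to $1/n$.
* **Classes** (`classify_cells`): positivity is strictly above the cutoff;
  both positive = `mixed` (double-positive), one positive = `CBC` or
  `RSC`, neither = `negative`. The four classes partition the QC-passed
  cells.

Note one structural consequence of a hard 95th-percentile cutoff: if CBC,
RSC and double-positive cells are truly 5%, 5% and 1% of the population,
6% of cells are elevated in each signature but only 5% can sit above the
cutoff, so per-signature recall is capped near 5/6 by construction. The
planted-recovery checks therefore score the two 5% populations; the mixed
class is reported but not given its own recovery bound.

## Cohort analytics

* **Polarized deciles** (`polarized_deciles`): samples ranked by the index;
  the lowest and highest 10% form the CBC- and RSC-enriched deciles. The
  index already encodes polarization on a single axis, so ranking by it
  (ties: CBC score descending, then sample id) replaces any two-axis
  selection; the above-median predominance label is emitted for plotting
  only.
* **CNV categories** (`categorize_cnv`): segment means below $-0.3$ are
  losses ($-1$), above $+0.3$ gains ($+1$), both strict; thresholds
  configurable.
* **Pathway prevalence** (`pathway_prevalence`): fraction of decile samples
  with at least one pathogenic mutation in any pathway gene; the mutation
  table is expected pre-filtered for pathogenicity upstream.
* **Plasticity** (`classify_plasticity`): a sample is RSC-positive iff its
  index is strictly positive, CBC-positive otherwise; an exactly-zero
  index is a measure-zero case and is classified CBC-positive by the
  strict reading of "positive index". A patient whose pre/post classes
  differ is `plastic`, otherwise `static`.
* **Response association** (`fisher_association`): two-sided Fisher exact
  p on the static/plastic x responder/non-responder table (responder =
  moderate or marked regression), i.e. the sum of hypergeometric
  probabilities no larger than the observed table's. Degenerate margins
  return $p = 1$ with a warning. The odds ratio is the sample OR with a
  Haldane 0.5 correction when a cell is zero.
* **Reproducibility** (`repro_stats`): one-way random-effects ANOVA with
  the unbalanced-design coefficient $k_0 = (N - \sum n_i^2/N)/(a-1)$;
  $\hat\sigma^2_b = \max(0, (\mathrm{MSB} - \mathrm{MSW})/k_0)$,
  $\hat\sigma^2_w = \mathrm{MSW}$, and ICC(1,1)
  $= \hat\sigma^2_b/(\hat\sigma^2_b + \hat\sigma^2_w)$ — the variant that
  matches "agreement of single random biopsies". CVs are
  $100\,\hat\sigma/|\bar y|$; on a signed index a near-zero grand mean
  makes them ill-defined, so the function returns them as `NA` with a
  warning in that branch while still returning the ICC.

## What the generators emulate

The synthetic cohorts define the conditions under which the pipeline is
tested; their defaults are fixed and are not tuned per run.

* `simulate_bulk`: 100 samples x 2000 genes; per sample the expectation is
  $(1-c)\,[(1-f)\,\mathrm{CBC} + f\,\mathrm{RSC}] + c\,\mathrm{stromal}$
  with disjoint 50-gene archetype blocks at $\log_2$ effect 2, negative
  binomial dispersion 0.2, library sizes 0.5-1M, $f$ uniform and stored as
  truth. Contamination defaults to 0 and is pushed to 40% in the
  robustness checks.
* `simulate_single_cell`: 5 patients x 400 cells; populations CBC/RSC/
  mixed/other-epithelial/stromal/myeloid/lymphoid at
  5/5/1/59/15/10/5%; multinomial counts over 4000 genes with 80-gene
  cell-type blocks and 40-gene CBC/RSC marker blocks at $\log_2$ effect 3;
  block baseline masses are equalized so library composition tilts stay
  small; lognormal depth (median 12k, sdlog 0.12); 13 `MT-` genes carry a
  per-cell mitochondrial share (mean 5%); 5% planted low-quality cells
  (high mito or collapsed depth); mild per-patient lognormal expression
  effects (sdlog 0.1). It does not attempt batch effects, doublets, or
  zero-inflation beyond what multinomial sampling produces, so passing
  recovery tests demonstrates correctness of the decision rules, not
  robustness to every real-data pathology.
* `simulate_paired`: 75 patients (the scale of a neoadjuvant trial arm),
  30% plastic, index magnitude 0.4 with noise sd 0.05 (separation >>
  noise, so the sign rule must recover labels exactly), responder rates
  0.6 (static) vs 0.2 (plastic).
* `simulate_biopsies`: 30 tumors x 5 biopsies; tumor effects and noise
  Gaussian with designed ICC 0.826 at grand mean 1 and total sd 0.3 —
  i.e. between- and within-subject CVs of about 27% and 13%, a
  between-dominant regime.
* `simulate_genomics`: per-group gain/loss probabilities on segment means
  (gains drawn in $(0.35, 1)$, losses in $(-1, -0.35)$, neutral in
  $(\pm 0.25)$ so the $\pm 0.3$ categorization recovers the planted state
  exactly) and per-group pathway mutation rates.

All generators take a single integer seed, use a local RNG state (the
global stream is untouched), and are bit-reproducible.

## Problem sizes and numerical tolerances

The test suite runs the enrichment engine against an independently
hand-executed oracle on a 6-gene x 4-sample instance at $10^{-10}$, TMM
against a literal-formula transcription at $10^{-12}$, and Fisher p-values
against exhaustive hypergeometric enumeration at $10^{-12}$. Recovery
checks use 10 bulk cohorts of 100 samples, one 2000-cell single-cell
cohort, 75 paired patients, and 50 biopsy cohorts of 30 x 5 — sizes chosen
to keep the full suite near a minute while leaving the statistical margins
(Spearman >= 0.9, recall/precision >= 0.8, ICC within 0.1) comfortably
resolvable.

## Known limitations

* Enrichment scores are cohort-relative; a sample's index changes when the
  cohort around it changes. The cohort fingerprint makes this visible but
  does not remove it.
* The specificity test leans on patient-level pseudobulk replicates; with
  very few patients its power is limited, and the margin-on-totals rule
  favors abundant cell types when sequencing depth differs grossly between
  types.
* CVs on a signed index are only meaningful away from a zero grand mean;
  use the reported variance components directly when the cohort straddles
  zero.
* The refinement thresholds (stromal z 0.5, flat z 0.5, $k$) are sensible
  defaults for 4-6 coarse cell types, not universal constants; they are
  exposed as arguments.
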