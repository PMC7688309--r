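---
title: "Models and design of the atacage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the atacage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open. Every empirical statement here is
one the test suite or `scripts/acceptance.R` computes itself.

## Accessibility scores

A cell's snATAC library is summarized by its complexity $C_j$ (estimated
distinct molecules) and its usable read count $k_j$. Under unbiased
amplification, the probability that a given molecule is sequenced at least
once is

$$s_j = 1 - \left(1 - \tfrac{1}{C_j}\right)^{k_j},$$

monotone increasing in $k_j$ and decreasing in $C_j$
(`sequencing_probability()`). Treating a peak (pseudo-locus) as the set of
minimal accessible loci it spans, the expected read count of peak $i$ in
cell $j$ is proportional to $a_i\,C_j s_j$, where $a_i$ is the underlying
accessibility. Summing over cells and inverting gives the
complexity-adjusted estimator

$$A_i = Z\,\frac{\sum_j O_{ij}}{\sum_j C_j s_j},$$

with $Z$ fixed by the convention $\sum_i A_i = 10^6$. Two remarks the code
makes explicit:

* The denominator does not depend on the peak, so on a *single* cell set
  the normalized $A_i$ coincides with the plain relative estimator
  $A_i = 10^6\,\sum_j O_{ij} / \sum_{ij} O_{ij}$
  (`relative_accessibility()`). The value of the corrected form is
  *cross-set* comparability: per-donor or per-cluster scores divide by
  each set's own expected yield, so donor depth and complexity differences
  cancel. The test suite verifies that per-donor $A_i$ are uncorrelated
  with planted donor sequencing yield while raw per-donor count sums are
  strongly confounded.
* $Z$ is defined as "the constant making scores sum to $10^6$" — the
  normalization that makes scores read as counts-per-million of corrected
  accessibility signal.

The percent-of-cells statistics work on a partitioning $S$ of the cells
and a background peak set $P$: $m_{ij}$ is the fraction of cells of
partition $i$ with at least one read in peak $j$ (strictly $O_{ij} \ge 1$
on integer counts; no fractional weighting), $s_{ij} = 10^6\, m_{ij} /
\sum_{j \in P} m_{ij}$, and $RS_{ij} = s_{ij} / \sum_i s_{ij}$. A peak
inaccessible in every partition has undefined $RS$, which propagates as
`NA` — never as 0, which would fabricate evidence of absence. Because
$m$ is a per-cell fraction, duplicating the cells of a partition changes
nothing: the statistic is depth-robust by construction.

**Defaults.** `filter_cells()` keeps cells with ≥ 1000 usable reads
(inclusive), the standard initial quality cutoff for combinatorial-barcoding
snATAC data.

## Ensemble co-accessibility

The engine estimates, within a genomic window, the sparse inverse
covariance of depth-normalized, per-peak standardized metacell counts
under an elementwise penalty that grows with genomic distance:

$$\hat\Theta = \arg\max \; \log\det\Theta - \mathrm{tr}(S\Theta)
  - \sum_{a \ne b} \rho_{ab} |\Theta_{ab}|, \qquad
  \rho_{ab} = \lambda_0 \sqrt{d_{ab}/W},$$

and reports the partial correlation $-\Theta_{ab} / \sqrt{\Theta_{aa}
\Theta_{bb}}$ as the co-accessibility score. Design choices:

* **Square-root distance decay.** The exponent 1/2 keeps the penalty
  sub-linear, so mid-range pairs are damped without being erased, and far
  pairs (beyond half the window) are driven to exact zeros by the lasso.
  The scale $\lambda_0$ is not hand-set: `calibrate_penalty()` bisects
  (20 iterations) for the smallest $\lambda_0$ such that at most 5% of
  far-pair scores are nonzero over a sample of at most 20 windows.
* **Metacells.** Single cells are too sparse for covariance estimation;
  `build_metacells()` aggregates each sampled seed cell with its $k-1$
  cosine nearest neighbors in a TF-IDF/truncated-SVD embedding (30
  dimensions), rejecting candidates sharing more than 10% of members with
  an accepted metacell, and sums binarized values. The metacell size must
  scale with the cohort: at the full-data scale of the design
  (15,000-cell subsets) $k = 50$ gives hundreds of metacells; on the
  ~2,000-cell desk-scale cohorts used in the tests we set $k = 20$ so the
  number of metacells stays well above the window peak count — an
  estimation-sample-size choice, not a screening threshold.
* **Windows and runs.** Windows tile each chromosome with 50% overlap; a
  pair scored in several windows gets the per-run mean; pairs spanning a
  window boundary get no score from that window. The ensemble runs one
  analysis per cluster at 1 Mb windows plus five runs on random subsets of
  min(15,000, $n$) cells at 250 kb windows. Cluster and subset scores pool
  into a single array per link (the most literal reading of the merge);
  `include_cluster_runs = FALSE` gives subset-only arrays for users wary
  of mixing the two window scales in one t-test — the scales are indeed
  mixed under the default, which we surface rather than hide.
* **Merging and filters.** Per link, a one-sample two-sided t-test of the
  score array against zero; retained at $p < 0.10$; arrays with fewer than
  2 observations are dropped (no variance estimate); a zero-variance array
  is retained iff its mean is nonzero ($p = 0$ vs $p = 1$). A pair absent
  from a run is missing from the array, not zero: a run that never
  evaluated a pair carries no evidence. Promoters are the 1000-bp regions
  centered on protein-coding TSSs; links are reported for a gene when
  exactly one anchor overlaps the promoter and the mean score strictly
  exceeds 0.05.
* **Numerics.** The graphical lasso is a blockwise coordinate descent
  (compiled; `glasso_fit_r()` is a pure-R reference kept for testing),
  with convergence at mean absolute change below `1e-5` of the mean
  off-diagonal scale. A singular penalized covariance (e.g. duplicated
  peaks at $\lambda_0 = 0$) raises an error that names the remedy: raise
  $\lambda_0$. Constant peaks are dropped from the window with a message.
  The solver is validated against a generic Nelder–Mead convex solve on
  windows of up to 4 peaks (agreement within $10^{-3}$ on partial
  correlations).

## Age-dynamic peaks

`pseudobulk()` sums counts per donor within one cell type, with the log
donor total as model offset. `nb_pairwise_test()` fits, per peak, a
negative-binomial log-linear model with age group plus technical
covariates (sex, dataset), and tests the group coefficient by a
likelihood-ratio test at a plug-in dispersion; p-values are BH-corrected
per comparison and the age-dynamic set is the union over the three
pairwise comparisons at FDR < 0.05.

**Dispersion estimation** is the choice that matters at $n = 3$ donors per
group. The per-peak evidence is the Cox–Reid adjusted profile likelihood
(the adjustment compensates for the coefficients estimated per peak,
without which the dispersion MLE collapses toward zero at these sample
sizes). Point-estimate shrinkage of log-dispersions toward a trend is not
enough: peaks whose own profile is flat still collapse, and the
likelihood-ratio test then rejects far above its nominal level. We
therefore shrink on the *likelihood* scale — each peak maximizes
$(1-w)\,\mathrm{APL}_i(\alpha) + w\,\overline{\mathrm{APL}}(\alpha)$,
where the second term is the trimmed mean of the per-peak curves — with
weight $w = d_0/(d_0 + d_{res})$, $d_0 = 10$ prior degrees of freedom,
following the empirical-Bayes convention of count-model packages. Under a
simulated null (equal NB means, 3 vs 3) this keeps the raw rejection rate
at the 0.05 level within the test suite's [0.03, 0.07] band; the planted
4-fold-change recovery stays above 70% at FDR < 0.05. Covariates that are
constant or aliased over the tested donors are dropped by rank inspection
rather than crashing the fit.

**Temporal clustering.** Profiles (peaks × age groups, relative
accessibility) are scaled to unit row sum, K-means is run for K = 5..8
with 20 seeded restarts each (best inertia kept), and K is chosen by the
Davies–Bouldin index $DB = K^{-1} \sum_x \max_{y \ne x}
(s_x + s_y)/d_{xy}$ (Euclidean; ties toward smaller K; coincident
centroids give $DB = \infty$; singleton clusters contribute zero scatter).

**Locus-restricted mode.** For a handful of candidate peaks the package
uses pooled-variance two-sample t-tests on per-donor fraction scores, with
*raw* p-values marked at $p < 0.05$ — deliberately uncorrected, mirroring
genome-wide FDR and locus-restricted raw-p as two separate reporting
modes. The per-donor statistic fed to the test is the within-donor score
$s_{ij}$ against the merged peak background; the cross-partition $RS$ is
also exposed, since the choice between the two is a genuine ambiguity —
`s` is the default because it keeps each donor's statistic free of the
other donors' values.

## Expression metrics

QC keeps genes detected in ≥ 3 nuclei and nuclei with 500–4000 detected
genes (inclusive bounds; gene filter before cell filter; idempotent).
Normalization is $x \mapsto \ln(1 + 10^4\,x/\mathrm{total})$ (natural
log). A nucleus expresses a gene iff it has ≥ 1 UMI; fractions are
reported at full precision — display rounding (e.g. one-decimal
percentages) belongs to the report layer, not the computation. Age-group
comparisons are unpaired two-tailed t-tests on per-donor fractions, pooled
variance by default (matching the equal-variance convention of the
locus-restricted accessibility tests), Welch as an option.

## Variant effects

* **Filters.** Singletons (allele count 1) and indels longer than 3 bp are
  removed; SNVs always pass the length rule. Commonness folds each
  population frequency to a MAF, $\min(f, 1-f)$, and requires MAF > 0.01
  (strict) in at least one population; 0.01 is the default with the
  threshold exposed (`maf_threshold`), since 0.05 is also a defensible
  convention; absent frequency data yields `NA`, not `FALSE`.
* **Motif scanning.** Log-odds scores in bits against the PWM's 0-order
  background, both strands, every offset; the match p-value
  $P(\text{score} \ge s)$ is computed *exactly* by dynamic programming
  over the integer-rounded score distribution at scale ×1000 —
  deterministic, and verified against brute-force enumeration of all
  $4^w$ sequences for widths ≤ 8. Zero-probability motif cells score
  $-\infty$ and can never reach a finite threshold; offsets covering N are
  skipped. The default match threshold is $p < 10^{-4}$, the canonical
  scanner default, configurable. A variant has *allelic binding* when at
  least one allele has at least one hit for at least one PWM; windows use
  width − 1 flanks so every placement overlapping the variant is scored,
  with allele-length-aware substitution so indels are scannable.
* **Delta scores.** For SNVs, each allele's score is the sum of weights of
  the 9 constituent 11-mers of the 19-bp window (±9 bp) around the
  variant; `delta = score(alt) − score(ref)`, antisymmetric under allele
  swap. Lookups are forward-strand with reverse-complement fallback when
  the table's policy allows; a missing k-mer is an error naming the k-mer.
  Indels are excluded from delta scoring — the fixed 19-bp window is only
  well-defined for substitutions — but still pass motif scanning. Training
  the sequence model behind the weight table is out of scope; tables are
  inputs (TSV), and the generator emits synthetic ones.
* **Permutation null.** One permutation = one reassignment of the weight
  value multiset across all k-mers, after which *every* variant is
  re-scored; the per-variant null mean and sd over `n_perm = 100`
  permutations give $z$, two-sided normal $p$, BH $q$, and significance at
  $q < 0.1$. Permuting the multiset jointly (rather than per variant) is
  the most literal reading of "permuting k-mer effects"; how many
  permutations the original design used is not recoverable, so `n_perm`
  is exposed. A degenerate all-equal table gives null sd 0 and a missing
  $z$. Type-I calibration of the resulting p-values is asserted by the
  acceptance suite on 1000 null variants.
* **Overlap annotation.** A 1-based variant position $p$ overlaps a
  0-based half-open peak $[start, end)$ iff $start \le p-1 < end$;
  annotations carry the peak's accessible cell types and the variant's
  credible-set PPA when present. `pos_1to0()` is the single, documented
  bridge between the two coordinate conventions.

## What the synthetic data emulates — and what it does not

`simulate_cohort()` / `simulate_genome()` draw one shared genomic layout
(peaks, modules, genes, motif occurrences, variant positions) and emit a
three-age-group × three-donor cohort:

* per-cell complexity $C_j$ lognormal (meanlog log 4000, sdlog 0.4) with a
  per-donor meanlog spread of 0.6; reads $k_j \sim$ Poisson$(2\,e^{\delta_d}
  C_j)$ with a per-donor depth spread $\delta_d$ of total range 0.8,
  assigned within age groups so depth is not confounded with age;
* accessibility as 0/1/2 allele-count draws with success probability
  logistic(baseline + age shift + latent module factor), thinned per
  fragment by $s_j$ — exactly the sampling model the estimator assumes, so
  the estimator is unbiased by construction and estimator tests are tests
  of the code, not of model mismatch;
* co-accessibility modules as consecutive peak triplets sharing a latent
  factor of strength $2.5\rho$ on the logit scale ($\rho = 0.6$ default);
  module peaks are floored at typical baseline accessibility, because a
  planted factor on a near-silent peak is unidentifiable at any cohort
  size; the first peak of each module hosts a gene TSS so planted links
  are promoter-anchored;
* age-dynamic peaks with monotone logit shifts (half up, half down, 1.2
  per age step); expression UMIs Poisson with rate $-\log(1-f)$ so the
  expressing fraction matches the planted $f$ in expectation; motif
  occurrences as planted consensus strings with near-point-mass PWMs
  (0.97/0.01) and disrupting SNVs placed inside occurrences.

All randomness flows from one master seed through named substreams, so any
stage can be re-run bit-identically. What the generator does **not**
emulate: read-level artifacts, doublets, batch effects, peak-calling
uncertainty, linkage disequilibrium between variants, and realistic motif
grammar. Passing recovery tests therefore demonstrates correctness of the
estimators and the detection machinery under the stated sampling model,
not robustness to upstream artifacts of real data.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
cohorts of ~2,000 cells over 120–200 peaks on a 1.2–1.6 Mb genome for the
link- and dynamics-recovery checks, 2,000-peak null panels for NB
calibration, 1,000 variants × 100 permutations for the delta-score null,
5,000 × 3 profiles for the Davies–Bouldin selection, and enumeration up to
motif width 8 for the exact-p cross-check. These sizes were chosen as the
smallest at which the planted effects are comfortably identifiable; the
methods themselves have no scale-specific constants beyond the documented
metacell-size guidance.

## Known limitations

* The NB likelihood-ratio test with plug-in dispersion is only
  approximately calibrated at $n = 3$ per group even with likelihood
  shrinkage; quasi-likelihood F-tests would be more conservative but test
  a different statistic than the one specified here.
* Pooling 1 Mb-window cluster runs with 250 kb-window subset runs into one
  t-test mixes two score scales (see the `include_cluster_runs` switch).
* Coordinates are treated as one abstract genome build; any liftover
  between builds is the caller's responsibility.
* The co-accessibility score is a regularized partial correlation; it is
  evidence of statistical coupling across metacells, not of physical
  enhancer–promoter contact.
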