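---
title: "Bayesian window GWAS and genomic prediction for fatty-acid composition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian window GWAS and genomic prediction for fatty-acid composition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fagwas implements a complete desk-scale pipeline for dissecting the genetic
architecture of fatty-acid composition in a genotyped beef-cattle
population: spike-and-slab Bayesian whole-genome regression, 1-Mb window
association testing, genomic prediction with clustered cross-validation,
and the trait algebra that turns chromatography measurements into the
composite traits and indices breeders care about. This vignette explains
the models, the defaults, and the choices made where the design was
genuinely open.

## The whole-genome regression model

For one trait at a time we fit

$$ y = Xb + Zu + e, $$

where $y$ holds the per-animal phenotype, $X$ relates animals to fixed
effects — a population mean, contemporary-group classes (management group:
feed location x harvest date x sex), and four continuous covariates
(subcutaneous fat thickness, longissimus muscle area, hot carcass weight,
chemically extracted fat) — $Z$ holds allele dosages (0/1/2 copies of the
B allele), and $u$ holds random marker effects. The spike-and-slab prior
sets $u_j = 0$ with probability $\pi$ and otherwise draws
$u_j \sim N(0, \sigma^2_{u_j})$. Two variants are provided:

* **BayesC**: one slab variance common to all markers, updated from its
  scaled inverse chi-square full conditional. Used for prior elicitation
  (see below) because it is less sensitive to the prior scales.
* **BayesB**: a locus-specific slab variance per marker. Used for the
  inference runs, with $\pi$ high (default 0.999 at 50K-panel scale) so
  the fitted architecture is sparse.

Residuals are $N(0, \sigma^2_e)$ with a scaled inverse chi-square prior;
fixed effects get flat priors. Degrees of freedom default to
$\nu_u = 4$ and $\nu_e = 10$, common whole-genome-regression defaults.

### Sampler

`wgr_fit()` runs a single-site Gibbs sampler written in C++. Each marker's
inclusion indicator is sampled from its marginal full conditional based on
the score $r_j = z_j' y_{corr}$ (the residual with the marker's own
contribution restored); included effects are then drawn from their
conditional normal. For BayesB we keep a slab variance for every marker
and refresh it from its full conditional when the marker is in the model
and from its prior when it is not. This data augmentation is an exact
Gibbs scheme for the BayesB posterior; we prefer it to the classical
Metropolis–Hastings proposal-from-the-prior construction because it has no
tuning parameter and mixes at least as well at these problem sizes.

Two further numerical conventions:

* Marker update order is fixed at map order — no random permutation — so a
  seed fully determines a run.
* The per-sample genetic variance $\sigma^2_g$ is computed as the variance
  across animals of $Zu$ (not as $\sum 2p_jq_j \sigma^2_u$). This makes
  the genome-wide quantity exactly the sum-consistent counterpart of the
  per-window variances below, so window fractions are coherent.

Heritability is reported as the ratio of posterior means,
$\hat h^2 = \overline{\sigma^2_g} / (\overline{\sigma^2_g} +
\overline{\sigma^2_e})$, not the posterior mean of per-sample ratios.

### Iteration bookkeeping

The full-scale configuration of record is 41,040 iterations with thinning
40. Because $41{,}040 - 1{,}000$ is not divisible by 40, a burn-in of
exactly 1,000 iterations cannot yield a whole number of thinned samples;
we therefore burn 1,040 iterations so that exactly
$(41{,}040 - 1{,}040)/40 = 1{,}000$ samples are stored. Package defaults
use 11,040 iterations (250 stored samples) — at the simulated problem
sizes below the posterior summaries are already stable at that length, and
a run completes in about a minute on one core.

### Prior elicitation

`elicit_priors()` follows the two-stage convention: a BayesC chain with
$\pi = 0.95$ and prior genetic and residual variances each set to half the
phenotypic variance produces posterior variance estimates, which are
converted into BayesB scale parameters:

$$ s^2_u = \frac{\hat\sigma^2_g \,(\nu_u - 2)/\nu_u}
   {(1-\pi)\sum_j 2 p_j (1 - p_j)}, \qquad
   s^2_e = \hat\sigma^2_e \,(\nu_e - 2)/\nu_e, $$

with $p_j$ the observed allele frequencies and $\pi$ the mixing proportion
of the subsequent BayesB run. The division by $(1-\pi)\sum 2pq$ spreads
the genetic variance over the markers expected to be in the model; this is
the standard convention where the exact construction is not published. The
BayesC run also supplies the heritability estimate used as the
denominator in realized accuracy.

## Window association

`assign_windows()` bins SNPs into 1-Mb windows labelled
`chrom_floor(bp/1e6)`, 0-based — a SNP at 51,384,922 bp on chromosome 19
is in window `19_51`. Unmapped SNPs form one extra window. The X
chromosome is treated like any autosome.

`window_scan()` computes, for every stored sample $s$ and window $w$, the
window DGVs $\sum_{j \in w} z_{ij} u_j^{(s)}$ across animals; the window's
variance fraction in that sample is its across-animal variance divided by
the variance of the total DGV. The reported "genetic variance (%)" is 100
times the posterior mean of the per-sample fractions. We average ratios
rather than the ratio of averages because the companion significance
measure (PPI) is likewise a per-sample quantity; samples with zero total
genetic variance are skipped and counted. The denominator includes all
markers, the unmapped window among them.

**PPI** — the posterior probability of inclusion of a window — is the
fraction of stored samples in which at least one member SNP is in the
model. `significant_windows()` applies a strict threshold: PPI must
*exceed* 0.90; a window at exactly 0.90 is not selected.

## Genomic prediction and validation

* `compute_grm()` builds the VanRaden method-1 relationship matrix
  $G = MM' / (2\sum p_j(1-p_j))$ with $M$ the column-centered dosages.
* `kmeans_folds()` converts $G$ to the squared genomic distance
  $d_{ij} = g_{ii} + g_{jj} - 2g_{ij}$, embeds animals as the rows of this
  matrix (classical MDS is available as an option; the two embeddings give
  the same partitions on our simulations), and runs Hartigan–Wong K-means
  with $K = 6$ and 25 restarts; the two smallest clusters are merged to
  give 5 unequally sized folds. Clustering on relationships rather than at
  random keeps close relatives out of each other's training sets, so
  validation accuracy reflects linkage disequilibrium rather than family
  structure.
* `cross_validate()` trains on four folds, predicts DGV
  ($\mathrm{DGV}_i = \sum_j z_{ij}\hat u_j$) for the held-out fold,
  and compares them with phenotypes *adjusted by the training-estimated
  fixed effects*. Raw phenotypes would confound contemporary-group
  differences with the genomic signal; this adjustment is a deliberate
  design choice and the single place where we go beyond a literal
  "correlation with phenotypes". Fold-level regression slopes and
  correlations are pooled by fold-size weighting (Fisher-z pooling changes
  nothing at these magnitudes and is not exposed). Realized accuracy is
  the pooled correlation divided by $\sqrt{\hat h^2}$, with $\hat h^2$ the
  full-data estimate; its sign is preserved.
* The BayesB prior is elicited once on the full data and reused across
  training folds, so fold differences reflect the data split only.

## Within-window pleiotropy

`region_correlation()` asks whether one window drives two traits in a
coordinated way. Traits are fitted in independent chains; stored samples
are paired by index, and the correlation is assembled from posterior means
of per-sample across-animal covariances and variances of the window DGVs:

$$ r_w = \frac{\overline{\mathrm{cov}(a_s, b_s)}}
  {\sqrt{\overline{\mathrm{var}(a_s)}\;\overline{\mathrm{var}(b_s)}}}, $$

clamped to $[-1, 1]$. Pairing independent chains by stored index ignores
any cross-chain dependence — there is none to recover, since the chains
never see each other — so this estimator should be read as a descriptive
posterior summary, not a joint-model genetic correlation. Correlating the
posterior-mean window DGVs across animals is available via
`method = "point"`.

## Fatty-acid trait algebra

Measurements arrive on the **beef basis** (g x 10^-5 of fatty acid per g
meat) and are converted by `to_fat_percent()` to the **fat-percent basis**
(percent of total extracted fatty acid, summing to 100 per animal, i.e. a
composition). `fa_composites()` derives the composite and index traits
over the 38 named fatty acids:

* **MCFA / LCFA**: by default all acids of 10–15 carbons vs 16+. Printed
  methods texts sometimes define MCFA as 12:0 + 13:0 and LCFA as 14+
  carbons; that literal variant is available (`mcfa_def = "text"`), but
  the chain-length default is the one under which MCFA + LCFA = 100 on
  the fat-percent basis and which matches typical composition tables.
* **MUFA / PUFA / SFA**: sums by bond count, with membership carried as
  explicit data in `fa_reference()` rather than parsed from names; the
  conjugated linoleic acids count as polyunsaturated, trans isomers as
  unsaturated.
* **n3**: the full omega-3 series (18:3n3, 20:3n3, 20:5, 22:5, 22:6) by
  default; the two-term literal definition is `n3_def = "text"`.
* **n6**: the published summaries are ambiguous about whether the CLA
  isomers belong to the omega-6 sum — no printed subset reproduces the
  reference mean exactly, and two candidates differ by only ~0.2%. We
  default to the chemically standard six-acid series (18:2, 18:3n6, 20:2,
  20:3n6, 20:4, 22:4) and expose `n6_def = "series_cla"` and `"text"`;
  none of the three is asserted in tests.
* **Ratio/index traits** (PUFA/SFA, (14:0+16:0)/All, n3/n6, and the
  atherogenic index $AI = (4\cdot 14{:}0 + 16{:}0)/(\Sigma MUFA + \Sigma
  PUFA)$): defined on the fat-percent basis only and reported x100, the
  scale obtained when per-animal percentage ratios are averaged; on the
  beef basis they are reported `NA`. The AI numerator deliberately
  excludes 12:0 — the original diet-health index includes it, but the
  composition-table convention implemented here is the two-term numerator,
  and at beef-like compositions the difference (~0.2%) is far below the
  reporting precision. "All" in the saturation index is the sum of the 38
  named acids.

`fa_summary()` reports mean, sample SD ($n-1$), and CV x 100 per trait,
with CV undefined (NA) at zero mean.

## The synthetic-data generator

The generator exists so every stage is testable without proprietary
genotypes. It emulates the *statistical structure* the analysis assumes,
at reduced scale:

* `simulate_genotypes()`: allele frequencies uniform on [0.05, 0.5],
  Hardy–Weinberg dosages, positions evenly spaced so each 1-Mb window
  holds a fixed SNP count (default 20, near 50K-panel density), optional
  unmapped fraction, and optional first-order Markov LD between adjacent
  haplotype alleles. This is deliberately not a coalescent simulation:
  Markov copying is enough to exercise window logic and LD-sensitive
  bounds, but it reproduces neither realistic LD decay nor population
  structure, so passing tests say nothing about, e.g., long-range LD
  leakage between windows in real cattle data.
* `simulate_trait()`: QTL effects drawn inside designated windows and
  scaled so each window contributes its requested fraction of genetic
  variance; the residual is rescaled so the realized sample heritability
  equals the target exactly. Contemporary-group effects are
  $N(0, \sigma^2_{cg})$ with $\sigma_{cg} = 1$ and covariate coefficients
  default to (0.2, 0.1, 0.15, 0.25) — magnitudes chosen to be comparable
  to the genetic standard deviation, since no empirical values are
  available for them.
* `simulate_fa_profiles()`: independent log-normal weights per acid with
  means/SDs from the representative profile shipped in `fa_reference()`,
  then closure to fat percent. Closure induces the mild negative
  correlations inherent to compositions; real profiles additionally have
  strong biochemical correlations (shared synthesis pathways) that this
  generator does not emulate.

All randomness flows from `set.seed()`; every `simulate_*` and fitting
function takes a `seed` argument.

### Reference problem sizes

The package's own end-to-end checks run at n = 1,000 animals x m = 2,000
SNPs with three QTL windows carrying 50/30/20% of genetic variance at
h² = 0.5, fitted with 11,040-iteration chains over three seeds; smaller
designs (n = 200–500) are used for structural checks. At these sizes the
posterior heritability lands within ±0.10 of truth, planted QTL windows
reach PPI ≥ 0.9, and window variance fractions come back within ±10
percentage points — the same recovery behavior expected of the full-scale
design, at desk scale.

One calibration note: when a Monte-Carlo estimate is compared against a
closed-form solution coefficient-by-coefficient, the usual ±3 SE rule is
miscalibrated once tens of coefficients are compared (the expected maximum
of 30 standard-normal deviations is itself ≈2.9). Our sampler-vs-ridge
checks therefore apply the 3-sigma confidence level jointly, via the
chi-square quantile of the summed squared MC z-scores.

## Degenerate inputs and numerical conventions

* $\pi = 1$ forces every marker out of the model (all effects exactly 0);
  $\pi = 0$ includes every marker (ridge regression when variances are
  held fixed).
* Monomorphic SNPs: zero contribution to the GRM numerator and excluded
  from its denominator; in the sampler a zero-variance dosage column is
  never updated.
* Missing dosages are mean-imputed at twice the allele frequency, which
  preserves allele frequency and adds no artificial association signal.
* Zero denominators in ratio traits yield NA with a warning, never an
  error; an all-zero composition is an error (the composition is
  undefined).
* Window variance fractions skip (and count) samples with zero total
  genetic variance.
* Contemporary-group levels absent from a training fold leave their
  validation animals unadjusted for that effect, with a warning.

## Known limitations

* Single-trait models only; the pleiotropy probe pairs independent chains
  and is descriptive, not a multi-trait posterior.
* No genotype quality filtering (call rate, MAF) is applied by default;
  none was specified for the analysis this pipeline operationalizes.
* The generator's LD model is first-order; window variance fractions under
  realistic LD will leak between adjacent windows in ways these tests do
  not measure.
* No convergence diagnostics beyond what can be computed from the stored
  chain; at the default chain lengths users should check stability under
  a second seed for publication-grade numbers.
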