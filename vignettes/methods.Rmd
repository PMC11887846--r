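---
title: "Models and design decisions in pbrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in pbrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pbrisk implements the downstream statistical machinery of a single-nucleus
multi-omic case/control study of psychiatric disorders in postmortem
cortex: pseudobulk differential expression (DE) and differential
chromatin-accessibility (DA) testing with a data-driven covariate and
hidden-noise model, contrasts between propensity-matched extreme
polygenic-risk-score (PRS) groups, hypergeometric over-representation of
gene sets and transcription-factor motifs, and Spearman correlation
networks that integrate expression, accessibility, PRS and diagnosis.
Because the motivating data are restricted human samples, the package
ships a seeded synthetic-cohort generator that reproduces the study's
*statistical structure*, so that every stage can be validated by
calibration, parameter recovery and oracle equivalence rather than by
re-listing genes.

```{r setup, eval = FALSE}
library(pbrisk)
study <- simulate_study(n_donors = 90, cell_types = paste0("ct", 1:4),
                        n_genes = 500, seed = 1)
res <- run_pipeline(study, pipeline_config(seed = 1))
```

## Pseudobulk and quality control

Nuclei are filtered with the study's thresholds — RNA nuclei with fewer
than 500 total counts, fewer than 300 detected genes, or a mitochondrial
fraction of 0.15 or more are removed, ATAC nuclei with fewer than 1,000 or
more than 100,000 unique fragments or a TSS enrichment below 4 likewise —
and genes detected in fewer than 500 nuclei are dropped (`qc_thresholds()`
exposes each value). Counts are then summed over nuclei within each
donor/cell-type pair. Aggregation is exact integer summation, so total
counts are conserved and the full per-donor pseudobulk equals the sum of
the per-cell-type pseudobulks; both identities are asserted in the test
suite.

Chromatin accessibility is carried at the gene level as a *gene activity
score*: for gene $g$ and sample $s$,

$$\mathrm{score}(g, s) \;=\; \sum_{p:\, d(p,g) \le 10^5}
  e^{-d(p,g)/\tau}\, c_{ps},$$

where $c_{ps}$ is the peak's count, $d(p,g)$ is zero for peaks overlapping
the gene body and otherwise the base-pair gap to the nearest gene-body
edge, the window is 100 kb on both sides, and the decay length is
$\tau = 5\,000$ bp. The upstream toolkits that popularized gene scores do
not publish a single closed-form kernel; we fix this exponential kernel
(with $w(0) = 1$, strand ignored, symmetric window) so that results are
exactly reproducible, and we verify the closed-form values
($w(5000) = e^{-1}$, zero beyond 100 kb) and the linearity of scores in
peak counts in the tests. Gene scores are divided by the number of nuclei
aggregated into each sample before testing; a second normalization is an
error.

Feature filters follow the study's wording exactly: counts use *at least*
10 in a fraction of samples (`value >= 10`), scores use *above* 0.1
(`value > 0.1`), and the required number of samples is
`ceiling(fraction * n)`, avoiding float-equality ambiguity at the
boundary.

## Covariate selection and the hidden-noise PC

Covariate screening operates on the full pseudobulk (counts summed across
all cell types, genes filtered at 10 counts in 90% of samples), under the
assumption that technical covariates act consistently across cell types.
Counts are stabilized with median-of-ratios size factors followed by
`log2(count / sf + 1)` — a closed-form, rank-preserving stand-in for the
reference variance-stabilizing transform that keeps every quantity exactly
testable. Continuous covariates are screened by Pearson correlation
against each of the first 10 principal components; categorical covariates
by a one-way ANOVA F test per PC, the univariate equivalent of the
canonical-correlation screen. A covariate enters the model when its
minimum p value over the screened PCs is at most $\alpha = 0.05$ (the
reference analysis says only "significant"); under a pure-noise covariate
this selection fires at the familywise rate $1 - 0.95^{10} \approx 0.40$,
and the test suite checks that simulated selection matches this rate.

The final design is the study's model: intercept, variable of interest
(diagnosis or risk group), sex, the selected continuous covariates
(centered), library-batch indicators, and `PC_noise`. For risk contrasts
the batch indicators are dropped — the small matched groups cannot support
a categorical covariate — and for gene scores RIN is dropped, both
following the reference analysis. Missing RIN is imputed to the cohort
median.

`PC_noise` is the first principal component of the residuals after
regressing every gene on the known design *including* the variable of
interest. It is standardized to unit variance and is orthogonal to every
design column by construction (asserted to machine precision). One
property deserves emphasis: because the residuals are orthogonalized
against the variable of interest, the component of a real hidden factor
that happens to lie along the contrast *in this sample* is deliberately
not removed — removing it would also remove true signal. When a strong
hidden factor is simulated, `PC_noise` recovers its estimable part almost
perfectly, yet the per-gene tests remain anti-conservative in proportion
to the factor's chance alignment with the contrast. This is a property of
the regress-out-then-PC construction itself, not of this implementation,
and it is why the calibration checks below use a generator without a
hidden factor while hidden-factor recovery is validated separately.

Outlier samples are removed iteratively: PC1 scores are computed, samples
more than 3 sample standard deviations from the mean score are dropped,
and the loop repeats until nothing is removed or fewer than 3 samples
remain. The transformation and size factors are recomputed on the retained
samples (the reference text leaves this open; recomputing keeps the
downstream model self-consistent). With two samples no removal is possible
(each point sits at $SD/\sqrt{2}$ from the mean), and zero variance stops
the loop.

## Differential testing

**Counts (DE).** Each gene is fit with a negative-binomial GLM with log
link and `log(size factor)` offset, by iteratively reweighted least
squares (relative tolerance $10^{-8}$, at most 100 iterations). The
per-gene dispersion is a method-of-moments estimate on normalized counts,
conditioned on the design: $\hat\alpha = \max\{(\hat v - \bar q)/\bar q^2,
10^{-8}\}$ with $\hat v$ the df-corrected residual variance, so that
design-explained variation does not masquerade as dispersion. There is no
dispersion shrinkage across genes — that is the one intentional deviation
from the reference toolkit, and it is compensated by validating the engine
through calibration and recovery rather than by replicating gene lists.
The Wald statistic divides the variable-of-interest coefficient by its
information-matrix standard error; log2 fold change is the coefficient
divided by $\ln 2$. p values use a $t$ reference with $n - p$ degrees of
freedom: with a plug-in dispersion the normal reference is visibly
anti-conservative at pseudobulk sample sizes, and the $t$ correction
restores uniform null p values (checked by KS tests over 50 seeded
cohorts). At the dispersion floor the engine reduces to a Poisson GLM and
matches an independent `glm(family = poisson)` oracle to $10^{-3}$.

**Gene scores (DA).** Scores are not counts, so the model is ordinary
least squares on `log2(normalized score + 1)` with the same design; the
Wald statistic is referred to $t_{n-p}$, conservative at small $n$. The
log2 fold change is defined as the group coefficient of this model (the
reference does not state its FC scale; this is the natural one for a log2
response). The engine equals the closed-form $(X^TX)^{-1}X^Ty$ oracle to
$10^{-10}$ on random fixtures. Residual normality is screened per gene
with Shapiro–Wilk as an advisory diagnostic only.

Benjamini–Hochberg adjustment is applied within each cell type; `NA` p
values pass through without counting toward the number of tests. Genes
with FDR $\le$ 0.1 are reported as significant, matching the study's
threshold for both modalities. Cell types with fewer than 6 samples after
outlier removal are skipped with a warning.

## Extreme polygenic-risk groups

For each trait the 20 donors with the highest and the 20 with the lowest
PRS form candidate pools (ties broken by donor id, deterministically).
Propensity for high-pool membership is estimated by logistic regression on
age, pH, PMI and RIN; sex is excluded from the model because it is matched
exactly. Under complete separation the fit falls back to a
standardized-covariate distance score with a warning. Matching is greedy
1:1 nearest neighbor without replacement on the absolute logit-propensity
difference, within exact sex strata, processing high-pool donors in
descending propensity order.

One design choice here is ours: a caliper of 1.0 standard deviations of
the logit propensity (configurable; `Inf` disables it). With equal-size
pools, 1:1 matching without replacement and no caliper retains essentially
every donor, so matching cannot improve covariate balance at all — the
excluded-donor mechanism is what buys balance. The conventional 0.2-SD
caliper, on the other hand, discards roughly half of the candidates of an
extreme-group design, below the retention the motivating study reports
(matched groups of 11–17 from pools of 20). At 1.0 SD, retention lands in
that range and the mean absolute standardized mean difference improves in
about 95% of confounded simulations. Matched groups are always equal-sized
and sex-exact (asserted on every run), and both groups typically mix cases
and controls, as expected when PRS only correlates with liability.

## Enrichment, networks and comparisons

Over-representation uses the exact upper-tail hypergeometric probability
$P(X \ge k)$ with BH adjustment across sets (significance at FDR
$\le 0.05$). Pathway enrichment takes the 250 most significant genes per
direction of regulation per cell type (ranked by FDR, then |log2FC|, then
gene id — fully deterministic), with the genes tested in that cell type as
the universe; directions with fewer than 10 genes are skipped. Motif
enrichment contrasts the peaks in a gene's promoter window — 2 kb upstream
to 500 bp downstream of the TSS, strand-aware; the reference never defines
"promoter", so the window is configurable and logged — against all peaks.
The hypergeometric p equals brute-force enumeration on every instance with
a universe of at most 25 (including the worked values 76/15504 and
1/4950), verified in the tests.

Networks are built on the matched risk donors: expression and
accessibility features are residualized against sex, age, RIN, PMI, pH and
library batch; PRS and diagnosis enter uncorrected. Spearman's rank
correlation (average ranks for ties) is computed for every feature pair, p
values come from the $t$ approximation with $n-2$ df (within 0.01 of a
10,000-draw permutation oracle at $n = 12$), and edges with nominal
$p \le 0.05$ are kept with weight $|\rho|$ and the sign retained. The edge
set shrinks monotonically as the threshold tightens.

Cell-type proportions are compared between modalities donor-paired with a
two-sided Wilcoxon signed-rank test per cell type (zeros dropped; exact
tie-aware null distribution via generating-function convolution up to
$n = 25$, normal approximation with continuity and tie correction above)
plus BH across cell types, alongside per-donor Pearson correlations of the
proportion profiles and their median. The exact distribution equals full
sign enumeration for $n \le 10$ in the tests; `stats::wilcox.test` cannot
provide exact p values under ties or zeros, which is why the distribution
is implemented here. Cross-study comparison correlates log2 fold changes
of shared genes per cell-type pair (Pearson; `NA` below 3 shared genes).

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions. Donor covariates follow the cohort's reported moments: age
$\mathcal N(54.27,\,13.64^2)$, PMI $\mathcal N(33.90,\,14.82^2)$ truncated
at 0, pH $\mathcal N(6.60,\,0.24^2)$, 38% female, 57/92 cases with
diagnoses drawn 38/7/7/5 (schizophrenia/schizoaffective/MDD/bipolar), and
exactly one donor with missing RIN to exercise imputation. Case status
thresholds a latent standard-normal liability; a simulated PRS is built as
$r \cdot \text{liability} + \sqrt{1-r^2}\,\varepsilon$ (default
$r = 0.3$), standardized, so both PRS tails contain cases and controls.

Pseudobulk counts are negative binomial (default dispersion 0.1) with
log-mean = gene baseline (log-normal around 50) + library-size factor
(4-fold range) + $\ln 2 \times$ planted log2 effects: a case/control
effect of magnitude 1 on 10% of genes per cell type (random sign), a
PRS-linked slope of 0.5 log2 units per PRS standard deviation on 10% of
genes in one targeted cell type, gene-wise loadings (SD 0.5) on a single
donor-level hidden factor, batch offsets (SD 0.2), and small age/pH
effects (SD 0.1) so the covariate screen has something to find. Planted
effects are restricted to genes whose baseline clears the pipeline's own
count filter: an effect planted on a gene the assay cannot measure would
conflate coverage with power, which is standard benchmarking practice.
Gene scores are log-normal, strictly positive, scaled by the number of
aggregated nuclei, with the same planted-effect structure. Per-donor
cell-type compositions are drawn once (Dirichlet) and shared between
modalities with modality-specific totals and noise, giving the high
donor-wise proportion correlations seen in matched assays. An optional
nucleus-level mode draws gamma-mixed Poisson nuclei whose sums are exactly
the negative-binomial pseudobulk, to exercise QC and aggregation. Every
generator records its truth (effects, loadings, factors, seed) before
noise is drawn, and identical seeds give identical output.

What the generator does *not* emulate: ambient contamination, doublets,
zero inflation beyond the NB, cell-type misassignment, and any genuinely
nonlinear covariate structure. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under its stated
model, not that the model captures every pathology of real single-nucleus
data.

## Validation strategy and problem sizes

The acceptance suite runs entirely on synthetic data: null calibration of
both engines (2,000 genes, 40 samples, 50 seeds), recovery of a planted
unit log2 fold change (|mean bias| $\le 0.1$, sensitivity $\ge 0.8$ at FDR
$\le 0.1$, 200 genes at $n = 20$ vs 20), oracle equivalence of every
statistical primitive, hidden-factor recovery at SNR 2, outlier
sensitivity/specificity, matching invariants over 1,000 randomized pools,
exact conservation laws, and a full end-to-end run (90 donors, 8 cell
types, 1,500 genes, 5,000 peaks, 50 motifs, 30 gene sets) that must be
byte-identical across reruns and recover at least 80% of planted risk
genes in the targeted cell type. These sizes keep a complete validation
run in a few minutes on one core while leaving each check comfortably
powered; `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.

## Known limitations

- No dispersion shrinkage across genes; at very small sample counts the
  per-gene moment estimate is noisy and the $t$ reference compensates only
  on average.
- A single noise PC is estimated, matching the reference design; multiple
  hidden factors would leak into the residuals.
- The hidden-factor component aligned with the contrast is intentionally
  retained (see above); strongly confounded hidden structure inflates the
  false-positive rate of any method with this design.
- Gene-score kernel parameters (exponential, 5 kb decay) are a documented
  stand-in for a toolkit internal the reference does not specify.
- The matching caliper default is a package choice; set `caliper = Inf`
  for the literal no-caliper behavior.
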