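---
title: "Cell-type-resolved comparison of two patient groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved comparison of two patient groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltypewise)
```

## The analysis problem

Single-nucleus RNA-seq of tumor biopsies from two clinical groups (for
example brain versus extracranial metastases) gives a sparse gene-by-cell
count matrix, cell-type annotations, and a patient label per cell.  Two
statistical obstacles separate those counts from a per-cell-type group
comparison:

1. **Cells are not replicates.**  Thousands of cells per patient are
   pseudo-replicates of one biological sample; treating them as independent
   grossly overstates evidence.  The remedy is *pseudobulk* aggregation:
   one value per (gene, patient, cell type), so that patients are the unit
   of replication.
2. **Integration imputes.**  Joint embedding/integration methods fill in
   expression at positions where nothing was measured.  Values synthesized
   at raw-zero positions must not enter statistics, so the pipeline masks
   every entry whose raw count is zero (`mask_imputed()`); downstream
   operations treat those entries as missing, never as zero.

`celltypewise` implements the full path from counts to: per-cell-type
moderated-t differential expression, correlation-based homogeneity analysis
with a random-intercept mixed model, signature clustering with multiscale
bootstrap stability, PCA that tolerates missing values, and ranked-list
gene-set enrichment — plus a hierarchical count simulator with planted
ground truth so every stage is testable without any external download.

## The synthetic-data generator

`simulate_dataset()` draws, for cell $c$ of patient $p$, cell type $t$ and
gene $g$,

$$ y_{gc} \sim \mathrm{NB}\!\left(\mu_{gc},\ \theta_g\right),\qquad
\log \mu_{gc} = b_{gt} + u_{pt} + \tau_g\, j_{gpt} + \delta_{gt}\,
\mathbf{1}[p \in A] + \log \ell_c , $$

with variance $\mu + \mu^2/\theta$ and:

* $b_{gt}$ — gene-by-cell-type baseline (drawn once, N(0.5, 1) gene effects
  plus N(0, 0.5) cell-type deviations, or supplied as a matrix);
* $u_{pt} \sim N(0, \sigma_{\text{group}(p)}^2)$ — a profile-wide patient
  intercept per cell type;
* $j_{gpt} \sim N(0, (0.5\,\sigma_{\text{group}(p)})^2)$ — gene-specific
  patient jitter at (patient, cell type) granularity.  The intercept shifts
  whole profiles without decorrelating them; the jitter is what makes one
  group's patients more alike than the other's, which the correlation
  module must recover;
* $\tau_g$ — a lognormal (mean-1, log-SD 0.6) gene-level multiplier on the
  jitter SD.  Real datasets show strongly heterogeneous between-patient
  variance across genes — equivalently, a finite prior df in an
  empirical-Bayes variance fit; without $\tau_g$ the simulated variances
  are so homogeneous that the prior df estimate diverges, a regime real
  data do not occupy;
* $\delta_{gt}$ — planted group effects ($\log 2 \times$ `log2_effect`),
  restricted by configuration to designated "microenvironment" cell types;
* $\ell_c$ — lognormal(0, 0.3) library-size factor.

**Dropout.**  Counts are then thinned entry-wise (Bernoulli) with a
gene-specific retention propensity tied to baseline expression
(`plogis(0.5 + centered mean baseline)`), so well-expressed genes drop out
less — as in real single-nucleus data.  A single scalar is calibrated by a
short fixed-point iteration so the *realized global zero fraction* meets
`dropout_target` (default 0.88, the sparsity level typical of
single-nucleus studies).  Because thinning is group-independent, planted
fold changes are preserved among the surviving entries.

**The default template** (`sim_template()`) is a desk-scale analogue of a
15-vs-10-patient study: 6 vs 6 patients; five cell types
(tumor 120, stromal 50, T cell 50, myeloid 40, endothelial 40 expected
cells per patient, Poisson); 2,000 genes; zero planted effects in the
tumor type and 60 effects of $|\log_2 \mathrm{FC}| = 1$ (75% negative) in
each of stromal/Tcell/myeloid; $\sigma_A = 0.15 < \sigma_B = 0.35$ (group
A more homogeneous).  Planted genes are placed on the top-20% baseline
stratum of their cell type: an effect on a gene too sparse to clear the
10-supporting-cell rule could never be tested, just as a real study's
discoveries are by construction among its testable genes.

The generator does **not** emulate: biological gene–gene correlation
modules, trajectories, doublets, ambient RNA, or batch chemistry.  Tests
passing on this generator therefore certify the statistical machinery
(calibration, recovery, invariances), not robustness to those artifacts.

## Preprocessing and masking

* QC keeps cells with 500–10,000 detected genes (inclusive), 1,000–60,000
  counts (inclusive) and mitochondrial fraction strictly below 10% — the
  punctuation of the usual printed rule decides the boundary semantics.
  `template_run_config()` rescales only the per-cell ranges to the
  2,000-gene template (100–2,000 genes, 200–100,000 counts).
* Patients whose focal-type (tumor) cell count falls below a configurable
  threshold (default 100; 50 at template scale) are excluded entirely.
* `lognormalize()` is $\ln(1 + 10^4 \, c_{gc} / \mathrm{total}_c)$.
* `select_variable_genes()` ranks genes by dispersion (variance/mean)
  z-scored within 20 equal-occupancy mean bins (bins shrink so each holds
  at least 5 genes); ties break by gene id.  This is a documented
  deterministic surrogate for integration-feature selection.
* `center_by_batch()` subtracts, per gene and patient, the patient's mean
  over nonzero entries — a deliberately simple alignment stand-in; a real
  integrated matrix can be supplied to `run_pipeline(integrated = ...)`
  instead.  **Limitation:** because the patient mean pools all of a
  patient's cell types, a true group effect in one cell type leaks a
  small opposite shift into the patient's other cell types.  The simulator
  emulates data already on a common scale (it has no batch structure), so
  the template configuration runs with `center_batches = FALSE`; the
  centered path remains available and exercised for real multi-batch data.

## Pseudobulk and differential expression

`pseudobulk()` averages the *observed* entries per (gene, patient, cell
type) and keeps an entry only with ≥ 10 supporting cells (the support
rule is evaluated on the raw-derived mask — the more conservative
reading).  Averaging over all cells instead would conflate missingness
with zero expression.

Per cell type, a gene is tested when observed in ≥ 4 patients *per group*
(3 for small-cohort variants).  Each gene is fit by OLS on its own
complete patients (per-gene row deletion), `expression ~ group
(+ covariates)`; the group contrast is reported as
$\log_2\mathrm{FC} = \hat\beta/\ln 2$ (models are fit on natural-log
values), positive meaning higher in group A.

Variance moderation follows the standard empirical-Bayes scaled
inverse-chi-square model: residual variances $s_g^2$ with $d_g$ df are
shrunken to

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, $$

with $(d_0, s_0^2)$ estimated by matching the mean and variance of
$\log s_g^2$ against digamma/trigamma identities of the scaled-F sampling
distribution (Newton inversion of the trigamma, tolerance $10^{-8}$, 100
iterations; $d_0$ above $10^6$ reported as infinite, i.e. complete
shrinkage).  The moderated $t = \hat\beta / \sqrt{\tilde s_g^2 v_g}$ has
$d_0 + d_g$ df.  BH FDR is applied within each cell type; significant
counts are reported at cutoffs 0.05/0.1/0.2 split by the sign of the fold
change.  The test suite checks the exact $d_0 = 0$ (ordinary $t$) and
$d_0 = \infty$ limits, hyperparameter recovery on simulated variances, and
agreement with the independent reference implementation in `limma`.

Calibration is assessed on the uncentered path: the generator plants no
batch effects, and the centering stand-in's leak (above) is an artifact of
the stand-in, not a property of the moderated-t machinery under test.

## Correlation homogeneity and the mixed model

`pseudobulk_pair_correlations()` computes Pearson correlations between all
patient pairs over the genes observed in both (pairwise complete, ≥ 10
shared genes), classed A–A / B–B / A–B.  Class distributions are compared
with Welch tests (the unpaired-t choice that does not assume equal
variances) and BH FDR over all tests performed; stars mark FDR < 0.05 and
< 0.001.  At single-cell resolution, `sample_cellpair_correlations()`
draws 100 *cross-sample* cell pairs per sample pair with replacement
(within-sample pairs cannot inform between-sample similarity) and records
the mean pair correlation; pairs with fewer than 10 jointly observed genes
are redrawn, boundedly.

`fit_lmm_contrasts()` fits `r ~ pair_class + (1 | patient_pair)` by REML,
profiling the likelihood over $\lambda = \sigma_u^2/\sigma_e^2$ in one
dimension (log-scale golden-section/parabolic search, boundary
$\sigma_u^2 = 0$ checked explicitly and flagged).  Pair-class means and
all pairwise contrasts use the GLS covariance with normal-approximation
p-values — a deliberate simplification relative to Satterthwaite df — and
BH FDR.  Correctness anchors: the balanced one-way closed form
$\hat\sigma_u^2 = (\mathrm{MSB} - \mathrm{MSW})/k$, exact OLS under the
$\sigma_u^2 = 0$ constraint, and agreement with `lme4`.  The random-effect
level is the unordered patient pair, shared across cell types when several
cell types are fit jointly; both per-cell-type and joint fits are
supported since the choice is genuinely open.

## Signature clustering and stability

The per-cell-type signature is the top 50 tested genes by unadjusted p
(ties: larger $|t|$, then gene id).  Patients are clustered on the
signature columns with complete linkage on the pairwise-complete scaled
Euclidean distance

$$ d(i,j) = \sqrt{\frac{D}{|S_{ij}|} \sum_{g \in S_{ij}} (x_{ig} -
x_{jg})^2 }, $$

which keeps distances comparable across pairs with different overlap; the
agglomeration breaks ties deterministically toward the smaller cluster
indices and returns a standard `hclust` object.  Separation is judged at
the root 2-cut: `perfect` iff the partition equals the group partition,
with the adjusted Rand index always reported.

`bootstrap_stability()` resamples signature columns with replacement at
scales $r = 0.5, \dots, 1.4$, reclusters, and counts how often each
original node's exact leaf set reappears ($BP_r$).  The approximately
unbiased value comes from the two-parameter multiscale model
$\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}$ fit by weighted least
squares (weights $B\,\phi(z_r)^2 / (BP_r(1-BP_r))$) over the informative
scales ($0 < BP_r < 1$), giving $AU = 100\,(1 - \Phi(v - c))$.  When
fewer than two scales are informative — a node present in essentially
every replicate at every scale — the extrapolation is undefined; the node
is flagged and AU falls back to the plain bootstrap support.  Note that
AU ≥ BP is *not* an invariant of the method.

### Selection circularity at small cohort size

One qualitative property of the template deserves its own discussion.  The
intended contrast is: signatures of effect-bearing cell types separate the
groups, while the signature of the effect-free tumor type does not.  The
union and per-effect-type halves hold robustly.  The tumor-only half does
**not** hold at 6v6 scale: selecting the 50 lowest-p genes from ~1,200
tested null genes picks genes whose sample group means differ by roughly
$|t| \cdot \mathrm{SE}$ each ($|t| \approx 2.3$–2.6 at these ranks), and
50 such columns jointly span a group-separating subspace for the very
samples used to select them.  Clustering 50 *random* tumor genes yields
ARI ≈ 0 — the generator itself plants no tumor-type structure; the
separation is manufactured entirely by p-ranked selection, and is further
amplified by the planted homogeneity asymmetry ($\sigma_B = 2.33\,
\sigma_A$ inflates B–B distances toward the A–B level).  With more
patients and a deeper gene universe the same arithmetic sits at the
boundary, which is why the phenomenon need not appear at full study
scale.  We report this honestly rather than adjusting the generator: it
is a real and instructive caveat for small-cohort signature clustering.

## Missing-value PCA

`nipals_pca()` mean-centers each column over its observed values and runs
the NIPALS iteration with every score/loading update summing only over
observed cells; components are deflated on the observed entries.
Convergence is a relative score change below $10^{-8}$ (at most 500
iterations; non-convergence flags the component and stops gracefully).
Signs are fixed by forcing each loading's first nonzero element positive.
On complete data the scores match SVD-based PCA component-wise; observed
variance captured is tracked as $1 - \|E\|^2_{\text{obs}} /
\|X_c\|^2_{\text{obs}}$.

## Ranked-list enrichment

`ordered_min_p()` tests a gene set against every prefix of a ranked list,
taking the minimum upper-tail hypergeometric probability; ranking ignores
the direction of change.  Only prefix lengths where a set member enters
(plus the full length) are evaluated: at fixed overlap the tail
probability decreases only when a member enters, so the reduced grid
provably contains every minimum (asserted against the all-prefix oracle in
the tests).  The background must be supplied explicitly — when a ranking
comes from outside the pipeline there is no defensible silent default.
Because the original correction for this incremental testing lives inside
an external web service, `calibrate_and_adjust()` instead calibrates
family-wise by permutation: `n_perm` shuffles of the ranking, each set's
minimum p recomputed, and a set's adjusted p is the fraction of
permutations whose *family minimum* falls at or below the observed value,
with the $(r+1)/(n_\text{perm}+1)$ estimator.  The raw minimum p is always
reported so any other correction can be applied.  Sets smaller than 3 or
larger than half the background are skipped by default.

## Numerical and reporting conventions

* Missing entries serialize as the literal string `NA`; floats with 6
  significant digits; Matrix Market indices are 1-based on disk.
* All randomness flows from explicit integer seeds; rerunning any stage on
  identical inputs and seed reproduces identical output.
* Problem sizes used throughout the test suite and the acceptance script:
  the 2,000-gene / 12-patient / ~300-cells-per-patient template, 20 seeds
  for every multi-seed recovery property, 2 pooled null simulations
  (≥ 2,000 tests) for type-I calibration, 5,000 genes for hyperparameter
  recovery, and 1,000 bootstrap replicates per scale for the stability
  fixture — sizes chosen so the whole suite runs comfortably on a laptop
  while keeping Monte-Carlo error far below every asserted margin.

## Known limitations

* The integration stand-in is per-patient centering, not an anchor-based
  method; its cross-cell-type leak is documented above.  Supply a real
  integrated matrix for production use.
* LMM contrasts use the normal approximation (no Satterthwaite df): with
  few patient pairs, p-values are mildly anti-conservative.
* The moderated-t fit is trend-free and non-robust (no `trend`/`robust`
  analogues).
* The enrichment calibration is family-wise within the supplied
  collection; it does not reproduce any external service's correction
  numerically.
* Tumor-only signature clustering at small cohort sizes is subject to the
  selection circularity described above; treat "does not separate" claims
  from 12-patient cohorts with caution.
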