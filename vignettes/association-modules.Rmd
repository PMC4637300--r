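---
title: "Discovering and validating multi-omic association modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating multi-omic association modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocmod)
```

## The model

An *association module* is an observed effector aberration on DNA — the
copy-number state of a chromosome arm, or the methylation state of a
gene — together with the set of target genes whose mRNA expression
statistically depends on it. Three module types are distinguished by the
mechanism they posit:

* **cis-acting CNV**: targets sit on the effector arm itself; the
  association is positive by construction (more copies, more
  transcript).
* **trans-acting CNV**: targets sit on other arms; the effect is
  mediated by regulators that are themselves cis targets of the
  effector arm, and may carry either sign.
* **methylation**: the effector is the methylation state of a gene;
  associations with target expression are negative (promoter
  methylation silences).

### Normalization and trinary states

All measurements enter the model through a rank transform: for each
feature, the vector of values across the cohort is replaced by
mid-rank/(n+1) values — an empirical CDF evaluated at the observation,
kept strictly inside (0, 1) so the logarithms below are always defined.
Any strictly monotone rescaling of the raw data (log, affine, platform
scaling) leaves the output unchanged, which is what makes cohorts from
different platforms comparable. A CDF value $y$ is then mapped to soft
probabilities over a hidden trinary state
$x \in \{\text{down} = -1, \text{none} = 0, \text{up} = +1\}$:

$$P(x = 1 \mid y) = \frac{y}{1 - \ln y}, \qquad
  P(x = -1 \mid y) = \frac{1 - y}{1 - \ln(1 - y)}, \qquad
  P(x = 0 \mid y) = 1 - P(1 \mid y) - P(-1 \mid y).$$

These closed forms sum to one, are symmetric
($P(1 \mid y) = P(-1 \mid 1 - y)$), and $P(1 \mid \cdot)$ is strictly
increasing; the test suite asserts all three on a $10^4$-point grid at
$10^{-12}$ tolerance. Copy-number probes are first aggregated to
chromosome arms by the per-sample median over probes (arms are the
segmentation unit throughout; finer segmentation is out of scope), and
tumor measurements are expressed relative to the paired adjacent-normal
tissue — a ratio for expression and CNV, a beta *difference* for
methylation, which preserves the bounded [-1, 1] scale. Downstream
screening uses correlations, which are indifferent to this affine
choice.

### Per-gene model and module assembly

For each gene, candidate effectors are screened by Pearson correlation
between the gene's CDF-normalized expression and the effector profile,
with a default threshold of $|r| \ge 0.5$ and a sign constraint per
kind (cis: positive with the own arm; methylation: negative; trans: any
sign with another arm). Surviving candidates enter a logistic model of
the trinary expression state $y$,

$$P(y \mid x) = \frac{1}{Z(x)} \exp\Big(\sum_i \lambda_i f_i(x, y)\Big),
  \qquad \lambda_i \ge 0,$$

with feature functions $f_i(x, y) = d_i \, \mathrm{E}[x_i] \, y$, where
$d_i \in \{+1, -1\}$ is the candidate's mechanistic direction and the
expectations are taken under the trinary soft assignments. This is the
simplest feature family consistent with signed associations under the
non-negativity constraint; the constraint itself is what encodes the
mechanism (an anti-correlated candidate for a positive-direction
feature is driven to $\lambda = 0$ and rejected). The expected
log-likelihood is concave in $\lambda$, and is maximized by projected
gradient ascent with backtracking line search (tolerance $10^{-8}$ on
the objective improvement, at most 500 iterations).

Candidates are added greedily in a fixed layer order — all cis
candidates first, then trans, then methylation, each layer sorted by
decreasing |screening correlation| — and a candidate is kept only if
BIC $= -2\,\ell + k \ln n$ strictly improves. The layer order encodes
decreasing mechanistic certainty; BIC was chosen as the
goodness-of-fit/complexity balance because the sample sizes are small
and the candidate pools large, so a conservative penalty is
appropriate. Genes sharing a selected effector are grouped into one
module per effector; trans modules additionally record as regulators
the cis targets of their effector arm. Modules with fewer than 5
targets are not reported (small enough to keep compact methylation
modules discoverable, large enough that the validation statistics are
meaningful). Ties anywhere are broken by lexicographic gene id, so the
whole fit is byte-deterministic.

## Validation battery

Each module is tested in each validation cohort three ways; a module
passes overall only if **all three** tests pass in **every** required
cohort, and any test that cannot be evaluated (unmappable targets,
empty patient group) counts as a failure — degenerate modules can never
validate.

1. **Expression coherence.** All pairwise correlations among the
   module's targets are compared against the pairwise correlations of
   1000 randomly selected genes (capped at 50,000 sampled pairs) by a
   one-sided Kolmogorov–Smirnov test for a positive shift. Because the
   KS p-value depends strongly on the number of pairs, the raw p is
   *size-adjusted*: it is ranked among the raw p-values of `n_adjust`
   random gene sets of the same size, with the add-one convention
   `(1 + #{null <= raw}) / (n_adjust + 1)` so the adjusted p is never
   exactly zero. Pass at adjusted p < 0.05.
2. **Cox-coefficient shift.** A univariate proportional-hazards
   coefficient is fitted per gene (partial likelihood, Breslow ties,
   Newton iterations to $10^{-9}$); positive coefficients mean high
   expression predicts shorter survival. The module's coefficient set
   is compared against the all-gene background by the same one-sided,
   size-adjusted KS machinery. Pass at adjusted p < 0.05.
3. **Aggregate-biomarker log-rank.** The per-patient median expression
   over the module's targets splits the cohort into high and low groups
   at the global mean of the expression matrix, and the two
   Kaplan–Meier curves are compared by the log-rank test (1 df). Pass
   at p < 0.1. On rank-normalized data the global mean sits at 0.5, so
   this split is nearly the biomarker median; splitting at the mean of
   the aggregate itself is available via `split = "module_mean"`. The
   global-mean rule is the default because it is the one consistent
   with the size-adjustment machinery used by the other two tests.

The one-sided (positive-deviation) KS p feeds the size adjustment in
both distribution tests, because the scientific question is directional:
coherent modules are *more* correlated than background, and risk
modules have *larger* Cox coefficients. The two-sided p is also
reported for the coherence test.

## Permutation FDR

*Pairwise level*: sample labels of each effector matrix are shuffled
relative to expression (breaking every cross-omics link while
preserving within-matrix structure — the null the FDR ratio requires),
the screening is re-run at identical thresholds, and
FDR = mean null count / observed count, per aberration type. When no
positives are observed the FDR is reported as `NA`, never 0. The
default is 100 permutations. *Module level*: genes are randomly
assigned to modules matching the real size multiset, the full
validation battery is applied, and the expected number of null modules
passing each test (and the all-test conjunction) is reported over
`n_runs` (default 200) runs. Inside this battery the size-matched
adjustment uses a reduced `n_adjust` of 200 for tractability, recorded
in the report. The null raw-p distributions are memoised per (cohort,
size, seed): random size-matched sets are exchangeable across modules
of equal size, so the cache is statistically neutral while letting
thousands of null modules be scored in seconds.

## Inter-module dependency by two-block PLS

Two modules' target sets are treated as X and Y blocks over shared
samples and decomposed by NIPALS partial least squares
($X = T_M P_M^\top + E_M$, tolerance $10^{-10}$). The default is
regression-mode (PLS2) deflation, treating the second block as the
response, because the dependency question is directional; a symmetric
canonical mode is available since both blocks are target sets, and when
a pair is compared both ways the report prints both orientations. The
first weight vector coincides with the top left singular vector of
$X_c^\top Y_c$ (asserted against an SVD oracle at cosine ≥ 0.999 over
100 random instances), scores are mutually orthogonal, and the
cumulative $R^2(m) = 1 - \|Y_c - \sum_{k \le m} t_k c_k^\top\|_F^2 /
\|Y_c\|_F^2$ is non-decreasing. The correlation circle places every
variable at its correlations with the first two scores; constant
columns are flagged at the origin. A companion test asks whether a
focal arm's CNV correlates with a target set more than background arms
do, again by one-sided KS.

## Offline annotation

Live literature queries and proprietary pathway software are replaced
by offline inputs so the analysis is self-contained: a two-column
citation-count table (module targets are intersected with the
top-ranking 5% of genes, ties at the cutoff included) and GMT gene-set
collections scored by the right-tailed hypergeometric test with
Benjamini–Hochberg adjustment. A set is reported only when the adjusted
p is below 0.01 **and** the overlap strictly exceeds 4 genes. The
background universe is the set of measured genes, not the genome,
because enrichment against unmeasurable genes is not interpretable
here.

## The synthetic study

`simulation_spec()` defines the study conditions; the generator is a
pure function of the spec (seed included). The defaults emulate a small
single-site multi-omic training cohort: 60 tumor/normal pairs, 2000
genes on 10 chromosomes (100 per arm, 20 CNV probes per arm), arm CNV
log-ratio dispersion $\sigma_{\text{arm}} = 1.0$, probe noise 0.3,
expression noise 1.0, and one planted 40-target cis module on chr7p
whose effect size is back-computed so the expected effector–target
correlation is 0.7 — the middle of the screening regime, matching the
magnitude of arm-level dosage effects reported for bulk tumor
expression data. Trans modules are generated through an explicitly
cis-driven regulator; methylation modules through a variable
tumor–normal beta difference. Validation cohorts default to four
gender-by-ethnicity subpopulations of 100 patients; survival times are
exponential with hazard
$\lambda_0 \exp(\gamma \cdot \text{biomarker})$, where the biomarker is
the planted module's standardized median expression,
$\lambda_0 = 0.1$, and $\gamma = 1.2$ in the East Asian female cohort
only — the plantable analogue of a subpopulation-specific prognostic
effect. Censoring is independent and calibrated by root-finding to a
target fraction of 0.3 (typical of lung adenocarcinoma follow-up).
A Weibull hazard is available by flag.

What the generator does *not* emulate: microarray probe-level
artifacts, batch effects, LD or CNV breakpoint structure within arms,
copurity/ploidy distortions, or correlated background genes. Passing
tests therefore demonstrate that the machinery recovers the statistical
structure it models, under noise levels chosen to be realistic — not
that it is robust to every artifact of real cohorts.

## Numerical choices and degenerate inputs

* Mid-rank/(n+1) keeps CDF values strictly interior, so
  $\ln y$ and $\ln(1-y)$ are always finite; constant features map to
  0.5 everywhere.
* Missing entries: features with > 20% missing are dropped, the rest
  are median-imputed — rank-neutral under the CDF transform.
* The KS statistic and its asymptotic p are computed directly (signed
  sup over the pooled points; one-sided p $= e^{-2 n_e D^2}$), so the
  one-sided statistic the battery needs is exactly the documented one;
  identical samples give D = 0, p = 1 exactly.
* Non-converged or separated Cox fits are recorded as missing and
  excluded from the module's coefficient set; a cohort with fewer than
  10 events refuses to run.
* The per-gene optimizer accepts a candidate only on a strict BIC
  improvement ($> 10^{-9}$), so tied models resolve to the smaller one.
* Zero-variance columns are dropped from PLS blocks with a warning;
  NIPALS failure to converge is a hard error, never a silent result.

## Problem sizes in the test suite

The acceptance-style tests run the generator at its default study
conditions (n = 60, 2000 genes) for discovery, and at 100–150 patients
per validation cohort. Monte-Carlo depths not fixed by the analysis
itself are run at the reduced sizes the FDR machinery documents
(`n_adjust` 200, 20–50 permutations, 50 runs of 40 null modules);
calibration checks give every random module its own adjustment sets so
rejection indicators are independent. These sizes are the package's
choice of a demonstration scale; the defaults users get
(`n_adjust = 1000`, `n_perm = 100`, `n_runs = 200`) match the analysis
as described above.

## Known limitations

* Sequence-mutation effectors and effector interaction terms are not
  modelled.
* Screening thresholds are a single global default (configurable per
  type); no attempt is made to tune them per aberration type.
* The trinary feature family is the simplest signed choice; richer
  feature functions (e.g. state-indicator features) would require a
  different identifiability argument for the non-negativity constraint.
* Multivariate Cox models with clinical covariates, hazard
  proportionality diagnostics, and sparse/regularized PLS are out of
  scope.
* Analytic (Benjamini–Hochberg) FDR is used only in enrichment; module
  discovery relies on permutation FDR by design.

## A minimal run

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 1)
sim <- simulate_training_cohort(spec)
b <- sim$bundle
expr <- tumor_normal_ratio(b$matrices$expression_tumor,
                           b$matrices$expression_normal)
cnv <- tumor_normal_ratio(b$matrices$cnv_tumor, b$matrices$cnv_normal)
fit <- discover_modules(expr, cnv, b$annotation,
                        cnv_annotation = sim$probe_annotation)
fit
score_recovery(fit, sim$truth)

cohorts <- simulate_validation_cohorts(spec, sim$truth)
validate_modules(fit, cohorts, n_adjust = 200, seed = 1)
```

The same flow, file-based and stage-by-stage, is available through
`run_pipeline()` and the wrapper script in `inst/scripts/`.
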