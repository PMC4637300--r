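# assocmod

Multi-omic **association modules**: linking effector DNA aberrations to
target gene expression and prognosis.

## The problem

Tumor genomes carry aberrations — chromosome-arm copy-number changes,
promoter methylation — that dysregulate the expression of downstream
genes, and some of those expression programs carry prognostic
information that is specific to patient subpopulations (gender,
ethnicity). `assocmod` is for analysts who have matched tumor/normal
expression, CNV and methylation data for a training cohort plus
expression + survival data for independent validation cohorts, and want
to (i) find which aberrations drive which genes, (ii) test whether
those gene sets replicate and predict survival elsewhere, and (iii)
quantify how often such findings arise by chance.

## The method in brief

Every feature is rank-normalized to CDF values y = midrank/(n+1) and
mapped to soft trinary states x ∈ {down, none, up} via

    P(x=1|y) = y / (1 − ln y),   P(x=−1|y) = (1−y) / (1 − ln(1−y)),

then each gene's expression state is modelled by a non-negative
logistic model

    P(y|x) = exp(Σ_i λ_i f_i(x, y)) / Z(x),   λ_i ≥ 0,
    f_i(x, y) = d_i · E[x_i] · y,

with candidates screened at |r| ≥ 0.5 and added greedily in mechanistic
layer order (cis CNV → trans CNV → methylation) under a strict BIC
improvement rule. Genes sharing an effector form an association module.
Modules are validated per cohort by (1) expression coherence and
(2) Cox-coefficient shift — both one-sided, size-adjusted KS tests
against random-gene backgrounds — and (3) the log-rank test on
Kaplan–Meier curves split by the module's median-expression aggregate
biomarker. Permutation FDRs are computed at the pairwise and module
levels, and inter-module dependency is measured by two-block NIPALS
PLS (correlation circles, cumulative R²). A seeded synthetic cohort
generator with planted modules and subpopulation-specific survival
effects exercises the whole pipeline end-to-end. Details and
justifications: `vignette("association-modules")`.

## Worked example

```r
library(assocmod)

spec <- simulation_spec(seed = 2)        # default synthetic study conditions
sim  <- simulate_training_cohort(spec)   # 60 tumor/normal pairs, 2000 genes
b    <- sim$bundle

expr <- tumor_normal_ratio(b$matrices$expression_tumor, b$matrices$expression_normal)
cnv  <- tumor_normal_ratio(b$matrices$cnv_tumor,        b$matrices$cnv_normal)

fit <- discover_modules(expr, cnv, b$annotation,
                        cnv_annotation = sim$probe_annotation)
fit
#> Association module fit: 1 modules (1 cis CNV, 0 trans CNV, 0 methylation)
#>   40 genes with non-null models; 60 samples; |r| threshold 0.5; min size 5

score_recovery(fit, sim$truth)
#>   planted type effector   matched precision recall jaccard
#> 1       1  cis    chr7p cis_chr7p         1  0.925   0.925

cohorts <- simulate_validation_cohorts(spec, sim$truth)
validate_modules(fit, cohorts, n_adjust = 200, seed = 2)
#> Module validation over cohorts: EastAsian-female, EastAsian-male, Caucasian-female, Caucasian-male
#>   0 of 1 modules pass all tests in all required cohorts (...)
#>  module_id           cohort coherence_adjusted_p cox_adjusted_p    logrank_p all_pass
#>  cis_chr7p EastAsian-female          0.004975124    0.004975124 5.115699e-11     TRUE
#>  cis_chr7p   EastAsian-male          0.004975124    0.228855721 6.709942e-01    FALSE
#>  cis_chr7p Caucasian-female          0.004975124    0.736318408 9.296011e-01    FALSE
#>  cis_chr7p   Caucasian-male          0.004975124    0.900497512 3.624705e-01    FALSE
```

Reading the output: the planted chr7p cis module is recovered at
precision 1.00 / recall 0.925; its targets are *coherent* in every
cohort (adjusted p ≈ 0.005, the add-one floor at 200 adjustment sets),
but the prognostic tests pass only in the East Asian female cohort —
exactly the subpopulation where the generator planted the survival
effect (log-rank p ≈ 5×10⁻¹¹ there, non-significant elsewhere). A
module "passes overall" only if all three tests pass in every required
cohort, so restrict `required_cohorts` to the relevant subpopulation
when that is the hypothesis.

The file-based pipeline (simulate → discover → validate → fdr → pls →
enrich, with per-stage manifests) is driven by one config:

```r
run_pipeline("all", default_pipeline_config(seed = 1), outdir = "results_demo")
```

or from a shell via `inst/scripts/run_pipeline.R`.

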