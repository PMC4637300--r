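#' Specify a synthetic multi-omic study
#'
#' Defines the study conditions for the synthetic cohort generator: a
#' genome layout of chromosome arms, a training cohort with tumor/normal
#' expression, probe-level CNV and methylation layers, planted
#' association modules, and validation cohorts whose survival hazard
#' depends on a planted module's aggregate expression only in designated
#' subpopulations.
#'
#' Defaults emulate the training conditions of a small single-site
#' multi-omic cohort: 60 tumor/normal pairs, 2000 genes on 10 chromosomes
#' (p and q arms, 100 genes each), arm CNV dispersion 1.0, probe noise
#' 0.3, expression noise 1.0, and one planted 40-target cis module on
#' chr7p whose effect size is chosen so the target-arm correlation is
#' about 0.7 -- inside the screening regime of the discovery threshold.
#' Validation cohorts default to four gender-by-ethnicity subpopulations
#' of 100 patients with the survival effect (log-hazard multiplier
#' gamma = 1.2 on the module median expression) planted only in the
#' East Asian female cohort; exponential baseline hazard 0.1, target
#' censoring fraction 0.3.
#'
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @param n_samples training cohort size (tumor/normal pairs).
#' @param n_chromosomes number of chromosomes (two arms each).
#' @param genes_per_arm genes annotated per arm.
#' @param probes_per_arm CNV probes per arm.
#' @param sigma_arm SD of the per-sample arm CNV log-ratio.
#' @param probe_noise SD of CNV probe noise around the arm value.
#' @param expr_noise SD of expression log-ratio noise.
#' @param planted list of planted modules; each a list with `type`
#'   (`"cis"`, `"trans"`, `"methylation"`), `arm` (effector arm for cis /
#'   trans) or `effector_genes` (methylation), `n_targets`, and
#'   `target_r` (intended effector-target correlation).
#' @param cohorts data.frame of validation cohorts: `name`, `n`,
#'   `gender`, `ethnicity`, `gamma` (per-cohort log-hazard multiplier on
#'   the planted module's median expression; 0 = no effect).
#' @param survival_module index into `planted` of the module driving the
#'   hazard (default 1).
#' @param baseline_hazard exponential baseline hazard rate.
#' @param censoring target censoring fraction in [0,1).
#' @param hazard_family `"exponential"` (default) or `"weibull"`.
#' @param weibull_shape shape when `hazard_family = "weibull"`.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1, n_samples = 60, n_chromosomes = 10,
                            genes_per_arm = 100, probes_per_arm = 20,
                            sigma_arm = 1.0, probe_noise = 0.3,
                            expr_noise = 1.0,
                            planted = list(list(type = "cis", arm = "chr7p",
                                                n_targets = 40, target_r = 0.7)),
                            cohorts = data.frame(
                              name = c("EastAsian-female", "EastAsian-male",
                                       "Caucasian-female", "Caucasian-male"),
                              n = 100,
                              gender = c("female", "male", "female", "male"),
                              ethnicity = c("EastAsian", "EastAsian",
                                            "Caucasian", "Caucasian"),
                              gamma = c(1.2, 0, 0, 0)),
                            survival_module = 1,
                            baseline_hazard = 0.1, censoring = 0.3,
                            hazard_family = c("exponential", "weibull"),
                            weibull_shape = 1.5) {
  hazard_family <- match.arg(hazard_family)
  stopifnot(n_samples > 0, n_chromosomes > 0, genes_per_arm > 0,
            probes_per_arm > 0, censoring >= 0, censoring < 1)
  arms <- as.vector(t(outer(seq_len(n_chromosomes), c("p", "q"), paste0)))
  arms <- paste0("chr", arms)
  for (p in planted) {
    stopifnot(p$type %in% c("cis", "trans", "methylation"))
    if (p$type %in% c("cis", "trans") && !(p$arm %in% arms)) {
      stopf("planted module arm '%s' not in layout", p$arm)
    }
    stopifnot(p$n_targets > 0, p$target_r >= 0, p$target_r < 1)
  }
  if (survival_module > length(planted)) {
    stopf("survival effect configured for unplanted module %d", survival_module)
  }
  structure(list(seed = seed, n_samples = n_samples,
                 n_chromosomes = n_chromosomes, genes_per_arm = genes_per_arm,
                 probes_per_arm = probes_per_arm, sigma_arm = sigma_arm,
                 probe_noise = probe_noise, expr_noise = expr_noise,
                 planted = planted, cohorts = cohorts,
                 survival_module = survival_module,
                 baseline_hazard = baseline_hazard, censoring = censoring,
                 hazard_family = hazard_family, weibull_shape = weibull_shape,
                 arms = arms),
            class = "simulation_spec")
}

spec_annotation <- function(spec) {
  n_arms <- length(spec$arms)
  n_genes <- n_arms * spec$genes_per_arm
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  arm_idx <- rep(seq_len(n_arms), each = spec$genes_per_arm)
  chrom <- rep(rep(seq_len(spec$n_chromosomes), each = 2), each = spec$genes_per_arm)
  arm <- rep(rep(c("p", "q"), spec$n_chromosomes), each = spec$genes_per_arm)
  data.frame(gene_id = gene_ids, chromosome = chrom, arm = arm,
             position = (seq_len(n_genes) - 1L) %% spec$genes_per_arm * 100000L)
}

spec_probe_annotation <- function(spec) {
  n_arms <- length(spec$arms)
  n_probes <- n_arms * spec$probes_per_arm
  data.frame(gene_id = sprintf("cnvp%04d", seq_len(n_probes)),
             chromosome = rep(rep(seq_len(spec$n_chromosomes), each = 2),
                              each = spec$probes_per_arm),
             arm = rep(rep(c("p", "q"), spec$n_chromosomes),
                       each = spec$probes_per_arm),
             position = (seq_len(n_probes) - 1L) %% spec$probes_per_arm * 1000000L)
}

# Effect size beta on a unit-variance driver that yields correlation r
# against noise of SD sigma_e: r = beta*sd_d / sqrt(beta^2 sd_d^2 + sigma_e^2).
beta_for_r <- function(r, sigma_e, sd_driver = 1) {
  r * sigma_e / (sd_driver * sqrt(1 - r^2))
}

# Reserve target gene ids for the planted modules: cis targets on the
# effector arm, trans/methylation targets on arms other than any effector
# arm, disjoint across modules.
plan_targets <- function(spec, annotation) {
  arm_genes <- split(annotation$gene_id, paste0("chr", annotation$chromosome,
                                                annotation$arm))
  used <- character()
  truth <- list()
  for (i in seq_along(spec$planted)) {
    p <- spec$planted[[i]]
    if (p$type == "cis") {
      pool <- setdiff(arm_genes[[p$arm]], used)
      if (length(pool) < p$n_targets) {
        stopf("arm %s has %d free genes; %d targets requested", p$arm,
              length(pool), p$n_targets)
      }
      targets <- pool[seq_len(p$n_targets)]
      regulators <- character()
      effector <- p$arm
    } else {
      avoid <- if (p$type == "trans") p$arm else character()
      pool <- setdiff(annotation$gene_id[!(paste0("chr", annotation$chromosome,
                                                  annotation$arm) %in% avoid)],
                      used)
      if (p$type == "trans") {
        reg_pool <- setdiff(arm_genes[[p$arm]], used)
        n_reg <- p$n_regulators %||% 3
        if (length(reg_pool) < n_reg) stopf("arm %s cannot host %d regulators",
                                            p$arm, n_reg)
        regulators <- reg_pool[seq_len(n_reg)]
        used <- c(used, regulators)
        pool <- setdiff(pool, regulators)
        effector <- p$arm
      } else {
        n_eff <- length(p$effector_genes %||% c("meffA", "meffB"))
        regulators <- character()
        effector <- p$effector_genes %||% paste0("meff", seq_len(n_eff))
      }
      if (length(pool) < p$n_targets) stopf("not enough free genes for module %d", i)
      targets <- pool[seq_len(p$n_targets)]
    }
    used <- c(used, targets)
    truth[[i]] <- list(index = i, type = p$type, effector = effector,
                       regulators = regulators, targets = targets,
                       target_r = p$target_r)
  }
  truth
}

#' Simulate the multi-omic training cohort
#'
#' Generates paired tumor and adjacent-normal matrices for expression,
#' probe-level CNV and methylation.  Per sample, each arm carries a CNV
#' log-ratio ~ Normal(0, sigma_arm) shared by all probes on the arm plus
#' probe noise.  Planted cis targets' expression log-ratios follow
#' beta * armCNV + noise; trans targets follow the (cis-driven) regulator
#' expression; methylation targets follow minus the effector's
#' tumor-normal beta difference.  All other genes are independent noise.
#' Deterministic given the spec (seed included).
#'
#' @param spec a [simulation_spec()].
#' @return list with `bundle` (a [cohort_bundle()] of tumor/normal
#'   matrices and annotation), `probe_annotation`, and `truth` (the
#'   planted ground truth: per module effector, targets, per-cohort
#'   gamma).
#' @export
simulate_training_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    ann <- spec_annotation(spec)
    pann <- spec_probe_annotation(spec)
    samples <- sprintf("S%03d", seq_len(spec$n_samples))
    n <- spec$n_samples
    n_genes <- nrow(ann)
    truth <- plan_targets(spec, ann)

    # per-sample arm CNV log-ratios
    arm_lr <- matrix(stats::rnorm(length(spec$arms) * n, 0, spec$sigma_arm),
                     length(spec$arms), n, dimnames = list(spec$arms, samples))

    # CNV probes: tumor = normal * exp(arm + probe noise)
    normal_cnv <- matrix(exp(stats::rnorm(nrow(pann) * n, 0, 0.05)),
                         nrow(pann), n, dimnames = list(pann$gene_id, samples))
    probe_arm <- paste0("chr", pann$chromosome, pann$arm)
    probe_sig <- arm_lr[probe_arm, , drop = FALSE] +
      matrix(stats::rnorm(nrow(pann) * n, 0, spec$probe_noise), nrow(pann), n)
    tumor_cnv <- normal_cnv * exp(probe_sig)
    dimnames(tumor_cnv) <- dimnames(normal_cnv)

    # expression log-ratios: noise baseline, then planted signals
    expr_lr <- matrix(stats::rnorm(n_genes * n, 0, spec$expr_noise),
                      n_genes, n, dimnames = list(ann$gene_id, samples))

    # methylation: baseline betas; effectors get a variable tumor-normal delta
    meth_genes <- unique(unlist(lapply(truth, function(tr) {
      if (tr$type == "methylation") tr$effector else character()
    })))
    meth_normal <- meth_tumor <- NULL
    if (length(meth_genes)) {
      base <- matrix(stats::runif(length(meth_genes) * n, 0.35, 0.65),
                     length(meth_genes), n,
                     dimnames = list(meth_genes, samples))
      delta <- matrix(stats::rnorm(length(meth_genes) * n, 0, 0.2),
                      length(meth_genes), n)
      meth_normal <- base
      meth_tumor <- base + delta
      meth_tumor[meth_tumor < 0] <- 0
      meth_tumor[meth_tumor > 1] <- 1
    }

    for (tr in truth) {
      p <- spec$planted[[tr$index]]
      if (tr$type == "cis") {
        beta <- beta_for_r(p$target_r, spec$expr_noise, spec$sigma_arm)
        sig <- matrix(rep(arm_lr[tr$effector, ], each = length(tr$targets)),
                      length(tr$targets), n)
        expr_lr[tr$targets, ] <- beta * sig +
          matrix(stats::rnorm(length(tr$targets) * n, 0, spec$expr_noise),
                 length(tr$targets), n)
      } else if (tr$type == "trans") {
        reg_r <- p$regulator_r %||% 0.9
        beta_reg <- beta_for_r(reg_r, spec$expr_noise, spec$sigma_arm)
        reg_expr <- beta_reg * matrix(rep(arm_lr[tr$effector, ],
                                          each = length(tr$regulators)),
                                      length(tr$regulators), n) +
          matrix(stats::rnorm(length(tr$regulators) * n, 0, spec$expr_noise),
                 length(tr$regulators), n)
        expr_lr[tr$regulators, ] <- reg_expr
        driver <- reg_expr[1, ]
        beta_t <- beta_for_r(p$target_r, spec$expr_noise, stats::sd(driver))
        sgn <- p$sign %||% 1
        expr_lr[tr$targets, ] <- sgn * beta_t *
          matrix(rep(driver, each = length(tr$targets)), length(tr$targets), n) +
          matrix(stats::rnorm(length(tr$targets) * n, 0, spec$expr_noise),
                 length(tr$targets), n)
      } else {
        delta <- meth_tumor[tr$effector[1], ] - meth_normal[tr$effector[1], ]
        beta_m <- beta_for_r(p$target_r, spec$expr_noise, stats::sd(delta))
        expr_lr[tr$targets, ] <- -beta_m *
          matrix(rep(delta, each = length(tr$targets)), length(tr$targets), n) +
          matrix(stats::rnorm(length(tr$targets) * n, 0, spec$expr_noise),
                 length(tr$targets), n)
      }
    }

    normal_expr <- matrix(exp(stats::rnorm(n_genes * n, 5, 0.2)), n_genes, n,
                          dimnames = list(ann$gene_id, samples))
    tumor_expr <- normal_expr * exp(expr_lr)
    dimnames(tumor_expr) <- dimnames(normal_expr)

    mats <- list(
      expression_tumor = omics_matrix(tumor_expr, "expression"),
      expression_normal = omics_matrix(normal_expr, "expression"),
      cnv_tumor = omics_matrix(tumor_cnv, "cnv_probe"),
      cnv_normal = omics_matrix(normal_cnv, "cnv_probe"))
    if (length(meth_genes)) {
      mats$methylation_tumor <- omics_matrix(meth_tumor, "methylation")
      mats$methylation_normal <- omics_matrix(meth_normal, "methylation")
    }
    bundle <- cohort_bundle("training", mats, ann)
    truth_out <- lapply(truth, function(tr) {
      tr$gamma <- stats::setNames(
        if (tr$index == spec$survival_module) spec$cohorts$gamma
        else rep(0, nrow(spec$cohorts)),
        spec$cohorts$name)
      tr
    })
    list(bundle = bundle, probe_annotation = pann, truth = truth_out)
  })
}

# Calibrate an exponential censoring rate so the expected censored
# fraction over the cohort's heterogeneous event rates matches `target`.
calibrate_censor_rate <- function(rates, target) {
  if (target <= 0) return(0)
  f <- function(rc) mean(rc / (rc + rates)) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e6, tol = 1e-10)$root
}

#' Simulate validation cohorts with subpopulation-specific survival
#'
#' Each validation cohort carries an expression matrix (planted module
#' targets share their latent driver; all other genes are independent
#' noise) and a right-censored clinical table.  Survival times are
#' exponential (or Weibull) with hazard
#' `baseline_hazard * exp(gamma_cohort * biomarker)`, where the biomarker
#' is the per-patient median expression over the survival module's
#' targets; `gamma` is zero in the designated no-effect subpopulations.
#' Censoring is independent and calibrated to the target fraction.
#'
#' @param spec a [simulation_spec()].
#' @param truth optional planted truth from [simulate_training_cohort()]
#'   (regenerated from the spec when missing).
#' @return named list of [cohort_bundle()]s with clinical tables.
#' @export
simulate_validation_cohorts <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  ann <- spec_annotation(spec)
  if (is.null(truth)) {
    truth <- simulate_training_cohort(spec)$truth
  }
  sm <- truth[[spec$survival_module]]
  out <- list()
  for (ci in seq_len(nrow(spec$cohorts))) {
    info <- spec$cohorts[ci, ]
    out[[info$name]] <- with_seed(spec$seed * 1000 + ci, {
      n <- info$n
      samples <- sprintf("%s_S%03d", gsub("[^A-Za-z]", "", info$name), seq_len(n))
      expr <- matrix(stats::rnorm(nrow(ann) * n, 0, spec$expr_noise),
                     nrow(ann), n, dimnames = list(ann$gene_id, samples))
      for (tr in truth) {
        z <- stats::rnorm(n)
        beta <- beta_for_r(tr$target_r, spec$expr_noise, 1)
        expr[tr$targets, ] <- beta *
          matrix(rep(z, each = length(tr$targets)), length(tr$targets), n) +
          matrix(stats::rnorm(length(tr$targets) * n, 0, spec$expr_noise),
                 length(tr$targets), n)
      }
      biomarker <- apply(expr[sm$targets, , drop = FALSE], 2, stats::median)
      biomarker <- as.vector(scale(biomarker))
      rates <- spec$baseline_hazard * exp(info$gamma * biomarker)
      times <- if (spec$hazard_family == "exponential") {
        stats::rexp(n, rate = rates)
      } else {
        # Weibull with shape k: S(t) = exp(-(rate) t^k)
        (stats::rexp(n, rate = rates))^(1 / spec$weibull_shape)
      }
      rc <- calibrate_censor_rate(rates, spec$censoring)
      cens <- if (rc > 0) stats::rexp(n, rate = rc) else rep(Inf, n)
      obs_time <- pmin(times, cens)
      event <- as.integer(times <= cens)
      clin <- data.frame(sample_id = samples, time = obs_time, event = event,
                         gender = info$gender, cohort = info$name)
      suppressWarnings(cohort_bundle(
        info$name,
        list(expression = omics_matrix(expr, "expression")),
        ann, clin))
    })
  }
  out
}

#' Score recovery of planted modules
#'
#' Matches each planted module to the inferred module with maximal target
#' Jaccard index and reports precision and recall of the matched target
#' sets.
#'
#' @param inferred list of `association_module`s (or an `assoc_modules`
#'   fit).
#' @param truth planted truth list from [simulate_training_cohort()].
#' @return data.frame: planted module index, type, effector, best
#'   matching inferred module id, precision, recall, jaccard.
#' @export
score_recovery <- function(inferred, truth) {
  if (inherits(inferred, "assoc_modules")) inferred <- inferred$modules
  rows <- lapply(truth, function(tr) {
    best <- list(id = NA_character_, precision = 0, recall = 0, jaccard = 0)
    for (m in inferred) {
      inter <- length(intersect(m$targets, tr$targets))
      un <- length(union(m$targets, tr$targets))
      j <- if (un > 0) inter / un else 0
      if (j > best$jaccard) {
        best <- list(id = m$module_id,
                     precision = inter / length(m$targets),
                     recall = inter / length(tr$targets), jaccard = j)
      }
    }
    data.frame(planted = tr$index, type = tr$type,
               effector = paste(tr$effector, collapse = ","),
               matched = best$id, precision = best$precision,
               recall = best$recall, jaccard = best$jaccard)
  })
  do.call(rbind, rows)
}
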