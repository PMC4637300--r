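# Permutation false-discovery rates at the pairwise-association and
# module-validation levels.

count_pairwise <- function(expr_cdf, arm_cdf, meth, arm_of, thr) {
  R <- suppressWarnings(stats::cor(t(expr_cdf), t(arm_cdf)))
  R[is.na(R)] <- 0
  genes <- rownames(expr_cdf)
  own <- arm_of[genes]
  own_idx <- match(own, colnames(R))
  cis_r <- R[cbind(seq_along(genes), own_idx)]
  cis_n <- sum(cis_r >= thr[["cis"]], na.rm = TRUE)
  trans_hits <- abs(R) >= thr[["trans"]]
  if (any(!is.na(own_idx))) {
    ok <- which(!is.na(own_idx))
    trans_hits[cbind(ok, own_idx[ok])] <- FALSE
  }
  trans_n <- sum(trans_hits)
  meth_n <- 0L
  if (!is.null(meth) && nrow(meth) > 0) {
    Rm <- suppressWarnings(stats::cor(t(expr_cdf), t(meth)))
    Rm[is.na(Rm)] <- 0
    meth_n <- sum(Rm <= -thr[["meth"]])
  }
  c(cis_cnv = cis_n, trans_cnv = trans_n, methylation = meth_n)
}

#' Permutation FDR of pairwise effector-gene associations
#'
#' For each molecular aberration type, the observed number of significant
#' pairwise associations at the screening thresholds is compared with the
#' expected count under a permutation null in which the effector
#' matrices' sample labels are shuffled relative to expression (breaking
#' all cross-omics links while preserving within-matrix structure).
#' FDR = mean null count / observed count.
#'
#' @param expression genes x samples tumor/normal expression ratio matrix.
#' @param cnv probes x samples CNV ratio matrix.
#' @param annotation,cnv_annotation annotation tables as in
#'   [discover_modules()].
#' @param methylation optional methylation difference matrix.
#' @param r_threshold screening threshold(s) fixed to the discovery
#'   configuration.
#' @param n_perm number of permutations (default 100; must be >= 1).
#' @param min_meth_sd methylation effector variability cutoff.
#' @param seed RNG seed.
#' @return data.frame of class `fdr_report`: one row per aberration type
#'   with observed_positives, expected_null_positives and fdr (`NA` when
#'   no positives are observed).
#' @export
pairwise_fdr <- function(expression, cnv, annotation, cnv_annotation = annotation,
                         methylation = NULL, r_threshold = 0.5, n_perm = 100,
                         min_meth_sd = 0.1, seed = 1) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  thr <- screen_thresholds(r_threshold)
  ann <- validate_annotation(annotation)
  expression <- unclass(expression)
  samples <- Reduce(intersect, c(list(colnames(expression), colnames(cnv)),
                                 if (!is.null(methylation)) list(colnames(methylation))))
  expression <- expression[rownames(expression) %in% ann$gene_id, samples, drop = FALSE]
  expr_cdf <- ecdf_normalize(expression)
  arm_cdf <- ecdf_normalize(arm_cnv_matrix(unclass(cnv)[, samples, drop = FALSE],
                                           cnv_annotation))
  meth <- NULL
  if (!is.null(methylation)) {
    meth <- select_methylation_effectors(unclass(methylation)[, samples, drop = FALSE],
                                         min_sd = min_meth_sd)
    if (nrow(meth) == 0) meth <- NULL
  }
  arm_of <- stats::setNames(ann$arm_id, ann$gene_id)
  observed <- count_pairwise(expr_cdf, arm_cdf, meth, arm_of, thr)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm_arm <- arm_cdf[, sample.int(ncol(arm_cdf)), drop = FALSE]
      colnames(perm_arm) <- colnames(arm_cdf)
      perm_meth <- NULL
      if (!is.null(meth)) {
        perm_meth <- meth[, sample.int(ncol(meth)), drop = FALSE]
        colnames(perm_meth) <- colnames(meth)
      }
      count_pairwise(expr_cdf, perm_arm, perm_meth, arm_of, thr)
    }, c(cis_cnv = 0, trans_cnv = 0, methylation = 0))
  })
  expected <- rowMeans(nulls)
  out <- data.frame(level = "pairwise", type = names(observed),
                    observed_positives = as.integer(observed),
                    expected_null_positives = as.numeric(expected),
                    fdr = ifelse(observed > 0, expected / observed, NA_real_),
                    row.names = NULL)
  class(out) <- c("fdr_report", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Module-level validation FDR by random module assignment
#'
#' Genes are randomly assigned to modules matching the observed module
#' size multiset; the full validation battery (coherence, Cox-shift,
#' log-rank) is applied to every random module in every cohort, over
#' `n_runs` runs.  Reports the expected number of random modules passing
#' each individual test and the all-tests conjunction; when the number of
#' real passing modules is supplied, the overall FDR is expected null
#' conjunction passes / real passes.
#'
#' Size-matched null raw-p distributions are memoised per (cohort, size):
#' random size-matched sets are exchangeable across modules of equal
#' size, so the cache is statistically neutral.  `n_adjust` defaults to a
#' reduced 200 for tractability.
#'
#' @param module_sizes integer vector of real module sizes.
#' @param cohorts list of [cohort_bundle()]s with clinical tables.
#' @param n_runs number of random-assignment runs (default 200).
#' @param n_adjust size-matched replicates inside each validation test.
#' @param n_background,pair_cap see [coherence_test()].
#' @param alpha_coherence,alpha_cox,alpha_logrank pass thresholds.
#' @param split Kaplan-Meier split rule.
#' @param observed_passing number of real modules passing all tests
#'   (optional; enables the overall fdr column).
#' @param seed RNG seed.
#' @return `fdr_report` data.frame with one row per test and one for the
#'   conjunction.
#' @export
module_level_fdr <- function(module_sizes, cohorts, n_runs = 200,
                             n_adjust = 200, n_background = 1000,
                             pair_cap = 50000, alpha_coherence = 0.05,
                             alpha_cox = 0.05, alpha_logrank = 0.1,
                             split = "global_mean", observed_passing = NA,
                             seed = 1) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  stopifnot(all(module_sizes >= 2))
  ctxs <- list()
  for (ch in cohorts) {
    if (is.null(ch$clinical)) stopf("cohort '%s' lacks survival data", ch$name)
    expr_cdf <- ecdf_normalize(ch$matrices$expression)
    ctxs[[ch$name]] <- cohort_validation_context(expr_cdf, ch$clinical,
                                                 n_background, pair_cap, seed)
  }
  n_tests <- 4L  # coherence, cox, logrank, conjunction
  pass_counts <- matrix(0, n_runs, n_tests,
                        dimnames = list(NULL, c("coherence", "cox", "logrank", "all")))
  run_seeds <- with_seed(seed, sample.int(2^30, n_runs))
  for (r in seq_len(n_runs)) {
    assignments <- with_seed(run_seeds[r], {
      lapply(module_sizes, function(sz) sample(ctxs[[1]]$genes, sz))
    })
    for (genes in assignments) {
      coh_pass <- cox_pass <- lr_pass <- TRUE
      for (nm in names(ctxs)) {
        ctx <- ctxs[[nm]]
        coh <- coherence_test(genes, ctx$expr_cdf, n_background, n_adjust,
                              pair_cap, seed, alpha_coherence, ctx = ctx)
        cox <- cox_shift_test(genes, ctx$cox_all, n_adjust, seed, alpha_cox,
                              ctx = ctx)
        lr <- suppressWarnings(
          km_logrank_on_aggregate(genes, ctx$expr_cdf, ctx$clinical, split,
                                  alpha_logrank))
        coh_pass <- coh_pass && coh$pass
        cox_pass <- cox_pass && cox$pass
        lr_pass <- lr_pass && lr$pass
      }
      pass_counts[r, "coherence"] <- pass_counts[r, "coherence"] + coh_pass
      pass_counts[r, "cox"] <- pass_counts[r, "cox"] + cox_pass
      pass_counts[r, "logrank"] <- pass_counts[r, "logrank"] + lr_pass
      pass_counts[r, "all"] <- pass_counts[r, "all"] +
        (coh_pass && cox_pass && lr_pass)
    }
  }
  expected <- colMeans(pass_counts)
  n_mod <- length(module_sizes)
  out <- data.frame(
    level = "module", test = colnames(pass_counts),
    modules_per_run = n_mod, n_runs = n_runs,
    expected_null_positives = as.numeric(expected),
    null_pass_fraction = as.numeric(expected) / n_mod,
    fdr = c(rep(NA_real_, 3),
            if (is.na(observed_passing) || observed_passing == 0) NA_real_
            else expected[["all"]] / observed_passing),
    row.names = NULL)
  class(out) <- c("fdr_report", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_adjust") <- n_adjust
  out
}

#' Write an FDR report as TSV (seed recorded in a header line)
#' @param report `fdr_report` data.frame.
#' @param path output path.
#' @export
write_fdr_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", attr(report, "seed") %||% NA), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
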