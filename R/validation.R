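#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the KS statistic between the empirical CDFs of two samples and
#' its asymptotic p-value.  `side = "greater"` tests whether `a` is
#' stochastically greater than `b` (positive shift): the statistic is
#' the signed supremum D+ = sup_x (F_b(x) - F_a(x)) and the p-value is
#' exp(-2 ne D+^2) with ne = n_a n_b / (n_a + n_b).  The two-sided p uses
#' the alternating Kolmogorov series.
#'
#' @param a,b numeric samples (length >= 1; degenerate constant samples
#'   are handled, D stays well-defined).
#' @param side `"two_sided"` or `"greater"`.
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(a, b, side = c("two_sided", "greater")) {
  side <- match.arg(side)
  a <- sort(a[is.finite(a)]); b <- sort(b[is.finite(b)])
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stopf("ks_compare: empty sample")
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, a) / na
  Fb <- findInterval(pts, b) / nb
  ne <- na * nb / (na + nb)
  if (side == "greater") {
    D <- max(c(Fb - Fa, 0))
    p <- exp(-2 * ne * D^2)
  } else {
    D <- max(abs(Fa - Fb))
    if (D == 0) {
      p <- 1
    } else {
      k <- 1:100
      p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * ne * D^2))
      p <- min(max(p, 0), 1)
    }
  }
  list(D = D, p = p)
}

# Pairwise Pearson correlations among a set of gene rows of a CDF matrix,
# as a flat vector (upper triangle), optionally capped by random
# subsampling (seeded by the caller's RNG state).
pairwise_correlations <- function(expr, genes, cap = Inf) {
  cm <- suppressWarnings(stats::cor(t(expr[genes, , drop = FALSE])))
  v <- upper_tri_values(cm)
  v <- v[is.finite(v)]
  if (length(v) > cap) v <- v[sample.int(length(v), cap)]
  v
}

# One-sided (positive-shift) KS against a background that has been sorted
# once, with its own-ECDF values precomputed: identical statistic and p to
# ks_compare(a, b, "greater") but O(|a| log + |b| lookup) per call.
sorted_background <- function(b) {
  bs <- sort(b[is.finite(b)])
  list(values = bs, F = findInterval(bs, bs) / length(bs))
}

ks_greater_sorted <- function(a, bg) {
  a <- sort(a[is.finite(a)])
  na <- length(a); nb <- length(bg$values)
  Fa_at_a <- findInterval(a, a) / na
  Fb_at_a <- findInterval(a, bg$values) / nb
  Fa_at_b <- findInterval(bg$values, a) / na
  D <- max(c(Fb_at_a - Fa_at_a, bg$F - Fa_at_b, 0))
  ne <- na * nb / (na + nb)
  list(D = D, p = exp(-2 * ne * D^2))
}

# Shared per-cohort context for the validation battery: CDF expression,
# sorted background correlation sample, per-gene Cox coefficients, and a
# memo environment for size-matched null raw-p distributions.
cohort_validation_context <- function(expr_cdf, clinical = NULL,
                                      n_background = 1000, pair_cap = 50000,
                                      seed = 1) {
  genes <- rownames(expr_cdf)
  bg <- with_seed(seed, {
    pick <- sample(genes, min(n_background, length(genes)))
    pairwise_correlations(expr_cdf, pick, cap = pair_cap)
  })
  cox_all <- NULL
  cox_bg <- NULL
  if (!is.null(clinical)) {
    cox_all <- cox_per_gene(expr_cdf, clinical)
    cox_bg <- sorted_background(cox_all)
  }
  env <- new.env(parent = emptyenv())
  list(expr_cdf = expr_cdf, genes = genes, bg_corr = bg,
       bg_corr_sorted = sorted_background(bg), cox_all = cox_all,
       cox_bg = cox_bg, clinical = clinical, global_mean = mean(expr_cdf),
       pair_cap = pair_cap, seed = seed, memo = env)
}

coherence_raw_p <- function(ctx, genes, two_sided = FALSE) {
  v <- pairwise_correlations(ctx$expr_cdf, genes, cap = ctx$pair_cap)
  ks <- ks_greater_sorted(v, ctx$bg_corr_sorted)
  p2 <- if (two_sided) ks_compare(v, ctx$bg_corr, side = "two_sided")$p else NA_real_
  list(p = ks$p, D = ks$D, p_two_sided = p2, correlations = v)
}

null_coherence_p <- function(ctx, size, n_adjust, seed) {
  key <- sprintf("coh_%d_%d_%d", size, n_adjust, seed)
  if (!is.null(ctx$memo[[key]])) return(ctx$memo[[key]])
  ps <- with_seed(seed + size, vapply(seq_len(n_adjust), function(i) {
    coherence_raw_p(ctx, sample(ctx$genes, size))$p
  }, 0))
  ctx$memo[[key]] <- ps
  ps
}

null_cox_p <- function(ctx, size, n_adjust, seed) {
  key <- sprintf("cox_%d_%d_%d", size, n_adjust, seed)
  if (!is.null(ctx$memo[[key]])) return(ctx$memo[[key]])
  bg <- ctx$cox_all[is.finite(ctx$cox_all)]
  ps <- with_seed(seed + size + 1L, vapply(seq_len(n_adjust), function(i) {
    ks_greater_sorted(sample(bg, size), ctx$cox_bg)$p
  }, 0))
  ctx$memo[[key]] <- ps
  ps
}

# Add-one permutation convention: adjusted p can never be exactly zero.
adjusted_p <- function(raw_p, null_ps) {
  (1 + sum(null_ps <= raw_p)) / (length(null_ps) + 1)
}

#' Expression-coherence test of a module in one cohort
#'
#' The module statistic is the one-sided (positive-shift) KS p-value of
#' all pairwise target-gene correlations against a background of pairwise
#' correlations among `n_background` randomly selected genes (pair sample
#' capped at `pair_cap`).  The size-adjusted p-value ranks that raw p
#' among `n_adjust` random gene sets of the same size.
#'
#' @param module an `association_module` (or character vector of gene ids).
#' @param expr_cdf CDF-normalized expression matrix of the cohort.
#' @param n_background number of background genes (default 1000).
#' @param n_adjust number of size-matched random sets (default 1000).
#' @param pair_cap cap on sampled correlation pairs (default 50000).
#' @param seed RNG seed.
#' @param alpha significance level for the pass flag (default 0.05).
#' @param ctx optional precomputed context (internal reuse).
#' @return list: evaluable, n_targets, ks_D, raw_p, raw_p_two_sided,
#'   adjusted_p, pass.
#' @export
coherence_test <- function(module, expr_cdf, n_background = 1000,
                           n_adjust = 1000, pair_cap = 50000, seed = 1,
                           alpha = 0.05, ctx = NULL) {
  genes <- if (inherits(module, "association_module")) module$targets else module
  if (is.null(ctx)) {
    ctx <- cohort_validation_context(expr_cdf, NULL, n_background, pair_cap, seed)
  }
  genes <- intersect(genes, ctx$genes)
  if (length(genes) < 2) {
    return(list(evaluable = FALSE, n_targets = length(genes), ks_D = NA_real_,
                raw_p = NA_real_, raw_p_two_sided = NA_real_,
                adjusted_p = NA_real_, pass = FALSE))
  }
  raw <- with_seed(seed, coherence_raw_p(ctx, genes, two_sided = TRUE))
  nulls <- null_coherence_p(ctx, length(genes), n_adjust, seed)
  ap <- adjusted_p(raw$p, nulls)
  list(evaluable = TRUE, n_targets = length(genes), ks_D = raw$D,
       raw_p = raw$p, raw_p_two_sided = raw$p_two_sided,
       adjusted_p = ap, pass = ap < alpha)
}

#' Univariate Cox proportional-hazards coefficient per gene
#'
#' Fits, for every gene, the proportional-hazards model of the cohort's
#' survival on that single gene's expression (partial likelihood, Breslow
#' tie handling, Newton iterations to tolerance 1e-9).  Positive
#' coefficients mean high expression associates with shorter survival.
#'
#' @param expr genes x samples matrix (CDF-normalized expression).
#' @param clinical clinical table with sample_id, time, event covering the
#'   matrix columns; needs >= 10 events unless `min_events` is lowered.
#' @param min_events minimum number of observed events (default 10).
#' @return named numeric vector of coefficients; non-converged or
#'   degenerate genes are `NA`.
#' @export
cox_per_gene <- function(expr, clinical, min_events = 10) {
  clinical <- validate_clinical(clinical)
  expr <- unclass(expr)
  samples <- intersect(colnames(expr), clinical$sample_id)
  if (length(samples) == 0) stopf("no overlap between expression and clinical samples")
  clin <- clinical[match(samples, clinical$sample_id), ]
  if (sum(clin$event) == 0) stopf("cohort has zero observed events")
  if (sum(clin$event) < min_events) {
    stopf("cohort has %d events; >= %d required", sum(clin$event), min_events)
  }
  expr <- expr[, samples, drop = FALSE]
  y <- survival::Surv(clin$time, clin$event)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  out <- rep(NA_real_, nrow(expr))
  names(out) <- rownames(expr)
  strata <- rep(1L, length(samples))
  for (i in seq_len(nrow(expr))) {
    x <- matrix(expr[i, ], ncol = 1)
    if (stats::sd(x) == 0) next
    fit <- tryCatch(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = 0,
                          control = ctrl, weights = NULL, method = "breslow",
                          rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit)) next
    b <- fit$coefficients[1]
    if (is.finite(b) && abs(b) < 50) out[i] <- b
  }
  out
}

#' Cox-coefficient distribution shift test of a module
#'
#' One-sided (positive-shift) KS comparison of the module targets'
#' per-gene Cox coefficients against the background of all genes'
#' coefficients, with a size-matched adjusted p-value as in
#' [coherence_test()].  A positive shift means the module's targets carry
#' systematically worse prognosis than average.
#'
#' @param module `association_module` or gene id vector.
#' @param cox_all named coefficient vector over all genes
#'   (from [cox_per_gene()]).
#' @param n_adjust size-matched null replicates (default 1000).
#' @param seed RNG seed.
#' @param alpha pass threshold (default 0.05).
#' @param ctx optional shared context.
#' @return list: evaluable, n_coefficients, ks_D, raw_p, adjusted_p, pass.
#' @export
cox_shift_test <- function(module, cox_all, n_adjust = 1000, seed = 1,
                           alpha = 0.05, ctx = NULL) {
  genes <- if (inherits(module, "association_module")) module$targets else module
  if (is.null(ctx)) {
    env <- new.env(parent = emptyenv())
    ctx <- list(cox_all = cox_all, cox_bg = sorted_background(cox_all),
                memo = env)
  }
  beta <- ctx$cox_all[intersect(genes, names(ctx$cox_all))]
  beta <- beta[is.finite(beta)]
  if (length(beta) < 2) {
    return(list(evaluable = FALSE, n_coefficients = length(beta), ks_D = NA_real_,
                raw_p = NA_real_, adjusted_p = NA_real_, pass = FALSE))
  }
  ks <- ks_greater_sorted(beta, ctx$cox_bg)
  nulls <- null_cox_p(ctx, length(beta), n_adjust, seed)
  ap <- adjusted_p(ks$p, nulls)
  list(evaluable = TRUE, n_coefficients = length(beta), ks_D = ks$D,
       raw_p = ks$p, adjusted_p = ap, pass = ap < alpha)
}

#' Aggregate-biomarker Kaplan-Meier log-rank test
#'
#' The per-patient aggregate biomarker is the median expression over the
#' module's targets.  Patients whose aggregate exceeds the global mean of
#' the expression matrix form the high group (`split = "global_mean"`,
#' the default; `split = "module_mean"` splits at the mean of the
#' aggregate itself).  Prognostic power is the two-group log-rank
#' chi-square (1 df) p-value; significance threshold p < 0.1.
#'
#' @param module `association_module` or gene id vector.
#' @param expr_cdf CDF-normalized expression matrix.
#' @param clinical clinical table.
#' @param split `"global_mean"` or `"module_mean"`.
#' @param alpha pass threshold (default 0.1).
#' @return list: evaluable, n_high, n_low, chisq, p, pass.
#' @export
km_logrank_on_aggregate <- function(module, expr_cdf, clinical,
                                    split = c("global_mean", "module_mean"),
                                    alpha = 0.1) {
  split <- match.arg(split)
  genes <- if (inherits(module, "association_module")) module$targets else module
  clinical <- validate_clinical(clinical)
  expr <- unclass(expr_cdf)
  genes <- intersect(genes, rownames(expr))
  samples <- intersect(colnames(expr), clinical$sample_id)
  clin <- clinical[match(samples, clinical$sample_id), ]
  if (length(genes) < 1 || length(samples) < 2) {
    return(list(evaluable = FALSE, n_high = 0L, n_low = 0L,
                chisq = NA_real_, p = NA_real_, pass = FALSE))
  }
  agg <- apply(expr[genes, samples, drop = FALSE], 2, stats::median)
  thr <- if (split == "global_mean") mean(expr) else mean(agg)
  high <- agg > thr
  if (all(high) || all(!high)) {
    warnf("aggregate-biomarker split produced an empty group; not evaluable")
    return(list(evaluable = FALSE, n_high = sum(high), n_low = sum(!high),
                chisq = NA_real_, p = NA_real_, pass = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(clin$time, clin$event) ~ high)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(evaluable = TRUE, n_high = sum(high), n_low = sum(!high),
       chisq = unname(sd$chisq), p = p, pass = p < alpha)
}

#' Validate association modules across cohorts
#'
#' Runs the three validation tests -- expression coherence, Cox-shift and
#' aggregate-biomarker log-rank -- for every module in every cohort.  A
#' module's `overall_pass` requires all three tests to pass in every
#' cohort named in `required_cohorts`; any not-evaluable test fails
#' closed.
#'
#' @param fit `assoc_modules` object, list of `association_module`s, or a
#'   named list of character gene-id vectors.
#' @param cohorts list of [cohort_bundle()]s, each with an expression
#'   matrix and a clinical table.
#' @param required_cohorts cohort names required for overall_pass
#'   (default: all supplied cohorts).
#' @param n_background,n_adjust,pair_cap see [coherence_test()].
#' @param alpha_coherence,alpha_cox,alpha_logrank pass thresholds
#'   (defaults 0.05, 0.05, 0.1).
#' @param split Kaplan-Meier split rule, see [km_logrank_on_aggregate()].
#' @param seed RNG seed.
#' @return object of class `module_validation`: `table` (one row per
#'   module x cohort), `overall` (per-module pass flags), and `contexts`.
#' @export
validate_modules <- function(fit, cohorts, required_cohorts = NULL,
                             n_background = 1000, n_adjust = 1000,
                             pair_cap = 50000, alpha_coherence = 0.05,
                             alpha_cox = 0.05, alpha_logrank = 0.1,
                             split = "global_mean", seed = 1) {
  modules <- if (inherits(fit, "assoc_modules")) fit$modules else fit
  if (length(modules) == 0) {
    return(structure(list(table = data.frame(), overall = logical(0)),
                     class = "module_validation"))
  }
  module_genes <- lapply(modules, function(m) {
    if (inherits(m, "association_module")) m$targets else m
  })
  ids <- names(modules) %||% vapply(modules, function(m) m$module_id, "")
  names(module_genes) <- ids
  if (is.null(required_cohorts)) {
    required_cohorts <- vapply(cohorts, function(ch) ch$name, "")
  }
  rows <- list()
  ctxs <- list()
  for (ch in cohorts) {
    expr <- ch$matrices$expression
    if (is.null(expr)) stopf("cohort '%s' has no expression matrix", ch$name)
    if (is.null(ch$clinical)) stopf("cohort '%s' has no clinical table", ch$name)
    expr_cdf <- ecdf_normalize(expr)
    ctx <- cohort_validation_context(expr_cdf, ch$clinical, n_background,
                                     pair_cap, seed)
    ctxs[[ch$name]] <- ctx
    for (id in ids) {
      genes <- module_genes[[id]]
      coh <- coherence_test(genes, expr_cdf, n_background, n_adjust, pair_cap,
                            seed, alpha_coherence, ctx = ctx)
      cox <- cox_shift_test(genes, ctx$cox_all, n_adjust, seed, alpha_cox,
                            ctx = ctx)
      lr <- suppressWarnings(
        km_logrank_on_aggregate(genes, expr_cdf, ch$clinical, split, alpha_logrank))
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = id, cohort = ch$name,
        coherence_D = coh$ks_D, coherence_raw_p = coh$raw_p,
        coherence_adjusted_p = coh$adjusted_p, coherence_pass = coh$pass,
        cox_D = cox$ks_D, cox_raw_p = cox$raw_p,
        cox_adjusted_p = cox$adjusted_p, cox_pass = cox$pass,
        logrank_chisq = lr$chisq, logrank_p = lr$p, logrank_pass = lr$pass,
        n_high = lr$n_high, n_low = lr$n_low,
        all_pass = coh$pass && cox$pass && lr$pass)
    }
  }
  tab <- do.call(rbind, rows)
  overall <- vapply(ids, function(id) {
    sub <- tab[tab$module_id == id & tab$cohort %in% required_cohorts, ]
    nrow(sub) > 0 && all(sub$all_pass)
  }, logical(1))
  structure(list(table = tab, overall = overall,
                 required_cohorts = required_cohorts, contexts = ctxs),
            class = "module_validation")
}

#' @export
print.module_validation <- function(x, ...) {
  if (nrow(x$table) == 0) {
    cat("Module validation: no modules\n")
    return(invisible(x))
  }
  cat(sprintf("Module validation over cohorts: %s\n",
              paste(unique(x$table$cohort), collapse = ", ")))
  cat(sprintf("  %d of %d modules pass all tests in all required cohorts (%s)\n",
              sum(x$overall), length(x$overall),
              paste(x$required_cohorts, collapse = ", ")))
  show <- x$table[, c("module_id", "cohort", "coherence_adjusted_p",
                      "cox_adjusted_p", "logrank_p", "all_pass")]
  print(utils::head(show, 20), row.names = FALSE)
  invisible(x)
}
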