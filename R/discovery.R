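#' Screen candidate effectors for one gene
#'
#' Candidates are retained when the absolute Pearson correlation between
#' the gene's CDF-normalized expression and the effector profile reaches
#' the screening threshold and the sign satisfies the mechanistic
#' constraint of the candidate kind: cis-acting arm CNV must correlate
#' positively (the targets sit on the amplified/deleted segment itself),
#' methylation must correlate negatively, trans-acting CNV of other arms
#' may take either sign.
#'
#' @param gene_expr numeric vector: one CDF-normalized expression row.
#' @param gene_arm arm id (`"chr7p"` style) of the gene, or `NA` if the
#'   gene is unannotated (then no cis candidate is possible).
#' @param arm_cnv arm-level CNV matrix (arms x samples), same samples.
#' @param meth optional methylation effector matrix (genes x samples).
#' @param threshold absolute-correlation screening threshold (default 0.5);
#'   may be a named vector with per-kind entries `cis`, `trans`, `meth`.
#' @return data.frame of candidates: kind, reference, direction, screen_score,
#'   ordered cis first, then trans, then methylation, by decreasing |score|.
#' @export
screen_candidates <- function(gene_expr, gene_arm, arm_cnv, meth = NULL,
                              threshold = 0.5) {
  thr <- screen_thresholds(threshold)
  out <- list()
  r_arm <- suppressWarnings(as.vector(stats::cor(gene_expr, t(unclass(arm_cnv)))))
  names(r_arm) <- rownames(arm_cnv)
  r_arm[is.na(r_arm)] <- 0
  if (!is.na(gene_arm) && gene_arm %in% names(r_arm)) {
    r <- r_arm[[gene_arm]]
    if (r >= thr[["cis"]]) {
      out$cis <- data.frame(kind = "cis_cnv", reference = gene_arm,
                            direction = 1, screen_score = r)
    }
  }
  others <- setdiff(names(r_arm), if (is.na(gene_arm)) character() else gene_arm)
  keep <- others[abs(r_arm[others]) >= thr[["trans"]]]
  if (length(keep)) {
    keep <- keep[order(-abs(r_arm[keep]), keep)]
    out$trans <- data.frame(kind = "trans_cnv", reference = keep,
                            direction = sign(r_arm[keep]),
                            screen_score = r_arm[keep])
  }
  if (!is.null(meth) && nrow(meth) > 0) {
    r_m <- suppressWarnings(as.vector(stats::cor(gene_expr, t(unclass(meth)))))
    names(r_m) <- rownames(meth)
    r_m[is.na(r_m)] <- 0
    keep <- names(r_m)[r_m <= -thr[["meth"]]]
    if (length(keep)) {
      keep <- keep[order(r_m[keep], keep)]
      out$meth <- data.frame(kind = "methylation", reference = keep,
                             direction = -1, screen_score = r_m[keep])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(kind = character(), reference = character(),
                      direction = numeric(), screen_score = numeric())
  }
  rownames(res) <- NULL
  res
}

screen_thresholds <- function(threshold) {
  if (length(threshold) == 1 && is.null(names(threshold))) {
    c(cis = threshold, trans = threshold, meth = threshold)
  } else {
    c(cis = unname(threshold["cis"]), trans = unname(threshold["trans"]),
      meth = unname(threshold["meth"]))
  }
}

# Expected log-likelihood of the non-negative logistic model
#   P(y | x) = exp(sum_i lambda_i f_i(x, y)) / Z(x),
# with feature f_i(x, y) = direction_i * E[x_i] * y and y the trinary state.
# With s_j = sum_i lambda_i d_i E[x_ij], Z = e^s + 1 + e^-s and the
# soft-label expected log-likelihood over samples j is
#   sum_j s_j E[y_j] - log(e^{s_j} + 1 + e^{-s_j}).
model_loglik <- function(lambda, feats, ey) {
  s <- as.vector(feats %*% lambda)
  sum(s * ey - log(exp(s) + 1 + exp(-s)))
}

model_grad <- function(lambda, feats, ey) {
  s <- as.vector(feats %*% lambda)
  es <- exp(s); ens <- exp(-s)
  eys <- (es - ens) / (es + 1 + ens)   # model expectation of y given s
  as.vector(crossprod(feats, ey - eys))
}

# Projected gradient ascent on lambda >= 0 with backtracking line search.
# The objective is concave (linear term minus a log-partition of a linear
# map), so this converges to the global constrained maximum.
fit_lambda <- function(feats, ey, tol = 1e-8, max_iter = 500) {
  k <- ncol(feats)
  lambda <- rep(0, k)
  ll <- model_loglik(lambda, feats, ey)
  step0 <- 1 / max(1, sum(feats^2) / nrow(feats))
  for (it in seq_len(max_iter)) {
    g <- model_grad(lambda, feats, ey)
    step <- step0
    cand <- pmax(0, lambda + step * g)
    llc <- model_loglik(cand, feats, ey)
    while (llc < ll && step > 1e-12) {
      step <- step / 2
      cand <- pmax(0, lambda + step * g)
      llc <- model_loglik(cand, feats, ey)
    }
    if (llc < ll) {
      cand <- lambda
      llc <- ll
    }
    moved <- sqrt(sum((cand - lambda)^2))
    improved <- llc - ll
    lambda <- cand; ll <- llc
    if (improved < tol && moved < 1e-6) {
      return(list(lambda = lambda, loglik = ll, converged = TRUE, iter = it))
    }
  }
  list(lambda = lambda, loglik = ll, converged = FALSE, iter = max_iter)
}

#' Fit the layered non-negative logistic model for one gene
#'
#' Candidates are tried by greedy forward inclusion strictly in layer
#' order -- all cis-acting CNV candidates first, then trans-acting CNV,
#' then DNA methylation, each layer ordered by decreasing |screening
#' score|.  At each trial all weights are re-optimized jointly by
#' projected gradient ascent under the non-negativity constraint, and the
#' candidate is kept only if BIC = -2 loglik + k log(n) strictly improves.
#'
#' @param ey numeric vector E[y_j] of expected trinary expression states
#'   (from [trinary_probabilities()] of the gene's CDF row).
#' @param candidates candidate data.frame from [screen_candidates()].
#' @param effector_ex named list mapping effector reference -> numeric
#'   vector E[x_j] of expected trinary effector states.
#' @param gene_id gene identifier carried into the result.
#' @param tol,max_iter optimizer controls.
#' @return object of class `gene_model`: gene_id, selected (data.frame of
#'   kept candidates with weights), loglik, bic, null_bic.
#' @export
fit_gene_model <- function(ey, candidates, effector_ex, gene_id = NA_character_,
                           tol = 1e-8, max_iter = 500) {
  n <- length(ey)
  null_ll <- -n * log(3)
  null_bic <- -2 * null_ll
  sel <- candidates[0, , drop = FALSE]
  sel$lambda <- numeric(0)
  feats <- matrix(0, n, 0)
  best_ll <- null_ll
  best_bic <- null_bic
  layer_rank <- c(cis_cnv = 1, trans_cnv = 2, methylation = 3)
  if (nrow(candidates)) {
    ord <- order(layer_rank[candidates$kind], -abs(candidates$screen_score),
                 candidates$reference)
    candidates <- candidates[ord, , drop = FALSE]
  }
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    ex <- effector_ex[[cand$reference]]
    if (is.null(ex)) next
    f_new <- cand$direction * ex
    trial <- cbind(feats, f_new)
    fit <- fit_lambda(trial, ey, tol = tol, max_iter = max_iter)
    if (!fit$converged) {
      warnf("optimizer did not converge for gene %s candidate %s; skipped",
            gene_id, cand$reference)
      next
    }
    bic <- -2 * fit$loglik + ncol(trial) * log(n)
    if (bic < best_bic - 1e-9) {
      feats <- trial
      keep <- cand
      keep$lambda <- fit$lambda[ncol(trial)]
      sel <- rbind(sel, keep)
      sel$lambda <- fit$lambda
      best_bic <- bic
      best_ll <- fit$loglik
    }
  }
  structure(list(gene_id = gene_id, selected = sel, loglik = best_ll,
                 bic = best_bic, null_bic = null_bic),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s: %d effectors, BIC %.2f (null %.2f)>\n",
              x$gene_id, nrow(x$selected), x$bic, x$null_bic))
  invisible(x)
}

#' Group fitted gene models into association modules
#'
#' Genes sharing a selected effector form one module.  A cis module's
#' targets all lie on the effector arm; a trans module's targets lie on
#' other arms and its regulators are the genes on the effector arm that
#' are themselves cis targets of that arm; a methylation module's targets
#' are the genes selecting that methylation effector.  A gene may belong
#' to several modules.  Modules below `min_size` targets are dropped.
#'
#' @param models list of `gene_model` objects.
#' @param annotation gene annotation (for arm membership).
#' @param min_size minimum number of targets to report a module (default 5).
#' @return list of `association_module` objects, sorted by module id.
#' @export
assemble_modules <- function(models, annotation, min_size = 5) {
  ann <- validate_annotation(annotation)
  arm_of <- stats::setNames(ann$arm_id, ann$gene_id)
  buckets <- list()
  for (m in models) {
    if (nrow(m$selected) == 0) next
    for (i in seq_len(nrow(m$selected))) {
      key <- paste(m$selected$kind[i], m$selected$reference[i], sep = "|")
      buckets[[key]] <- c(buckets[[key]], m$gene_id)
    }
  }
  mods <- list()
  for (key in sort(names(buckets))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    kind <- parts[1]; ref <- parts[2]
    targets <- sort(unique(buckets[[key]]))
    if (length(targets) < min_size) next
    regulators <- character()
    if (kind == "trans_cnv") {
      cis_key <- paste("cis_cnv", ref, sep = "|")
      regulators <- sort(unique(buckets[[cis_key]] %||% character()))
    }
    id <- paste0(c(cis_cnv = "cis_", trans_cnv = "trans_", methylation = "meth_")[kind], ref)
    mods[[id]] <- structure(list(module_id = id, type = kind, effector = ref,
                                 regulators = regulators, targets = targets),
                            class = "association_module")
  }
  if (length(mods) == 0) return(mods)
  mods[order(names(mods))]
}

#' @export
print.association_module <- function(x, ...) {
  cat(sprintf("<association_module %s [%s]: effector %s, %d targets%s>\n",
              x$module_id, x$type, x$effector, length(x$targets),
              if (length(x$regulators)) sprintf(", %d regulators", length(x$regulators)) else ""))
  invisible(x)
}

#' Discover association modules from a multi-omic training cohort
#'
#' The central fitting function.  Takes tumor/normal expression ratios,
#' probe-level tumor/normal CNV ratios and (optionally) tumor-normal
#' methylation beta differences, and returns the fitted per-gene models
#' and the association modules they imply:
#' \enumerate{
#'   \item CNV probes are aggregated to chromosome-arm medians.
#'   \item Expression and arm CNV are rank-CDF normalized per feature.
#'   \item Candidate effectors per gene are screened by correlation.
#'   \item A layered non-negative logistic model of the trinary expression
#'     state is grown per gene under BIC.
#'   \item Genes sharing effectors are grouped into modules.
#' }
#'
#' @param expression genes x samples matrix of tumor/normal expression
#'   ratios (any strictly monotone scale; CDF normalization removes it).
#' @param cnv probes x samples matrix of tumor/normal CNV ratios.
#' @param annotation gene annotation data.frame.
#' @param cnv_annotation probe annotation for `cnv` rows (defaults to
#'   `annotation`, for data already keyed by gene).
#' @param methylation optional genes x samples matrix of tumor-normal
#'   beta differences.
#' @param r_threshold screening threshold(s), see [screen_candidates()].
#' @param min_size minimum module size (default 5).
#' @param min_meth_sd variability cutoff for methylation effectors.
#' @param tol,max_iter optimizer controls for [fit_gene_model()].
#' @return object of class `assoc_modules` with elements `modules`,
#'   `models` (non-null fits only), `expr_cdf`, `arm_cnv`, `arm_cdf`,
#'   `meth_effectors`, `annotation`, `config`.
#' @export
discover_modules <- function(expression, cnv, annotation,
                             cnv_annotation = annotation,
                             methylation = NULL,
                             r_threshold = 0.5, min_size = 5,
                             min_meth_sd = 0.1,
                             tol = 1e-8, max_iter = 500) {
  ann <- validate_annotation(annotation)
  expression <- unclass(expression)
  samples <- Reduce(intersect, c(list(colnames(expression), colnames(cnv)),
                                 if (!is.null(methylation)) list(colnames(methylation))))
  if (length(samples) < 10) stopf("need >= 10 shared samples, got %d", length(samples))
  expression <- expression[rownames(expression) %in% ann$gene_id, samples, drop = FALSE]
  arm_cnv <- arm_cnv_matrix(unclass(cnv)[, samples, drop = FALSE], cnv_annotation)
  expr_cdf <- ecdf_normalize(expression)
  arm_cdf <- ecdf_normalize(arm_cnv)
  meth_eff <- NULL
  if (!is.null(methylation)) {
    meth_eff <- select_methylation_effectors(unclass(methylation)[, samples, drop = FALSE],
                                             min_sd = min_meth_sd)
    if (nrow(meth_eff) == 0) meth_eff <- NULL
  }

  # expected trinary states of every effector, precomputed once
  effector_ex <- c(
    lapply(seq_len(nrow(arm_cdf)), function(i) trinary_probabilities(arm_cdf[i, ])$ex),
    if (!is.null(meth_eff)) {
      meth_cdf <- ecdf_normalize(meth_eff)
      lapply(seq_len(nrow(meth_cdf)), function(i) trinary_probabilities(meth_cdf[i, ])$ex)
    }
  )
  names(effector_ex) <- c(rownames(arm_cdf),
                          if (!is.null(meth_eff)) rownames(meth_eff))

  arm_of <- stats::setNames(ann$arm_id, ann$gene_id)
  genes <- sort(rownames(expr_cdf))
  models <- vector("list", length(genes))
  names(models) <- genes
  for (g in genes) {
    cands <- screen_candidates(expr_cdf[g, ], arm_of[[g]] %||% NA_character_,
                               arm_cdf, meth_eff, threshold = r_threshold)
    if (nrow(cands) == 0) {
      models[[g]] <- structure(list(gene_id = g,
                                    selected = cands, loglik = -ncol(expr_cdf) * log(3),
                                    bic = 2 * ncol(expr_cdf) * log(3),
                                    null_bic = 2 * ncol(expr_cdf) * log(3)),
                               class = "gene_model")
      next
    }
    ey <- trinary_probabilities(expr_cdf[g, ])$ex
    models[[g]] <- fit_gene_model(ey, cands, effector_ex, gene_id = g,
                                  tol = tol, max_iter = max_iter)
  }
  modules <- assemble_modules(models, ann, min_size = min_size)
  fitted <- Filter(function(m) nrow(m$selected) > 0, models)
  structure(list(modules = modules, models = fitted,
                 expr_cdf = expr_cdf, arm_cnv = arm_cnv, arm_cdf = arm_cdf,
                 meth_effectors = meth_eff, annotation = ann,
                 config = list(r_threshold = r_threshold, min_size = min_size,
                               min_meth_sd = min_meth_sd, n_samples = length(samples))),
            class = "assoc_modules")
}

#' @export
print.assoc_modules <- function(x, ...) {
  types <- vapply(x$modules, function(m) m$type, "")
  cat(sprintf("Association module fit: %d modules (%d cis CNV, %d trans CNV, %d methylation)\n",
              length(x$modules), sum(types == "cis_cnv"), sum(types == "trans_cnv"),
              sum(types == "methylation")))
  cat(sprintf("  %d genes with non-null models; %d samples; |r| threshold %s; min size %d\n",
              length(x$models), x$config$n_samples,
              paste(format(x$config$r_threshold), collapse = "/"), x$config$min_size))
  invisible(x)
}

#' @export
summary.assoc_modules <- function(object, ...) {
  tab <- as.data.frame(object)
  class(tab) <- c("summary.assoc_modules", "data.frame")
  tab
}

#' @export
print.summary.assoc_modules <- function(x, ...) {
  print.data.frame(x)
  invisible(x)
}

#' Flatten a module fit into a data frame
#' @param x `assoc_modules` object.
#' @param ... unused.
#' @export
as.data.frame.assoc_modules <- function(x, ...) {
  if (length(x$modules) == 0) {
    return(data.frame(module_id = character(), type = character(),
                      effector = character(), n_targets = integer(),
                      regulators = character(), targets = character()))
  }
  data.frame(
    module_id = vapply(x$modules, function(m) m$module_id, ""),
    type = vapply(x$modules, function(m) m$type, ""),
    effector = vapply(x$modules, function(m) m$effector, ""),
    n_targets = vapply(x$modules, function(m) length(m$targets), 0L),
    regulators = vapply(x$modules, function(m) paste(m$regulators, collapse = ","), ""),
    targets = vapply(x$modules, function(m) paste(m$targets, collapse = ","), ""),
    row.names = NULL
  )
}

#' Write discovered modules as TSV (and optionally JSON)
#' @param fit `assoc_modules` object.
#' @param path TSV output path.
#' @param json_path optional JSON output path.
#' @export
write_modules <- function(fit, path, json_path = NULL) {
  tab <- as.data.frame(fit)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(fit$modules, unclass), json_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
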