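# End-to-end orchestration: simulate -> discover -> validate -> fdr ->
# pls -> enrich, driven by one YAML-able config with per-stage manifests
# and seeded reproducibility.

#' Default pipeline configuration
#'
#' Defaults mirror the analysis defaults: screening |r| threshold 0.5,
#' coherence/Cox alpha 0.05, log-rank alpha 0.1, minimum module size 5,
#' 1000 background genes, 1000 size-matched adjustment sets, 100 pairwise
#' permutations, 200 module-level runs.
#'
#' @param seed global seed; every stage derives its own offset from it.
#' @return nested named list (YAML-serializable).
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulation = list(n_samples = 60, n_chromosomes = 10, genes_per_arm = 100,
                      probes_per_arm = 20, sigma_arm = 1.0, probe_noise = 0.3,
                      expr_noise = 1.0),
    thresholds = list(screen_r = 0.5, alpha_coherence = 0.05, alpha_cox = 0.05,
                      alpha_logrank = 0.1, min_module_size = 5),
    validation = list(n_background = 1000, n_adjust = 1000, pair_cap = 50000,
                      required_cohorts = NULL, split = "global_mean"),
    fdr = list(n_perm = 100, n_runs = 200, n_adjust = 200)
  )
}

validate_pipeline_config <- function(config) {
  th <- config$thresholds
  for (f in c("alpha_coherence", "alpha_cox", "alpha_logrank", "screen_r")) {
    v <- th[[f]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v >= 1) {
      stopf("config field thresholds.%s must be in (0,1), got %s", f,
            format(v %||% NA))
    }
  }
  for (f in c("min_module_size")) {
    if (is.null(th[[f]]) || th[[f]] < 1) stopf("config field thresholds.%s must be >= 1", f)
  }
  for (f in c("n_background", "n_adjust", "pair_cap")) {
    if (is.null(config$validation[[f]]) || config$validation[[f]] < 1) {
      stopf("config field validation.%s must be positive", f)
    }
  }
  for (f in c("n_perm", "n_runs", "n_adjust")) {
    if (is.null(config$fdr[[f]]) || config$fdr[[f]] < 1) {
      stopf("config field fdr.%s must be positive", f)
    }
  }
  if (is.null(config$seed)) stopf("config field seed is required")
  invisible(config)
}

stage_dir <- function(outdir, stage, force) {
  d <- file.path(outdir, stage)
  manifest <- file.path(d, "manifest.json")
  if (file.exists(manifest) && !force) {
    stopf("stage '%s' already has outputs in %s; use force = TRUE to overwrite",
          stage, d)
  }
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(dir, stage, config, seed, inputs = character(),
                           elapsed = NA_real_) {
  outputs <- setdiff(list.files(dir, full.names = TRUE),
                     file.path(dir, "manifest.json"))
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    stage = stage, seed = seed,
    package_version = as.character(utils::packageVersion("assocmod")),
    r_version = as.character(getRversion()),
    config_md5 = unname(tools::md5sum(cfg_file)),
    inputs = as.list(stats::setNames(as.character(tools::md5sum(inputs)),
                                     basename(inputs))),
    outputs = as.list(stats::setNames(as.character(tools::md5sum(outputs)),
                                      basename(outputs))),
    elapsed_seconds = elapsed)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

pipeline_spec <- function(config) {
  do.call(simulation_spec, c(list(seed = config$seed), config$simulation))
}

stage_simulate <- function(config, outdir, force) {
  d <- stage_dir(outdir, "simulate", force)
  spec <- pipeline_spec(config)
  sim <- simulate_training_cohort(spec)
  b <- sim$bundle
  for (nm in names(b$matrices)) {
    write_omics_matrix(b$matrices[[nm]], file.path(d, paste0(nm, ".tsv")))
  }
  utils::write.table(b$annotation[, c("gene_id", "chromosome", "arm", "position")],
                     file.path(d, "annotation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$probe_annotation, file.path(d, "probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(d, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cohorts <- simulate_validation_cohorts(spec, sim$truth)
  for (nm in names(cohorts)) {
    safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
    write_omics_matrix(cohorts[[nm]]$matrices$expression,
                       file.path(d, paste0(safe, "_expression.tsv")))
    utils::write.table(cohorts[[nm]]$clinical,
                       file.path(d, paste0(safe, "_clinical.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  d
}

read_training <- function(simdir) {
  tum <- read_omics_matrix(file.path(simdir, "expression_tumor.tsv"), "expression")
  nor <- read_omics_matrix(file.path(simdir, "expression_normal.tsv"), "expression")
  ctum <- read_omics_matrix(file.path(simdir, "cnv_tumor.tsv"), "cnv_probe")
  cnor <- read_omics_matrix(file.path(simdir, "cnv_normal.tsv"), "cnv_probe")
  ann <- read_annotation(file.path(simdir, "annotation.tsv"))
  pann <- read_annotation(file.path(simdir, "probe_annotation.tsv"))
  meth <- NULL
  mt <- file.path(simdir, "methylation_tumor.tsv")
  if (file.exists(mt)) {
    mtum <- read_omics_matrix(mt, "methylation")
    mnor <- read_omics_matrix(file.path(simdir, "methylation_normal.tsv"), "methylation")
    meth <- tumor_normal_ratio(mtum, mnor)
  }
  list(expression = tumor_normal_ratio(tum, nor),
       cnv = tumor_normal_ratio(ctum, cnor),
       annotation = ann, probe_annotation = pann, methylation = meth)
}

read_validation_cohorts <- function(simdir, config) {
  spec <- pipeline_spec(config)
  ann <- read_annotation(file.path(simdir, "annotation.tsv"))
  out <- list()
  for (nm in spec$cohorts$name) {
    safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
    expr <- read_omics_matrix(file.path(simdir, paste0(safe, "_expression.tsv")),
                              "expression")
    clin <- read_clinical(file.path(simdir, paste0(safe, "_clinical.tsv")))
    out[[nm]] <- suppressWarnings(
      cohort_bundle(nm, list(expression = expr), ann, clin))
  }
  out
}

stage_discover <- function(config, outdir, force) {
  d <- stage_dir(outdir, "discover", force)
  simdir <- file.path(outdir, "simulate")
  tr <- read_training(simdir)
  fit <- discover_modules(tr$expression, tr$cnv, tr$annotation,
                          cnv_annotation = tr$probe_annotation,
                          methylation = tr$methylation,
                          r_threshold = config$thresholds$screen_r,
                          min_size = config$thresholds$min_module_size)
  write_modules(fit, file.path(d, "modules.tsv"), file.path(d, "modules.json"))
  d
}

read_modules_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  mods <- lapply(seq_len(nrow(tab)), function(i) {
    regs <- tab$regulators[i]
    structure(list(module_id = tab$module_id[i], type = tab$type[i],
                   effector = tab$effector[i],
                   regulators = if (!is.na(regs) && nzchar(regs))
                     strsplit(regs, ",")[[1]] else character(),
                   targets = strsplit(tab$targets[i], ",")[[1]]),
              class = "association_module")
  })
  names(mods) <- tab$module_id
  mods
}

stage_validate <- function(config, outdir, force) {
  d <- stage_dir(outdir, "validate", force)
  simdir <- file.path(outdir, "simulate")
  mods <- read_modules_tsv(file.path(outdir, "discover", "modules.tsv"))
  cohorts <- read_validation_cohorts(simdir, config)
  v <- config$validation
  th <- config$thresholds
  res <- validate_modules(mods, cohorts,
                          required_cohorts = v$required_cohorts,
                          n_background = v$n_background, n_adjust = v$n_adjust,
                          pair_cap = v$pair_cap,
                          alpha_coherence = th$alpha_coherence,
                          alpha_cox = th$alpha_cox,
                          alpha_logrank = th$alpha_logrank,
                          split = v$split %||% "global_mean",
                          seed = config$seed + 11L)
  if (nrow(res$table) > 0) {
    write_validation_report(res, file.path(d, "validation.tsv"))
  }
  jsonlite::write_json(list(overall_pass = as.list(res$overall)),
                       file.path(d, "overall.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  d
}

stage_fdr <- function(config, outdir, force) {
  d <- stage_dir(outdir, "fdr", force)
  simdir <- file.path(outdir, "simulate")
  tr <- read_training(simdir)
  pw <- pairwise_fdr(tr$expression, tr$cnv, tr$annotation,
                     cnv_annotation = tr$probe_annotation,
                     methylation = tr$methylation,
                     r_threshold = config$thresholds$screen_r,
                     n_perm = config$fdr$n_perm, seed = config$seed + 21L)
  write_fdr_report(pw, file.path(d, "pairwise_fdr.tsv"))
  mods <- read_modules_tsv(file.path(outdir, "discover", "modules.tsv"))
  if (length(mods) > 0) {
    sizes <- vapply(mods, function(m) length(m$targets), 0L)
    cohorts <- read_validation_cohorts(simdir, config)
    overall <- jsonlite::read_json(file.path(outdir, "validate", "overall.json"))
    observed <- sum(unlist(overall$overall_pass))
    ml <- module_level_fdr(sizes, cohorts, n_runs = config$fdr$n_runs,
                           n_adjust = config$fdr$n_adjust,
                           n_background = config$validation$n_background,
                           pair_cap = config$validation$pair_cap,
                           alpha_coherence = config$thresholds$alpha_coherence,
                           alpha_cox = config$thresholds$alpha_cox,
                           alpha_logrank = config$thresholds$alpha_logrank,
                           observed_passing = observed,
                           seed = config$seed + 22L)
    write_fdr_report(ml, file.path(d, "module_fdr.tsv"))
  }
  d
}

stage_pls <- function(config, outdir, force) {
  d <- stage_dir(outdir, "pls", force)
  simdir <- file.path(outdir, "simulate")
  tr <- read_training(simdir)
  mods <- read_modules_tsv(file.path(outdir, "discover", "modules.tsv"))
  expr_cdf <- ecdf_normalize(unclass(tr$expression)[
    rownames(tr$expression) %in% tr$annotation$gene_id, , drop = FALSE])
  pick <- function(genes) t(expr_cdf[intersect(genes, rownames(expr_cdf)), , drop = FALSE])
  pairs <- list()
  if (length(mods) >= 2) {
    pairs$module_pair <- list(x = mods[[1]]$targets, y = mods[[2]]$targets)
  } else if (length(mods) == 1) {
    other <- with_seed(config$seed + 31L,
                       sample(setdiff(rownames(expr_cdf), mods[[1]]$targets),
                              length(mods[[1]]$targets)))
    pairs$module_vs_random <- list(x = mods[[1]]$targets, y = other)
  }
  rnd <- with_seed(config$seed + 32L, {
    g <- sample(rownames(expr_cdf), 40)
    list(x = g[1:20], y = g[21:40])
  })
  pairs$random_pair <- rnd
  rows <- list()
  for (nm in names(pairs)) {
    X <- pick(pairs[[nm]]$x); Y <- pick(pairs[[nm]]$y)
    M <- min(2, ncol(X), ncol(Y))
    fit <- fit_pls(X, Y, M = M)
    write_correlation_circle(correlation_circle(fit),
                             file.path(d, paste0(nm, "_circle.tsv")))
    rows[[nm]] <- data.frame(pair = nm, components = M,
                             r2_1 = cumulative_r2(fit, m = 1),
                             r2_2 = if (M >= 2) cumulative_r2(fit, m = 2) else NA_real_)
  }
  utils::write.table(do.call(rbind, rows), file.path(d, "pls_r2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d
}

stage_enrich <- function(config, outdir, force) {
  d <- stage_dir(outdir, "enrich", force)
  simdir <- file.path(outdir, "simulate")
  ann <- read_annotation(file.path(simdir, "annotation.tsv"))
  mods <- read_modules_tsv(file.path(outdir, "discover", "modules.tsv"))
  if (length(mods) == 0) {
    utils::write.table(data.frame(), file.path(d, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(d)
  }
  # demonstration inputs: arm-membership gene sets, plus a synthetic
  # citation-count table (labelled synthetic; stands in for an offline
  # literature count table the user would normally supply)
  sets <- split(ann$gene_id, ann$arm_id)
  names(sets) <- paste0("arm:", names(sets))
  citations <- with_seed(config$seed + 41L, data.frame(
    gene_id = ann$gene_id,
    count = stats::rnbinom(nrow(ann), mu = 5, size = 1)))
  utils::write.table(citations, file.path(d, "synthetic_citation_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  all_rows <- list()
  top_rows <- list()
  for (m in mods) {
    enr <- geneset_enrichment(m$targets, sets, ann$gene_id)
    enr$module_id <- m$module_id
    all_rows[[m$module_id]] <- enr
    top <- top_cited_intersection(citations, m)
    top_rows[[m$module_id]] <- data.frame(
      module_id = m$module_id,
      top_cited = paste(top, collapse = ","))
  }
  utils::write.table(do.call(rbind, all_rows), file.path(d, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, top_rows), file.path(d, "top_cited.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d
}

#' Run the analysis pipeline
#'
#' Orchestrates the synthetic-study pipeline as subcommands sharing one
#' configuration: `simulate` writes the training and validation cohorts,
#' `discover` fits association modules, `validate` runs the validation
#' battery, `fdr` the permutation FDR analyses, `pls` the inter-module
#' dependency analysis and `enrich` the offline annotation step; `all`
#' runs every stage in order.  Each stage writes its artifacts plus a
#' manifest (input checksums, config hash, seed, versions) under
#' `outdir/<stage>/`, and no stage mutates another stage's outputs.
#'
#' @param subcommand one of simulate, discover, validate, fdr, pls,
#'   enrich, all.
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file.
#' @param outdir output directory.
#' @param seed optional override of the config seed.
#' @param force overwrite a stage's existing artifacts.
#' @return invisibly, the outdir.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "discover", "validate",
                                        "fdr", "pls", "enrich"),
                         config = default_pipeline_config(),
                         outdir = "assocmod_results", seed = NULL,
                         force = FALSE) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (!is.null(seed)) config$seed <- seed
  validate_pipeline_config(config)
  stages <- if (subcommand == "all") {
    c("simulate", "discover", "validate", "fdr", "pls", "enrich")
  } else {
    subcommand
  }
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[assocmod] stage %s ...", st))
    d <- switch(st,
                simulate = stage_simulate(config, outdir, force),
                discover = stage_discover(config, outdir, force),
                validate = stage_validate(config, outdir, force),
                fdr = stage_fdr(config, outdir, force),
                pls = stage_pls(config, outdir, force),
                enrich = stage_enrich(config, outdir, force))
    elapsed <- proc.time()[["elapsed"]] - t0
    write_manifest(d, st, config, config$seed, elapsed = elapsed)
    message(sprintf("[assocmod] stage %s done (%.1fs)", st, elapsed))
  }
  invisible(outdir)
}
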