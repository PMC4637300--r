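# Shared fixture builders; everything is generated in code at test time.

# Small genome layout: 4 chromosomes x 2 arms x 25 genes = 200 genes.
small_spec <- function(seed = 1, ...) {
  args <- list(seed = seed, n_samples = 40, n_chromosomes = 4,
               genes_per_arm = 25, probes_per_arm = 8,
               planted = list(list(type = "cis", arm = "chr2p",
                                   n_targets = 12, target_r = 0.7)),
               cohorts = data.frame(
                 name = c("eff", "null"), n = 80,
                 gender = c("female", "male"),
                 ethnicity = c("EastAsian", "Caucasian"),
                 gamma = c(1.2, 0)))
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(simulation_spec, args)
}

training_ratios <- function(sim) {
  b <- sim$bundle
  out <- list(
    expression = tumor_normal_ratio(b$matrices$expression_tumor,
                                    b$matrices$expression_normal),
    cnv = tumor_normal_ratio(b$matrices$cnv_tumor, b$matrices$cnv_normal),
    annotation = b$annotation, probe_annotation = sim$probe_annotation)
  if (!is.null(b$matrices$methylation_tumor)) {
    out$methylation <- tumor_normal_ratio(b$matrices$methylation_tumor,
                                          b$matrices$methylation_normal)
  }
  out
}

# A tiny deterministic expression matrix with named dims.
toy_matrix <- function(nr = 6, nc = 8, seed = 42, prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  m
}

# Brute-force one/two-sided KS over the pooled points (independent oracle).
ks_brute <- function(a, b, side = "two_sided") {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), 0)
  Fb <- vapply(pts, function(x) mean(b <= x), 0)
  if (side == "greater") max(c(Fb - Fa, 0)) else max(abs(Fa - Fb))
}

# Breslow partial log-likelihood for a single covariate (oracle).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_grid_oracle <- function(time, event, x, lower = -10, upper = 10) {
  opt <- optimize(function(b) breslow_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)
  opt$maximum
}
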