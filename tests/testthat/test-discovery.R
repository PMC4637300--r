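make_screen_fixture <- function(r_own = 0.6, r_meth = -0.6, n = 40, seed = 9) {
  set.seed(seed)
  arm_own <- rnorm(n)
  arm_other <- rnorm(n)
  make_cor <- function(driver, r) {
    if (r == 0) return(rnorm(n))
    r * scale(driver)[, 1] + sqrt(1 - r^2) * rnorm(n)
  }
  list(arm_cnv = rbind(chr1p = arm_own, chr2q = arm_other),
       arm_own = arm_own, make_cor = make_cor)
}

test_that("screening enforces threshold and per-kind sign constraints", {
  fx <- make_screen_fixture()
  n <- 40
  # strong positive own-arm correlation -> cis candidate
  g_cis <- 0.9 * scale(fx$arm_own)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  cands <- screen_candidates(g_cis, "chr1p", fx$arm_cnv, threshold = 0.5)
  expect_true("cis_cnv" %in% cands$kind)
  expect_equal(cands$direction[cands$kind == "cis_cnv"], 1)

  # below-threshold correlation -> no candidates (threshold set above |r|)
  cands2 <- screen_candidates(g_cis, "chr1p", fx$arm_cnv, threshold = 0.999)
  expect_equal(nrow(cands2), 0)

  # negative own-arm correlation violates the cis sign constraint
  cands3 <- screen_candidates(-g_cis, "chr1p", fx$arm_cnv, threshold = 0.5)
  expect_false("cis_cnv" %in% cands3$kind)

  # positively correlated methylation effector is rejected (must be negative)
  meth <- rbind(me1 = g_cis)
  cands4 <- screen_candidates(g_cis, "chr1p", fx$arm_cnv, meth, threshold = 0.5)
  expect_false("methylation" %in% cands4$kind)
  cands5 <- screen_candidates(-g_cis, "chr1p", fx$arm_cnv, meth, threshold = 0.5)
  expect_true("methylation" %in% cands5$kind)
  expect_equal(cands5$direction[cands5$kind == "methylation"], -1)

  # unannotated gene: no cis candidate, trans still screened
  cands6 <- screen_candidates(g_cis, NA, fx$arm_cnv, threshold = 0.5)
  expect_false("cis_cnv" %in% cands6$kind)
  expect_true(all(cands6$kind == "trans_cnv"))
})

test_that("single-candidate lambda maximizer matches a brute-force grid", {
  set.seed(11)
  n <- 20
  driver <- rnorm(n)
  y_cdf <- rank(driver + 0.3 * rnorm(n)) / (n + 1)
  x_cdf <- rank(driver) / (n + 1)
  ey <- trinary_probabilities(y_cdf)$ex
  ex <- trinary_probabilities(x_cdf)$ex
  feats <- matrix(ex, ncol = 1)
  grid <- seq(0, 10, by = 1e-3)
  ll_grid <- vapply(grid, function(l) assocmod:::model_loglik(l, feats, ey), 0)
  lam_star <- grid[which.max(ll_grid)]
  fit <- assocmod:::fit_lambda(feats, ey)
  expect_true(fit$converged)
  expect_equal(fit$lambda, lam_star, tolerance = 2e-3)
  expect_gt(fit$loglik, -n * log(3))  # beats the null model
})

test_that("noise-free cis candidate is kept with positive weight, BIC improves", {
  set.seed(21)
  n <- 20
  driver <- rnorm(n)
  y_cdf <- rank(driver) / (n + 1)
  ey <- trinary_probabilities(y_cdf)$ex
  ex <- trinary_probabilities(y_cdf)$ex
  cands <- data.frame(kind = "cis_cnv", reference = "chr1p", direction = 1,
                      screen_score = 1)
  gm <- fit_gene_model(ey, cands, list(chr1p = ex), "g1")
  expect_equal(nrow(gm$selected), 1)
  expect_gt(gm$selected$lambda, 0)
  expect_lt(gm$bic, gm$null_bic)
})

test_that("permuted (independent) candidates are rejected in >= 95/100 seeds", {
  n <- 60
  rejected <- 0
  for (s in 1:100) {
    set.seed(s)
    y_cdf <- rank(rnorm(n)) / (n + 1)
    x_cdf <- rank(rnorm(n)) / (n + 1)
    ey <- trinary_probabilities(y_cdf)$ex
    ex <- trinary_probabilities(x_cdf)$ex
    cands <- data.frame(kind = "cis_cnv", reference = "a", direction = 1,
                        screen_score = 0.5)
    gm <- fit_gene_model(ey, cands, list(a = ex), "g")
    if (nrow(gm$selected) == 0) rejected <- rejected + 1
  }
  expect_gte(rejected, 95)
})

test_that("anti-correlated candidate hits the non-negativity boundary and is dropped", {
  set.seed(31)
  n <- 30
  y_cdf <- rank(rnorm(n)) / (n + 1)
  ey <- trinary_probabilities(y_cdf)$ex
  ex <- -ey  # perfectly anti-correlated with a direction = +1 feature
  cands <- data.frame(kind = "cis_cnv", reference = "a", direction = 1,
                      screen_score = 0.9)
  gm <- fit_gene_model(ey, cands, list(a = ex), "g")
  expect_equal(nrow(gm$selected), 0)
  expect_equal(gm$bic, gm$null_bic)
})

test_that("assemble_modules groups by effector, applies min_size, finds regulators", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    chromosome = c(rep(7, 5), rep(3, 5)),
                    arm = c(rep("p", 5), rep("q", 5)),
                    position = 1:10)
  mk <- function(gene, kind, ref) {
    sel <- data.frame(kind = kind, reference = ref, direction = 1,
                      screen_score = 0.8, lambda = 1)
    structure(list(gene_id = gene, selected = sel, loglik = 0, bic = 0,
                   null_bic = 1), class = "gene_model")
  }
  models <- c(lapply(sprintf("g%02d", 1:3), mk, kind = "cis_cnv", ref = "chr7p"),
              lapply(sprintf("g%02d", 6:8), mk, kind = "trans_cnv", ref = "chr7p"))
  mods <- assemble_modules(models, ann, min_size = 3)
  expect_setequal(names(mods), c("cis_chr7p", "trans_chr7p"))
  expect_identical(mods$cis_chr7p$targets, sprintf("g%02d", 1:3))
  # trans regulators are the cis targets of the effector arm
  expect_identical(mods$trans_chr7p$regulators, sprintf("g%02d", 1:3))
  expect_identical(mods$trans_chr7p$targets, sprintf("g%02d", 6:8))
  # below min_size the module disappears
  mods5 <- assemble_modules(models, ann, min_size = 5)
  expect_length(mods5, 0)
})

test_that("discover_modules is deterministic and recovers a planted cis module", {
  sim <- simulate_training_cohort(small_spec(seed = 2))
  tr <- training_ratios(sim)
  fit1 <- suppressWarnings(discover_modules(tr$expression, tr$cnv, tr$annotation,
                                            cnv_annotation = tr$probe_annotation,
                                            min_size = 5))
  fit2 <- suppressWarnings(discover_modules(tr$expression, tr$cnv, tr$annotation,
                                            cnv_annotation = tr$probe_annotation,
                                            min_size = 5))
  expect_identical(as.data.frame(fit1), as.data.frame(fit2))
  sc <- score_recovery(fit1, sim$truth)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$recall, 0.8)
})

test_that("methylation effectors form negative-association modules", {
  spec <- small_spec(seed = 4, planted = list(
    list(type = "methylation", effector_genes = c("mA", "mB"),
         n_targets = 10, target_r = 0.75)))
  sim <- simulate_training_cohort(spec)
  tr <- training_ratios(sim)
  fit <- suppressWarnings(discover_modules(tr$expression, tr$cnv, tr$annotation,
                                           cnv_annotation = tr$probe_annotation,
                                           methylation = tr$methylation,
                                           min_size = 5))
  types <- vapply(fit$modules, function(m) m$type, "")
  expect_true("methylation" %in% types)
  sc <- score_recovery(fit, sim$truth)
  expect_gte(sc$recall, 0.8)
})
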