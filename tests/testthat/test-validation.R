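test_that("ks_compare matches the brute-force ECDF oracle and stats::ks.test", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(30 + i)
    b <- rnorm(50, mean = 0.3)
    ks <- ks_compare(a, b)
    expect_equal(ks$D, ks_brute(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ks$p, ref$p.value, tolerance = 1e-3)
    kg <- ks_compare(a, b, side = "greater")
    expect_equal(kg$D, ks_brute(a, b, side = "greater"), tolerance = 1e-12)
  }
})

test_that("ks_compare handles identity and disjoint supports", {
  x <- c(1, 2, 3, 4)
  id <- ks_compare(x, x)
  expect_equal(id$D, 0)
  expect_equal(id$p, 1)
  idg <- ks_compare(x, x, side = "greater")
  expect_equal(idg$D, 0)
  expect_equal(idg$p, 1)
  dj <- ks_compare(rep(0, 4), rep(1, 4))
  expect_equal(dj$D, 1)
  # constant-but-identical inputs stay well-defined
  cc <- ks_compare(rep(2, 3), rep(2, 5))
  expect_equal(cc$D, 0)
})

test_that("fast sorted-background KS equals ks_compare on random inputs", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(5:200, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(50:2000, 1))
    fast <- assocmod:::ks_greater_sorted(a, assocmod:::sorted_background(b))
    slow <- ks_compare(a, b, side = "greater")
    expect_equal(fast$D, slow$D, tolerance = 1e-14)
    expect_equal(fast$p, slow$p, tolerance = 1e-14)
  }
})

test_that("one-sided KS direction: negative shift gives p near 1", {
  set.seed(3)
  bg <- rnorm(2000)
  shifted_down <- rnorm(50, mean = -1)
  expect_gt(ks_compare(shifted_down, bg, side = "greater")$p, 0.9)
  shifted_up <- rnorm(50, mean = 1)
  expect_lt(ks_compare(shifted_up, bg, side = "greater")$p, 1e-6)
})

test_that("coherence test flags a planted coherent module and fails closed", {
  set.seed(12)
  n <- 60; n_genes <- 400
  expr <- matrix(rnorm(n_genes * n), n_genes, n,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("S%02d", 1:n)))
  z <- rnorm(n)
  module_genes <- sprintf("g%03d", 1:30)
  expr[module_genes, ] <- 0.9 * matrix(rep(z, each = 30), 30, n) +
    0.8 * matrix(rnorm(30 * n), 30, n)
  cdf <- ecdf_normalize(expr)
  res <- coherence_test(module_genes, cdf, n_background = 200, n_adjust = 100,
                        seed = 1)
  expect_true(res$evaluable)
  expect_lt(res$adjusted_p, 0.05)

  # a 2-gene module is still evaluable
  res2 <- coherence_test(module_genes[1:2], cdf, n_background = 200,
                         n_adjust = 50, seed = 1)
  expect_true(res2$evaluable)

  # unmappable module fails closed
  res3 <- coherence_test(c("nope1", "nope2"), cdf, n_background = 200,
                         n_adjust = 50, seed = 1)
  expect_false(res3$evaluable)
  expect_false(res3$pass)
})

test_that("cox_per_gene matches the grid-search oracle on a 4-subject toy", {
  # events on both covariate levels keep the partial likelihood maximizer
  # interior (a covariate separating early events from late censorings has
  # a divergent likelihood and no finite oracle value)
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(0, 1, 0, 1)
  expr <- matrix(x, 1, 4, dimnames = list("g1", paste0("S", 1:4)))
  clin <- data.frame(sample_id = paste0("S", 1:4), time = time, event = event)
  beta <- cox_per_gene(expr, clin, min_events = 1)
  expect_equal(unname(beta["g1"]), cox_grid_oracle(time, event, x),
               tolerance = 1e-4)
})

test_that("cox_per_gene recovers planted effects and is near zero under the null", {
  hits_null <- 0; hits_eff <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    x_null <- rnorm(n)
    x_eff <- rnorm(n)
    times <- rexp(n, rate = 0.1 * exp(0.8 * x_eff))
    cens <- rexp(n, rate = 0.045)
    clin <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       time = pmin(times, cens),
                       event = as.integer(times <= cens))
    expr <- rbind(gnull = x_null, geff = x_eff)
    colnames(expr) <- clin$sample_id
    beta <- cox_per_gene(expr, clin)
    if (abs(beta["gnull"]) < 0.1) hits_null <- hits_null + 1
    if (beta["geff"] > 0.5 && beta["geff"] < 1.1) hits_eff <- hits_eff + 1
  }
  expect_gte(hits_null, 9)
  expect_gte(hits_eff, 9)
})

test_that("cox_per_gene enforces the event-count precondition", {
  expr <- toy_matrix(2, 8)
  clin <- data.frame(sample_id = colnames(expr), time = 1:8, event = 0)
  expect_error(cox_per_gene(expr, clin), "zero observed events")
  clin$event <- c(1, rep(0, 7))
  expect_error(cox_per_gene(expr, clin), ">= 10")
})

test_that("cox_shift_test detects a shifted coefficient set and fails closed", {
  set.seed(17)
  bg <- rnorm(1500)
  names(bg) <- sprintf("g%04d", seq_along(bg))
  shifted <- names(bg)[1:25]
  bg[shifted] <- bg[shifted] + 1.0
  res <- cox_shift_test(shifted, bg, n_adjust = 200, seed = 2)
  expect_true(res$evaluable)
  expect_lt(res$adjusted_p, 0.05)
  # negative shift: one-sided p near 1, never significant
  neg <- names(bg)[26:50]
  bg[neg] <- bg[neg] - 2.0
  res2 <- cox_shift_test(neg, bg, n_adjust = 200, seed = 2)
  expect_gt(res2$raw_p, 0.9)
  # all-missing coefficients fail closed
  bg2 <- bg; bg2[shifted] <- NA
  res3 <- cox_shift_test(shifted, bg2, n_adjust = 50, seed = 2)
  expect_false(res3$evaluable)
  expect_false(res3$pass)
})

test_that("log-rank on identical groups gives statistic 0 and p exactly 1", {
  n <- 10
  expr <- matrix(rep(c(0.1, 0.9), each = n / 2), 1, n,
                 dimnames = list("g1", sprintf("S%02d", 1:n)))
  # both groups carry identical survival records
  clin <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     time = rep(c(1, 2, 3, 4, 5), 2),
                     event = rep(c(1, 1, 0, 1, 0), 2))
  res <- km_logrank_on_aggregate("g1", expr, clin, split = "module_mean")
  expect_true(res$evaluable)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("log-rank p is invariant under monotone transforms of time", {
  set.seed(23)
  n <- 60
  expr <- matrix(runif(n), 1, n, dimnames = list("g1", sprintf("S%02d", 1:n)))
  clin <- data.frame(sample_id = colnames(expr),
                     time = rexp(n, 0.2) + 0.01, event = rbinom(n, 1, 0.7))
  p1 <- km_logrank_on_aggregate("g1", expr, clin, split = "module_mean")$p
  clin2 <- clin; clin2$time <- log(1 + clin$time)
  p2 <- km_logrank_on_aggregate("g1", expr, clin2, split = "module_mean")$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("log-rank split on a CDF matrix puts the threshold near the median", {
  sim <- simulate_validation_cohorts(small_spec(seed = 6))
  ch <- sim$eff
  cdf <- ecdf_normalize(ch$matrices$expression)
  expect_equal(mean(cdf), 0.5, tolerance = 1e-6)
  genes <- rownames(cdf)[1:12]
  res <- km_logrank_on_aggregate(genes, cdf, ch$clinical)
  expect_true(res$evaluable)
  # near-balanced groups because the global mean sits at the rank midpoint
  expect_gt(min(res$n_high, res$n_low) / (res$n_high + res$n_low), 0.2)
})

test_that("validate_modules passes a planted module only where the effect exists", {
  spec <- small_spec(seed = 15)
  sim <- simulate_training_cohort(spec)
  cohorts <- simulate_validation_cohorts(spec, sim$truth)
  mod <- structure(list(module_id = "m1", type = "cis_cnv", effector = "chr2p",
                        regulators = character(),
                        targets = sim$truth[[1]]$targets),
                   class = "association_module")
  v <- validate_modules(list(m1 = mod), cohorts, n_background = 150,
                        n_adjust = 100, seed = 3)
  tab <- v$table
  expect_true(tab$all_pass[tab$cohort == "eff"])
  expect_false(tab$logrank_pass[tab$cohort == "null"])
  expect_false(v$overall[["m1"]])  # fails in the required null cohort
  v2 <- validate_modules(list(m1 = mod), cohorts, required_cohorts = "eff",
                         n_background = 150, n_adjust = 100, seed = 3)
  expect_true(v2$overall[["m1"]])
  # empty module list gives an empty result
  v0 <- validate_modules(list(), cohorts)
  expect_equal(nrow(v0$table), 0)
})
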