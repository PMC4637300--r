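test_that("tumor/normal ratio follows the per-role convention", {
  t_ex <- omics_matrix(matrix(4, 1, 2, dimnames = list("g1", c("S1", "S2"))),
                       "expression")
  n_ex <- omics_matrix(matrix(2, 1, 2, dimnames = list("g1", c("S1", "S2"))),
                       "expression")
  expect_equal(unname(unclass(tumor_normal_ratio(t_ex, n_ex))[1, 1]), 2.0)

  t_me <- omics_matrix(matrix(0.8, 1, 2, dimnames = list("g1", c("S1", "S2"))),
                       "methylation")
  n_me <- omics_matrix(matrix(0.3, 1, 2, dimnames = list("g1", c("S1", "S2"))),
                       "methylation")
  expect_equal(unname(unclass(tumor_normal_ratio(t_me, n_me))[1, 1]), 0.5)

  # zero denominator drops the feature with a warning
  tm <- omics_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                            dimnames = list(c("g1", "g2"), c("S1", "S2"))),
                     "expression")
  nm <- matrix(c(0, 1, 1, 1), 2, 2, dimnames = dimnames(tm))
  nm <- omics_matrix(nm, "expression")
  expect_warning(r <- tumor_normal_ratio(tm, nm), "non-positive")
  expect_identical(rownames(r), "g2")
})

test_that("ecdf_normalize computes mid-rank/(n+1) values", {
  m <- matrix(c(5.1, 2.3, 9.9, 2.3), 1, 4,
              dimnames = list("g1", paste0("S", 1:4)))
  # hand mid-ranks: (3, 1.5, 4, 1.5) / 5
  expect_equal(unname(ecdf_normalize(m)[1, ]), c(0.6, 0.3, 0.8, 0.3),
               tolerance = 1e-15, ignore_attr = TRUE)

  inc <- matrix(sort(rnorm(7)), 1, 7, dimnames = list("g", paste0("S", 1:7)))
  expect_equal(unname(ecdf_normalize(inc)[1, ]), (1:7) / 8, ignore_attr = TRUE)

  const <- matrix(3, 1, 5, dimnames = list("g", paste0("S", 1:5)))
  expect_equal(unname(ecdf_normalize(const)[1, ]), rep(0.5, 5), ignore_attr = TRUE)
})

test_that("ecdf_normalize is exactly invariant under monotone transforms", {
  m <- toy_matrix(10, 30)
  base <- ecdf_normalize(m)
  expect_identical(ecdf_normalize(exp(m)), base)
  expect_identical(ecdf_normalize(3 * m + 7), base)
  expect_identical(ecdf_normalize(m^3), base)
  expect_true(all(base > 0 & base < 1))
})

test_that("trinary probabilities: frozen value, sum-to-one, monotone, symmetric", {
  # direct evaluation of the closed form at y = 0.5
  tp <- trinary_probabilities(0.5)
  expect_equal(tp$up, 0.5 / (1 - log(0.5)), tolerance = 1e-15)
  expect_equal(tp$up, 0.295308, tolerance = 1e-6)
  expect_equal(tp$up, tp$down)
  expect_equal(tp$up + tp$down + tp$none, 1, tolerance = 1e-15)

  y <- seq(1e-4, 1 - 1e-4, length.out = 10000)
  g <- trinary_probabilities(y)
  expect_lt(max(abs(g$up + g$down + g$none - 1)), 1e-12)
  expect_true(all(diff(g$up) > 0))
  expect_true(all(g$up >= 0 & g$down >= 0 & g$none >= 0))
  sym <- trinary_probabilities(1 - y)
  expect_lt(max(abs(g$up - sym$down)), 1e-12)

  # boundary behaviour
  expect_gt(trinary_probabilities(1 - 1e-12)$up, 1 - 1e-10)
  expect_lt(trinary_probabilities(1 - 1e-12)$down, 1e-10)
  expect_error(trinary_probabilities(0), "strictly")
  expect_error(trinary_probabilities(1.2), "strictly")
})

test_that("aggregate_by_group takes per-sample medians and drops empty groups", {
  m <- matrix(c(0.2, 0.4, 0.9, 0.2, 0.4, 0.9), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("S1", "S2")))
  g3 <- c(p1 = "A", p2 = "A", p3 = "A")
  expect_equal(unname(aggregate_by_group(m, g3)["A", ]), c(0.4, 0.4),
               ignore_attr = TRUE)
  g2 <- c(p1 = "A", p2 = "A")
  expect_equal(unname(aggregate_by_group(m, g2)["A", "S1"]), 0.3)
  g1 <- c(p3 = "B")
  expect_equal(unname(aggregate_by_group(m, g1)["B", "S1"]), 0.9)
  expect_warning(aggregate_by_group(m, c(p1 = "A", zz = "C")), "empty")
})

test_that("aggregation commutes with sample permutation", {
  m <- toy_matrix(9, 12, prefix = "p")
  grouping <- setNames(rep(c("A", "B", "C"), each = 3), rownames(m))
  agg <- aggregate_by_group(m, grouping)
  perm <- sample(ncol(m))
  expect_equal(aggregate_by_group(m[, perm], grouping), agg[, perm])
})

test_that("arm_cnv_matrix groups probes by annotated arm", {
  m <- toy_matrix(6, 5, prefix = "cp")
  ann <- data.frame(gene_id = rownames(m), chromosome = c(1, 1, 1, 2, 2, 2),
                    arm = c("p", "p", "q", "p", "p", "p"), position = 1:6)
  arm <- arm_cnv_matrix(m, ann)
  expect_setequal(rownames(arm), c("chr1p", "chr1q", "chr2p"))
  expect_equal(arm["chr1q", ], m["cp03", ])
  expect_equal(arm["chr2p", "S01"], median(m[4:6, "S01"]))
})
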