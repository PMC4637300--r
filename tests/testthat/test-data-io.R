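test_that("omics matrix TSV round-trips and enforces the dialect", {
  m <- toy_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, "expression")
  expect_equal(unclass(back), m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(m))
  expect_error(read_omics_matrix(file.path(tempdir(), "nope.tsv"), "expression"),
               "nope.tsv")
})

test_that("reader drops high-missingness features and median-imputes the rest", {
  m <- toy_matrix(5, 10)
  m[1, 1:6] <- NA  # 60% missing -> dropped
  m[2, 1] <- NA    # 10% missing -> imputed
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, "expression")
  expect_false("g01" %in% rownames(back))
  expect_equal(unname(back["g02", "S01"]), median(m[2, -1]))
})

test_that("non-numeric cells are reported with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "g1\t1.0\toops", "g2\t2\t3"), path)
  expect_error(read_omics_matrix(path, "expression"), "non-numeric")
})

test_that("cohort alignment keeps the clinical sample order and drops extras", {
  m <- toy_matrix(6, 5)
  clin <- data.frame(sample_id = c("S04", "S02", "S01"), time = c(3, 2, 1),
                     event = c(1, 0, 1))
  ann <- data.frame(gene_id = rownames(m), chromosome = 1, arm = "p",
                    position = seq_len(6))
  expect_warning(
    b <- cohort_bundle("t", list(expression = omics_matrix(m, "expression")),
                       ann, clin),
    "dropping")
  expect_identical(b$samples, c("S04", "S02", "S01"))
  expect_identical(colnames(b$matrices$expression), c("S04", "S02", "S01"))
  # idempotence: same inputs give identical bundles
  b2 <- suppressWarnings(
    cohort_bundle("t", list(expression = omics_matrix(m, "expression")), ann, clin))
  expect_identical(b, b2)
  # empty intersection is fatal
  clin_bad <- data.frame(sample_id = c("X1", "X2"), time = 1:2, event = c(1, 1))
  expect_error(suppressWarnings(
    cohort_bundle("t", list(expression = omics_matrix(m, "expression")),
                  ann, clin_bad)), "intersection")
})

test_that("load_cohort reads matrices, annotation and clinical from disk", {
  d <- withr::local_tempdir()
  m <- toy_matrix(4, 6)
  write_omics_matrix(m, file.path(d, "expr.tsv"))
  ann <- data.frame(gene_id = rownames(m), chromosome = 2, arm = "q",
                    position = 1:4)
  write.table(ann, file.path(d, "ann.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  clin <- data.frame(sample_id = colnames(m), time = 1:6, event = rep(c(0, 1), 3),
                     gender = "female", cohort = "t")
  write.table(clin, file.path(d, "clin.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  b <- load_cohort(list(name = "t",
                        matrices = list(expression = list(path = file.path(d, "expr.tsv"),
                                                          role = "expression")),
                        annotation = file.path(d, "ann.tsv"),
                        clinical = file.path(d, "clin.tsv")))
  expect_s3_class(b, "cohort_bundle")
  expect_length(b$samples, 6)
})

test_that("validation report round-trips losslessly and rejects empty input", {
  tab <- data.frame(module_id = rep(c("m1", "m2", "m3"), each = 4),
                    cohort = rep(c("a", "b", "c", "d"), 3),
                    coherence_adjusted_p = runif(12),
                    logrank_p = exp(-runif(12) * 20),
                    all_pass = rep(c(TRUE, FALSE), 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_report(tab, path)
  back <- read_validation_report(path)
  expect_equal(nrow(back), 12)
  expect_equal(back$coherence_adjusted_p, tab$coherence_adjusted_p,
               tolerance = 1e-12)
  expect_equal(back$logrank_p, tab$logrank_p, tolerance = 1e-12)
  expect_identical(back$all_pass, tab$all_pass)
  expect_error(write_validation_report(tab[0, ], path), "empty")
})

test_that("GMT and citation tables parse", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setB, c("g2", "g4"))

  cpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("g1", "g2", "g3"), count = c(5, 9, 5)),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  cc <- read_citation_counts(cpath)
  expect_identical(cc$gene_id, c("g2", "g1", "g3"))
})
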