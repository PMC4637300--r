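#' Construct a role-tagged omics matrix
#'
#' A light container for a numeric features-by-samples matrix carrying the
#' data role it plays in the analysis.  Rows are probes or genes, columns
#' are samples.
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids).
#' @param role one of `"expression"`, `"cnv_probe"`, `"methylation"`.
#' @return An object of class `omics_matrix`: the matrix with a `role`
#'   attribute.
#' @export
omics_matrix <- function(values, role = c("expression", "cnv_probe", "methylation")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("omics matrix values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("omics matrix requires feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate feature ids in omics matrix")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids in omics matrix")
  if (role == "methylation") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stopf("methylation beta values must lie in [0,1]")
  }
  structure(values, role = role, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix role=%s: %d features x %d samples>\n",
              attr(x, "role"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a TSV omics matrix
#'
#' Dialect: UTF-8 TSV, first row sample ids, first column feature ids,
#' "NA" for missing.  Features with more than `max_missing` missing values
#' are dropped; remaining missing entries are imputed with the feature
#' median (rank-neutral under the downstream CDF transform).
#'
#' @param path file path.
#' @param role data role, see [omics_matrix()].
#' @param max_missing maximum tolerated fraction of missing entries per
#'   feature before the feature is dropped (default 0.2).
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, role, max_missing = 0.2) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))) & !is.na(df[[bad]]))[1]
    stopf("non-numeric cell in %s at row '%s', column '%s'",
          path, rownames(df)[badrow %||% 1], colnames(df)[bad])
  }
  miss <- rowMeans(is.na(m))
  if (any(miss > max_missing)) {
    m <- m[miss <= max_missing, , drop = FALSE]
  }
  if (anyNA(m)) {
    for (i in which(rowSums(is.na(m)) > 0L)) {
      v <- m[i, ]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      m[i, ] <- v
    }
  }
  omics_matrix(m, role)
}

#' Write an omics matrix in the package TSV dialect
#' @param x matrix with dimnames.
#' @param path output path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x),
                   check.names = FALSE), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/probe annotation table
#'
#' Expects TSV columns `gene_id`, `chromosome`, `arm` (p/q), `position`.
#' Features without a p/q arm annotation are dropped with a warning.
#'
#' @param path file path.
#' @return data.frame with an `arm_id` column `"chr{chromosome}{arm}"`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_annotation(df)
}

#' Validate and normalize an annotation data frame
#' @param df data.frame with columns gene_id, chromosome, arm, position.
#' @return the validated data.frame with an added `arm_id` column.
#' @export
validate_annotation <- function(df) {
  need <- c("gene_id", "chromosome", "arm", "position")
  if (!all(need %in% names(df))) {
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  }
  bad_arm <- !(df$arm %in% c("p", "q"))
  if (any(bad_arm)) {
    warnf("dropping %d annotation rows with arm not in {p,q}", sum(bad_arm))
    df <- df[!bad_arm, , drop = FALSE]
  }
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in annotation")
  if (any(df$position < 0)) stopf("annotation positions must be >= 0")
  df$arm_id <- paste0("chr", df$chromosome, df$arm)
  df
}

#' Read a clinical table
#'
#' TSV columns: `sample_id`, `time` (> 0, any consistent unit), `event`
#' (0/1 death indicator), `gender`, `cohort`.
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_clinical(df)
}

#' Validate a clinical data frame
#' @param df data.frame with at least sample_id, time, event.
#' @return the validated data.frame.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stopf("clinical table must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in clinical table")
  if (any(df$time <= 0)) stopf("survival times must be > 0")
  if (!all(df$event %in% c(0, 1))) stopf("event must be 0/1")
  if (is.null(df$gender)) df$gender <- "unknown"
  if (is.null(df$cohort)) df$cohort <- "cohort"
  df
}

#' Assemble a cohort bundle
#'
#' Aligns the sample columns of all matrices to the clinical table (when
#' present), preserving the clinical table's sample order; samples absent
#' from the intersection are dropped with a warning.
#'
#' @param name cohort name.
#' @param matrices named list of [omics_matrix()] objects.
#' @param annotation gene annotation data.frame (see [read_annotation()]).
#' @param clinical optional clinical data.frame.
#' @return object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(name, matrices, annotation, clinical = NULL) {
  stopifnot(is.list(matrices), length(matrices) > 0)
  annotation <- validate_annotation(annotation)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  if (!is.null(clinical)) {
    clinical <- validate_clinical(clinical)
    shared <- clinical$sample_id[clinical$sample_id %in% shared]
  }
  if (length(shared) == 0) stopf("empty sample intersection in cohort '%s'", name)
  dropped <- unique(unlist(lapply(matrices, function(m) setdiff(colnames(m), shared))))
  if (length(dropped)) {
    warnf("cohort '%s': dropping %d unmatched samples (%s%s)", name,
          length(dropped), paste(utils::head(dropped, 3), collapse = ", "),
          if (length(dropped) > 3) ", ..." else "")
  }
  matrices <- lapply(matrices, function(m) {
    omics_matrix(unclass(m)[, shared, drop = FALSE], attr(m, "role"))
  })
  if (!is.null(clinical)) clinical <- clinical[match(shared, clinical$sample_id), ]
  structure(list(name = name, matrices = matrices, clinical = clinical,
                 annotation = annotation, samples = shared),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle '%s': %d samples, matrices: %s%s>\n", x$name,
              length(x$samples), paste(names(x$matrices), collapse = ", "),
              if (is.null(x$clinical)) "" else ", clinical"))
  invisible(x)
}

#' Load a cohort from files
#'
#' @param entry list with elements `name`, `matrices` (named list of
#'   `list(path=, role=)`), `annotation` (path), optional `clinical` (path).
#' @return a [cohort_bundle()].
#' @export
load_cohort <- function(entry) {
  mats <- lapply(entry$matrices, function(m) read_omics_matrix(m$path, m$role))
  ann <- read_annotation(entry$annotation)
  clin <- if (!is.null(entry$clinical)) read_clinical(entry$clinical) else NULL
  cohort_bundle(entry$name, mats, ann, clin)
}

#' Read a GMT gene-set collection
#' @param path GMT file (set name, description, genes; tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Read an offline gene citation-count table
#' @param path two-column TSV `gene_id`, `count`.
#' @return data.frame sorted by count descending, gene_id ascending.
#' @export
read_citation_counts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "count") %in% names(df))) {
    stopf("citation table must have columns gene_id, count")
  }
  df[order(-df$count, df$gene_id), ]
}

#' Write a module validation report
#'
#' One TSV row per (module, cohort) with statistics, raw/adjusted p-values
#' and pass flags; round-trips through [read_validation_report()].
#'
#' @param results a `module_validation` object or its `table` data.frame.
#' @param path output TSV path.
#' @export
write_validation_report <- function(results, path) {
  tab <- if (inherits(results, "module_validation")) results$table else results
  if (is.null(tab) || nrow(tab) == 0) stopf("empty validation results")
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module validation report written by [write_validation_report()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_validation_report <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  for (nm in names(df)) {
    if (is.character(df[[nm]]) && all(!is.na(suppressWarnings(as.numeric(df[[nm]]))) |
                                      is.na(df[[nm]]))) {
      suppressWarnings({
        conv <- as.numeric(df[[nm]])
        if (!anyNA(conv[!is.na(df[[nm]])])) df[[nm]] <- conv
      })
    }
    if (all(df[[nm]] %in% c("TRUE", "FALSE", NA))) df[[nm]] <- as.logical(df[[nm]])
  }
  df
}
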