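#' Tumor/normal ratio (or beta difference) per feature
#'
#' Expression and CNV values are compared as element-wise tumor/normal
#' ratios.  Methylation beta values are already on a bounded [0,1] scale,
#' so the tumor - normal difference is used instead, preserving a bounded
#' [-1,1] result; downstream screening uses correlations, which do not
#' depend on this affine choice.
#'
#' @param tumor,normal [omics_matrix()] objects with identical feature ids
#'   and paired sample columns, same role.
#' @return an `omics_matrix` of ratios (or differences for methylation).
#'   Features with a non-positive normal value in any sample (ratio roles
#'   only) are dropped with a warning.
#' @export
tumor_normal_ratio <- function(tumor, normal) {
  role <- attr(tumor, "role")
  if (!identical(role, attr(normal, "role"))) stopf("tumor/normal role mismatch")
  if (!identical(rownames(tumor), rownames(normal)) ||
      !identical(colnames(tumor), colnames(normal))) {
    stopf("tumor and normal matrices must share feature and sample ids")
  }
  tm <- unclass(tumor); nm <- unclass(normal)
  if (role == "methylation") {
    d <- tm - nm
    # differences leave [0,1]; keep as plain matrix with methylation role tag
    out <- structure(d, role = "methylation_diff",
                     class = c("omics_matrix", "matrix", "array"))
    return(out)
  }
  bad <- rowSums(nm <= 0) > 0
  if (any(bad)) {
    warnf("dropping %d features with non-positive normal values", sum(bad))
    tm <- tm[!bad, , drop = FALSE]; nm <- nm[!bad, , drop = FALSE]
  }
  omics_matrix(tm / nm, role)
}

#' Rank-CDF normalization of each feature across a cohort
#'
#' Each row is replaced by mid-rank/(n+1) values, mapping any strictly
#' monotone transform of the data to the same output and keeping values
#' strictly inside (0,1) (so the trinary transform's logarithms are always
#' defined).  Constant rows map to 0.5 everywhere.
#'
#' @param m numeric matrix (features x samples).
#' @return matrix of the same shape with values in (0,1).
#' @export
ecdf_normalize <- function(m) {
  m <- unclass(m)
  if (anyNA(m)) stopf("ecdf_normalize: missing values must be imputed first")
  n <- ncol(m)
  out <- t(apply(m, 1, function(v) rank(v, ties.method = "average"))) / (n + 1)
  dimnames(out) <- dimnames(m)
  out
}

#' Trinary state probabilities from a CDF value
#'
#' Converts rank-CDF values y in (0,1) into soft probabilities over the
#' hidden trinary state x in \{up = +1, down = -1, no-change = 0\}:
#' \deqn{P(x=1|y) = y / (1 - \ln y)}
#' \deqn{P(x=-1|y) = (1-y) / (1 - \ln(1-y))}
#' \deqn{P(x=0|y) = 1 - P(x=1|y) - P(x=-1|y)}
#' The triple sums to one, P(x=1|y) is strictly increasing in y, and the
#' symmetry P(x=1|y) = P(x=-1|1-y) holds exactly.
#'
#' @param y numeric vector or matrix of CDF values, all in (0,1).
#' @return a list with elements `up`, `down`, `none` of the same shape as
#'   `y`, plus `ex` = E[x|y] = up - down.
#' @export
trinary_probabilities <- function(y) {
  v <- unclass(y)
  if (any(v <= 0 | v >= 1)) stopf("trinary_probabilities: y must lie strictly in (0,1)")
  up <- v / (1 - log(v))
  down <- (1 - v) / (1 - log(1 - v))
  none <- 1 - up - down
  list(up = up, down = down, none = none, ex = up - down)
}

#' Median aggregation of features into groups
#'
#' Used both to summarize multiple probes of a gene into one value and to
#' summarize CNV probes on a chromosome arm into an arm-level proxy value
#' (the median over member probes, per sample).
#'
#' @param m numeric matrix (features x samples).
#' @param grouping named character vector mapping feature id -> group id.
#'   Features absent from the map are ignored; empty groups are omitted
#'   with a warning.
#' @return matrix with one row per group (sorted by group id).
#' @export
aggregate_by_group <- function(m, grouping) {
  m <- unclass(m)
  feats <- intersect(rownames(m), names(grouping))
  groups <- sort(unique(grouping[feats]))
  empty <- setdiff(unique(grouping), groups)
  if (length(empty)) warnf("omitting %d empty groups", length(empty))
  out <- matrix(NA_real_, length(groups), ncol(m),
                dimnames = list(groups, colnames(m)))
  idx <- split(feats, grouping[feats])
  for (g in groups) {
    sub <- m[idx[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median)
  }
  out
}

#' Arm-level CNV matrix from probe-level CNV
#'
#' Chromosome arms serve as natural segmentation boundaries: the proxy CNV
#' value of an arm in a sample is the median over its probes' values.
#'
#' @param cnv probe-level CNV matrix (tumor/normal ratios), probes x samples.
#' @param probe_annotation annotation data.frame for the probes (columns
#'   gene_id = probe id, chromosome, arm, position).
#' @return matrix with rows `"chr{c}{arm}"`, one per arm with >= 1 probe.
#' @export
arm_cnv_matrix <- function(cnv, probe_annotation) {
  ann <- validate_annotation(probe_annotation)
  grouping <- stats::setNames(ann$arm_id, ann$gene_id)
  aggregate_by_group(cnv, grouping)
}

#' Select methylation effector features by variability
#'
#' Candidate methylation effectors are genes whose tumor-normal beta
#' difference shows sufficient variation across subjects.
#'
#' @param meth methylation difference matrix (genes x samples).
#' @param min_sd minimum across-sample standard deviation (default 0.1).
#' @return row-subset of `meth`.
#' @export
select_methylation_effectors <- function(meth, min_sd = 0.1) {
  m <- unclass(meth)
  sds <- apply(m, 1, stats::sd)
  m[sds >= min_sd, , drop = FALSE]
}
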