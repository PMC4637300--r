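#' Two-block partial least squares by NIPALS
#'
#' Fits a PLS model between two sample-matched blocks of variables
#' (typically the target-gene expressions of two association modules).
#' Components are extracted by NIPALS iteration to tolerance `tol`; in
#' the default regression (PLS2) mode X is deflated by t p' and Y by
#' t c', so components are ordered by their covariance with the response
#' block.  The canonical mode (symmetric deflation of Y by its own
#' scores) is available since the two blocks may both be target sets.
#'
#' @param X samples x p numeric matrix (predictor block).
#' @param Y samples x q numeric matrix (response block).
#' @param M number of components (0 allowed: returns the centered data
#'   with no components); must not exceed min(rank X, rank Y).
#' @param mode `"regression"` (default) or `"canonical"`.
#' @param tol NIPALS convergence tolerance (default 1e-10).
#' @param max_iter maximum NIPALS iterations per component.
#' @return object of class `pls_fit`: `scores` (T, n x M), `loadings`
#'   (P, p x M), `weights` (W, p x M), `y_weights` (C, q x M),
#'   `y_scores` (U), `residual` (E_M, deflated X), `X_center`,
#'   `Y_center`, `X0`, `Y0` (centered blocks), `M`.
#' @export
fit_pls <- function(X, Y, M = 2, mode = c("regression", "canonical"),
                    tol = 1e-10, max_iter = 5000) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same samples (rows)")
  if (nrow(X) < 3) stopf("need >= 3 samples")
  drop_const <- function(m, label) {
    v <- apply(m, 2, stats::var)
    if (any(v == 0)) {
      warnf("dropping %d zero-variance %s columns", sum(v == 0), label)
      m <- m[, v > 0, drop = FALSE]
    }
    m
  }
  X <- drop_const(X, "X"); Y <- drop_const(Y, "Y")
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  Ex <- Xc; Ey <- Yc
  n <- nrow(Xc)
  Tm <- matrix(0, n, M); U <- matrix(0, n, M)
  W <- matrix(0, ncol(Xc), M); P <- matrix(0, ncol(Xc), M)
  C <- matrix(0, ncol(Yc), M)
  for (m in seq_len(M)) {
    u <- Ey[, which.max(apply(Ey, 2, stats::var))]
    t_old <- rep(0, n)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Ex, u)
      w <- w / sqrt(sum(w^2))
      t <- Ex %*% w
      cvec <- crossprod(Ey, t) / sum(t^2)
      u <- Ey %*% cvec / sum(cvec^2)
      if (sqrt(sum((t - t_old)^2)) < tol * max(1, sqrt(sum(t^2)))) {
        conv <- TRUE
        break
      }
      t_old <- t
    }
    if (!conv) stopf("NIPALS did not converge for component %d after %d iterations",
                     m, max_iter)
    p <- crossprod(Ex, t) / sum(t^2)
    Ex <- Ex - t %*% t(p)
    if (mode == "regression") {
      Ey <- Ey - t %*% t(cvec)
    } else {
      Ey <- Ey - u %*% t(crossprod(Ey, u) / sum(u^2))
    }
    Tm[, m] <- t; U[, m] <- u
    W[, m] <- w; P[, m] <- p; C[, m] <- cvec
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(C) <- colnames(Y)
  structure(list(scores = Tm, loadings = P, weights = W, y_weights = C,
                 y_scores = U, residual = Ex, X_center = xc, Y_center = yc,
                 X0 = Xc, Y0 = Yc, M = M, mode = mode),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit (%s mode): %d components, X %d x %d, Y %d x %d>\n",
              x$mode, x$M, nrow(x$X0), ncol(x$X0), nrow(x$Y0), ncol(x$Y0)))
  if (x$M >= 1) {
    r2 <- vapply(seq_len(x$M), function(m) cumulative_r2(x, m = m), 0)
    cat("  cumulative R2 of Y:", paste(sprintf("%.3f", r2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cumulative R-squared of the response block
#'
#' Fraction of the centered Y block's total variance reconstructed by the
#' first `m` components: R2(m) = 1 - ||Yc - sum_k<=m t_k c_k'||_F^2 /
#' ||Yc||_F^2.  Non-decreasing in m.
#'
#' @param model a `pls_fit`.
#' @param m number of components to retain (1..M).
#' @return numeric scalar.
#' @export
cumulative_r2 <- function(model, m = model$M) {
  stopifnot(m >= 1, m <= model$M)
  Yhat <- model$scores[, seq_len(m), drop = FALSE] %*%
    t(model$y_weights[, seq_len(m), drop = FALSE])
  1 - sum((model$Y0 - Yhat)^2) / sum(model$Y0^2)
}

#' Correlation-circle coordinates of both blocks
#'
#' Each variable of X and Y is placed at its Pearson correlations with
#' the first two component scores; angular proximity of two variables on
#' the circle encodes their correlation as projected onto these axes.
#' Constant columns get coordinate (0,0) and are flagged.
#'
#' @param model a `pls_fit` with M >= 2.
#' @return data.frame: variable, block, c1, c2, constant.
#' @export
correlation_circle <- function(model) {
  if (model$M < 2) stopf("correlation_circle requires >= 2 components")
  t1 <- model$scores[, 1]; t2 <- model$scores[, 2]
  coord <- function(m, block) {
    sds <- apply(m, 2, stats::sd)
    c1 <- rep(0, ncol(m)); c2 <- rep(0, ncol(m))
    ok <- sds > 0
    c1[ok] <- suppressWarnings(as.vector(stats::cor(m[, ok, drop = FALSE], t1)))
    c2[ok] <- suppressWarnings(as.vector(stats::cor(m[, ok, drop = FALSE], t2)))
    data.frame(variable = colnames(m) %||% paste0(block, seq_len(ncol(m))),
               block = block, c1 = c1, c2 = c2, constant = !ok)
  }
  rbind(coord(model$X0, "X"), coord(model$Y0, "Y"))
}

#' Write correlation-circle coordinates as TSV
#' @param coords data.frame from [correlation_circle()].
#' @param path output path.
#' @export
write_correlation_circle <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Effector-arm versus target-correlation shift
#'
#' Tests whether a focal chromosome arm's CNV profile correlates with a
#' set of target gene expressions more strongly than background arms do:
#' Pearson correlations of the focal arm with every target are compared
#' with the pooled correlations of the background arms with the same
#' targets by a one-sided (positive-shift) KS test.
#'
#' @param focal_arm numeric vector: the focal arm's CNV values per sample.
#' @param other_arms matrix of background arm CNV rows (arms x samples).
#' @param targets matrix of target expression rows (genes x samples),
#'   same samples; needs >= 5 targets.
#' @return list: focal_correlations, background_correlations, D, p.
#' @export
effector_target_shift <- function(focal_arm, other_arms, targets) {
  targets <- unclass(targets)
  other_arms <- if (is.null(dim(other_arms))) matrix(other_arms, nrow = 1) else unclass(other_arms)
  if (nrow(targets) < 5) stopf("need >= 5 targets")
  r_focal <- suppressWarnings(as.vector(stats::cor(focal_arm, t(targets))))
  r_bg <- suppressWarnings(as.vector(stats::cor(t(other_arms), t(targets))))
  r_focal <- r_focal[is.finite(r_focal)]
  r_bg <- r_bg[is.finite(r_bg)]
  ks <- ks_compare(r_focal, r_bg, side = "greater")
  list(focal_correlations = r_focal, background_correlations = r_bg,
       D = ks$D, p = ks$p)
}
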