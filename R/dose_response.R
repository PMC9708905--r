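#' Fit per-feature linear concentration-response models
#'
#' For every feature fits an ordinary-least-squares model of log-scale
#' expression on compound concentration, optionally adjusting for cell system
#' with indicator covariates:
#' `expression ~ beta0 + beta1 * concentration (+ beta2 * cell_system) + eps`.
#' `beta1` is the concentration-response slope in expression units per
#' micromolar; a two-sided p-value comes from the t distribution with the
#' residual degrees of freedom, and FDR from [bh_adjust()] across all
#' features jointly.
#'
#' Features with exactly zero residual variance cannot carry a finite
#' t-statistic: when `beta1 != 0` they get `p = 0` and the `degenerate` flag
#' (a perfect noiseless line); when the feature is flat (`beta1 == 0`) they
#' get `t = 0, p = 1`. Flagged features are placed at the extremes of any
#' downstream t-ranking (see [rank_genes()]).
#'
#' Missing values are dropped per feature (pairwise deletion); features left
#' with fewer residual degrees of freedom than 1 get `NA` statistics and the
#' `degenerate` flag.
#'
#' @param em An [expression_matrix()].
#' @param adjust_for_cell_system Logical; include cell-system indicator
#'   covariates (the combined, "core gene" model). Default `TRUE` when more
#'   than one cell system is present.
#' @return A data.frame of class `dose_response_stats` with columns
#'   `feature`, `beta0`, `beta1`, `beta1_se`, `t_stat`, `p_value`, `fdr`,
#'   `n_obs`, `degenerate`.
#' @export
fit_dose_response <- function(em,
                              adjust_for_cell_system =
                                length(unique(em$sample_meta$cell_system)) > 1L) {
  stopifnot(inherits(em, "expression_matrix"))
  meta <- em$sample_meta
  conc <- as.numeric(meta$concentration)
  if (length(unique(conc)) < 2L)
    stop("design error: need >= 2 distinct concentrations")
  if (!adjust_for_cell_system && length(unique(conc)) < 3L)
    stop("design error: need >= 3 distinct concentrations without the ",
         "cell-system covariate")
  if (adjust_for_cell_system && length(unique(meta$cell_system)) > 1L) {
    X <- stats::model.matrix(~ factor(cell_system) + concentration,
                             data = data.frame(cell_system = meta$cell_system,
                                               concentration = conc))
  } else {
    X <- cbind(`(Intercept)` = 1, concentration = conc)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design error: rank-deficient design matrix")
  n <- nrow(X)
  df <- n - p
  if (df < 1L) stop("design error: no residual degrees of freedom")
  Y <- em$values
  slope_col <- which(colnames(X) == "concentration")

  if (anyNA(Y)) {
    res <- t(apply(Y, 1L, function(y) ols_one(y, X, slope_col)))
  } else {
    XtXi <- chol2inv(chol(crossprod(X)))
    B <- XtXi %*% crossprod(X, t(Y))          # p x features
    resid <- t(Y) - X %*% B
    rss <- colSums(resid^2)
    s2 <- rss / df
    beta1 <- B[slope_col, ]
    se1 <- sqrt(s2 * XtXi[slope_col, slope_col])
    res <- cbind(beta0 = B[1L, ], beta1 = beta1, beta1_se = se1,
                 rss = rss, n_obs = n, df = df)
  }
  res <- as.data.frame(res)
  scale_ref <- pmax(abs(res$beta0) + abs(res$beta1), 1)
  degenerate <- res$rss <= (1e-12 * scale_ref)^2 * res$n_obs | res$df < 1L
  t_stat <- ifelse(res$beta1_se > 0, res$beta1 / res$beta1_se, 0)
  p_value <- 2 * pt(-abs(t_stat), df = pmax(res$df, 1L))
  # zero-residual fits: perfect nonflat line -> p = 0 (flagged); flat -> p = 1
  zero_rss <- degenerate & res$df >= 1L
  flat <- abs(res$beta1) <= 1e-12 * scale_ref
  p_value[zero_rss & !flat] <- 0
  t_stat[zero_rss & !flat] <- 0   # replaced by extreme rank placement later
  p_value[zero_rss & flat] <- 1
  t_stat[zero_rss & flat] <- 0
  res$beta1[zero_rss & flat] <- 0
  p_value[res$df < 1L] <- NA_real_
  out <- data.frame(feature = rownames(Y),
                    beta0 = res$beta0, beta1 = res$beta1,
                    beta1_se = res$beta1_se, t_stat = t_stat,
                    p_value = p_value, fdr = NA_real_,
                    n_obs = as.integer(res$n_obs),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  class(out) <- c("dose_response_stats", "data.frame")
  out
}

# single-feature OLS with NA dropping; returns the row layout used above
ols_one <- function(y, X, slope_col) {
  keep <- !is.na(y)
  n <- sum(keep)
  p <- ncol(X)
  if (n < p + 1L)
    return(c(beta0 = NA_real_, beta1 = NA_real_, beta1_se = NA_real_,
             rss = NA_real_, n_obs = n, df = n - p))
  Xk <- X[keep, , drop = FALSE]
  fit <- stats::lm.fit(Xk, y[keep])
  XtXi <- chol2inv(chol(crossprod(Xk)))
  rss <- sum(fit$residuals^2)
  s2 <- rss / fit$df.residual
  c(beta0 = unname(fit$coefficients[1L]),
    beta1 = unname(fit$coefficients[slope_col]),
    beta1_se = sqrt(s2 * XtXi[slope_col, slope_col]),
    rss = rss, n_obs = n, df = fit$df.residual)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with order statistics `p_(1) <= ... <=
#' p_(m)`, the adjusted value at rank i is `min_{j >= i} p_(j) * m / j`,
#' capped at 1 and returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p)) stop("NA/NaN p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[order(o)]
}

#' Compute a systems response profile (treatment vs vehicle contrast)
#'
#' Per-feature pairwise comparison of one treatment concentration against the
#' vehicle control: `log2_fc = mean(treated) - mean(control)` (inputs are
#' log2-scale), two-sided equal-variance two-sample t-test, BH adjustment
#' across features. With one replicate per group the fold change is reported
#' and the p-value is `NA`. Zero pooled variance with a non-zero fold change
#' yields `p = 0` plus the `degenerate` flag.
#'
#' @param em An [expression_matrix()].
#' @param treatment_level,control_level Concentration values selecting the
#'   two groups.
#' @param cell_system Optional; restrict the contrast to one cell system.
#' @return data.frame of class `srp_result`: `feature`, `log2_fc`, `t_stat`,
#'   `p_value`, `fdr`, `contrast`, `degenerate`.
#' @export
compute_srp <- function(em, treatment_level, control_level = 0,
                        cell_system = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  meta <- em$sample_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_system)) keep <- meta$cell_system %in% cell_system
  trt <- keep & meta$concentration == treatment_level
  ctl <- keep & meta$concentration == control_level
  if (!any(trt)) stop("treatment level ", treatment_level, " not present")
  if (!any(ctl)) stop("control level ", control_level, " not present")
  Yt <- em$values[, trt, drop = FALSE]
  Yc <- em$values[, ctl, drop = FALSE]
  n1 <- ncol(Yt); n0 <- ncol(Yc)
  m1 <- rowMeans(Yt); m0 <- rowMeans(Yc)
  fc <- m1 - m0
  if (n1 >= 2L && n0 >= 2L) {
    v1 <- apply(Yt, 1L, stats::var)
    v0 <- apply(Yc, 1L, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    t_stat <- ifelse(se > 0, fc / se, 0)
    p <- 2 * pt(-abs(t_stat), df = n1 + n0 - 2)
    degenerate <- se == 0 & fc != 0
    p[degenerate] <- 0
    p[se == 0 & fc == 0] <- 1
  } else {
    t_stat <- rep(NA_real_, length(fc))
    p <- rep(NA_real_, length(fc))
    degenerate <- rep(FALSE, length(fc))
  }
  out <- data.frame(feature = rownames(em$values), log2_fc = fc,
                    t_stat = t_stat, p_value = p, fdr = NA_real_,
                    contrast = paste0(treatment_level, "_vs_", control_level),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  class(out) <- c("srp_result", "data.frame")
  out
}

#' Pearson correlation between two per-concentration feature profiles
#'
#' Used to relate a protein's concentration-response profile to the
#' matching transcript's. Requires at least 3 paired points and non-zero
#' variance on both sides; otherwise returns `NA` with attribute
#' `flagged = TRUE`.
#'
#' @param profile_a,profile_b Numeric vectors of equal length (e.g. per
#'   concentration mean log2 fold changes).
#' @return Pearson r in `[-1, 1]`, or flagged `NA`.
#' @export
correlate_features <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b))
  keep <- complete.cases(profile_a, profile_b)
  a <- profile_a[keep]; b <- profile_b[keep]
  if (length(a) < 3L) stop("need >= 3 paired points")
  if (sd(a) == 0 || sd(b) == 0)
    return(structure(NA_real_, flagged = TRUE))
  cor(a, b)
}
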