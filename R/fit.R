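#' Least-squares fit by singular value decomposition with truncated
#' singular values
#'
#' Solves the least-squares problem for a polynomial design by SVD,
#' zeroing singular values below `rel_tol` times the largest one. This
#' yields the minimum-norm solution on rank-deficient designs (e.g. a
#' duplicated column) instead of failing, and stabilizes the near-collinear
#' columns a raw-unit quadratic design produces (Xi vs Xi^2 over a narrow
#' trait range).
#'
#' Leverages h_ii are the diagonal of the hat matrix restricted to the
#' retained singular directions, predicted (leave-one-out, PRESS) residuals
#' are e_i / (1 - h_ii), and the residual standard deviation uses
#' denominator n - p with p the number of terms.
#'
#' @param design a `design_matrix`.
#' @param rel_tol relative truncation threshold for singular values
#'   (default 1e-10).
#' @return An `mlr_fit` object with components `slopes`, `fitted`, `resid`,
#'   `hat`, `pred_resid` (NA where h_ii is numerically 1), `hc3_cov`,
#'   `resid_sd`, `n`, `p`, `dof`, `rank`, plus the design and SVD factors
#'   used by downstream operations.
#' @export
fit_svd <- function(design, rel_tol = 1e-10) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$values
  y <- design$response
  n <- nrow(X)
  p <- ncol(X)
  if (n < 1L || p < 1L) stop("empty design")
  if (all(X == 0)) stop("all-zero design matrix")
  sv <- svd(X)
  keep <- sv$d > rel_tol * max(sv$d)
  r <- sum(keep)
  if (r == 0L) stop("design has numerical rank 0 at rel_tol = ", rel_tol)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  beta <- drop(V %*% ((crossprod(U, y)) / d))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  e <- y - fitted
  h <- rowSums(U^2)
  dof <- n - p
  resid_sd <- if (dof > 0) sqrt(sum(e^2) / dof) else NA_real_
  fit <- structure(
    list(slopes = beta, fitted = fitted, resid = e, hat = h,
         pred_resid = NULL, hc3_cov = NULL, resid_sd = resid_sd,
         n = n, p = p, dof = dof, rank = r, rel_tol = rel_tol,
         design = design, svd = list(u = U, v = V, d = d)),
    class = "mlr_fit"
  )
  fit$pred_resid <- tryCatch(predicted_residuals(fit), error = function(e) NULL)
  fit$hc3_cov <- hc3_covariance(fit)
  fit
}

#' Predicted (leave-one-out) residuals
#'
#' The predicted residual of record i, e_i / (1 - h_ii), equals the error
#' the model makes on record i when refitted without it (the PRESS
#' residual). It is the basis of all holdout performance measures and of
#' the error-nullity test.
#'
#' @param fit an `mlr_fit`.
#' @return Numeric vector of predicted residuals.
#' @export
predicted_residuals <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  tol <- max(fit$rel_tol, 1e-8)
  bad <- fit$hat >= 1 - tol
  if (any(bad)) {
    stop("holdout prediction undefined: leverage numerically 1 for record(s) ",
         paste(fit$design$record_id[bad], collapse = ", "))
  }
  fit$resid / (1 - fit$hat)
}

#' HC3 heteroskedasticity-consistent slope covariance
#'
#' The sandwich estimator
#' S = (X'X)^+ X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^+,
#' with inverses taken through the truncated pseudo-inverse of the fit.
#' The inner weights are the squared predicted residuals, so each record's
#' contribution is judged by its own holdout error; the square roots of
#' diag(S) are the robust standard deviations reported for the slopes.
#'
#' @param fit an `mlr_fit`.
#' @return p x p symmetric covariance matrix.
#' @export
hc3_covariance <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  w <- (fit$resid / (1 - fit$hat))^2
  # A = pseudo-inverse of X = V D^-1 U'
  A <- fit$svd$v %*% (t(fit$svd$u) / fit$svd$d)
  S <- A %*% (w * t(A))
  S <- (S + t(S)) / 2
  dimnames(S) <- list(names(fit$slopes), names(fit$slopes))
  S
}

#' Holdout and in-sample performance measures
#'
#' RMSE_HO and MAE_HO are the root-mean-square and mean-absolute predicted
#' (leave-one-out) residuals. R2_HO replaces the in-sample error sum of
#' squares with the predicted-residual sum in the coefficient of
#' determination; R2_adj is the adjusted in-sample coefficient.
#'
#' For models without an intercept term the total sum of squares is, by
#' default, uncentered (sum of y^2, `tss = "uncentered"`); `tss =
#' "centered"` forces the centered convention, and `tss = "auto"` (the
#' default) centers exactly when an intercept term is present. The
#' adjusted-R2 centering constant is 1 with an intercept and 0 without.
#'
#' @param fit an `mlr_fit`.
#' @param tss total-sum-of-squares convention: "auto", "uncentered" or
#'   "centered".
#' @return A `measures` list: `rmse_ho`, `mae_ho`, `r2_adj`, `r2_ho`,
#'   plus `r2` and the convention used.
#' @export
performance_measures <- function(fit, tss = c("auto", "uncentered", "centered")) {
  stopifnot(inherits(fit, "mlr_fit"))
  tss <- match.arg(tss)
  y <- fit$design$response
  has_intercept <- "intercept" %in% fit$design$terms$kind
  centered <- switch(tss, auto = has_intercept,
                     uncentered = FALSE, centered = TRUE)
  TSS <- if (centered) sum((y - mean(y))^2) else sum(y^2)
  if (TSS <= 0) stop("total sum of squares is zero; R2 undefined")
  cc <- if (has_intercept) 1 else 0
  pr <- predicted_residuals(fit)
  SSE <- sum(fit$resid^2)
  r2 <- 1 - SSE / TSS
  structure(
    list(rmse_ho = sqrt(mean(pr^2)),
         mae_ho = mean(abs(pr)),
         r2 = r2,
         r2_adj = 1 - (1 - r2) * (fit$n - cc) / (fit$n - fit$p),
         r2_ho = 1 - sum(pr^2) / TSS,
         tss_centered = centered),
    class = "measures"
  )
}

#' @export
print.measures <- function(x, ...) {
  cat(sprintf("RMSE_HO = %.4g  MAE_HO = %.4g  R2_adj = %.4g  R2_HO = %.4g (%s TSS)\n",
              x$rmse_ho, x$mae_ho, x$r2_adj, x$r2_ho,
              if (x$tss_centered) "centered" else "uncentered"))
  invisible(x)
}

#' Overall model-adequacy F-test
#'
#' Tests the fitted model against the null model with no terms. Without an
#' intercept the null predicts 0 and the statistic is
#' F = ((TSS - SSE)/p) / (SSE/(n - p)) on (p, n - p) degrees of freedom
#' with TSS per the chosen convention; with an intercept the classical
#' overall F on (p - 1, n - p) with centered TSS is used.
#'
#' @inheritParams performance_measures
#' @return Upper-tail p-value.
#' @export
adequacy_anova <- function(fit, tss = c("auto", "uncentered", "centered")) {
  stopifnot(inherits(fit, "mlr_fit"))
  tss <- match.arg(tss)
  has_intercept <- "intercept" %in% fit$design$terms$kind
  centered <- switch(tss, auto = has_intercept,
                     uncentered = FALSE, centered = TRUE)
  y <- fit$design$response
  TSS <- if (centered) sum((y - mean(y))^2) else sum(y^2)
  df1 <- fit$p - if (has_intercept) 1L else 0L
  df2 <- fit$n - fit$p
  if (df1 < 1L || df2 < 1L) stop("degenerate degrees of freedom for ANOVA")
  SSE <- sum(fit$resid^2)
  if (SSE <= 0) return(0)
  Fstat <- ((TSS - SSE) / df1) / (SSE / df2)
  stats::pf(Fstat, df1, df2, lower.tail = FALSE)
}

#' Expected-error nullity test
#'
#' Two-sided one-sample Student t-test that the mean of the predicted
#' (leave-one-out) residuals is zero — the check that the model is not
#' systematically biased on held-out records.
#'
#' @param fit an `mlr_fit`.
#' @return Two-sided p-value.
#' @export
error_nullity_test <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  pr <- predicted_residuals(fit)
  if (length(pr) < 2L) stop("need at least 2 records for the nullity test")
  if (stats::sd(pr) == 0) {
    return(if (mean(pr) == 0) 1 else 0)
  }
  stats::t.test(pr)$p.value
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("mlr_fit:", x$n, "records,", x$p, "terms (rank", x$rank, ")\n")
  se <- sqrt(diag(x$hc3_cov))
  tab <- data.frame(slope = x$slopes, hc3_sd = se, row.names = names(x$slopes))
  print(tab, digits = 4)
  cat(sprintf("residual SD = %.4g on %d degrees of freedom\n", x$resid_sd, x$dof))
  invisible(x)
}
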