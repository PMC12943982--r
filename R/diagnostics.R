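#' Heteroskedasticity test on squared predicted residuals
#'
#' An auxiliary-regression (White-style) test: the squared predicted
#' (leave-one-out) residuals of `fit` are regressed on the full 15-term
#' quadratic design in the four raw predictors of the same records. The
#' overall F-test p-value and the adjusted R2 of this auxiliary regression
#' are reported; the fit is judged homoskedastic exactly when the p-value
#' is at least `alpha_het` and the auxiliary adjusted R2 is below
#' `r2_ceiling`. The auxiliary regression reuses the same SVD fitting path
#' as every other fit in the package.
#'
#' @param data the phenotype records the fit was computed on (same rows,
#'   same order).
#' @param fit an `mlr_fit` on those records.
#' @param alpha_het significance level for the auxiliary F-test
#'   (default 0.05).
#' @param r2_ceiling maximum auxiliary adjusted R2 compatible with
#'   homoskedasticity (default 0.05).
#' @param rel_tol singular-value truncation passed to [fit_svd()].
#' @return A list: `anova_p`, `aux_r2_adj`, `verdict`
#'   ("homoskedastic" or "heteroskedastic"), and the thresholds used.
#' @export
run_mhtra <- function(data, fit, alpha_het = 0.05, r2_ceiling = 0.05,
                      rel_tol = 1e-10) {
  stopifnot(inherits(fit, "mlr_fit"))
  data <- as_phenotypes(data)
  if (nrow(data) != fit$n) {
    stop("data must contain exactly the records the fit was computed on")
  }
  pr <- predicted_residuals(fit)
  zero_scale <- 1e-10 * (stats::sd(fit$design$response) + 1e-300)
  if (stats::var(pr^2) == 0 || max(abs(pr)) <= zero_scale) {
    # exactly constant squared residuals: nothing for the auxiliary
    # quadratic to explain
    anova_p <- 1
    aux_r2_adj <- 0
  } else {
    aux_design <- build_design(data, quadratic_terms(), response = pr^2)
    aux_fit <- fit_svd(aux_design, rel_tol = rel_tol)
    aux_r2_adj <- performance_measures(aux_fit)$r2_adj
    anova_p <- adequacy_anova(aux_fit)
  }
  verdict <- if (anova_p >= alpha_het && aux_r2_adj < r2_ceiling) {
    "homoskedastic"
  } else {
    "heteroskedastic"
  }
  list(anova_p = anova_p, aux_r2_adj = aux_r2_adj, verdict = verdict,
       alpha_het = alpha_het, r2_ceiling = r2_ceiling)
}

jarque_bera_stat <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- mean(z^2)
  if (m2 == 0) stop("constant input: skewness and kurtosis undefined")
  skew <- mean(z^3) / m2^1.5
  kurt <- mean(z^4) / m2^2
  n / 6 * (skew^2 + (kurt - 3)^2 / 4)
}

#' Monte-Carlo Jarque-Bera normality test
#'
#' Computes the Jarque-Bera statistic JB = n/6 (skew^2 + (kurtosis - 3)^2/4)
#' of the input and calibrates it against `n_mc` simulated standard-normal
#' samples of the same length ("pseudo-realities") rather than the
#' asymptotic chi-square, which is inaccurate at moderate n. The p-value
#' uses the add-one estimator p = (1 + #\{JB* >= JB\}) / (1 + n_mc), which is
#' never zero and reproducible given the seed.
#'
#' @param residuals numeric vector (length >= 8) to test for normality.
#' @param n_mc number of Monte-Carlo pseudo-realities (default 10000,
#'   minimum 100).
#' @param seed integer seed for the simulated null.
#' @return A list: `jb_stat`, `p_value`, `n_mc`, `seed`.
#' @export
mc_jarque_bera <- function(residuals, n_mc = 10000L, seed = 1L) {
  n <- length(residuals)
  stopifnot(n >= 8L, n_mc >= 100L)
  jb <- jarque_bera_stat(residuals)
  set.seed(seed)
  sims <- matrix(stats::rnorm(n * n_mc), nrow = n)
  cm <- colMeans(sims)
  z <- sweep(sims, 2L, cm)
  m2 <- colMeans(z^2)
  m3 <- colMeans(z^3)
  m4 <- colMeans(z^4)
  jb_star <- n / 6 * ((m3 / m2^1.5)^2 + (m4 / m2^2 - 3)^2 / 4)
  p <- (1 + sum(jb_star >= jb)) / (1 + n_mc)
  list(jb_stat = jb, p_value = p, n_mc = as.integer(n_mc),
       seed = as.integer(seed))
}
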