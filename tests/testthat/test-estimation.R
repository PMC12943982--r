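test_that("SVD fit solves exact, collinear and rank-deficient systems", {
  # 3 collinear points through the origin with slope 1
  d <- make_phenotypes(spad = 0:2, gs = 0:2, na = 0:2, k = 0:2, sdw = 0:2)
  dm <- build_design(d, term_set(c("(Intercept)", "X2")))
  fit <- fit_svd(dm)
  expect_equal(unname(fit$slopes), c(0, 1), tolerance = 1e-12)

  # response exactly in the column span -> zero residuals
  d2 <- random_phenotypes(30, seed = 9)
  dm2 <- build_design(d2, term_set(c("X2", "X4", "X2^2")))
  dm2$response <- drop(dm2$values %*% c(0.05, 0.01, -5e-4))
  fit2 <- fit_svd(dm2)
  expect_lt(max(abs(fit2$resid)), 1e-10)
  expect_lt(fit2$resid_sd, 1e-10)

  # duplicated column: finite minimum-norm solution, no failure
  dm3 <- dm2
  dm3$values <- cbind(dm2$values, dup = dm2$values[, 1])
  fit3 <- fit_svd(dm3)
  expect_true(all(is.finite(fit3$slopes)))
  expect_equal(fit3$rank, 3L)
  # minimum-norm: duplicated columns share the coefficient
  expect_equal(unname(fit3$slopes[1]), unname(fit3$slopes[4]), tolerance = 1e-8)

  expect_error(fit_svd(build_design(
    make_phenotypes(0, 0, 0, 0, 1), term_set("X1"))), "zero")
})

test_that("fit agrees with the normal-equations/lm solution when well conditioned", {
  d <- random_phenotypes(60, seed = 21)
  dm <- build_design(d, term_set(c("(Intercept)", "X1", "X2", "X4")))
  fit <- fit_svd(dm)
  ref <- lm(d$sdw_g ~ spad + gs_mmol_m2_s + shoot_k_mM, data = d)
  expect_equal(unname(fit$slopes), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$hat), unname(hatvalues(ref)), tolerance = 1e-8)
  expect_equal(fit$resid_sd, summary(ref)$sigma, tolerance = 1e-8)
})

test_that("leverages sum to the effective rank", {
  for (s in 1:5) {
    dm <- random_design(25, c("(Intercept)", "X1", "X2", "X4", "X2^2"), seed = s)
    fit <- fit_svd(dm)
    expect_equal(sum(fit$hat), fit$rank, tolerance = 1e-9)
    expect_true(all(fit$hat >= -1e-12 & fit$hat <= 1 + 1e-12))
  }
})

test_that("predicted residuals equal literal leave-one-out refits", {
  for (s in 1:4) {
    n <- c(6, 12, 20, 30)[s]
    dm <- random_design(n, c("(Intercept)", "X2", "X4"), seed = 100 + s)
    fit <- fit_svd(dm)
    pr <- predicted_residuals(fit)
    for (i in seq_len(n)) {
      expect_equal(pr[i], loo_prediction_error(dm, i), tolerance = 1e-8)
    }
  }

  # zero-residual fit has zero predicted residuals
  dm <- random_design(15, c("X2", "X4"), seed = 7, noise_sd = 0)
  expect_equal(max(abs(predicted_residuals(fit_svd(dm)))), 0, tolerance = 1e-10)
})

test_that("HC3 covariance matches brute force, sandwich, and large-n theory", {
  # element-wise brute force on a small instance
  dm <- random_design(8, c("(Intercept)", "X2"), seed = 31)
  fit <- fit_svd(dm)
  X <- dm$values
  e <- fit$resid
  h <- fit$hat
  XtX_inv <- solve(crossprod(X))
  S_brute <- XtX_inv %*% t(X) %*% diag(e^2 / (1 - h)^2) %*% X %*% XtX_inv
  expect_equal(unname(fit$hc3_cov), unname(S_brute), tolerance = 1e-10)

  # independent implementation: sandwich::vcovHC on the lm path
  d <- random_phenotypes(40, seed = 13)
  fit2 <- fit_svd(build_design(d, term_set(c("(Intercept)", "X1", "X2", "X4"))))
  ref <- lm(d$sdw_g ~ spad + gs_mmol_m2_s + shoot_k_mM, data = d)
  expect_equal(unname(fit2$hc3_cov),
               unname(sandwich::vcovHC(ref, type = "HC3")),
               tolerance = 1e-8)

  # symmetric PSD
  ev <- eigen(fit2$hc3_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * sum(diag(fit2$hc3_cov)))

  # zero residuals -> zero matrix
  dm0 <- random_design(15, c("X2", "X4"), seed = 7, noise_sd = 0)
  expect_lt(max(abs(fit_svd(dm0)$hc3_cov)), 1e-18)

  # homoskedastic large-n: diagonal within 10% of sigma^2 (X'X)^-1
  set.seed(77)
  n <- 5000
  x <- runif(n, 1, 3)
  X <- cbind(1, x)
  y <- 2 + 0.5 * x + rnorm(n, 0, 0.4)
  dmx <- structure(list(values = X, terms = term_set(c("(Intercept)", "X1")),
                        response = y, record_id = seq_len(n)),
                   class = "design_matrix")
  fitx <- fit_svd(dmx)
  target <- 0.4^2 * diag(solve(crossprod(X)))
  expect_equal(unname(diag(fitx$hc3_cov)), unname(target), tolerance = 0.1)
})

test_that("performance measures follow their definitions and conventions", {
  # perfect fit
  dm <- random_design(15, c("X2", "X4"), seed = 7, noise_sd = 0)
  m <- performance_measures(fit_svd(dm))
  expect_equal(m$rmse_ho, 0)
  expect_equal(m$mae_ho, 0)
  expect_equal(m$r2_ho, 1)

  # intercept-only model has adjusted R2 exactly 0 under centered TSS
  d <- random_phenotypes(20, seed = 41)
  m2 <- performance_measures(fit_svd(build_design(d, term_set("(Intercept)"))))
  expect_true(m2$tss_centered)
  expect_equal(m2$r2_adj, 0, tolerance = 1e-12)

  # holdout residuals inflate ordinary ones: rmse_ho >= in-sample rmse
  for (s in 1:100) {
    dm <- random_design(12, c("(Intercept)", "X2", "X4"), seed = 200 + s)
    fit <- fit_svd(dm)
    m <- performance_measures(fit)
    expect_gte(m$rmse_ho, sqrt(mean(fit$resid^2)))
    expect_gte(m$mae_ho, 0)
    expect_lte(m$r2_adj, 1)
    expect_lte(m$r2_ho, 1)
  }

  # constant response with centered TSS is rejected
  dc <- make_phenotypes(spad = 1:5, gs = 1:5, na = 1:5, k = 1:5,
                        sdw = rep(2, 5))
  fitc <- fit_svd(build_design(dc, term_set(c("(Intercept)", "X2"))))
  expect_error(performance_measures(fitc, tss = "centered"), "zero")
})

test_that("adequacy ANOVA detects signal and holds its level on pure noise", {
  # strong planted signal
  cfg <- synth_config(seed = 8, outlier_fraction = 0)
  g <- generate_phenotypes(cfg)
  fit <- fit_svd(build_design(g$data, sdw_terms()))
  expect_lt(adequacy_anova(fit), 1e-10)

  # zero-residual fit
  dm0 <- random_design(15, c("X2", "X4"), seed = 7, noise_sd = 0)
  expect_equal(adequacy_anova(fit_svd(dm0)), 0)

  # type-I under the no-intercept null: y pure noise around 0
  set.seed(99)
  d <- random_phenotypes(25, seed = 99)
  dm <- build_design(d, term_set(c("X2", "X4")))
  rej <- replicate(1000, {
    dm$response <- rnorm(25)
    adequacy_anova(fit_svd(dm)) < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("error-nullity t-test behaves at its edge cases and holds level", {
  # antisymmetric predicted residuals -> mean exactly 0 -> p = 1
  dm <- random_design(8, c("(Intercept)", "X2"), seed = 55)
  fit <- fit_svd(dm)
  fit$resid <- c(-0.2, 0.2, -0.4, 0.4, -0.1, 0.1, -0.3, 0.3) * (1 - fit$hat)
  expect_equal(error_nullity_test(fit), 1, tolerance = 1e-12)

  # constant nonzero predicted residuals -> p = 0 by convention
  fit$resid <- (1 - fit$hat)
  expect_equal(error_nullity_test(fit), 0)

  # level on normal residuals
  set.seed(123)
  rej <- replicate(1000, {
    fit$resid <- rnorm(8, 0, 0.5) * (1 - fit$hat)
    error_nullity_test(fit) < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
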