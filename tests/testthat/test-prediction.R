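test_that("reference model reproduces its printed standard deviations", {
  m <- rice_sdw_model()
  expect_equal(unname(signif(sqrt(diag(m$cov)), 3)),
               c(4.91e-3, 1.46e-3, 9.46e-5, 5.39e-5, 5.81e-6))
  expect_equal(m$resid_sd, 0.280)
  expect_equal(m$dof, 119L)
})

test_that("mean prediction is exact arithmetic on the slopes", {
  m <- rice_sdw_model()
  expect_equal(predict_mean(m, 0, 0, 0), 0)
  expect_equal(predict_mean(m, spad = 30, gs = 50, k = 200), 2.09313,
               tolerance = 1e-9)
  # SPAD enters only squared
  expect_equal(predict_mean(m, -30, 50, 200), predict_mean(m, 30, 50, 200))
  # additive across the three raw inputs (no cross terms)
  set.seed(5)
  for (r in 1:20) {
    s <- runif(1, 10, 50); gv <- runif(1, 10, 90); kv <- runif(1, 10, 300)
    expect_equal(predict_mean(m, s, gv, kv),
                 predict_mean(m, s, 0, 0) + predict_mean(m, 0, gv, 0) +
                   predict_mean(m, 0, 0, kv),
                 tolerance = 1e-10)
  }
})

test_that("prediction variance is the quadratic form in the slope covariance", {
  m <- rice_sdw_model()
  expect_equal(predict_variance(m, 0, 0, 0), 0)
  set.seed(6)
  for (r in 1:20) {
    x <- runif(5, -2, 2) * c(50, 200, 900, 2500, 40000)
    v <- predict_variance(m, x = x)
    # two-nested-loop brute force
    vb <- 0
    for (i in 1:5) for (j in 1:5) vb <- vb + x[i] * m$cov[i, j] * x[j]
    expect_equal(v, max(vb, 0), tolerance = 1e-12)
  }
  expect_error(predict_variance(m, x = 1:4), "length")
})

test_that("confidence intervals use the t quantile on the model dof", {
  m <- rice_sdw_model()
  ci <- confidence_interval(m, 30, 50, 200, level = 0.5)
  half <- (ci$hi - ci$lo) / 2
  expect_equal(half, qt(0.75, df = 119) * sqrt(ci$var), tolerance = 1e-12)
  # half-width agrees with an independently computed Student quantile:
  # for nu = 119 the 75th percentile is 0.6766 (between the tabulated
  # 0.6765 at nu = 120 and 0.6770 at nu = 100)
  expect_equal(qt(0.75, 119), 0.6766, tolerance = 1e-4)

  # shrinking level collapses the interval onto the mean
  ci_tiny <- confidence_interval(m, 30, 50, 200, level = 1e-10)
  expect_equal(ci_tiny$lo, ci_tiny$mean, tolerance = 1e-6)

  # zero observation vector gives a (0, 0) interval
  ci0 <- confidence_interval(m, 0, 0, 0)
  expect_equal(c(ci0$lo, ci0$hi), c(0, 0))

  # prediction intervals are wider by the residual variance
  cip <- confidence_interval(m, 30, 50, 200, interval = "prediction")
  expect_equal(cip$var, ci$var + 0.280^2, tolerance = 1e-12)
})

test_that("figure scenario grids have the stated sweep geometry", {
  m <- rice_sdw_model()
  sweep_points <- c(41, 59, 41, 41, 59)
  curves <- c(15, 15, 15, 15, 15)
  for (f in 1:5) {
    tab <- scenario_grid(m, figure_scenario(f))
    expect_equal(length(unique(tab$sweep_value)), sweep_points[f])
    expect_equal(nrow(tab), sweep_points[f] * curves[f])
    expect_true(all(tab$ci_lo <= tab$mean_sdw_g + 1e-12))
    expect_true(all(tab$mean_sdw_g <= tab$ci_hi + 1e-12))
  }
  expect_error(scenario_spec("gs", 90, 10, 2, fixed = list(spad = 30, k = 100)),
               "to > from|TRUE")
})

test_that("mean response is monotone around the K+ optimum", {
  m <- rice_sdw_model()
  kopt <- parabola_optimum(m, "k")
  ks <- seq(10, 300, by = 5)
  mu <- predict_mean(m, spad = 30, gs = 50, k = ks)
  below <- ks < kopt
  expect_true(all(diff(mu[below]) > 0))
  above <- ks > kopt
  expect_true(all(diff(mu[above]) < 0))
})

test_that("parabola optima follow the closed form", {
  m <- rice_sdw_model()
  expect_equal(parabola_optimum(m, "gs"), 4.874e-2 / (2 * 5.280e-4),
               tolerance = 1e-12)
  expect_equal(parabola_optimum(m, "k"), 1.261e-2 / (2 * 3.009e-5),
               tolerance = 1e-12)
  # toy parabola y = x - x^2 peaks at 1/2
  toy <- final_model(c(X2 = 1, `X2^2` = -1), diag(1e-6, 2), 0.1, 10)
  expect_equal(parabola_optimum(toy, "gs"), 0.5)
  # no interior maximum without negative curvature
  toy2 <- final_model(c(X2 = 1, `X2^2` = 1), diag(1e-6, 2), 0.1, 10)
  expect_error(parabola_optimum(toy2, "gs"), "nonnegative")
  expect_error(parabola_optimum(m, "na"), "no quadratic")
})

test_that("model JSON round-trips", {
  m <- rice_sdw_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$slopes, m$slopes)
  expect_equal(back$cov, m$cov, tolerance = 1e-12)
  expect_equal(back$dof, m$dof)
  expect_equal(predict_mean(back, 30, 50, 200), predict_mean(m, 30, 50, 200))
})
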