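#' Construct a final prediction model
#'
#' A `final_model` bundles everything the prediction engine needs: the
#' selected term structure, its slopes (in raw units, response in g/plant),
#' the robust slope covariance S, the residual standard deviation and the
#' degrees of freedom used for t-based interval quantiles.
#'
#' @param slopes named numeric vector; names are term labels (e.g. `"X2"`,
#'   `"X4^2"`).
#' @param cov symmetric p x p slope covariance matrix in matching order.
#' @param resid_sd residual standard deviation (g/plant).
#' @param dof degrees of freedom for interval quantiles.
#' @param provenance free-text note on where the numbers came from.
#' @return A `final_model` object.
#' @export
final_model <- function(slopes, cov, resid_sd, dof, provenance = "") {
  stopifnot(is.numeric(slopes), !is.null(names(slopes)))
  terms <- term_set(names(slopes))
  cov <- as.matrix(cov)
  p <- length(slopes)
  if (!all(dim(cov) == c(p, p))) stop("cov must be ", p, " x ", p)
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1e-300)) {
    stop("cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * sum(abs(diag(cov)))) {
    stop("cov must be positive semidefinite")
  }
  stopifnot(dof >= 1, resid_sd >= 0)
  dimnames(cov) <- list(names(slopes), names(slopes))
  structure(
    list(slopes = slopes, cov = cov, resid_sd = resid_sd,
         dof = dof, terms = terms, provenance = provenance),
    class = "final_model"
  )
}

#' Extract a final model from a pipeline fit
#'
#' @param fit an `mlr_fit` (typically the refit on outlier-purged records).
#' @param provenance free-text provenance note.
#' @return A `final_model`.
#' @export
as_final_model <- function(fit, provenance = "fitted") {
  stopifnot(inherits(fit, "mlr_fit"))
  final_model(fit$slopes, fit$hc3_cov, fit$resid_sd, fit$dof,
              provenance = provenance)
}

#' The reference shoot-dry-weight model
#'
#' The five-slope quadratic model of rice shoot dry weight fitted to the
#' outlier-purged glasshouse dataset of ten rice genotypes (six cultivated,
#' four wild) grown at 0, 50 and 100 mM NaCl: positive linear effects of
#' stomatal conductance (X2) and shoot sap K+ (X4) with negative curvature
#' in both, and a negative pure-quadratic SPAD effect (X1^2); shoot Na+
#' carries no term. Ships with its robust HC3 slope covariance, residual
#' standard deviation 0.280 g/plant and 119 degrees of freedom
#' (124 records minus 5 slopes), so predictions and confidence bands can
#' be reproduced without refitting.
#'
#' @return A `final_model`.
#' @export
#' @examples
#' m <- rice_sdw_model()
#' predict_mean(m, spad = 30, gs = 50, k = 200)  # 2.09313 g/plant
rice_sdw_model <- function() {
  labels <- c("X2", "X4", "X1^2", "X2^2", "X4^2")
  slopes <- c(4.874e-2, 1.261e-2, -3.803e-4, -5.280e-4, -3.009e-5)
  names(slopes) <- labels
  cov <- matrix(0, 5, 5, dimnames = list(labels, labels))
  cov[upper.tri(cov, diag = TRUE)] <- c(
    2.411e-5,
    -5.088e-6, 2.135e-6,
    -3.172e-7, 1.585e-8, 8.942e-9,
    -2.381e-7, 5.244e-8, 2.227e-9, 2.908e-9,
    1.764e-8, -8.001e-9, -1.135e-11, -2.118e-10, 3.380e-11
  )
  cov <- cov + t(cov) - diag(diag(cov))
  final_model(slopes, cov, resid_sd = 0.280, dof = 119L,
              provenance = "reference glasshouse study, purged records")
}

# n x p matrix evaluating the model's terms at raw trait values
observation_matrix <- function(model, spad, gs, k, na = 0) {
  vals <- cbind(spad, gs, na, k)  # recycled to common length
  X <- cbind(X1 = vals[, 1], X2 = vals[, 2], X3 = vals[, 3], X4 = vals[, 4])
  ts <- model$terms
  out <- matrix(NA_real_, nrow(X), nrow(ts),
                dimnames = list(NULL, ts$label))
  for (t in seq_len(nrow(ts))) {
    out[, t] <- switch(ts$kind[t],
      intercept = rep(1, nrow(X)),
      linear = X[, ts$i[t]],
      square = X[, ts$i[t]]^2,
      cross = X[, ts$i[t]] * X[, ts$j[t]]
    )
  }
  out
}

#' Predicted mean shoot dry weight
#'
#' Evaluates the model's mean response E[Y | x] at the given raw trait
#' values; for the reference model this is
#' b2 Gs + b4 K + b11 SPAD^2 + b22 Gs^2 + b44 K^2 (g/plant).
#' Arguments are vectorized and recycled.
#'
#' @param model a `final_model`.
#' @param spad SPAD chlorophyll index (arbitrary units).
#' @param gs stomatal conductance (mmol m-2 s-1).
#' @param k shoot sap K+ (mM).
#' @param na shoot sap Na+ (mM); only used if the model has an Na+ term.
#' @return Numeric vector of predicted means (g/plant).
#' @export
predict_mean <- function(model, spad, gs, k, na = 0) {
  stopifnot(inherits(model, "final_model"))
  x <- observation_matrix(model, spad, gs, k, na)
  stopifnot(all(is.finite(x)))
  drop(x %*% model$slopes)
}

#' Variance of the predicted mean
#'
#' The quadratic form x' S x of each observation vector in the slope
#' covariance S; tiny negative values arising from rounding are clipped
#' at zero.
#'
#' @inheritParams predict_mean
#' @param x optionally, a precomputed observation matrix (rows = points,
#'   columns in model term order) instead of raw trait values.
#' @return Numeric vector of variances.
#' @export
predict_variance <- function(model, spad, gs, k, na = 0, x = NULL) {
  stopifnot(inherits(model, "final_model"))
  if (is.null(x)) {
    x <- observation_matrix(model, spad, gs, k, na)
  } else {
    x <- rbind(x)
    if (ncol(x) != length(model$slopes)) {
      stop("observation vector length must match the number of slopes")
    }
  }
  v <- rowSums((x %*% model$cov) * x)
  unname(pmax(v, 0))
}

#' t-based interval for the predicted response
#'
#' mean +/- t_{(1+level)/2, dof} * sqrt(x' S x). The default is a
#' confidence interval for the mean response, whose variance is the slope
#' uncertainty x' S x alone; `interval = "prediction"` additionally adds
#' the residual variance for a single new observation.
#'
#' @inheritParams predict_mean
#' @param level interval coverage in (0, 1); default 0.50.
#' @param interval "confidence" (default) or "prediction".
#' @return A data frame with columns `mean`, `var`, `lo`, `hi`.
#' @export
confidence_interval <- function(model, spad, gs, k, na = 0, level = 0.5,
                                interval = c("confidence", "prediction")) {
  stopifnot(inherits(model, "final_model"), level > 0, level < 1)
  interval <- match.arg(interval)
  x <- observation_matrix(model, spad, gs, k, na)
  m <- drop(x %*% model$slopes)
  v <- predict_variance(model, x = x)
  if (interval == "prediction") v <- v + model$resid_sd^2
  half <- stats::qt((1 + level) / 2, df = model$dof) * sqrt(v)
  data.frame(mean = m, var = v, lo = m - half, hi = m + half)
}

#' Response-surface scenario specification
#'
#' Describes one family of prediction curves: a sweep variable with its
#' range and step, and fixed levels for the two remaining traits; the five
#' standard figure templates are available through [figure_scenario()].
#'
#' @param sweep one of "spad", "gs", "k".
#' @param from,to,by sweep range and step, in the trait's raw units.
#' @param fixed named list giving the level vector of each non-sweep trait
#'   (names among "spad", "gs", "k").
#' @param level interval coverage (default 0.50).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(sweep = c("spad", "gs", "k"), from, to, by,
                          fixed, level = 0.5) {
  sweep <- match.arg(sweep)
  stopifnot(to > from, by > 0)
  others <- setdiff(c("spad", "gs", "k"), sweep)
  if (!all(others %in% names(fixed))) {
    stop("fixed must name level vectors for: ", paste(others, collapse = ", "))
  }
  structure(list(sweep = sweep, from = from, to = to, by = by,
                 fixed = fixed[others], level = level),
            class = "scenario_spec")
}

#' Standard figure scenario templates
#'
#' The five response-surface grids used for the reference model's figures:
#' 1. SPAD 10-50 step 1; K+ in \{50, 100, 200\} mM; Gs in \{10, 30, 50, 70,
#'    90\}.
#' 2. K+ 10-300 step 5; SPAD in \{20, 30, 40\}; Gs in \{10, 30, 50, 70, 90\}.
#' 3. Gs 10-90 step 2; SPAD in \{20, 30, 40\}; K+ in \{20, 50, 100, 200,
#'    300\} mM.
#' 4. Gs 10-90 step 2; K+ in \{50, 100, 200\} mM; SPAD in \{10, 20, 30, 40,
#'    50\}.
#' 5. K+ 10-300 step 5; Gs in \{30, 60, 90\}; SPAD in \{10, 20, 30, 40, 50\}.
#'
#' @param figure integer 1 to 5.
#' @param level interval coverage (default 0.50).
#' @return A `scenario_spec`.
#' @export
figure_scenario <- function(figure, level = 0.5) {
  switch(as.character(figure),
    "1" = scenario_spec("spad", 10, 50, 1,
                        fixed = list(k = c(50, 100, 200),
                                     gs = c(10, 30, 50, 70, 90)),
                        level = level),
    "2" = scenario_spec("k", 10, 300, 5,
                        fixed = list(spad = c(20, 30, 40),
                                     gs = c(10, 30, 50, 70, 90)),
                        level = level),
    "3" = scenario_spec("gs", 10, 90, 2,
                        fixed = list(spad = c(20, 30, 40),
                                     k = c(20, 50, 100, 200, 300)),
                        level = level),
    "4" = scenario_spec("gs", 10, 90, 2,
                        fixed = list(k = c(50, 100, 200),
                                     spad = c(10, 20, 30, 40, 50)),
                        level = level),
    "5" = scenario_spec("k", 10, 300, 5,
                        fixed = list(gs = c(30, 60, 90),
                                     spad = c(10, 20, 30, 40, 50)),
                        level = level),
    stop("figure must be 1, 2, 3, 4 or 5")
  )
}

#' Evaluate a scenario grid
#'
#' One row per combination of sweep value and fixed levels, with the
#' predicted mean, its variance and the t-based interval bounds.
#'
#' @param model a `final_model`.
#' @param spec a `scenario_spec` (e.g. from [figure_scenario()]).
#' @return A data frame: `sweep_var`, `sweep_value`, `spad`, `gs`, `k`,
#'   `mean_sdw_g`, `var`, `ci_lo`, `ci_hi`.
#' @export
scenario_grid <- function(model, spec) {
  stopifnot(inherits(model, "final_model"), inherits(spec, "scenario_spec"))
  sweep_vals <- seq(spec$from, spec$to, by = spec$by)
  if (length(sweep_vals) == 0L) stop("empty sweep range")
  grid_args <- c(list(sweep_vals), spec$fixed)
  names(grid_args)[1] <- spec$sweep
  grid <- expand.grid(grid_args, KEEP.OUT.ATTRS = FALSE)
  ci <- confidence_interval(model, spad = grid$spad, gs = grid$gs,
                            k = grid$k, level = spec$level)
  data.frame(
    sweep_var = spec$sweep,
    sweep_value = grid[[spec$sweep]],
    spad = grid$spad, gs = grid$gs, k = grid$k,
    mean_sdw_g = ci$mean, var = ci$var, ci_lo = ci$lo, ci_hi = ci$hi
  )
}

#' Interior optimum of a parabolic trait response
#'
#' For a trait entering the model with a linear and a negative pure-square
#' coefficient and no cross terms, the mean response is maximized at
#' -(linear)/(2 * quadratic), independent of the other traits. For the
#' reference model: Gs optimum near 46.2 mmol m-2 s-1 and K+ optimum near
#' 209.5 mM.
#'
#' @param model a `final_model`.
#' @param variable one of "spad", "gs", "k", "na".
#' @return The argmax, in the trait's raw units.
#' @export
parabola_optimum <- function(model, variable = c("gs", "k", "spad", "na")) {
  stopifnot(inherits(model, "final_model"))
  variable <- match.arg(variable)
  idx <- match(variable, c("spad", "gs", "na", "k"))
  ts <- model$terms
  involves <- ts$kind == "cross" & (ts$i == idx | ts$j == idx)
  if (any(involves)) {
    stop("response in ", variable, " is not a free-standing parabola: ",
         "cross terms present")
  }
  lin_lab <- paste0("X", idx)
  sq_lab <- paste0("X", idx, "^2")
  lin <- if (lin_lab %in% names(model$slopes)) model$slopes[[lin_lab]] else 0
  if (!sq_lab %in% names(model$slopes)) {
    stop("no quadratic term in ", variable, "; no interior maximum")
  }
  quad <- model$slopes[[sq_lab]]
  if (quad >= 0) stop("quadratic coefficient in ", variable,
                      " is nonnegative; no interior maximum")
  -lin / (2 * quad)
}

#' @export
print.final_model <- function(x, ...) {
  cat("final_model (", x$provenance, ")\n", sep = "")
  tab <- data.frame(slope = x$slopes, hc3_sd = sqrt(diag(x$cov)),
                    row.names = names(x$slopes))
  print(tab, digits = 4)
  cat(sprintf("residual SD = %.4g g/plant; %d degrees of freedom\n",
              x$resid_sd, x$dof))
  invisible(x)
}

#' Write / read a final model as JSON
#'
#' @param model a `final_model`.
#' @param path JSON file path.
#' @return `path` (write) or a `final_model` (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "final_model"))
  obj <- list(
    term_labels = names(model$slopes),
    slopes = unname(model$slopes),
    cov = model$cov,
    resid_sd = model$resid_sd,
    dof = model$dof,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("term_labels", "slopes", "cov", "resid_sd", "dof")
  if (!all(required %in% names(obj))) {
    stop("model JSON must contain: ", paste(required, collapse = ", "))
  }
  slopes <- as.numeric(obj$slopes)
  names(slopes) <- obj$term_labels
  final_model(slopes, as.matrix(obj$cov), obj$resid_sd, obj$dof,
              provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}
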