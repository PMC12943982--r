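#' Robust per-slope p-values
#'
#' Two-sided p-value for each slope from t_j = slope_j / sqrt(S_jj) with S
#' the HC3 covariance, referred to a Student t distribution on n - p
#' degrees of freedom. A slope with zero robust SD gets p = 1 when the
#' slope itself is zero and p = 0 otherwise.
#'
#' @param fit an `mlr_fit`.
#' @return Named numeric vector of p-values, one per term.
#' @export
robust_slope_pvalues <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  se <- sqrt(pmax(diag(fit$hc3_cov), 0))
  p <- rep(NA_real_, fit$p)
  zero_se <- se == 0
  p[zero_se] <- ifelse(fit$slopes[zero_se] == 0, 1, 0)
  tt <- fit$slopes[!zero_se] / se[!zero_se]
  p[!zero_se] <- 2 * stats::pt(-abs(tt), df = fit$dof)
  names(p) <- names(fit$slopes)
  p
}

min_abs_t <- function(fit) {
  se <- sqrt(pmax(diag(fit$hc3_cov), 0))
  tt <- ifelse(se == 0, ifelse(fit$slopes == 0, 0, Inf), abs(fit$slopes / se))
  min(tt)
}

#' Three-phase stepwise search for the largest all-significant term set
#'
#' Searches the candidate-term space for a maximal-cardinality model in
#' which every slope is statistically significant under the robust (HC3)
#' t-test. Three phases, each recording one audit step per accepted change:
#'
#' * Phase 1 (backward elimination): starting from all candidate terms,
#'   repeatedly refit and remove the single term whose robust p-value is
#'   the largest one at or above `alpha`, until all remaining slopes are
#'   significant. Ties are broken by removing the term latest in canonical
#'   order.
#' * Phase 2 (re-entry): each previously removed term is tentatively added
#'   back, in canonical order; an addition is accepted only if every slope
#'   of the refitted model, including the new one, is significant.
#' * Phase 3 (exchange): every (retained, removed) pair is tentatively
#'   swapped; a swap is accepted only if the swapped model is
#'   all-significant and has strictly more terms or a strictly larger
#'   minimum |t|.
#'
#' Phases 2-3 are repeated until a full pass accepts no change. P-values
#' are recomputed after every accepted change. The intercept is an
#' ordinary candidate, eligible for elimination like any other term.
#'
#' @param data a validated phenotype data frame.
#' @param alpha two-sided significance level for retaining a slope
#'   (default 0.05).
#' @param terms candidate `term_set` (default the full quadratic set).
#' @param rel_tol singular-value truncation passed to [fit_svd()].
#' @return A list with `terms` (the selected `term_set`), `trace` (a data
#'   frame of steps: phase, action, term, p_value), `phase_counts`
#'   (steps per phase), and `fit` (the final refit, or NULL if the
#'   selected set is empty).
#' @export
run_msra <- function(data, alpha = 0.05, terms = quadratic_terms(),
                     rel_tol = 1e-10) {
  data <- as_phenotypes(data)
  validate_term_set(terms)
  full <- build_design(data, terms)
  labels <- terms$label
  in_set <- rep(TRUE, length(labels))

  steps <- list()
  add_step <- function(phase, action, term, p_value) {
    steps[[length(steps) + 1L]] <<- data.frame(
      phase = phase, action = action, term = term,
      p_value = p_value, stringsAsFactors = FALSE)
  }
  fit_mask <- function(mask) {
    fit_svd(select_terms(full, term_set(labels[mask])), rel_tol = rel_tol)
  }
  all_sig <- function(fit) all(robust_slope_pvalues(fit) < alpha)

  # Phase 1: backward elimination
  fit <- NULL
  while (any(in_set)) {
    fit <- fit_mask(in_set)
    pv <- robust_slope_pvalues(fit)
    not_sig <- which(pv >= alpha)
    if (length(not_sig) == 0L) break
    worst_p <- max(pv[not_sig])
    # tie-break: remove the term latest in canonical order
    cand <- names(pv)[not_sig][pv[not_sig] == worst_p]
    drop_lab <- cand[which.max(match(cand, labels))]
    in_set[match(drop_lab, labels)] <- FALSE
    add_step(1L, "remove", drop_lab, worst_p)
    fit <- NULL
  }
  if (!any(in_set)) fit <- NULL else if (is.null(fit)) fit <- fit_mask(in_set)

  # Phases 2-3 until a full pass makes no change
  repeat {
    changed <- FALSE

    # Phase 2: re-entry in canonical order
    for (idx in which(!in_set)) {
      trial <- in_set
      trial[idx] <- TRUE
      tf <- fit_mask(trial)
      if (all_sig(tf)) {
        in_set <- trial
        fit <- tf
        add_step(2L, "add", labels[idx],
                 robust_slope_pvalues(tf)[labels[idx]])
        changed <- TRUE
      }
    }

    # Phase 3: exchange; restart the scan after each accepted swap
    if (any(in_set) && any(!in_set)) {
      repeat {
        swapped <- FALSE
        cur_min_t <- if (is.null(fit)) -Inf else min_abs_t(fit)
        for (i_in in which(in_set)) {
          for (i_out in which(!in_set)) {
            trial <- in_set
            trial[i_in] <- FALSE
            trial[i_out] <- TRUE
            tf <- fit_mask(trial)
            if (all_sig(tf) &&
                (sum(trial) > sum(in_set) || min_abs_t(tf) > cur_min_t)) {
              in_set <- trial
              fit <- tf
              add_step(3L, "swap",
                       paste0(labels[i_in], "->", labels[i_out]),
                       robust_slope_pvalues(tf)[labels[i_out]])
              changed <- TRUE
              swapped <- TRUE
              break
            }
          }
          if (swapped) break
        }
        if (!swapped) break
      }
    }
    if (!changed) break
  }

  trace <- if (length(steps)) do.call(rbind, steps) else
    data.frame(phase = integer(), action = character(),
               term = character(), p_value = numeric())
  selected <- if (any(in_set)) term_set(labels[in_set]) else
    terms[0, , drop = FALSE]
  if (any(in_set) && is.null(fit)) fit <- fit_mask(in_set)
  list(
    terms = selected,
    trace = trace,
    phase_counts = c(phase1 = sum(trace$phase == 1L),
                     phase2 = sum(trace$phase == 2L),
                     phase3 = sum(trace$phase == 3L)),
    fit = if (any(in_set)) fit else NULL
  )
}
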