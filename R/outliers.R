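#' Externally studentized residual p-values
#'
#' Each record's residual is studentized by the residual scale of the model
#' fitted without that record, using the closed-form deletion identity
#' s_(i)^2 = ((n - p) s^2 - e_i^2 / (1 - h_ii)) / (n - p - 1), so
#' r_i = e_i / (s_(i) sqrt(1 - h_ii)). Under the normal-error null r_i is
#' exactly Student t on n - p - 1 degrees of freedom, giving the two-sided
#' p-values screened by the outlier cycle. A record whose leverage is
#' numerically 1 is flagged unconditionally with p = 0.
#'
#' @param fit an `mlr_fit` with n > p + 1.
#' @return Numeric vector of two-sided p-values, one per record.
#' @export
studentized_pvalues <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  n <- fit$n
  p <- fit$p
  if (n <= p + 1L) stop("need n > p + 1 for externally studentized residuals")
  tol <- max(fit$rel_tol, 1e-8)
  h <- fit$hat
  e <- fit$resid
  s2 <- sum(e^2) / (n - p)
  out <- numeric(n)
  high <- h >= 1 - tol
  out[high] <- 0
  ok <- !high
  s2i <- ((n - p) * s2 - e[ok]^2 / (1 - h[ok])) / (n - p - 1L)
  s2i <- pmax(s2i, 0)
  r <- ifelse(s2i == 0, ifelse(e[ok] == 0, 0, Inf),
              e[ok] / sqrt(s2i * (1 - h[ok])))
  out[ok] <- 2 * stats::pt(-abs(r), df = n - p - 1L)
  out
}

#' Benjamini-Hochberg step-up flagging
#'
#' Sorts the p-values, finds the largest k with p_(k) <= k q / m, and flags
#' every test with p at or below that threshold. Controls the false-discovery
#' rate at q over the m per-record tests of one cycle.
#'
#' @param p numeric vector of p-values.
#' @param q target false-discovery rate.
#' @return Logical vector, TRUE where flagged.
#' @export
bh_flag <- function(p, q) {
  stopifnot(q > 0, q < 1)
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  below <- which(p[o] <= q * seq_len(m) / m)
  flagged <- logical(m)
  if (length(below) > 0L) {
    k <- max(below)
    flagged[o[seq_len(k)]] <- TRUE
  }
  flagged
}

#' Cyclic outlier screening with false-discovery-rate control
#'
#' Repeats fit -> externally studentized p-values -> Benjamini-Hochberg at
#' `max_fdr` -> purge all flagged records, one cycle per purge, until a
#' cycle flags nothing or `max_cycles` is reached. The model structure
#' (`terms`) is held fixed throughout; it is typically the selected
#' structure from [run_msra()]. If a purge would leave n <= p + 1 records
#' the algorithm stops with a warning and returns the current state.
#'
#' @param data a validated phenotype data frame.
#' @param terms the fixed `term_set` screened against.
#' @param max_fdr Benjamini-Hochberg false-discovery rate per cycle
#'   (default 0.30).
#' @param max_cycles cycle cap (default 25).
#' @param rel_tol singular-value truncation passed to [fit_svd()].
#' @return A list with `data` (the purged phenotype table), `cycles` (one
#'   report per cycle: cycle index, flagged record_ids, the step-up
#'   threshold used, and the flagged p-values), `removed_ids`, and
#'   `n_cycles`.
#' @export
run_codpa <- function(data, terms, max_fdr = 0.30, max_cycles = 25L,
                      rel_tol = 1e-10) {
  stopifnot(max_fdr > 0, max_fdr < 1, max_cycles >= 1)
  data <- as_phenotypes(data)
  validate_term_set(terms)
  current <- data
  cycles <- list()
  repeat {
    if (length(cycles) >= max_cycles) break
    fit <- fit_svd(build_design(current, terms), rel_tol = rel_tol)
    pv <- studentized_pvalues(fit)
    flagged <- bh_flag(pv, max_fdr)
    if (!any(flagged)) break
    if (nrow(current) - sum(flagged) <= nrow(terms) + 1L) {
      warning("outlier purge would leave n <= p + 1 records; stopping")
      break
    }
    m <- length(pv)
    k <- sum(flagged)
    cycles[[length(cycles) + 1L]] <- list(
      cycle = length(cycles) + 1L,
      record_ids = current$record_id[flagged],
      bh_threshold = k * max_fdr / m,
      p_values = pv[flagged]
    )
    current <- current[!flagged, , drop = FALSE]
  }
  list(
    data = current,
    cycles = cycles,
    removed_ids = setdiff(data$record_id, current$record_id),
    n_cycles = length(cycles)
  )
}
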