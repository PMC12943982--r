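#' Build a polynomial design matrix from a phenotype table
#'
#' Evaluates each term of `terms` on the raw (unscaled) predictors of every
#' record, in the given term order. No centering or standardization is
#' applied anywhere: coefficients are in raw trait units so that fitted
#' slopes are directly comparable across runs and interpretable in
#' g/plant per trait unit.
#'
#' @param data a validated phenotype data frame ([as_phenotypes()]).
#' @param terms a `term_set`; defaults to the full 15-term quadratic set.
#' @param response optional numeric response vector overriding `sdw_g`
#'   (used by the auxiliary heteroskedasticity regression).
#' @return A `design_matrix`: list with `values` (n x p matrix, columns
#'   named by term label), `terms`, `response`, `record_id`.
#' @export
#' @examples
#' d <- generate_phenotypes(synth_config(seed = 1))$data
#' dm <- build_design(d)
#' ncol(dm$values)  # 15
build_design <- function(data, terms = quadratic_terms(), response = NULL) {
  data <- as_phenotypes(data)
  validate_term_set(terms)
  X <- predictor_matrix(data)
  k <- ncol(X)
  if (any(stats::na.omit(c(terms$i, terms$j)) > k)) {
    stop("term indexes a predictor beyond X", k)
  }
  n <- nrow(data)
  p <- nrow(terms)
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, terms$label))
  for (t in seq_len(p)) {
    vals[, t] <- switch(terms$kind[t],
      intercept = rep(1, n),
      linear = X[, terms$i[t]],
      square = X[, terms$i[t]]^2,
      cross = X[, terms$i[t]] * X[, terms$j[t]]
    )
  }
  y <- if (is.null(response)) data$sdw_g else as.numeric(response)
  if (length(y) != n) stop("response length must equal the record count")
  structure(
    list(values = vals, terms = terms, response = y,
         record_id = data$record_id),
    class = "design_matrix"
  )
}

#' Restrict a design matrix to a subset of terms
#'
#' Columns are restricted and reordered to the `keep` set; the response is
#' unchanged. Equivalent to building the subset design directly.
#'
#' @param design a `design_matrix`.
#' @param keep a `term_set` (or character vector of labels) contained in
#'   `design$terms`.
#' @return A `design_matrix` with the kept columns.
#' @export
select_terms <- function(design, keep) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.character(keep)) keep <- term_set(keep)
  validate_term_set(keep)
  idx <- match(keep$label, design$terms$label)
  if (anyNA(idx)) {
    stop("term(s) not present in design: ",
         paste(keep$label[is.na(idx)], collapse = ", "))
  }
  out <- design
  out$values <- design$values[, idx, drop = FALSE]
  out$terms <- keep
  out
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$values), "records x", ncol(x$values),
      "terms (", paste(x$terms$label, collapse = ", "), ")\n")
  invisible(x)
}
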