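#' Candidate-term algebra for quadratic response-surface models
#'
#' A term set describes the columns of a polynomial design matrix over the
#' four phenotype predictors X1 = SPAD, X2 = Gs, X3 = shoot Na+, X4 = shoot
#' K+. Terms are one of four kinds: the intercept, a linear term `Xi`, a pure
#' square `Xi^2`, or a cross product `Xi:Xj` with i < j. The canonical order
#' is intercept, X1..X4, X1^2..X4^2, then cross terms lexicographically
#' (X1:X2, X1:X3, X1:X4, X2:X3, X2:X4, X3:X4): the full quadratic set over
#' four predictors has exactly 1 + 4 + 4 + 6 = 15 terms.
#'
#' @param k number of predictors (default 4; the phenotype model uses 4).
#' @return A `term_set` object: a data frame with columns `kind`, `i`, `j`
#'   and `label`, one row per term, in canonical order.
#' @export
#' @examples
#' quadratic_terms()        # all 15 candidate terms
#' term_set(c("X2", "X4", "X1^2", "X2^2", "X4^2"))
quadratic_terms <- function(k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  kind <- c("intercept", rep("linear", k), rep("square", k))
  i <- c(NA_integer_, seq_len(k), seq_len(k))
  j <- rep(NA_integer_, 1L + 2L * k)
  if (k >= 2L) {
    cross <- t(utils::combn(k, 2L))
    kind <- c(kind, rep("cross", nrow(cross)))
    i <- c(i, cross[, 1L])
    j <- c(j, cross[, 2L])
  }
  new_term_set(kind, i, j)
}

new_term_set <- function(kind, i, j) {
  ts <- data.frame(kind = kind, i = i, j = j, stringsAsFactors = FALSE)
  ts$label <- term_label(ts$kind, ts$i, ts$j)
  validate_term_set(ts)
  class(ts) <- c("term_set", "data.frame")
  ts
}

term_label <- function(kind, i, j) {
  ifelse(kind == "intercept", "(Intercept)",
    ifelse(kind == "linear", paste0("X", i),
      ifelse(kind == "square", paste0("X", i, "^2"),
        paste0("X", i, ":X", j))))
}

validate_term_set <- function(ts) {
  ok_kind <- ts$kind %in% c("intercept", "linear", "square", "cross")
  if (!all(ok_kind)) {
    stop("unknown term kind(s): ", paste(unique(ts$kind[!ok_kind]), collapse = ", "))
  }
  need_i <- ts$kind != "intercept"
  if (any(is.na(ts$i[need_i])) || any(ts$i[need_i] < 1L)) {
    stop("linear/square/cross terms need a valid predictor index")
  }
  cr <- ts$kind == "cross"
  if (any(cr) && (any(is.na(ts$j[cr])) || any(ts$i[cr] >= ts$j[cr]))) {
    stop("cross terms must have two distinct indices with i < j")
  }
  if (anyDuplicated(ts$label)) {
    stop("duplicate term(s): ", paste(unique(ts$label[duplicated(ts$label)]), collapse = ", "))
  }
  invisible(ts)
}

#' Build a term set from labels
#'
#' Labels follow the canonical notation: `"(Intercept)"`, `"X2"`, `"X1^2"`,
#' `"X3:X4"`. The returned set preserves the given order.
#'
#' @param labels character vector of term labels.
#' @return A `term_set`.
#' @export
term_set <- function(labels) {
  parse_one <- function(lab) {
    if (lab == "(Intercept)") return(list(kind = "intercept", i = NA_integer_, j = NA_integer_))
    m <- regmatches(lab, regexec("^X([0-9]+)\\^2$", lab))[[1]]
    if (length(m) == 2L) return(list(kind = "square", i = as.integer(m[2]), j = NA_integer_))
    m <- regmatches(lab, regexec("^X([0-9]+):X([0-9]+)$", lab))[[1]]
    if (length(m) == 3L) return(list(kind = "cross", i = as.integer(m[2]), j = as.integer(m[3])))
    m <- regmatches(lab, regexec("^X([0-9]+)$", lab))[[1]]
    if (length(m) == 2L) return(list(kind = "linear", i = as.integer(m[2]), j = NA_integer_))
    stop("cannot parse term label: ", lab)
  }
  parsed <- lapply(as.character(labels), parse_one)
  new_term_set(
    kind = vapply(parsed, `[[`, character(1), "kind"),
    i = vapply(parsed, `[[`, integer(1), "i"),
    j = vapply(parsed, `[[`, integer(1), "j")
  )
}

#' The selected shoot-dry-weight model structure
#'
#' The five-term structure retained by the stepwise search on the rice
#' glasshouse data: linear Gs and K+ terms plus pure squares of SPAD, Gs and
#' K+, with no intercept, no Na+ term and no cross terms.
#'
#' @return A `term_set` with terms X2, X4, X1^2, X2^2, X4^2.
#' @export
sdw_terms <- function() {
  term_set(c("X2", "X4", "X1^2", "X2^2", "X4^2"))
}

#' @export
print.term_set <- function(x, ...) {
  cat("term_set with", nrow(x), "term(s):", paste(x$label, collapse = ", "), "\n")
  invisible(x)
}
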