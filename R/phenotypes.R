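#' Read a record-level phenotype table
#'
#' The expected dialect is comma-separated UTF-8 with a header row naming the
#' canonical columns: `genotype`, `salinity_mM`, `spad`, `gs_mmol_m2_s`,
#' `shoot_na_mM`, `shoot_k_mM`, `sdw_g`, and optionally `record_id`. One row
#' is one plant observation: the SPAD chlorophyll index (X1), stomatal
#' conductance in mmol m-2 s-1 (X2), shoot sap Na+ and K+ in mM (X3, X4) and
#' shoot dry weight in g/plant (the response Y).
#'
#' Validation is strict: all trait columns must be finite, `gs_mmol_m2_s`,
#' `shoot_na_mM`, `shoot_k_mM` and `sdw_g` must be non-negative, and
#' `record_id` (assigned sequentially when absent) must be unique. Missing
#' values are rejected; the pipeline performs no imputation.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with the canonical columns, one row per record,
#'   in file order.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_phenotypes(raw)
}

phenotype_columns <- function() {
  c("genotype", "salinity_mM", "spad", "gs_mmol_m2_s",
    "shoot_na_mM", "shoot_k_mM", "sdw_g")
}

#' Validate a data frame as a phenotype table
#'
#' @param data a data frame holding the canonical columns (see
#'   [read_phenotypes()]).
#' @return The validated data frame with a `record_id` column first.
#' @export
as_phenotypes <- function(data) {
  cols <- phenotype_columns()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"record_id" %in% names(data)) {
    data$record_id <- seq_len(nrow(data))
  }
  if (anyDuplicated(data$record_id)) {
    stop("record_id values must be unique")
  }
  numeric_cols <- setdiff(cols, "genotype")
  for (cl in numeric_cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(as.numeric(v))
      if (anyNA(bad)) {
        stop("non-numeric value in column '", cl, "' at row ",
             which(is.na(bad))[1])
      }
      v <- bad
      data[[cl]] <- v
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-finite value in column '", cl, "' at row ",
           which(!is.finite(v))[1])
    }
  }
  nonneg <- c("gs_mmol_m2_s", "shoot_na_mM", "shoot_k_mM", "sdw_g")
  for (cl in nonneg) {
    if (any(data[[cl]] < 0)) {
      stop("negative value forbidden in column '", cl, "' at row ",
           which(data[[cl]] < 0)[1])
    }
  }
  data[, c("record_id", cols)]
}

#' Write a phenotype table in the canonical CSV dialect
#'
#' @param data a validated phenotype data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  data <- as_phenotypes(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# n x 4 matrix of raw predictors in model order X1..X4
predictor_matrix <- function(data) {
  cbind(X1 = data$spad, X2 = data$gs_mmol_m2_s,
        X3 = data$shoot_na_mM, X4 = data$shoot_k_mM)
}
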