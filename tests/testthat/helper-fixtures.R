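# Shared fixtures: tiny phenotype tables and random design instances built
# in code at test time.

# minimal valid phenotype table with given trait columns
make_phenotypes <- function(spad, gs, na, k, sdw, genotype = NULL,
                            salinity = 0) {
  n <- length(sdw)
  data.frame(
    genotype = if (is.null(genotype)) rep("G01", n) else genotype,
    salinity_mM = rep_len(salinity, n),
    spad = spad, gs_mmol_m2_s = gs, shoot_na_mM = na,
    shoot_k_mM = k, sdw_g = sdw
  )
}

# random small phenotype table with smooth positive response
random_phenotypes <- function(n, seed) {
  set.seed(seed)
  make_phenotypes(
    spad = runif(n, 15, 45),
    gs = runif(n, 15, 85),
    na = runif(n, 50, 350),
    k = runif(n, 30, 280),
    sdw = runif(n, 0.3, 3)
  )
}

# random full-rank design_matrix with arbitrary response
random_design <- function(n, labels, seed, noise_sd = 0.3) {
  d <- random_phenotypes(n, seed)
  dm <- saltreg::build_design(d, saltreg::term_set(labels))
  dm$response <- drop(dm$values %*% runif(ncol(dm$values), -1, 1)) +
    rnorm(n, 0, noise_sd)
  dm
}

# literal leave-one-out refit prediction error for record i
loo_prediction_error <- function(dm, i, rel_tol = 1e-10) {
  sub <- dm
  sub$values <- dm$values[-i, , drop = FALSE]
  sub$response <- dm$response[-i]
  sub$record_id <- dm$record_id[-i]
  fit <- saltreg::fit_svd(sub, rel_tol = rel_tol)
  dm$response[i] - drop(dm$values[i, , drop = FALSE] %*% fit$slopes)
}

planted_labels <- c("X2", "X4", "X1^2", "X2^2", "X4^2")
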