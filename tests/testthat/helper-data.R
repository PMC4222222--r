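# Shared fixture builders.  All data are generated in code at test time.

ICV_MIX_MEAN <- (49 * 1712.01 + 92 * 1513.88) / 141   # two-sex mixture mean

# Uniform-ICV power-law data for optimizer tests.
make_powerlaw_data <- function(n, alpha, beta, sigma, seed,
                               icv_range = c(1300, 1900)) {
  set.seed(seed)
  icv <- runif(n, icv_range[1], icv_range[2])
  list(icv = icv, voi = alpha * icv^beta + rnorm(n, 0, sigma))
}

# Single-region spec at the study's sex-mixture ICV design.  sigma is
# calibrated so a fit at n = 141 reports roughly `se_target`; the anchor
# (typical volume, target SE) defaults to the reference region whose
# exponent is nearest to beta.
make_region_spec <- function(beta, seed, n_male = 49, n_female = 92,
                             typ = NULL, se_target = NULL, name = "r",
                             noise_mode = "additive_normal") {
  ref <- reference_exponents()
  anchor <- ref[which.min(abs(ref$beta - beta)), ]
  if (is.null(typ)) typ <- anchor$typical_vol
  if (is.null(se_target)) se_target <- anchor$se
  alpha <- typ / ICV_MIX_MEAN^beta
  sigma <- calibrate_sigma(alpha, beta, se_target = se_target)
  synthetic_spec(n_male, n_female,
                 regions = data.frame(region = name, alpha = alpha,
                                      beta = beta, sigma = sigma),
                 noise_mode = noise_mode, seed = seed)
}

write_tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}

# A hand-built power_law_fit for flag/printing tests.
fake_fit <- function(ci, beta = mean(ci), converged = TRUE) {
  structure(list(region = "fake", n = 141, alpha_hat = 1, beta_hat = beta,
                 se_alpha = 0.1, se_beta = diff(ci) / 4, sigma2_hat = 1,
                 sse = 139, df = 139L, ci_level = 0.95, ci_beta = ci,
                 converged = converged, iterations = 1L),
            class = "power_law_fit")
}
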