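test_that("power-proportion correction special cases and worked value", {
  set.seed(31)
  icv <- runif(50, 1300, 1900)
  voi <- 0.002 * icv^0.8 + rnorm(50, 0, 0.2)

  # b = 1 is bit-identical to the proportion method; b = 0 is the identity
  expect_identical(apply_power_proportion(voi, icv, b = 1),
                   apply_proportion(voi, icv))
  expect_identical(apply_power_proportion(voi, icv, b = 0), voi)

  # worked value, cross-checked by independent exponentiation via logs
  got <- apply_power_proportion(3.5, 1600, b = 0.80)
  expect_equal(got, exp(log(3.5) - 0.80 * log(1600)), tolerance = 1e-12)
  expect_equal(got, 9.566e-3, tolerance = 1e-4)

  expect_error(apply_power_proportion(voi, -icv, b = 1))
  expect_error(apply_power_proportion(voi, icv, b = Inf))
})

test_that("linear ANCOVA residual correction matches the normal equations", {
  # a perfect line leaves zero residuals: all corrected values = mean
  expect_equal(apply_ancova_residual(c(2, 4, 6), c(1, 2, 3)),
               rep(4, 3), ignore_attr = TRUE)
  # zero fitted slope returns the data unchanged (recentred residuals)
  y <- c(5, 7, 5, 7)
  x <- c(1, 1, 2, 2)
  expect_equal(apply_ancova_residual(y, x), y, ignore_attr = TRUE)

  set.seed(32)
  icv <- runif(60, 1300, 1900)
  voi <- 1 + 0.004 * icv + rnorm(60, 0, 0.3)
  got <- apply_ancova_residual(voi, icv, recentre = FALSE)
  want <- oracle_ols_residuals(cbind(1, icv), voi)
  expect_equal(as.numeric(got), want, tolerance = 1e-10)

  expect_error(apply_ancova_residual(voi[1:5], rep(1500, 5)), "constant")
})

test_that("quadratic ANCOVA correction nests the linear fit", {
  x <- seq(1300, 1900, length.out = 30)
  para <- 2 + 0.001 * (x - 1600) + 1e-5 * (x - 1600)^2
  expect_equal(as.numeric(apply_ancova_quadratic(para, x, recentre = FALSE)),
               rep(0, 30), tolerance = 1e-8)

  lin <- 1 + 0.004 * x
  qfit <- apply_ancova_quadratic(lin, x)
  expect_lt(abs(attr(qfit, "coefficients")[["quadratic"]]), 1e-8)
  expect_false(attr(qfit, "quad_significant"))

  d <- make_powerlaw_data(141, alpha = 3.5 / 1600^0.6, beta = 0.6,
                          sigma = 0.3, seed = 33)
  sse_quad <- sum(apply_ancova_quadratic(d$voi, d$icv,
                                         recentre = FALSE)^2)
  sse_lin <- sum(apply_ancova_residual(d$voi, d$icv, recentre = FALSE)^2)
  expect_lte(sse_quad, sse_lin)

  expect_error(apply_ancova_quadratic(c(1, 2, 3, 4), c(1, 1, 2, 2)),
               "distinct")
})

test_that("log-log residual correction is exact without noise and unbiased under its own model", {
  icv <- seq(1300, 1900, length.out = 40)
  alpha <- 3.5 / 1600^0.8
  voi <- alpha * icv^0.8
  got <- apply_loglog_residual(voi, icv)
  expect_equal(attr(got, "b_log"), 0.8, tolerance = 1e-10)
  expect_equal(as.numeric(got), rep(alpha, 40), tolerance = 1e-10)

  # proportional noiseless data: identical to the plain ratio
  expect_equal(as.numeric(apply_loglog_residual(2e-3 * icv, icv)),
               as.numeric(apply_proportion(2e-3 * icv, icv)),
               tolerance = 1e-10)

  # under multiplicative log-normal noise the log-log slope is unbiased
  set.seed(34)
  voi_m <- alpha * icv^0.7 * exp(rnorm(40, 0, 0.1))
  got_m <- apply_loglog_residual(voi_m, icv)
  se_blog <- summary(lm(log(voi_m) ~ log(icv)))$coefficients[2, 2]
  expect_lt(abs(attr(got_m, "b_log") - 0.7), 2 * se_blog)

  expect_error(apply_loglog_residual(c(-1, 2, 3), icv[1:3]), "positive")
})

test_that("table-level correction records parameters that reproduce the values", {
  tab <- simulate_table(make_region_spec(0.8, seed = 35, name = "caudate"),
                        quiet = TRUE)
  corr <- correct_volumes(tab, method = "power_proportion")
  expect_s3_class(corr, "corrected_table")
  expect_true(all(is.finite(corr$corrected_value)))
  pars <- attr(corr, "parameters")[["caudate"]]
  expect_equal(pars$b_source, "fitted")
  # reproduce from the recorded exponent alone
  expect_equal(corr$corrected_value,
               as.numeric(tab$caudate / tab$icv^pars$b), tolerance = 1e-12)

  # supplied b and fits-object b agree with direct computation
  corr_b <- correct_volumes(tab, method = "power_proportion", b = 1)
  expect_identical(corr_b$corrected_value,
                   as.numeric(apply_proportion(tab$caudate, tab$icv)))
  fits <- fit_all_regions(tab)
  corr_f <- correct_volumes(tab, method = "power_proportion", fits = fits)
  expect_equal(corr_f$corrected_value, corr$corrected_value,
               tolerance = 1e-12)

  # writer emits a parseable long CSV with provenance
  p <- tempfile(fileext = ".csv")
  write_corrected_table(corr, p)
  got <- utils::read.csv(p)
  expect_equal(nrow(got), nrow(corr))
  expect_match(got$parameters[1], "b=.*b_source=fitted")

  # residual methods stay on the volume scale when recentred
  corr_r <- correct_volumes(tab, method = "ancova_residual")
  expect_equal(mean(corr_r$corrected_value), mean(tab$caudate),
               tolerance = 1e-10)
})

test_that("corrections remove (or fail to remove) the ICV trend as expected", {
  # power-proportion with the fitted exponent: no residual ICV correlation
  big <- simulate_table(make_region_spec(0.8, seed = 36, n_male = 695,
                                         n_female = 1305, name = "r"),
                        quiet = TRUE)
  f <- fit_power_law(big$icv, big$r)
  ppc <- apply_power_proportion(big$r, big$icv, f$beta_hat)
  expect_lt(abs(cor(ppc, big$icv)), 3 / sqrt(nrow(big)))

  # the plain ratio under-corrects a sublinear structure: negative trend
  # (putamen-class scale and precision, the classic beta ~ 0.7 structure)
  tab <- simulate_table(make_region_spec(0.7, seed = 37, name = "r",
                                         typ = 4.0, se_target = 0.08),
                        quiet = TRUE)
  ratio <- apply_proportion(tab$r, tab$icv)
  ds <- residual_slope(ratio, tab$icv)
  expect_lt(ds$slope, 0)
  expect_lt(ds$p_value, 0.05)

  # residual methods are orthogonal to ICV by construction
  res <- apply_ancova_residual(tab$r, tab$icv)
  expect_lt(abs(residual_slope(res, tab$icv)$slope), 1e-8)
  resq <- apply_ancova_quadratic(tab$r, tab$icv)
  expect_lt(abs(residual_slope(resq, tab$icv)$slope), 1e-8)
  ic2 <- (tab$icv - mean(tab$icv))^2
  expect_lt(abs(lm.fit(cbind(1, ic2), as.numeric(resq))$coefficients[[2]]),
            1e-8)
})
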