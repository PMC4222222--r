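# Nonlinear least-squares estimation of the allometric scaling model
#   voi = alpha * icv^beta + e,   e ~ N(0, sigma^2)  (additive noise).
#
# ICV is rescaled by its sample geometric mean before optimization:
# icv^beta with icv ~ 1500 cc makes the two Jacobian columns differ by
# orders of magnitude, while u = icv/gm keeps u^beta near 1.  beta and
# se(beta) are invariant to this rescaling; alpha is back-transformed.

# residuals and their Jacobian on the rescaled axis
# (data arguments are named xs/ys: a bare `u` would partially match
# nls.lm's `upper`)
.pl_resid <- function(par, xs, ys) ys - par[1] * xs^par[2]
.pl_jac <- function(par, xs, ys) {
  ub <- xs^par[2]
  -cbind(ub, par[1] * ub * log(xs))
}

.pl_lm <- function(u, voi, start, max_iter, ftol) {
  minpack.lm::nls.lm(
    par = start, fn = .pl_resid, jac = .pl_jac, xs = u, ys = voi,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = 1e-12, gtol = 1e-12))
}

#' Profiled least-squares scale constant for a fixed exponent
#'
#' For fixed `beta`, the alpha minimizing `sum((voi - alpha * icv^beta)^2)`
#' has the closed form `sum(voi * icv^beta) / sum(icv^(2*beta))`.  Used to
#' profile alpha out in the exponent grid search and to refine starting
#' values.
#'
#' @param beta fixed exponent.
#' @param icv,voi numeric vectors of equal length; `icv > 0`.
#' @return The profiled alpha (scalar).
#' @examples
#' profile_alpha(1, icv = c(1, 2), voi = c(3, 5))  # 13/5
#' @export
profile_alpha <- function(beta, icv, voi) {
  stopifnot(length(icv) == length(voi), length(icv) >= 1, all(icv > 0))
  w <- icv^beta
  den <- sum(w^2)
  if (!is.finite(den) || den == 0)
    stop("icv^(2*beta) degenerate (overflow or all zero)", call. = FALSE)
  sum(voi * w) / den
}

#' Brute-force exponent search with profiled scale constant
#'
#' Minimizes the residual sum of squares over a regular grid of exponents
#' with alpha profiled out at each grid point.  This is the package's
#' derivative-free fallback when Levenberg-Marquardt stalls, and an
#' independent route for cross-checking the nonlinear optimizer.
#'
#' @param icv,voi data vectors, `icv > 0`.
#' @param lower,upper,step grid of exponents (default 0 to 3 by 1e-3).
#' @return List with `beta`, `alpha`, `sse` at the best grid point.
#' @export
grid_search_exponent <- function(icv, voi, lower = 0, upper = 3, step = 1e-3) {
  stopifnot(length(icv) == length(voi), all(icv > 0))
  gm <- exp(mean(log(icv)))
  lu <- log(icv / gm)
  betas <- seq(lower, upper, by = step)
  syy <- sum(voi^2)
  best <- c(sse = Inf, beta = NA_real_, alpha = NA_real_)
  for (chunk in split(betas, ceiling(seq_along(betas) / 512))) {
    M <- exp(outer(lu, chunk))              # n x k matrix of u^beta
    num <- as.numeric(crossprod(voi, M))
    den <- .colSums(M * M, length(lu), length(chunk))
    sse <- syy - num^2 / den
    j <- which.min(sse)
    if (sse[j] < best["sse"])
      best <- c(sse = sse[j], beta = chunk[j], alpha = num[j] / den[j])
  }
  list(beta = unname(best["beta"]),
       alpha = unname(best["alpha"]) / gm^unname(best["beta"]),
       sse = unname(best["sse"]))
}

#' Fit the power-law scaling model by nonlinear least squares
#'
#' Estimates `(alpha, beta)` in `voi = alpha * icv^beta + e` by
#' Levenberg-Marquardt with an analytic Jacobian, started from the log-log
#' ordinary-least-squares fit (slope -> beta, exp(intercept) -> alpha),
#' which is the closely related multiplicative-error linearization and is
#' near-optimal for additive noise of moderate size.  Standard errors come
#' from the Gauss-Newton linearization, `sigma2_hat * (J'J)^-1` with
#' `sigma2_hat = SSE / (n - 2)`, and the confidence interval for beta is
#' the Wald interval with t quantiles on `n - 2` degrees of freedom.
#'
#' If Levenberg-Marquardt fails to converge the fit falls back to
#' [grid_search_exponent()] followed by a restarted Marquardt pass;
#' `converged = FALSE` is reported if that also stalls, together with the
#' best point found.
#'
#' @param icv,voi paired observations; at least 3 finite pairs with
#'   `icv > 0`, `icv` not all equal.  Non-finite pairs are dropped.
#'   Nonpositive `voi` values (possible under heavy additive noise) are
#'   tolerated by the least-squares fit.
#' @param region optional region label carried into the result.
#' @param init optional starting values `c(alpha, beta)` on the original
#'   icv scale; default log-log OLS.
#' @param max_iter maximum Marquardt iterations (default 200).
#' @param tol relative SSE-change convergence tolerance (default 1e-10).
#' @param ci_level nominal confidence level (default 0.95).
#' @return An object of class `power_law_fit`: a list with elements
#'   `region`, `n`, `alpha_hat`, `beta_hat`, `se_alpha`, `se_beta`,
#'   `sigma2_hat`, `sse`, `df`, `ci_level`, `ci_beta` (length-2),
#'   `converged`, `iterations`.
#' @examples
#' icv <- seq(1300, 1900, length.out = 20)
#' fit <- fit_power_law(icv, 0.002 * icv)   # proportional, noiseless
#' round(fit$beta_hat, 6)
#' @export
fit_power_law <- function(icv, voi, region = NA_character_, init = NULL,
                          max_iter = 200L, tol = 1e-10, ci_level = 0.95) {
  # volumes are positive by definition, but under additive noise a large
  # sigma can push observations to/below zero; the least-squares fit is
  # well defined there, so only non-finite pairs are dropped
  keep <- is.finite(icv) & is.finite(voi) & icv > 0
  icv <- icv[keep]; voi <- voi[keep]
  n <- length(icv)
  if (n < 3L)
    stop("insufficient data: at least 3 paired observations with positive icv needed",
         call. = FALSE)
  if (diff(range(icv)) <= .Machine$double.eps * max(icv) * 8)
    stop("icv is constant: the exponent is not identifiable", call. = FALSE)

  gm <- exp(mean(log(icv)))
  u <- icv / gm
  if (is.null(init)) {
    pos <- voi > 0
    if (sum(pos) >= 3) {         # log-log OLS start on the positive subset
      ll <- lm.fit(cbind(1, log(u[pos])), log(voi[pos]))
      start <- c(alpha = exp(ll$coefficients[[1]]),
                 beta = ll$coefficients[[2]])
    } else {                     # degenerate data: coarse grid start
      g0 <- grid_search_exponent(u, voi, 0, 3, 1e-2)
      start <- c(alpha = g0$alpha, beta = g0$beta)
    }
  } else {
    start <- c(alpha = init[[1]] * gm^init[[2]], beta = init[[2]])
  }
  start[1] <- profile_alpha(start[2], u, voi)   # refine scale at beta0

  fit <- .pl_lm(u, voi, start, max_iter, tol)
  converged <- fit$info %in% 1:4
  if (!converged) {
    g <- grid_search_exponent(u, voi, 0, 3, 1e-3)
    refit <- .pl_lm(u, voi, c(alpha = g$alpha, beta = g$beta), max_iter, tol)
    if (refit$deviance <= fit$deviance) fit <- refit
    converged <- fit$info %in% 1:4
  }

  a_s <- fit$par[[1]]; b <- fit$par[[2]]
  res <- .pl_resid(fit$par, u, voi)
  sse <- sum(res^2)
  df <- n - 2L
  sigma2 <- sse / df
  J <- -.pl_jac(fit$par, u, voi)                # Jacobian of the mean function
  cov_s <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov_s)) {
    se_beta <- se_alpha <- NA_real_
  } else {
    se_beta <- sqrt(cov_s[2, 2])
    # back-transform alpha = a_s * gm^-b by the delta method
    grad <- c(gm^(-b), -a_s * gm^(-b) * log(gm))
    se_alpha <- sqrt(drop(t(grad) %*% cov_s %*% grad))
  }
  ci <- if (is.na(se_beta)) c(NA_real_, NA_real_) else
    wald_ci(b, se_beta, level = ci_level, df = df)

  structure(list(
    region = region, n = n,
    alpha_hat = a_s / gm^b, beta_hat = b,
    se_alpha = se_alpha, se_beta = se_beta,
    sigma2_hat = sigma2, sse = sse, df = df,
    ci_level = ci_level, ci_beta = ci,
    converged = converged, iterations = fit$niter),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law scaling fit%s (n = %d%s)\n",
              if (is.na(x$region)) "" else paste0(": ", x$region),
              x$n, if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  beta  = %.4f  (SE %.4f, %d%% CI %.4f to %.4f)\n",
              x$beta_hat, x$se_beta, round(100 * x$ci_level),
              x$ci_beta[1], x$ci_beta[2]))
  cat(sprintf("  alpha = %.6g  (SE %.3g)   sigma2 = %.4g on %d df\n",
              x$alpha_hat, x$se_alpha, x$sigma2_hat, x$df))
  invisible(x)
}

#' Wald confidence interval
#'
#' `estimate +/- t_{df,(1+level)/2} * se`.  At the sample sizes typical of
#' volumetric studies the t and normal quantiles agree to two decimals;
#' the t quantile is used because the residual variance is estimated.
#'
#' @param estimate point estimate.
#' @param se standard error, `>= 0`.
#' @param level nominal level in (0, 1).
#' @param df residual degrees of freedom, `>= 1`.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' round(wald_ci(0.72, 0.08, 0.95, 139), 2)
#' @export
wald_ci <- function(estimate, se, level = 0.95, df) {
  stopifnot(se >= 0, level > 0, level < 1, df >= 1)
  half <- qt((1 + level) / 2, df = df) * se
  c(estimate - half, estimate + half)
}

#' Flag a region as non-proportional to ICV
#'
#' A region scales non-proportionally when the confidence interval for its
#' exponent excludes 1 (the proportionality value).  The closed-interval
#' convention is used: an interval with an endpoint exactly at 1 is *not*
#' flagged.
#'
#' @param fit a converged [fit_power_law()] result.
#' @return `TRUE` iff 1 lies strictly outside the interval.
#' @export
flag_nonproportional <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!isTRUE(fit$converged))
    stop("nonproportionality flag is undefined for an unconverged fit",
         call. = FALSE)
  ci <- fit$ci_beta
  !(ci[1] <= 1 && 1 <= ci[2])
}

#' Fit the scaling model to every region of a volume table
#'
#' Each region is fitted independently on its own non-missing subjects;
#' a failure in one region (too few observations, degenerate ICV) is
#' recorded and does not abort the batch.  No multiplicity adjustment is
#' applied across regions; interval levels are per-region nominal levels
#' and should be interpreted accordingly.
#'
#' @param table a [volume_table()].
#' @param ci_level nominal confidence level (default 0.95).
#' @param group_col,reference optional: fit exponents on the subset of
#'   rows with `table[[group_col]] == reference` (e.g. healthy controls),
#'   for studies where the scaling norm should come from a reference group.
#' @param ... passed to [fit_power_law()].
#' @return An object of class `power_law_fits`: a named list of
#'   `power_law_fit` objects with a `"failures"` attribute (named character
#'   vector of error messages for regions that could not be fitted).
#'   `as.data.frame()` turns it into a fit table.
#' @export
fit_all_regions <- function(table, ci_level = 0.95, group_col = NULL,
                            reference = NULL, ...) {
  validate_volume_table(table)
  if (!is.null(group_col)) {
    if (!group_col %in% names(table))
      stop("no column '", group_col, "' in table", call. = FALSE)
    table <- table[table[[group_col]] %in% reference, , drop = FALSE]
    class(table) <- c("volume_table", "data.frame")
  }
  fits <- list()
  failures <- character(0)
  for (r in region_names(table)) {
    p <- region_pairs(table, r)
    f <- tryCatch(
      fit_power_law(p$icv, p$voi, region = r, ci_level = ci_level, ...),
      error = function(e) conditionMessage(e))
    if (inherits(f, "power_law_fit")) fits[[r]] <- f
    else failures[r] <- f
  }
  structure(fits, failures = failures, class = "power_law_fits")
}

#' @export
as.data.frame.power_law_fits <- function(x, ...) {
  rows <- lapply(unclass(x), function(f) data.frame(
    region = f$region, n = f$n,
    beta = f$beta_hat, se = f$se_beta,
    ci_lower = f$ci_beta[1], ci_upper = f$ci_beta[2],
    nonproportional = if (f$converged) flag_nonproportional(f) else NA,
    alpha = f$alpha_hat, se_alpha = f$se_alpha,
    sigma2 = f$sigma2_hat, sse = f$sse, df = f$df,
    converged = f$converged, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.power_law_fit <- function(x, ...) {
  as.data.frame(structure(list(x), names = x$region %||% "region",
                          class = "power_law_fits"))
}

#' @export
print.power_law_fits <- function(x, ...) {
  cat(sprintf("Power-law fits for %d region(s)\n", length(x)))
  print(format(as.data.frame(x)[c("region", "n", "beta", "se", "ci_lower",
                                  "ci_upper", "nonproportional", "converged")],
               digits = 3), row.names = FALSE)
  fl <- attr(x, "failures")
  if (length(fl))
    cat("Failed regions:\n",
        paste(sprintf("  %s: %s", names(fl), fl), collapse = "\n"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
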