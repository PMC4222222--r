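# Model comparison by leave-one-out cross-validation, and the
# corrected-volume-vs-ICV slope diagnostic.

# One fold's fit + prediction for each candidate mean model.  The power
# model is warm-started from the full-data parameters (scaled axis); cold
# starts re-derive log-log OLS starts inside each fold.
.fold_predict <- function(model, icv_tr, voi_tr, icv_new, warm = NULL) {
  switch(model,
    linear = {
      if (length(icv_tr) < 3) stop("fold too small for the linear model")
      co <- lm.fit(cbind(1, icv_tr), voi_tr)$coefficients
      co[[1]] + co[[2]] * icv_new
    },
    quadratic = {
      if (length(icv_tr) < 4) stop("fold too small for the quadratic model")
      m <- mean(icv_tr)
      ic <- icv_tr - m
      co <- lm.fit(cbind(1, ic, ic^2), voi_tr)$coefficients
      d <- icv_new - m
      co[[1]] + co[[2]] * d + co[[3]] * d^2
    },
    power_law = {
      if (length(icv_tr) < 3) stop("fold too small for the power-law model")
      if (is.null(warm)) {
        f <- fit_power_law(icv_tr, voi_tr, max_iter = 100L)
        f$alpha_hat * icv_new^f$beta_hat
      } else {
        u <- icv_tr / warm$gm
        start <- c(alpha = warm$alpha_s, beta = warm$beta)
        fit <- .pl_lm(u, voi_tr, start, max_iter = 100L, ftol = 1e-10)
        fit$par[[1]] * (icv_new / warm$gm)^fit$par[[2]]
      }
    },
    stop("unknown model '", model, "'"))
}

#' Leave-one-out cross-validated prediction error
#'
#' For each subject i the chosen mean model is refitted without subject i
#' and subject i's volume is predicted; the prediction error is the sum of
#' squared differences between observed and predicted volumes.  Candidate
#' mean models: the power law `alpha * icv^beta` (nonlinear least
#' squares), the straight line `a + b * icv` (OLS) and the quadratic
#' `a + b * icv + c * icv^2` (OLS, centred ICV).
#'
#' @param icv,voi paired observations (cc); at least 4 pairs.
#' @param model `"power_law"`, `"linear"` or `"quadratic"`.
#' @param warm_start warm-start the power-law refits from the full-data
#'   fit (default `TRUE`; cold and warm starts agree to optimizer
#'   tolerance, the warm path just skips the per-fold initialization).
#' @param region optional label carried into the result.
#' @return An object of class `cv_result`: list with `region`, `model`,
#'   `prediction_error` (cc^2, summed over successful folds), `n_folds`,
#'   `per_fold_errors` (length n, `NA` at failed folds) and
#'   `failed_folds` (integer indices).  A warning is raised when any fold
#'   fails.
#' @export
loocv_error <- function(icv, voi, model = c("power_law", "linear",
                                            "quadratic"),
                        warm_start = TRUE, region = NA_character_) {
  model <- match.arg(model)
  keep <- is.finite(icv) & is.finite(voi)
  icv <- icv[keep]; voi <- voi[keep]
  n <- length(icv)
  if (n < 4L) stop("leave-one-out needs at least 4 observations",
                   call. = FALSE)
  warm <- NULL
  if (model == "power_law" && warm_start) {
    full <- tryCatch(fit_power_law(icv, voi), error = function(e) NULL)
    if (!is.null(full)) {
      gm <- exp(mean(log(icv)))
      warm <- list(gm = gm, alpha_s = full$alpha_hat * gm^full$beta_hat,
                   beta = full$beta_hat)
    }
  }
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pred <- tryCatch(
      .fold_predict(model, icv[-i], voi[-i], icv[i], warm = warm),
      error = function(e) NA_real_)
    if (is.finite(pred)) errs[i] <- (voi[i] - pred)^2
  }
  failed <- which(is.na(errs))
  if (length(failed) == n)
    stop("every leave-one-out fold failed for model '", model, "'",
         call. = FALSE)
  if (length(failed))
    warning(length(failed), " of ", n, " folds failed for model '", model,
            "'; prediction error summed over successful folds",
            call. = FALSE)
  structure(list(region = region, model = model,
                 prediction_error = sum(errs[is.finite(errs)]),
                 n_folds = n, per_fold_errors = errs,
                 failed_folds = failed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOOCV %s%s: prediction error %.6g over %d folds%s\n",
              x$model, if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
              x$prediction_error, x$n_folds,
              if (length(x$failed_folds))
                sprintf(" (%d failed)", length(x$failed_folds)) else ""))
  invisible(x)
}

#' Compare mean models by LOOCV across all regions
#'
#' Runs [loocv_error()] for every (region, model) pair, fits the scaling
#' exponent per region, and summarizes which model has the lowest
#' prediction error together with whether the exponent's confidence
#' interval excludes 1.  Regions where the exponent differs from 1 are
#' where the power-law and straight-line mean models genuinely diverge;
#' where the interval contains 1 the two are expected to predict almost
#' identically.
#'
#' @param table a [volume_table()].
#' @param models subset of `c("power_law", "linear", "quadratic")`.
#' @param ci_level level for the exponent interval (default 0.95).
#' @param warm_start passed to [loocv_error()].
#' @return An object of class `model_comparison`: list with `results`
#'   (long data frame: region, model, prediction_error, n_folds,
#'   failed_folds, failed), `summary` (per region: best model, exponent
#'   interval excludes 1), and `fits` (the `power_law_fits`).
#' @export
compare_models <- function(table,
                           models = c("power_law", "linear", "quadratic"),
                           ci_level = 0.95, warm_start = TRUE) {
  validate_volume_table(table)
  models <- match.arg(models, several.ok = TRUE)
  fits <- fit_all_regions(table, ci_level = ci_level)
  rows <- list()
  for (r in region_names(table)) {
    p <- region_pairs(table, r)
    for (m in models) {
      cv <- tryCatch(
        suppressWarnings(loocv_error(p$icv, p$voi, model = m,
                                     warm_start = warm_start, region = r)),
        error = function(e) conditionMessage(e))
      rows[[paste(r, m)]] <- if (inherits(cv, "cv_result")) data.frame(
        region = r, model = m, prediction_error = cv$prediction_error,
        n_folds = cv$n_folds, failed_folds = length(cv$failed_folds),
        failed = FALSE, stringsAsFactors = FALSE)
      else data.frame(region = r, model = m, prediction_error = NA_real_,
                      n_folds = p$n, failed_folds = p$n, failed = TRUE,
                      stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summ <- do.call(rbind, lapply(split(results, results$region), function(d) {
    ok <- d[!d$failed & is.finite(d$prediction_error), , drop = FALSE]
    best <- if (nrow(ok)) ok$model[which.min(ok$prediction_error)]
            else NA_character_
    r <- d$region[1]
    excl <- if (r %in% names(fits) && fits[[r]]$converged)
      flag_nonproportional(fits[[r]]) else NA
    data.frame(region = r, best_model = best, ci_excludes_1 = excl,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("LOOCV model comparison\n")
  wide <- stats::reshape(x$results[c("region", "model", "prediction_error")],
                         idvar = "region", timevar = "model",
                         direction = "wide")
  names(wide) <- sub("^prediction_error\\.", "", names(wide))
  out <- merge(wide, x$summary, by = "region")
  print(format(out, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Slope of corrected volume on ICV
#'
#' The graphical check of an ICV correction: regress corrected values on
#' ICV by OLS.  A successful correction leaves no trend (slope and
#' correlation near 0); under-correction (e.g. the plain ratio applied to
#' a sublinear structure) shows a negative slope.
#'
#' @param corrected corrected volumes.
#' @param icv intracranial volumes (cc), non-constant.
#' @param region,method optional labels.
#' @return Object of class `slope_diagnostic`: `slope`, `pearson_r`,
#'   two-sided `p_value` for slope = 0, `n`, `degenerate` (`TRUE` when the
#'   corrected values are constant, in which case slope and r are reported
#'   as 0 with p = 1).
#' @export
residual_slope <- function(corrected, icv, region = NA_character_,
                           method = NA_character_) {
  corrected <- as.numeric(corrected)
  stopifnot(length(corrected) == length(icv))
  keep <- is.finite(corrected) & is.finite(icv)
  corrected <- corrected[keep]; icv <- icv[keep]
  n <- length(icv)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (var(icv) == 0) stop("zero ICV variance", call. = FALSE)
  if (var(corrected) == 0) {
    out <- list(region = region, method = method, slope = 0, pearson_r = 0,
                p_value = 1, n = n, degenerate = TRUE)
  } else {
    fit <- lm.fit(cbind(1, icv), corrected)
    slope <- fit$coefficients[[2]]
    s2 <- sum(fit$residuals^2) / (n - 2)
    se <- sqrt(s2 / sum((icv - mean(icv))^2))
    tval <- slope / se
    out <- list(region = region, method = method, slope = slope,
                pearson_r = cor(corrected, icv),
                p_value = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE),
                n = n, degenerate = FALSE)
  }
  structure(out, class = "slope_diagnostic")
}

#' @export
print.slope_diagnostic <- function(x, ...) {
  cat(sprintf("Corrected-vs-ICV slope%s: %.4g (r = %.3f, p = %.3g, n = %d)%s\n",
              if (is.na(x$method)) "" else paste0(" [", x$method, "]"),
              x$slope, x$pearson_r, x$p_value, x$n,
              if (x$degenerate) " [degenerate: constant corrected values]"
              else ""))
  invisible(x)
}
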