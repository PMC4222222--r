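# ICV-correction operations.  All vector-level functions take raw volumes
# and ICV (cc) and return corrected values; correct_volumes() applies one
# method across a volume table and records the parameters used.

#' Power-proportion correction
#'
#' `voi / icv^b`, with `b` the fitted scaling exponent of the power-law
#' model.  With `b = 1` this is exactly the proportion method; with
#' `b = 0` volumes are returned unchanged.
#'
#' @param voi,icv numeric vectors (cc); `icv > 0`.
#' @param b scaling exponent (finite scalar), typically `beta_hat` from
#'   [fit_power_law()].
#' @return `voi / icv^b` (units cc / cc^b).
#' @examples
#' apply_power_proportion(3.5, 1600, b = 0.80)
#' @export
apply_power_proportion <- function(voi, icv, b) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), all(icv > 0))
  voi / icv^b
}

#' Proportion correction
#'
#' The classical VOI-to-ICV ratio, `voi / icv`; identical to
#' [apply_power_proportion()] with `b = 1`.
#'
#' @inheritParams apply_power_proportion
#' @return `voi / icv` (dimensionless).
#' @export
apply_proportion <- function(voi, icv) {
  stopifnot(all(icv > 0))
  voi / icv
}

#' Linear ANCOVA (residual) correction
#'
#' Residuals of the ordinary least-squares regression `voi ~ 1 + icv`.
#' With `recentre = TRUE` (default) `mean(voi)` is added back so corrected
#' values stay on the cc scale.
#'
#' @inheritParams apply_power_proportion
#' @param recentre add `mean(voi)` to the residuals (default `TRUE`).
#' @return Corrected values (cc with recentring, else raw residuals).
#' @export
apply_ancova_residual <- function(voi, icv, recentre = TRUE) {
  stopifnot(length(voi) == length(icv), length(voi) >= 3)
  if (diff(range(icv)) <= .Machine$double.eps * max(abs(icv)) * 8)
    stop("icv is constant: linear correction not identifiable", call. = FALSE)
  fit <- lm.fit(cbind(1, icv), voi)
  r <- fit$residuals
  out <- if (recentre) r + mean(voi) else r
  attr(out, "coefficients") <- c(intercept = fit$coefficients[[1]],
                                 slope = fit$coefficients[[2]])
  out
}

#' Quadratic ANCOVA correction
#'
#' Residuals of `voi ~ 1 + icv + icv^2` (ICV mean-centred before squaring
#' for conditioning), recentred as in [apply_ancova_residual()].  The
#' result also reports whether the quadratic coefficient differs from 0
#' at the 5% level (attribute `quad_significant`), the check used to ask
#' whether curvature beyond a straight line is even detectable.
#'
#' @inheritParams apply_ancova_residual
#' @return Corrected values with attributes `coefficients` (on the centred
#'   scale), `quad_significant` and `quad_p_value`.
#' @export
apply_ancova_quadratic <- function(voi, icv, recentre = TRUE) {
  stopifnot(length(voi) == length(icv), length(voi) >= 4)
  if (length(unique(icv)) < 3)
    stop("icv needs at least 3 distinct values for a quadratic fit",
         call. = FALSE)
  ic <- icv - mean(icv)
  X <- cbind(1, ic, ic^2)
  qrX <- qr(X)
  if (qrX$rank < 3) stop("quadratic design is rank deficient", call. = FALSE)
  fit <- lm.fit(X, voi)
  r <- fit$residuals
  n <- length(voi)
  s2 <- sum(r^2) / (n - 3)
  covb <- s2 * chol2inv(qr.R(qrX))
  tq <- fit$coefficients[3] / sqrt(covb[3, 3])
  p <- 2 * pt(abs(tq), df = n - 3, lower.tail = FALSE)
  out <- if (recentre) r + mean(voi) else r
  attr(out, "coefficients") <- c(intercept = fit$coefficients[[1]],
                                 linear = fit$coefficients[[2]],
                                 quadratic = fit$coefficients[[3]])
  attr(out, "quad_p_value") <- p
  attr(out, "quad_significant") <- is.finite(p) && p < 0.05
  out
}

#' Log-log residual correction
#'
#' Fits `log(voi) ~ 1 + log(icv)` by OLS and returns the back-transformed
#' ratio `voi / icv^b_log`, where `b_log` is the log-log slope.  This is
#' the residual method applied on the log scale, returned in ratio form so
#' it is directly comparable with the power-proportion output.  The
#' log-log model implies multiplicative noise (variability growing with
#' ICV), in contrast to the additive-noise power-law fit.
#'
#' @inheritParams apply_power_proportion
#' @return `voi / icv^b_log`, with attribute `b_log`.
#' @export
apply_loglog_residual <- function(voi, icv) {
  stopifnot(length(voi) == length(icv), length(voi) >= 3)
  if (any(voi <= 0) || any(icv <= 0))
    stop("log-log correction requires strictly positive volumes and ICV",
         call. = FALSE)
  fit <- lm.fit(cbind(1, log(icv)), log(voi))
  b_log <- fit$coefficients[[2]]
  out <- voi / icv^b_log
  attr(out, "b_log") <- b_log
  out
}

#' Apply an ICV-correction method across a volume table
#'
#' Applies one of the five correction methods to every region of a volume
#' table.  For `power_proportion` the exponent can be supplied explicitly
#' (`b`, scalar or named per-region vector — e.g. fitted on a reference
#' group), taken from an existing [fit_all_regions()] result (`fits`), or
#' fitted in place.  The parameters actually used are recorded per region
#' so any corrected value can be reproduced exactly.
#'
#' @param table a [volume_table()].
#' @param method one of `"power_proportion"`, `"proportion"`,
#'   `"ancova_residual"`, `"ancova_quadratic"`, `"loglog_residual"`.
#' @param b optional exponent(s) for `power_proportion`.
#' @param fits optional `power_law_fits` providing exponents.
#' @param recentre passed to the residual methods.
#' @param ... passed to [fit_power_law()] for in-place fitting.
#' @return A `corrected_table`: long data frame with columns
#'   `subject_id`, `region`, `method`, `corrected_value`, plus a
#'   `"parameters"` attribute (named list per region).
#' @export
correct_volumes <- function(table,
                            method = c("power_proportion", "proportion",
                                       "ancova_residual", "ancova_quadratic",
                                       "loglog_residual"),
                            b = NULL, fits = NULL, recentre = TRUE, ...) {
  method <- match.arg(method)
  validate_volume_table(table)
  out <- list()
  params <- list()
  for (r in region_names(table)) {
    p <- region_pairs(table, r)
    if (p$n == 0) next
    res <- switch(method,
      power_proportion = {
        br <- if (!is.null(b)) {
          if (length(b) == 1L && is.null(names(b))) as.numeric(b)
          else if (r %in% names(b)) as.numeric(b[[r]])
          else stop("no exponent supplied for region '", r, "'", call. = FALSE)
        } else if (!is.null(fits)) {
          if (!r %in% names(fits))
            stop("fits object has no entry for region '", r, "'",
                 call. = FALSE)
          fits[[r]]$beta_hat
        } else fit_power_law(p$icv, p$voi, region = r, ...)$beta_hat
        params[[r]] <- list(b = br,
                            b_source = if (!is.null(b)) "supplied"
                                       else if (!is.null(fits)) "fits"
                                       else "fitted")
        apply_power_proportion(p$voi, p$icv, br)
      },
      proportion = {
        params[[r]] <- list(b = 1, b_source = "fixed")
        apply_proportion(p$voi, p$icv)
      },
      ancova_residual = {
        v <- apply_ancova_residual(p$voi, p$icv, recentre = recentre)
        params[[r]] <- c(as.list(attr(v, "coefficients")),
                         list(recentre = as.numeric(recentre),
                              mean_voi = mean(p$voi)))
        as.numeric(v)
      },
      ancova_quadratic = {
        v <- apply_ancova_quadratic(p$voi, p$icv, recentre = recentre)
        params[[r]] <- c(as.list(attr(v, "coefficients")),
                         list(icv_centre = mean(p$icv),
                              recentre = as.numeric(recentre),
                              mean_voi = mean(p$voi),
                              quad_p_value = attr(v, "quad_p_value")))
        as.numeric(v)
      },
      loglog_residual = {
        v <- apply_loglog_residual(p$voi, p$icv)
        params[[r]] <- list(b_log = attr(v, "b_log"))
        as.numeric(v)
      })
    out[[r]] <- data.frame(subject_id = p$subject_id, region = r,
                           method = method, corrected_value = as.numeric(res),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no usable region data to correct", call. = FALSE)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, parameters = params,
            class = c("corrected_table", "data.frame"))
}
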