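# Synthetic volume tables with the statistical structure the power-law
# correction assumes: sex-specific normal ICV, and per-region volumes
# alpha * icv^beta + e with additive homoscedastic Gaussian noise (or a
# multiplicative log-normal alternative).

# Default study conditions: 49 male / 92 female healthy adults with
# sex-specific ICV distributions N(1712.01, 138.54^2) and
# N(1513.88, 122.12^2) cc, and 43 FreeSurfer regions (9 subcortical
# including CSF, 34 cortical) at published scaling exponents with their
# standard errors at that sample size.
.icv_defaults <- list(n_male = 49L, n_female = 92L,
                      icv_male = c(mean = 1712.01, sd = 138.54),
                      icv_female = c(mean = 1513.88, sd = 122.12))

.region_table <- function() {
  # region, scaling exponent, SE of the exponent at n = 141, and a
  # plausible structure volume (cc) at the mean ICV used to set alpha.
  tab <- rbind(
    c("caudate",                  0.80, 0.10,  3.5),
    c("putamen",                  0.72, 0.08,  4.0),
    c("amygdala",                 0.77, 0.08,  1.5),
    c("hippocampus",              0.62, 0.06,  3.5),
    c("pallidum",                 0.80, 0.08,  1.5),
    c("accumbens",                0.95, 0.11,  0.6),
    c("thalamus",                 0.89, 0.07,  6.5),
    c("lateral_ventricle",        1.57, 0.41, 15.0),
    c("csf",                      0.66, 0.19,  1.0),
    c("bankssts",                 0.86, 0.12,  2.5),
    c("caudalanteriorcingulate",  0.69, 0.14,  1.8),
    c("caudalmiddlefrontal",      0.93, 0.11,  6.0),
    c("cuneus",                   0.52, 0.12,  3.0),
    c("entorhinal",               1.04, 0.12,  1.7),
    c("fusiform",                 0.80, 0.08,  9.0),
    c("inferiorparietal",         0.80, 0.10, 12.0),
    c("inferiortemporal",         1.06, 0.09, 10.0),
    c("isthmuscingulate",         0.88, 0.10,  2.5),
    c("lateraloccipital",         0.67, 0.08, 11.0),
    c("lateralorbitofrontal",     0.89, 0.07,  7.5),
    c("lingual",                  0.57, 0.11,  6.5),
    c("medialorbitofrontal",      0.94, 0.08,  5.5),
    c("middletemporal",           1.00, 0.09, 10.0),
    c("parahippocampal",          0.61, 0.10,  2.0),
    c("paracentral",              0.71, 0.10,  3.5),
    c("parsopercularis",          1.04, 0.12,  4.5),
    c("parsorbitalis",            0.65, 0.11,  2.0),
    c("parstriangularis",         0.94, 0.12,  4.0),
    c("pericalcarine",            0.64, 0.16,  2.0),
    c("postcentral",              0.88, 0.09, 10.0),
    c("posteriorcingulate",       0.96, 0.09,  3.0),
    c("precentral",               0.73, 0.08, 13.0),
    c("precuneus",                0.91, 0.09,  9.5),
    c("rostralanteriorcingulate", 1.17, 0.12,  2.5),
    c("rostralmiddlefrontal",     1.04, 0.10, 16.0),
    c("superiorfrontal",          0.96, 0.08, 20.0),
    c("superiorparietal",         0.80, 0.10, 13.0),
    c("superiortemporal",         0.89, 0.08, 11.0),
    c("supramarginal",            0.94, 0.09, 10.0),
    c("frontalpole",              0.68, 0.15,  1.0),
    c("temporalpole",             0.52, 0.11,  2.0),
    c("transversetemporal",       0.81, 0.13,  1.0),
    c("insula",                   1.06, 0.07,  6.5))
  data.frame(region = tab[, 1], beta = as.numeric(tab[, 2]),
             se = as.numeric(tab[, 3]), typical_vol = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Reference scaling exponents used by the default generator
#'
#' The 43 (region, exponent, SE) triples the default synthetic spec is
#' built on — published nonlinear-least-squares estimates for FreeSurfer
#' subcortical and cortical volumes in a healthy adult sample of 141 —
#' plus the plausible typical structure volume (cc) used to set each
#' region's scale constant.
#'
#' @return Data frame with columns `region`, `beta`, `se`, `typical_vol`.
#' @export
reference_exponents <- function() .region_table()

# Deterministic n-point sample of the two-sex ICV mixture (per-sex normal
# quantiles at mid-probabilities), used for calibration, not simulation.
.icv_calibration_sample <- function(n_male = 49L, n_female = 92L,
                                    icv_male = .icv_defaults$icv_male,
                                    icv_female = .icv_defaults$icv_female) {
  c(qnorm((seq_len(n_male) - 0.5) / n_male, icv_male[1], icv_male[2]),
    qnorm((seq_len(n_female) - 0.5) / n_female, icv_female[1], icv_female[2]))
}

#' Noise level implying a target exponent standard error
#'
#' Under the additive-noise power-law model the Gauss-Newton standard
#' error of the exponent is `sigma * sqrt([(J'J)^-1]_bb)`, with `J` the
#' Jacobian of the mean function over the design.  Inverting this gives
#' the residual standard deviation `sigma` at which a study with the given
#' ICV design would report standard error `se_target` — the calibration
#' used so simulated data reproduce the precision of a real study.
#'
#' @param alpha,beta generating parameters.
#' @param icv the ICV design (cc); defaults to a deterministic 141-point
#'   sample of the default sex-mixture distribution.
#' @param se_target desired standard error of the fitted exponent.
#' @return `sigma` in cc.
#' @export
calibrate_sigma <- function(alpha, beta, icv = .icv_calibration_sample(),
                            se_target) {
  gm <- exp(mean(log(icv)))
  u <- icv / gm
  a_s <- alpha * gm^beta
  J <- cbind(u^beta, a_s * u^beta * log(u))
  c_bb <- solve(crossprod(J))[2, 2]
  se_target / sqrt(c_bb)
}

#' Construct a synthetic-data specification
#'
#' Bundles everything [simulate_table()] needs: per-sex sample sizes and
#' ICV normal parameters, per-region generating triples
#' `(alpha, beta, sigma)`, the noise mode and the seed.
#'
#' @param n_male,n_female subject counts (total at least 3).
#' @param icv_male,icv_female `c(mean, sd)` in cc, sd > 0.
#' @param regions data frame with columns `region`, `alpha`, `beta`,
#'   `sigma` (`sigma` is the additive residual SD in cc, or the log-scale
#'   SD in multiplicative mode; `sigma >= 0`).
#' @param noise_mode `"additive_normal"` (constant-variance noise, the
#'   working assumption of the power-law fit) or
#'   `"multiplicative_lognormal"` (variability growing with ICV, the
#'   log-log model's implication).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @seealso [default_spec()] for the calibrated 43-region default.
#' @export
synthetic_spec <- function(n_male, n_female,
                           icv_male = .icv_defaults$icv_male,
                           icv_female = .icv_defaults$icv_female,
                           regions,
                           noise_mode = c("additive_normal",
                                          "multiplicative_lognormal"),
                           seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  n_male <- as.integer(n_male); n_female <- as.integer(n_female)
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female >= 3,
            icv_male[2] > 0, icv_female[2] > 0,
            is.data.frame(regions),
            all(c("region", "alpha", "beta", "sigma") %in% names(regions)),
            all(is.finite(regions$beta)), all(regions$sigma >= 0),
            all(regions$alpha > 0), !anyDuplicated(regions$region))
  structure(list(n_male = n_male, n_female = n_female,
                 icv_male = c(mean = unname(icv_male[1]),
                              sd = unname(icv_male[2])),
                 icv_female = c(mean = unname(icv_female[1]),
                                sd = unname(icv_female[2])),
                 regions = regions[c("region", "alpha", "beta", "sigma")],
                 noise_mode = noise_mode, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default calibrated synthetic specification
#'
#' The study conditions the package simulates by default: 49 males and 92
#' females with the sex-specific ICV normals above, and the 43 regions of
#' [reference_exponents()] generated at their published exponents.  Each
#' region's `alpha` is set so its volume at the mixture-mean ICV equals
#' the region's typical volume, and `sigma` is calibrated with
#' [calibrate_sigma()] so that a fit at n = 141 reports approximately the
#' published standard error.  The calibration is approximate by
#' construction (real per-region residual SDs are not published).
#'
#' @param seed integer seed (default 1).
#' @param noise_mode passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @examples
#' sp <- default_spec()
#' sp$regions[sp$regions$region == "caudate", ]
#' @export
default_spec <- function(seed = 1L, noise_mode = "additive_normal") {
  tab <- .region_table()
  icv_cal <- .icv_calibration_sample()
  mu <- mean(icv_cal)
  tab$alpha <- tab$typical_vol / mu^tab$beta
  tab$sigma <- mapply(function(a, b, s)
    calibrate_sigma(a, b, icv_cal, s), tab$alpha, tab$beta, tab$se)
  synthetic_spec(n_male = .icv_defaults$n_male,
                 n_female = .icv_defaults$n_female,
                 regions = tab[c("region", "alpha", "beta", "sigma")],
                 noise_mode = noise_mode, seed = seed)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic volume spec: %d male + %d female subjects, ",
                     "%d regions, %s noise, seed %d\n"),
              x$n_male, x$n_female, nrow(x$regions),
              sub("_.*", "", x$noise_mode), x$seed))
  cat(sprintf("  ICV male  ~ N(%.2f, %.2f^2) cc\n",
              x$icv_male[1], x$icv_male[2]))
  cat(sprintf("  ICV female~ N(%.2f, %.2f^2) cc\n",
              x$icv_female[1], x$icv_female[2]))
  invisible(x)
}

# Deterministic per-region seed so adding/removing a region never
# perturbs the draws of the others.
.region_seed <- function(seed, region) {
  h <- 0
  for (ch in utf8ToInt(region)) h <- (h * 31 + ch) %% 2147483563
  as.integer(((as.numeric(seed) %% 2147483563) * 48271 + h) %% 2147483563)
}

# Normal draws truncated to (0, Inf) by resampling; mean may be a vector.
# Returns the draws with attribute "resampled" counting redraws.
.rnorm_pos <- function(n, mean, sd, max_rounds = 1000L) {
  x <- rnorm(n, mean, sd)
  total <- 0L
  rounds <- 0L
  while (any(bad <- x <= 0)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("could not draw positive volumes after ", max_rounds,
           " resampling rounds; sigma is too large relative to the mean",
           call. = FALSE)
    total <- total + sum(bad)
    m <- if (length(mean) == 1L) mean else mean[bad]
    s <- if (length(sd) == 1L) sd else sd[bad]
    x[bad] <- rnorm(sum(bad), m, s)
  }
  attr(x, "resampled") <- total
  x
}

#' Simulate a volume table from a synthetic specification
#'
#' ICV is drawn per sex from the spec's normal distributions; each
#' region's volume is `alpha * icv^beta + e` with
#' `e ~ N(0, sigma^2)` in additive mode, or
#' `alpha * icv^beta * exp(h)`, `h ~ N(0, sigma^2)`, in multiplicative
#' mode.  Nonpositive draws (possible in the additive normal model) are
#' resampled and counted; the count is reported in the `"resampled"`
#' attribute and as a message when nonzero.  The same spec always yields
#' the identical table, and each region has its own deterministic
#' substream, so subsetting the region list never changes the others.
#'
#' @param spec a [synthetic_spec()].
#' @param quiet suppress the resampling message.
#' @return A [volume_table()] with a `sex` column and attributes
#'   `generator` (the spec) and `resampled` (per-region redraw counts).
#' @export
simulate_table <- function(spec, quiet = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_male + spec$n_female
  set.seed(spec$seed)
  icv <- c(if (spec$n_male > 0)
             .rnorm_pos(spec$n_male, spec$icv_male[1], spec$icv_male[2]),
           if (spec$n_female > 0)
             .rnorm_pos(spec$n_female, spec$icv_female[1],
                        spec$icv_female[2]))
  sex <- rep(c("male", "female"), c(spec$n_male, spec$n_female))
  ids <- sprintf("S%04d", seq_len(n))
  regs <- spec$regions
  vols <- list()
  resampled <- integer(nrow(regs))
  names(resampled) <- regs$region
  for (k in seq_len(nrow(regs))) {
    set.seed(.region_seed(spec$seed, regs$region[k]))
    mu <- regs$alpha[k] * icv^regs$beta[k]
    if (spec$noise_mode == "additive_normal") {
      if (regs$sigma[k] == 0) {
        v <- mu
      } else {
        v <- .rnorm_pos(n, mu, regs$sigma[k])
        resampled[k] <- attr(v, "resampled")
      }
    } else {
      v <- mu * exp(rnorm(n, 0, regs$sigma[k]))
    }
    vols[[regs$region[k]]] <- as.numeric(v)
  }
  if (sum(resampled) > 0 && !quiet)
    message(sum(resampled), " nonpositive volume draw(s) resampled ",
            "(largest in region '", names(which.max(resampled)), "')")
  out <- volume_table(ids, icv, as.data.frame(vols, optional = TRUE),
                      sex = sex)
  attr(out, "generator") <- spec
  attr(out, "resampled") <- resampled
  out
}

#' Write a simulated table plus its generating parameters
#'
#' Writes the volume table as CSV and a YAML sidecar holding the full
#' generating specification, so parameter-recovery analyses can compare
#' fits against truth.
#'
#' @param table a simulated [volume_table()] (attribute `generator` set),
#'   or any volume table if `spec` is given explicitly.
#' @param path CSV output path; the sidecar goes to
#'   `<path>.params.yaml` unless `params_path` is given.
#' @param spec,params_path optional overrides.
#' @return Invisibly, `c(path, params_path)`.
#' @export
write_simulation <- function(table, path, spec = attr(table, "generator"),
                             params_path = paste0(path, ".params.yaml")) {
  if (is.null(spec)) stop("no generating spec available", call. = FALSE)
  write_volumes_table(table, path)
  lst <- unclass(spec)
  lst$icv_male <- as.list(lst$icv_male)
  lst$icv_female <- as.list(lst$icv_female)
  lst$regions <- lapply(seq_len(nrow(spec$regions)), function(i)
    as.list(spec$regions[i, ]))
  yaml::write_yaml(lst, params_path, precision = 15L)
  invisible(c(path, params_path))
}

#' Read back a generating specification sidecar
#'
#' @param params_path path written by [write_simulation()].
#' @return A `synthetic_spec`.
#' @export
read_simulation_params <- function(params_path) {
  lst <- yaml::read_yaml(params_path)
  regs <- do.call(rbind, lapply(lst$regions, as.data.frame))
  synthetic_spec(n_male = lst$n_male, n_female = lst$n_female,
                 icv_male = c(lst$icv_male$mean, lst$icv_male$sd),
                 icv_female = c(lst$icv_female$mean, lst$icv_female$sd),
                 regions = regs, noise_mode = lst$noise_mode,
                 seed = lst$seed)
}
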