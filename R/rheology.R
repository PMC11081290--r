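#' Rheometer curve containers
#'
#' Lightweight validated data frames for the three curve types consumed by
#' the response-extraction functions.
#'
#' `amplitude_sweep()`: oscillatory amplitude sweep (strain, storage modulus
#' G', optionally oscillatory stress and loss modulus G''). When `stress` is
#' omitted it is reconstructed as `G' * strain`, the elastic approximation
#' valid in and near the linear-viscoelastic region.
#'
#' `flow_curve()`: steady-shear flow curve (shear rate in 1/s, apparent
#' viscosity in Pa.s).
#'
#' `temperature_sweep()`: oscillatory temperature ramp (temperature in
#' degrees C, storage modulus in Pa).
#'
#' @param strain Dimensionless strain amplitude, strictly increasing.
#' @param gprime Storage modulus G' (Pa), positive.
#' @param stress Oscillatory stress (Pa); defaults to `gprime * strain`.
#' @param gloss Optional loss modulus G'' (Pa).
#' @param rate Shear rate (1/s), strictly increasing, positive.
#' @param viscosity Apparent viscosity (Pa.s), positive.
#' @param temperature Temperature (degrees C), strictly increasing.
#' @return A data frame of the corresponding class.
#' @name rheo_curves
NULL

#' @rdname rheo_curves
#' @export
amplitude_sweep <- function(strain, gprime, stress = NULL, gloss = NULL) {
  stopifnot(length(strain) == length(gprime))
  if (any(diff(strain) <= 0))
    stop("strain must be strictly increasing", call. = FALSE)
  if (any(gprime <= 0)) stop("moduli must be positive", call. = FALSE)
  if (is.null(stress)) stress <- gprime * strain
  df <- data.frame(strain = strain, stress = stress, gprime = gprime)
  if (!is.null(gloss)) df$gloss <- gloss
  class(df) <- c("amplitude_sweep", class(df))
  df
}

#' @rdname rheo_curves
#' @export
flow_curve <- function(rate, viscosity) {
  stopifnot(length(rate) == length(viscosity))
  if (any(diff(rate) <= 0))
    stop("shear rate must be strictly increasing", call. = FALSE)
  if (any(rate <= 0) || any(viscosity <= 0))
    stop("shear rates and viscosities must be positive", call. = FALSE)
  df <- data.frame(rate = rate, viscosity = viscosity)
  class(df) <- c("flow_curve", class(df))
  df
}

#' @rdname rheo_curves
#' @export
temperature_sweep <- function(temperature, gprime) {
  stopifnot(length(temperature) == length(gprime))
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing", call. = FALSE)
  if (any(gprime <= 0)) stop("moduli must be positive", call. = FALSE)
  df <- data.frame(temperature = temperature, gprime = gprime)
  class(df) <- c("temperature_sweep", class(df))
  df
}

#' Yield stress from an amplitude sweep
#'
#' Detects the linear-viscoelastic (LVR) plateau of G' at low strain -- the
#' longest initial run of points each within `deviation_fraction` of the
#' running plateau mean -- and returns the oscillatory stress at the first
#' point where G' falls below `(1 - deviation_fraction)` of that plateau
#' mean. This is the standard amplitude-sweep onset definition of the yield
#' stress of a soft solid.
#'
#' @param sweep An [amplitude_sweep()].
#' @param deviation_fraction Allowed relative departure from the plateau
#'   mean, default 0.05 (a 5 percent G' drop marks yielding).
#' @return Yield stress (Pa), with attributes `plateau_gprime` (LVR mean)
#'   and `critical_strain` (strain at the returned point).
#' @export
yield_stress <- function(sweep, deviation_fraction = 0.05) {
  stopifnot(inherits(sweep, "amplitude_sweep"),
            deviation_fraction > 0, deviation_fraction < 1)
  g <- sweep$gprime
  n <- length(g)
  if (n < 3L) stop("no plateau detected: fewer than 3 points", call. = FALSE)
  # grow the plateau while each next point stays within f of the running mean
  upto <- 1L
  mean_g <- g[1L]
  for (i in 2L:n) {
    if (abs(g[i] - mean_g) <= deviation_fraction * mean_g) {
      upto <- i
      mean_g <- mean(g[1:i])
    } else break
  }
  if (upto < 3L)
    stop("no plateau detected: linear-viscoelastic region shorter than 3 points",
         call. = FALSE)
  plateau <- mean(g[1:upto])
  idx <- which(g < (1 - deviation_fraction) * plateau)
  idx <- idx[idx > upto]
  if (!length(idx))
    stop("no yield: G' never falls below the plateau band", call. = FALSE)
  out <- sweep$stress[idx[1L]]
  attr(out, "plateau_gprime") <- plateau
  attr(out, "critical_strain") <- sweep$strain[idx[1L]]
  out
}

#' Fit the power-law (Ostwald--de Waele) flow model
#'
#' Least-squares fit of `log(eta) = log(K) + (n - 1) * log(rate)` over the
#' chosen shear-rate window, i.e. the viscosity form `eta = K * rate^(n-1)`
#' of the power law, so the fitted `n` is the flow (behaviour) index:
#' `n < 1` pseudoplastic (shear thinning), `n = 1` Newtonian, `n > 1`
#' dilatant. `K` is the consistency (Pa.s^n).
#'
#' @param curve A [flow_curve()].
#' @param window `c(min, max)` shear-rate window (1/s); default `c(1, 100)`,
#'   the medium-to-high shear range.
#' @return An object of class `power_law_fit` with elements `K`, `n`,
#'   `r_squared`, `window`, `classification`.
#' @examples
#' rate <- 10^seq(-2, 2, length.out = 50)
#' fit <- fit_power_law(flow_curve(rate, 173.5 * rate^(0.32 - 1)))
#' fit$K; fit$n
#' @export
fit_power_law <- function(curve, window = c(1, 100)) {
  stopifnot(inherits(curve, "flow_curve"), length(window) == 2L,
            window[1] < window[2])
  sel <- curve$rate >= window[1] & curve$rate <= window[2]
  if (sum(sel) < 3L)
    stop("fewer than 3 points inside the fit window", call. = FALSE)
  lr <- log(curve$rate[sel])
  lv <- log(curve$viscosity[sel])
  fit <- stats::lm(lv ~ lr)
  n <- unname(stats::coef(fit)[2L]) + 1
  K <- exp(unname(stats::coef(fit)[1L]))
  tss <- sum((lv - mean(lv))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  cls <- if (abs(n - 1) < 1e-8) "Newtonian"
         else if (n < 1) "pseudoplastic" else "dilatant"
  structure(list(K = K, n = n, r_squared = r2, window = window,
                 classification = cls),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: K = %.4g Pa.s^n, n = %.4g (%s), R2 = %.4f, window [%g, %g] 1/s\n",
              x$K, x$n, x$classification, x$r_squared,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Viscosity at the low- and high-shear query rates
#'
#' Log-log linear interpolation of the apparent viscosity at two stated
#' shear rates (defaults: curve convention endpoints 0.01 and 100 1/s).
#'
#' @param curve A [flow_curve()].
#' @param low_rate,high_rate Query shear rates (1/s), inside the measured
#'   range.
#' @return Named numeric vector `c(low = , high = )` (Pa.s).
#' @export
shear_viscosities <- function(curve, low_rate = 0.01, high_rate = 100) {
  stopifnot(inherits(curve, "flow_curve"))
  rng <- range(curve$rate)
  for (r in c(low_rate, high_rate)) {
    if (r < rng[1] || r > rng[2])
      stop("query rate ", r, " outside measured range [", rng[1], ", ",
           rng[2], "]", call. = FALSE)
  }
  interp <- stats::approx(log(curve$rate), log(curve$viscosity),
                          xout = log(c(low_rate, high_rate)))$y
  stats::setNames(exp(interp), c("low", "high"))
}

#' Storage modulus at a readout temperature
#'
#' Linear interpolation of G' at temperature `T` (default 37 degrees C,
#' body temperature).
#'
#' @param sweep A [temperature_sweep()].
#' @param T Readout temperature (degrees C), inside the sweep range.
#' @return G' (Pa).
#' @export
modulus_at_temperature <- function(sweep, T = 37) {
  stopifnot(inherits(sweep, "temperature_sweep"))
  rng <- range(sweep$temperature)
  if (T < rng[1] || T > rng[2])
    stop("temperature ", T, " outside sweep range [", rng[1], ", ", rng[2],
         "]", call. = FALSE)
  stats::approx(sweep$temperature, sweep$gprime, xout = T)$y
}

#' Extract the four DoE responses from one run's rheometer curves
#'
#' Convenience wrapper applying [yield_stress()], [shear_viscosities()] and
#' [modulus_at_temperature()] to one run's three curves.
#'
#' @param amplitude An [amplitude_sweep()].
#' @param flow A [flow_curve()].
#' @param temperature A [temperature_sweep()].
#' @param readout_temp Storage-modulus readout temperature, default 37.
#' @return One-row data frame with `yield_stress`, `high_shear_visc`,
#'   `low_shear_visc`, `storage_modulus`.
#' @export
extract_responses <- function(amplitude, flow, temperature,
                              readout_temp = 37) {
  visc <- shear_viscosities(flow)
  data.frame(
    yield_stress = as.numeric(yield_stress(amplitude)),
    high_shear_visc = unname(visc["high"]),
    low_shear_visc = unname(visc["low"]),
    storage_modulus = modulus_at_temperature(temperature, readout_temp))
}

#' Read rheometer curve CSV exports
#'
#' Unit-annotated two/three-column CSV dialects: amplitude sweeps
#' (`strain, Gprime_Pa[, stress_Pa[, Gdoubleprime_Pa]]`), flow curves
#' (`shear_rate_1_per_s, viscosity_Pa_s`) and temperature sweeps
#' (`temperature_C, Gprime_Pa`).
#'
#' @param path CSV file path.
#' @return The corresponding curve object.
#' @name read_rheo_csv
NULL

read_numeric_csv <- function(path, required) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(path), " lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[nm]])))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   nm, bad, basename(path)), call. = FALSE)
    }
  }
  df
}

#' @rdname read_rheo_csv
#' @export
read_amplitude_csv <- function(path) {
  df <- read_numeric_csv(path, c("strain", "Gprime_Pa"))
  amplitude_sweep(df$strain, df$Gprime_Pa, stress = df$stress_Pa,
                  gloss = df$Gdoubleprime_Pa)
}

#' @rdname read_rheo_csv
#' @export
read_flow_csv <- function(path) {
  df <- read_numeric_csv(path, c("shear_rate_1_per_s", "viscosity_Pa_s"))
  flow_curve(df$shear_rate_1_per_s, df$viscosity_Pa_s)
}

#' @rdname read_rheo_csv
#' @export
read_temperature_csv <- function(path) {
  df <- read_numeric_csv(path, c("temperature_C", "Gprime_Pa"))
  temperature_sweep(df$temperature_C, df$Gprime_Pa)
}
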