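#' Generate a synthetic DoE response table
#'
#' Evaluates the ground-truth response models at every design run and adds
#' independent Gaussian residual noise, emulating the averaged rheometer
#' readouts of a screening campaign. With all residual SDs zero the table
#' equals the exact model evaluations. Pure function of
#' `(design, models, residual_sd, seed)`.
#'
#' @param design A `dsd_design`.
#' @param models Named list of ground-truth `response_model`s.
#' @param residual_sd Named per-response residual SDs (response units);
#'   default 5 percent of each model's intercept magnitude.
#' @param seed RNG seed.
#' @return Data frame with one numeric column per response, rows aligned
#'   with `design$runs`.
#' @export
gen_doe_responses <- function(design, models = ointment_models(),
                              residual_sd = NULL, seed = 1L) {
  stopifnot(inherits(design, "dsd_design"))
  models <- lapply(models, function(m) if (inherits(m, "rsm_fit")) m$model else m)
  for (m in models) {
    if (!all(names(m$factors) %in% names(design$factors)))
      stop("model factors do not match the design's factor space",
           call. = FALSE)
  }
  if (is.null(residual_sd)) {
    residual_sd <- vapply(models, function(m) 0.05 * abs(m$intercept),
                          numeric(1))
    names(residual_sd) <- names(models)
  }
  n <- nrow(design$runs)
  with_seed(seed, {
    out <- lapply(names(models), function(nm) {
      y <- predict(models[[nm]], design$runs)
      sd_ <- residual_sd[nm]
      if (is.na(sd_)) sd_ <- 0
      y + stats::rnorm(n, 0, sd_)
    })
    stats::setNames(as.data.frame(out), names(models))
  })
}

#' Generate synthetic rheometer curves with known ground truth
#'
#' Produces the three curves the response-extraction functions consume,
#' on log-spaced grids matching the instrument protocol (strain 0.001--100,
#' shear rate 0.01--100 1/s, temperature 20--50 C), with optional
#' multiplicative log-normal noise. With `sigma_log = 0` the curves
#' round-trip exactly through [fit_power_law()], [yield_stress()] and
#' [modulus_at_temperature()] to the generating parameters.
#'
#' The amplitude sweep has G' equal to `plateau_gprime` up to
#' `critical_strain` and decaying as `plateau * (critical_strain/strain)`
#' beyond it, with oscillatory stress `G' * strain`. The flow curve follows
#' the power law `eta = K * rate^(n - 1)`. The temperature sweep decays
#' linearly from the modulus at 20 C with slope `modulus_slope` (Pa per C,
#' negative for softening).
#'
#' @param plateau_gprime LVR storage modulus (Pa), > 0.
#' @param critical_strain Strain at yield onset, inside (0.001, 100).
#' @param K,n Power-law consistency (Pa.s^n, > 0) and flow index.
#' @param modulus_at_37 Storage modulus at 37 C (Pa), > 0.
#' @param modulus_slope dG'/dT (Pa/C), default negative (softening).
#' @param sigma_log SD of multiplicative log-normal noise, default 0.02.
#' @param points_per_decade Grid density for the log-spaced sweeps.
#' @param seed RNG seed.
#' @return List with `amplitude`, `flow`, `temperature` curve objects.
#' @export
gen_rheograms <- function(plateau_gprime = 1000, critical_strain = 0.04,
                          K = 400, n = 0.15, modulus_at_37 = 1000,
                          modulus_slope = -40, sigma_log = 0.02,
                          points_per_decade = 30L, seed = 1L) {
  stopifnot(plateau_gprime > 0, K > 0, modulus_at_37 > 0,
            critical_strain > 0.001, critical_strain < 100, sigma_log >= 0)
  with_seed(seed, {
    mnoise <- function(n_pts) {
      if (sigma_log == 0) rep(1, n_pts)
      else exp(stats::rnorm(n_pts, 0, sigma_log))
    }
    strain <- 10^seq(log10(0.001), log10(100),
                     by = 1 / points_per_decade)
    g <- ifelse(strain <= critical_strain, plateau_gprime,
                plateau_gprime * critical_strain / strain)
    g <- g * mnoise(length(g))
    amp <- amplitude_sweep(strain, g, stress = g * strain)

    rate <- 10^seq(log10(0.01), log10(100), by = 1 / points_per_decade)
    eta <- K * rate^(n - 1) * mnoise(length(rate))
    flow <- flow_curve(rate, eta)

    temp <- seq(20, 50, by = 0.5)
    gt <- modulus_at_37 + modulus_slope * (temp - 37)
    if (any(gt <= 0))
      stop("temperature sweep reaches non-positive modulus; adjust slope",
           call. = FALSE)
    gt <- gt * mnoise(length(gt))
    ts <- temperature_sweep(temp, gt)
    list(amplitude = amp, flow = flow, temperature = ts)
  })
}

#' Generate labelled in/out-of-specification points
#'
#' Samples factor settings over the factor box (uniformly, or radially via
#' [sample_radial()]), evaluates the ground-truth models with residual
#' noise, and labels each point `pass` when every response lies inside its
#' window -- the training set for [grow_tree()].
#'
#' @param models Named list of ground-truth `response_model`s.
#' @param limits A [spec_limits()].
#' @param noise A [noise_model()] (only `response_sd` is used; settings are
#'   sampled, not perturbed).
#' @param n Number of points.
#' @param sampling `"uniform"` (default) or `"radial"`.
#' @param level Categorical level to sample at; `NULL` alternates levels.
#' @param seed RNG seed.
#' @return Data frame of natural-unit settings plus logical `pass`.
#' @export
gen_labeled_points <- function(models, limits, noise = default_noise_model(models),
                               n = 5000L, sampling = c("uniform", "radial"),
                               level = NULL, seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(n >= 1L)
  models <- lapply(models, function(m) if (inherits(m, "rsm_fit")) m$model else m)
  factors <- models[[1L]]$factors
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  m <- length(cont)
  with_seed(seed, {
    coded <- if (sampling == "uniform") {
      matrix(stats::runif(n * m, -1, 1), n, m)
    } else {
      # sample_radial reseeds internally; derive its seed from this stream
      sample_radial(m, n = n, seed = stats::runif(1) * 1e8)
    }
    settings <- as.data.frame(lapply(seq_len(m), function(j)
      decode_value(cont[[j]], coded[, j])))
    names(settings) <- names(cont)
    if (!is.null(cat_f)) {
      settings[[cat_f$name]] <- if (is.null(level))
        cat_f$levels[1L + (seq_len(n) %% 2L)] else level
    }
    ok <- rep(TRUE, n)
    for (nm in names(limits)) {
      y <- predict(models[[nm]], settings)
      sd_ <- noise$response_sd[nm]
      if (!is.na(sd_) && sd_ > 0) y <- y + stats::rnorm(n, 0, sd_)
      w <- limits[[nm]]
      ok <- ok & y >= w[1] & y <= w[2]
    }
    settings$pass <- ok
    settings
  })
}
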