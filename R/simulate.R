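#' Perturbation model for defect simulation
#'
#' Describes how a nominal operating point is perturbed in the Monte Carlo
#' defect simulation: per-factor perturbations of the continuous settings
#' (normal SD or uniform half-width, natural units) and per-response
#' additive Gaussian residual noise (response units).
#'
#' @param factor_sd Named numeric vector of per-factor normal SDs in
#'   natural units (0 disables). Missing factors default to 0.
#' @param response_sd Named numeric vector of per-response residual SDs.
#' @param factor_dist `"normal"` or `"uniform"`; for `"uniform"` the values
#'   in `factor_sd` are half-widths.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(factor_sd = numeric(0), response_sd = numeric(0),
                        factor_dist = c("normal", "uniform")) {
  factor_dist <- match.arg(factor_dist)
  stopifnot(all(factor_sd >= 0), all(response_sd >= 0))
  structure(list(factor_sd = factor_sd, response_sd = response_sd,
                 factor_dist = factor_dist),
            class = "noise_model")
}

#' Default case-study perturbation model
#'
#' Factor SDs of 5 percent of each continuous factor's half-range, and
#' response residual SDs taken from each model's fit RMSE when available,
#' otherwise 5 percent of the model's intercept magnitude.
#'
#' @param models Named list of `response_model`s (or `rsm_fit`s).
#' @return A [noise_model()].
#' @export
default_noise_model <- function(models = ointment_models()) {
  models <- lapply(models, function(m) if (inherits(m, "rsm_fit")) m$model else m)
  cont <- continuous_factors(models[[1L]]$factors)
  fsd <- vapply(cont, function(f) 0.05 * (f$high - f$low) / 2, numeric(1))
  names(fsd) <- names(cont)
  rsd <- vapply(models, function(m) {
    r <- m$stats$rmse
    if (!is.null(r) && is.finite(r)) r else 0.05 * abs(m$intercept)
  }, numeric(1))
  names(rsd) <- vapply(models, `[[`, character(1), "response")
  noise_model(factor_sd = fsd, response_sd = rsd)
}

#' Radial stratification scheme
#'
#' Contiguous radial layers for stratified sampling of the factor space:
#' layer 0 spans radii `[0, d]` and layer `i >= 1` spans
#' `[d + (i-1)*2d, d + i*2d]`. With the default `d` the outermost radius
#' equals `sqrt(dims)`, the coded-box corner distance.
#'
#' @param layers Number of layers (>= 1).
#' @param d Base distance (> 0); default `sqrt(dims) / (2 * layers - 1)`.
#' @param dims Dimension used for the default `d`.
#' @return An object of class `radial_scheme` with a `bounds` matrix
#'   (`layers` rows of inner/outer radius).
#' @export
radial_scheme <- function(layers, d = NULL, dims = NULL) {
  stopifnot(layers >= 1L)
  if (is.null(d)) {
    stopifnot(!is.null(dims))
    d <- sqrt(dims) / (2 * layers - 1)
  }
  if (d <= 0) stop("base distance d must be positive", call. = FALSE)
  inner <- c(0, d + (seq_len(layers - 1L) - 1) * 2 * d)
  outer <- c(d, d + seq_len(layers - 1L) * 2 * d)
  structure(list(d = d, layers = layers,
                 bounds = cbind(inner = inner, outer = outer)),
            class = "radial_scheme")
}

#' Stratified radial sampling of the coded factor box
#'
#' Run `i` is assigned layer `(i - 1) mod layers`; a uniform random
#' direction on the unit sphere is scaled by a radius drawn uniformly
#' within the layer's bounds, and the point is clamped coordinate-wise to
#' the coded box `[-1, 1]^dims`.
#'
#' @param dims Dimension of the coded space.
#' @param scheme A [radial_scheme()].
#' @param n Number of points.
#' @param seed RNG seed.
#' @return `n x dims` matrix of coded points, with attributes `"layer"`
#'   (0-based layer index per row) and `"weight"` (normalised stratification
#'   weights, proportional to each layer's radial width over its allocation,
#'   so that a weighted mean over the points estimates the same expectation
#'   as plain i.i.d. sampling of the radial distribution).
#' @export
sample_radial <- function(dims, scheme = radial_scheme(4L, dims = dims),
                          n, seed = 1L) {
  stopifnot(inherits(scheme, "radial_scheme"), n >= 1L)
  layer <- (seq_len(n) - 1L) %% scheme$layers
  with_seed(seed, {
    dir <- matrix(stats::rnorm(n * dims), n, dims)
    dir <- dir / sqrt(rowSums(dir^2))
    b <- scheme$bounds[layer + 1L, , drop = FALSE]
    radius <- stats::runif(n, b[, "inner"], b[, "outer"])
    pts <- dir * radius
    pts[pts > 1] <- 1 # clamp into the coded box, preserving shape
    pts[pts < -1] <- -1
    attr(pts, "layer") <- layer
    widths <- scheme$bounds[, "outer"] - scheme$bounds[, "inner"]
    alloc <- tabulate(layer + 1L, nbins = scheme$layers)
    w <- (widths[layer + 1L] / sum(widths)) / alloc[layer + 1L]
    attr(pts, "weight") <- w / sum(w)
    pts
  })
}

# draw n perturbed natural-unit setting rows around a nominal point,
# or uniformly over a factor_box
draw_settings <- function(nominal, factors, noise, n) {
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  out <- list()
  if (inherits(nominal, "factor_box")) {
    for (nm in names(cont)) {
      iv <- nominal$intervals[[nm]]
      out[[nm]] <- stats::runif(n, iv[1], iv[2])
    }
    lev <- nominal$level %||% if (!is.null(cat_f)) cat_f$levels[2L] else NULL
  } else {
    for (nm in names(cont)) {
      sd_ <- noise$factor_sd[nm]
      if (is.na(sd_)) sd_ <- 0
      base <- nominal[[nm]]
      out[[nm]] <- if (sd_ == 0) rep(base, n)
      else if (noise$factor_dist == "normal") stats::rnorm(n, base, sd_)
      else stats::runif(n, base - sd_, base + sd_)
    }
    lev <- if (!is.null(cat_f)) as.character(nominal[[cat_f$name]]) else NULL
  }
  if (!is.null(cat_f)) out[[cat_f$name]] <- rep(lev, n)
  as.data.frame(out)
}

#' Monte Carlo defect rate at an operating point
#'
#' Simulates `n` batches: the continuous settings are perturbed per the
#' noise model (or, when `settings` is a [factor_box()], drawn uniformly
#' over the box), each response model is evaluated, Gaussian residual noise
#' is added, and every response is compared with its specification window.
#' A batch is defective when at least one response is out of its window.
#'
#' @param models Named list of `response_model`s (or `rsm_fit`s); names
#'   must cover the names of `limits`.
#' @param settings One-row natural-unit data frame (the nominal point), or
#'   a `factor_box`.
#' @param limits A [spec_limits()].
#' @param noise A [noise_model()].
#' @param n Number of simulated batches, default 100000.
#' @param seed RNG seed; reusing the seed gives common random numbers
#'   across operating points for fair comparisons.
#' @return An object of class `defect_report`: per-response defect
#'   fractions, overall defect fraction, `log10_overall` (floored at
#'   `log10(1/n)` when no defects occur), `n`, `seed`.
#' @export
defect_rate <- function(models, settings, limits, noise = noise_model(),
                        n = 100000L, seed = 1L) {
  models <- lapply(models, function(m) if (inherits(m, "rsm_fit")) m$model else m)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  missing <- setdiff(names(limits), names(models))
  if (length(missing))
    stop("no model for response(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  factors <- models[[1L]]$factors
  with_seed(seed, {
    draws <- draw_settings(settings, factors, noise, n)
    out_of <- matrix(FALSE, n, length(limits),
                     dimnames = list(NULL, names(limits)))
    for (nm in names(limits)) {
      y <- predict(models[[nm]], draws)
      sd_ <- noise$response_sd[nm]
      if (!is.na(sd_) && sd_ > 0) y <- y + stats::rnorm(n, 0, sd_)
      w <- limits[[nm]]
      out_of[, nm] <- y < w[1] | y > w[2]
    }
    per <- colMeans(out_of)
    overall <- mean(rowSums(out_of) > 0)
    structure(list(per_response = per, overall = overall,
                   log10_overall = log10(max(overall, 1 / n)),
                   n = n, seed = seed),
              class = "defect_report")
  })
}

#' @export
print.defect_report <- function(x, ...) {
  cat(sprintf("Defect report (n = %d, seed = %d)\n", x$n, x$seed))
  for (nm in names(x$per_response))
    cat(sprintf("  %-16s %.4f\n", nm, x$per_response[[nm]]))
  cat(sprintf("  overall          %.4f  (log10 %.3f)\n",
              x$overall, x$log10_overall))
  invisible(x)
}

#' Defect-rate surface over a set of design points
#'
#' Runs [defect_rate()] at every row of `points`, with per-point seeds
#' derived as `seed + row index` so identical rows give identical results.
#'
#' @param models,limits,noise As in [defect_rate()].
#' @param points Data frame of natural-unit settings (one row per point,
#'   categorical column included when the space has one).
#' @param n_inner Monte Carlo runs per point.
#' @param seed Master seed.
#' @return Data frame: the settings columns plus `defect` and
#'   `log10_defect`.
#' @export
defect_surface <- function(models, points, limits, noise = noise_model(),
                           n_inner = 100000L, seed = 1L) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L)
  defects <- vapply(seq_len(nrow(points)), function(i) {
    rep_ <- defect_rate(models, points[i, , drop = FALSE], limits, noise,
                        n = n_inner, seed = seed + i)
    c(rep_$overall, rep_$log10_overall)
  }, numeric(2))
  cbind(points, defect = defects[1L, ], log10_defect = defects[2L, ])
}
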