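#' Per-response desirability specification
#'
#' Two-sided desirability for a target window `(lower, upper)`: zero outside
#' the window, rising linearly from 0 at the window edges to 1 across the
#' middle portion of the window (by default the central 50 percent), and 1
#' there. Weights scale each response's influence on the geometric-mean
#' overall desirability.
#'
#' @param limits A [spec_limits()] object giving the windows.
#' @param plateau Fraction of each window over which desirability is 1,
#'   centred in the window; default 0.5.
#' @param weights Named positive weights, default 1 for every response.
#' @return An object of class `desirability_spec`.
#' @export
desirability_spec <- function(limits, plateau = 0.5, weights = NULL) {
  stopifnot(inherits(limits, "spec_limits"), plateau > 0, plateau < 1)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(limits)),
                                                   names(limits))
  stopifnot(all(weights > 0), all(names(limits) %in% names(weights)))
  structure(list(limits = limits, plateau = plateau, weights = weights),
            class = "desirability_spec")
}

# scalar/vector desirability of response values y for window w = c(L, U)
desirability_value <- function(y, w, plateau = 0.5) {
  L <- w[1]; U <- w[2]
  margin <- (1 - plateau) / 2 * (U - L)
  lo <- L + margin
  hi <- U - margin
  d <- numeric(length(y))
  d[y >= lo & y <= hi] <- 1
  ramp_up <- y > L & y < lo
  d[ramp_up] <- (y[ramp_up] - L) / margin
  ramp_dn <- y > hi & y < U
  d[ramp_dn] <- (U - y[ramp_dn]) / margin
  d
}

#' Overall desirability of predicted responses
#'
#' Weighted geometric mean of per-response desirabilities; zero as soon as
#' any response leaves its window.
#'
#' @param predictions Named numeric vector (one value per response).
#' @param spec A [desirability_spec()].
#' @return Scalar in `[0, 1]`.
#' @export
overall_desirability <- function(predictions, spec) {
  stopifnot(inherits(spec, "desirability_spec"))
  nms <- names(spec$limits)
  d <- vapply(nms, function(nm)
    desirability_value(predictions[[nm]], spec$limits[[nm]], spec$plateau),
    numeric(1))
  w <- spec$weights[nms]
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

#' Jointly optimise the responses by desirability
#'
#' Maximises the overall desirability of the four model predictions over
#' the coded factor box (continuous factors in `[-1, 1]`) at a fixed
#' categorical level, by seeded multi-start search: a maximin Latin
#' hypercube of starting points followed by Nelder--Mead polish (coded
#' coordinates clamped to the box). Ties in desirability are broken in
#' favour of the largest margin to the nearest window edge.
#'
#' @param models Named list of `response_model` (or `rsm_fit`) objects
#'   sharing one factor space.
#' @param spec A [desirability_spec()].
#' @param level Categorical level at which to optimise (default the second
#'   level; ignored when the space has no categorical factor).
#' @param n_starts Number of Latin-hypercube starts, default 32.
#' @param seed RNG seed for the starts.
#' @return List with `settings` (one-row natural-unit data frame),
#'   `predictions` (named vector), `desirability` (scalar).
#' @export
desirability_optimize <- function(models, spec, level = NULL,
                                  n_starts = 32L, seed = 1L) {
  models <- lapply(models, function(m) if (inherits(m, "rsm_fit")) m$model else m)
  stopifnot(all(vapply(models, inherits, logical(1), "response_model")))
  factors <- models[[1L]]$factors
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  if (!is.null(cat_f) && is.null(level)) level <- cat_f$levels[2L]
  m <- length(cont)

  settings_from_coded <- function(z) {
    s <- as.data.frame(lapply(seq_len(m), function(j)
      decode_value(cont[[j]], z[j])))
    names(s) <- names(cont)
    if (!is.null(cat_f)) s[[cat_f$name]] <- level
    s
  }
  predict_all <- function(s) {
    vapply(models, predict, numeric(1), newdata = s)
  }
  # margin to nearest window edge, for tie-breaking among desirability-1 points
  margin <- function(pred) {
    min(vapply(names(spec$limits), function(nm) {
      w <- spec$limits[[nm]]
      min(pred[[nm]] - w[1], w[2] - pred[[nm]]) / (w[2] - w[1])
    }, numeric(1)))
  }
  objective <- function(z) {
    z <- pmin(1, pmax(-1, z))
    -overall_desirability(predict_all(settings_from_coded(z)), spec)
  }

  starts <- with_seed(seed, 2 * lhs::maximinLHS(n_starts, m) - 1)
  best <- NULL
  for (i in seq_len(n_starts)) {
    opt <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = 500))
    z <- pmin(1, pmax(-1, opt$par))
    pred <- predict_all(settings_from_coded(z))
    d <- overall_desirability(pred, spec)
    key <- c(d, margin(pred))
    if (is.null(best) || key[1] > best$key[1] + 1e-12 ||
        (abs(key[1] - best$key[1]) <= 1e-12 && key[2] > best$key[2])) {
      best <- list(z = z, pred = pred, key = key)
    }
  }
  if (best$key[1] <= 0)
    stop("empty feasible region: every sampled candidate has desirability 0",
         call. = FALSE)
  list(settings = settings_from_coded(best$z),
       predictions = best$pred,
       desirability = best$key[1])
}
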