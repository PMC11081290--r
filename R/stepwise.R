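#' Bidirectional stepwise fit of a coded response-surface model
#'
#' Fits a second-order coded-factor model to one response by bidirectional
#' stepwise selection over the columns of the design's model matrix: at each
#' iteration the best admissible term is entered if its partial t-test
#' p-value is at or below `p_enter`, then the worst in-model term is removed
#' if its p-value exceeds `p_remove`, until the selected set is stable.
#' With `criterion = "aicc"` steps are instead accepted while they lower
#' the small-sample-corrected AIC.
#'
#' With `heredity = TRUE` (weak heredity, the standard practice when
#' analysing definitive screening designs) a quadratic or interaction term
#' may only enter while at least one of its parent main effects is in the
#' model, and a main effect is not removed while it is the only in-model
#' parent of a selected second-order term.
#'
#' Candidate steps that would make the fit rank deficient, or exhaust the
#' residual degrees of freedom, are skipped with a warning.
#'
#' @param design A `dsd_design` (or a model matrix produced by
#'   [model_matrix()]; then `factors` must be given).
#' @param y Numeric response vector, one value per run.
#' @param response Response name for the fitted model.
#' @param p_enter,p_remove Entry/removal p-value thresholds (default 0.10).
#' @param criterion `"p"` (default) or `"aicc"`.
#' @param heredity Enforce weak effect heredity (default `TRUE`).
#' @param term_set Passed to [model_matrix()].
#' @param factors `factor_space`; only needed when `design` is a matrix.
#' @param units Response units (printing only).
#' @return An object of class `rsm_fit`: the selected [response_model()]
#'   (element `model`), the underlying `lm` fit, the model matrix and
#'   response, and fit statistics (`r_squared`, `p_value` of the overall
#'   F-test, `rmse`).
#' @export
stepwise_rsm <- function(design, y, response = "y",
                         p_enter = 0.10, p_remove = 0.10,
                         criterion = c("p", "aicc"), heredity = TRUE,
                         term_set = "full_quadratic", factors = NULL,
                         units = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(design, "dsd_design")) {
    X <- model_matrix(design, term_set)
    factors <- design$factors
  } else {
    X <- design
    if (is.null(factors))
      stop("factors must be supplied with a raw model matrix", call. = FALSE)
  }
  stopifnot(is.numeric(y), length(y) == nrow(X))
  labels <- setdiff(colnames(X), "(Intercept)")
  n <- length(y)

  parents <- function(lab) {
    tp <- term_parts(lab)
    if (length(tp$factors) == 1L && tp$powers[1L] == 1L) character(0)
    else unique(tp$factors)
  }
  admissible <- function(lab, sel) {
    if (!heredity) return(TRUE)
    p <- parents(lab)
    !length(p) || any(p %in% sel)
  }
  removable <- function(lab, sel) {
    if (!heredity) return(TRUE)
    rest <- setdiff(sel, lab)
    for (child in rest) {
      p <- parents(child)
      if (length(p) && lab %in% p && !any(p %in% rest)) return(FALSE)
    }
    TRUE
  }
  fit_set <- function(sel) {
    Xs <- X[, c("(Intercept)", sel), drop = FALSE]
    stats::lm.fit(Xs, y)
  }
  term_pvals <- function(fit, sel) {
    # partial t-tests of the selected terms
    df <- fit$df.residual
    if (df < 1L) return(NULL)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    Xs <- X[, c("(Intercept)", sel), drop = FALSE]
    XtXi <- tryCatch(chol2inv(chol(crossprod(Xs))), error = function(e) NULL)
    if (is.null(XtXi)) return(NULL)
    se <- sqrt(sigma2 * diag(XtXi))
    tval <- fit$coefficients / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    stats::setNames(p[-1L], sel)
  }
  aicc <- function(fit, k) {
    # k = number of estimated coefficients (incl. intercept); +1 for sigma
    rss <- sum(fit$residuals^2)
    p <- k + 1
    if (n - p - 1 <= 0) return(Inf)
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }

  sel <- character(0)
  warned <- FALSE
  for (iter in seq_len(50L)) {
    changed <- FALSE
    # forward
    cands <- setdiff(labels, sel)
    cands <- cands[vapply(cands, admissible, logical(1), sel = sel)]
    best <- NULL
    for (cand in cands) {
      trial <- c(sel, cand)
      if (n - length(trial) - 2L < 1L) next # keep residual df >= 1
      fit <- fit_set(trial)
      if (anyNA(fit$coefficients)) {
        if (!warned) {
          warning("rank-deficient candidate step skipped (", cand, ")",
                  call. = FALSE)
          warned <- TRUE
        }
        next
      }
      if (criterion == "p") {
        pv <- term_pvals(fit, trial)
        if (is.null(pv)) next
        score <- pv[[cand]]
      } else {
        score <- aicc(fit, length(trial) + 1L)
      }
      if (is.null(best) || score < best$score)
        best <- list(term = cand, score = score)
    }
    if (!is.null(best)) {
      accept <- if (criterion == "p") best$score <= p_enter
                else best$score < aicc(fit_set(sel), length(sel) + 1L) - 1e-9
      if (accept) {
        sel <- c(sel, best$term)
        changed <- TRUE
      }
    }
    # backward
    if (length(sel)) {
      fit <- fit_set(sel)
      rem <- sel[vapply(sel, removable, logical(1), sel = sel)]
      if (length(rem)) {
        if (criterion == "p") {
          pv <- term_pvals(fit, sel)
          if (!is.null(pv)) {
            pv <- pv[rem]
            worst <- names(pv)[which.max(pv)]
            if (max(pv) > p_remove) {
              sel <- setdiff(sel, worst)
              changed <- TRUE
            }
          }
        } else {
          base_aicc <- aicc(fit, length(sel) + 1L)
          scores <- vapply(rem, function(t)
            aicc(fit_set(setdiff(sel, t)), length(sel)), numeric(1))
          if (min(scores) < base_aicc - 1e-9) {
            sel <- setdiff(sel, rem[which.min(scores)])
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  Xs <- X[, c("(Intercept)", sel), drop = FALSE]
  fit <- stats::lm(y ~ Xs - 1)
  names(fit$coefficients) <- colnames(Xs)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  dfres <- fit$df.residual
  p_overall <- if (length(sel) && dfres >= 1L && tss > rss) {
    fstat <- ((tss - rss) / length(sel)) / (rss / dfres)
    stats::pf(fstat, length(sel), dfres, lower.tail = FALSE)
  } else NA_real_
  rmse <- if (dfres >= 1L) sqrt(rss / dfres) else NA_real_
  mdl <- response_model(response, intercept = unname(cf["(Intercept)"]),
                        coef = cf[sel], factors = factors, units = units,
                        stats = list(r_squared = r2, p_value = p_overall,
                                     rmse = rmse))
  structure(list(model = mdl, terms = sel, lm = fit, X = Xs, y = y,
                 criterion = criterion, heredity = heredity,
                 stats = mdl$stats),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Stepwise response-surface fit (%s criterion, heredity %s)\n",
              x$criterion, if (x$heredity) "on" else "off"))
  print(x$model, ...)
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) coef(object$model)

#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(unname(object$X %*% coef(object$lm))[, 1L])
  predict(object$model, newdata)
}

#' @export
residuals.rsm_fit <- function(object, ...) unname(stats::residuals(object$lm))

#' @export
fitted.rsm_fit <- function(object, ...) unname(stats::fitted(object$lm))

#' Per-term inference sorted by absolute t-ratio
#'
#' Ordinary linear-model inference (estimate, standard error, t-ratio,
#' two-sided p-value) for a set of model-matrix columns, sorted by
#' decreasing |t|. For an `rsm_fit` the selected terms are used.
#'
#' @param object An `rsm_fit`, or a model matrix with an intercept column.
#' @param y Response vector (only with a matrix).
#' @return Data frame with one row per non-intercept term.
#' @export
t_ratios <- function(object, y = NULL) {
  if (inherits(object, "rsm_fit")) {
    X <- object$X
    y <- object$y
  } else {
    X <- object
    stopifnot(!is.null(y))
  }
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("model matrix is rank deficient", call. = FALSE)
  dfres <- n - ncol(X)
  if (dfres < 1L)
    stop("inference unavailable: zero residual degrees of freedom",
         call. = FALSE)
  fit <- stats::lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXi))
  est <- fit$coefficients
  tval <- est / se
  pv <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  out <- data.frame(term = colnames(X), estimate = unname(est),
                    std_error = unname(se), t_ratio = unname(tval),
                    p_value = unname(pv))
  out <- out[out$term != "(Intercept)", , drop = FALSE]
  out <- out[order(-abs(out$t_ratio)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
summary.rsm_fit <- function(object, ...) {
  out <- list(response = object$model$response,
              terms = t_ratios(object),
              stats = object$stats)
  class(out) <- "summary.rsm_fit"
  out
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  cat(sprintf("Response: %s\n", x$response))
  print(x$terms, digits = 4)
  cat(sprintf("R-squared %.4f, overall F-test p = %.4g, RMSE %.4g\n",
              x$stats$r_squared, x$stats$p_value, x$stats$rmse))
  invisible(x)
}

#' Fit all four case-study responses
#'
#' Runs [stepwise_rsm()] on each column of a response table over a design.
#'
#' @param design A `dsd_design`.
#' @param responses Data frame with one numeric column per response.
#' @param ... Passed to [stepwise_rsm()].
#' @return Named list of `rsm_fit` objects.
#' @export
fit_all_responses <- function(design, responses, ...) {
  out <- lapply(names(responses), function(nm)
    stepwise_rsm(design, responses[[nm]], response = nm, ...))
  stats::setNames(out, names(responses))
}
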