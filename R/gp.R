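#' Gaussian correlation between two input points
#'
#' `exp(-sum_k theta_k * (x_ik - x_jk)^2)`, the squared-exponential
#' (Gaussian) correlation used by the kriging surrogate.
#'
#' @param x_i,x_j Numeric input vectors of equal length.
#' @param theta Positive kernel scales, one per coordinate (recycled if
#'   scalar).
#' @return Correlation in `(0, 1]`.
#' @examples
#' gp_correlation(0, 1, 1) # exp(-1)
#' @export
gp_correlation <- function(x_i, x_j, theta) {
  if (length(x_i) != length(x_j))
    stop("input dimension mismatch", call. = FALSE)
  theta <- rep_len(theta, length(x_i))
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  exp(-sum(theta * (x_i - x_j)^2))
}

# full correlation matrix of rows of X (n x K) for scales theta
corr_matrix <- function(X, theta) {
  n <- nrow(X)
  R <- matrix(1, n, n)
  for (k in seq_len(ncol(X))) {
    dk <- outer(X[, k], X[, k], "-")
    R <- R * exp(-theta[k] * dk^2)
  }
  R
}

# profiled negative log likelihood: beta and sigma2 concentrated out
gp_nll <- function(log_theta, X, y, nugget) {
  theta <- exp(log_theta)
  n <- length(y)
  R <- corr_matrix(X, theta) + diag(nugget, n)
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  one <- rep(1, n)
  Ri_y <- backsolve(L, forwardsolve(t(L), y))
  Ri_1 <- backsolve(L, forwardsolve(t(L), one))
  beta <- sum(one * Ri_y) / sum(one * Ri_1)
  resid <- y - beta
  Ri_r <- backsolve(L, forwardsolve(t(L), resid))
  sigma2 <- sum(resid * Ri_r) / n
  if (sigma2 <= 0) sigma2 <- 1e-300
  n / 2 * log(sigma2) + sum(log(diag(L)))
}

#' Fit a Gaussian-process (kriging) surrogate
#'
#' Constant-mean kriging with the Gaussian correlation kernel of
#' [gp_correlation()]. The kernel scales `theta` and process variance
#' `sigma2` are estimated by maximising the multivariate-normal log
#' likelihood (profiled over the constant mean, which is estimated by
#' generalised least squares), via seeded multi-start optimisation over
#' `log(theta)`. A fixed quadratic mean `m(x) = 0.25 * sum(x^2)` is
#' available as an alternative prior mean; the residual `y - m(x)` is then
#' modelled with a constant-mean GP.
#'
#' @param X Numeric input matrix (`n x K`), ideally on the coded scale.
#' @param y Numeric targets (e.g. log10 defect rate).
#' @param mean `"constant"` (default) or `"quadratic"`.
#' @param nugget Diagonal inflation of the correlation matrix, default
#'   1e-8; raised automatically (with a warning) on Cholesky failure.
#' @param n_starts Multi-start count, default 10.
#' @param seed RNG seed for the starts.
#' @return An object of class `gp_model` with elements `theta`, `sigma2`,
#'   `beta` (constant-mean GLS estimate), `nugget`, `X`, `y`, `mean`,
#'   `log_lik`.
#' @export
gp_fit <- function(X, y, mean = c("constant", "quadratic"), nugget = 1e-8,
                   n_starts = 10L, seed = 1L) {
  mean <- match.arg(mean)
  X <- as.matrix(X)
  n <- length(y)
  K <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n < K + 2L)
    stop("at least K + 2 training points are required", call. = FALSE)
  if (anyDuplicated(as.data.frame(X)) && nugget <= 0)
    stop("duplicate rows require a positive nugget", call. = FALSE)
  y_fit <- y
  if (mean == "quadratic") y_fit <- y - 0.25 * rowSums(X^2)

  # raise the nugget until the worst-case correlation matrix factorises
  for (try in 1:6) {
    ok <- !is.null(tryCatch(chol(corr_matrix(X, rep(1e-6, K)) +
                                   diag(nugget, n)),
                            error = function(e) NULL))
    if (ok) break
    nugget <- nugget * 100
    warning("correlation matrix not positive definite; nugget raised to ",
            nugget, call. = FALSE)
  }

  starts <- with_seed(seed, {
    s <- lhs::maximinLHS(n_starts, K)
    log(0.01) + s * (log(50) - log(0.01)) # log theta in [log 0.01, log 50]
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    opt <- stats::optim(starts[i, ], gp_nll, X = X, y = y_fit,
                        nugget = nugget, method = "L-BFGS-B",
                        lower = rep(log(1e-6), K), upper = rep(log(1e4), K))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  theta <- exp(best$par)
  R <- corr_matrix(X, theta) + diag(nugget, n)
  L <- chol(R)
  one <- rep(1, n)
  Ri_y <- backsolve(L, forwardsolve(t(L), y_fit))
  Ri_1 <- backsolve(L, forwardsolve(t(L), one))
  beta <- sum(one * Ri_y) / sum(one * Ri_1)
  resid <- y_fit - beta
  Ri_r <- backsolve(L, forwardsolve(t(L), resid))
  sigma2 <- sum(resid * Ri_r) / n
  structure(list(theta = stats::setNames(theta, colnames(X)),
                 sigma2 = sigma2, beta = beta, nugget = nugget,
                 X = X, y = y, mean = mean, chol = L, Ri_r = Ri_r,
                 Ri_1 = Ri_1, log_lik = -best$value),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("Gaussian-process surrogate: %d points, %d inputs, %s mean\n",
              nrow(x$X), ncol(x$X), x$mean))
  cat("  theta:", paste(format(x$theta, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  sigma2 = %.4g, beta = %.4g, nugget = %g\n",
              x$sigma2, x$beta, x$nugget))
  invisible(x)
}

#' @export
coef.gp_model <- function(object, ...) {
  c(beta = object$beta, sigma2 = object$sigma2, object$theta)
}

#' Kriging prediction
#'
#' Standard kriging mean and variance at new inputs (variance includes the
#' uncertainty of the estimated constant mean; it vanishes at training
#' points as the nugget goes to zero and approaches `sigma2` far from the
#' data).
#'
#' @param object A `gp_model`.
#' @param newdata Numeric matrix (or vector) of new inputs.
#' @param ... Unused.
#' @return Data frame with columns `mean` and `variance`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xn <- if (is.null(dim(newdata))) matrix(newdata, ncol = ncol(object$X))
        else as.matrix(newdata)
  n <- nrow(object$X)
  mu <- numeric(nrow(Xn))
  v <- numeric(nrow(Xn))
  one_Ri_1 <- sum(rep(1, n) * object$Ri_1)
  for (i in seq_len(nrow(Xn))) {
    r <- vapply(seq_len(n), function(j)
      gp_correlation(Xn[i, ], object$X[j, ], object$theta), numeric(1))
    # the nugget is numerical jitter, not noise: at an exact training-point
    # match it belongs to the correlation vector, keeping kriging an
    # interpolator
    exact <- which(colSums(abs(t(object$X) - Xn[i, ])) == 0)
    r[exact] <- r[exact] + object$nugget
    mu[i] <- object$beta + sum(r * object$Ri_r)
    Ri_rv <- backsolve(object$chol, forwardsolve(t(object$chol), r))
    v[i] <- object$sigma2 *
      (1 - sum(r * Ri_rv) + (1 - sum(Ri_rv))^2 / one_Ri_1)
    if (v[i] < 0) v[i] <- 0
  }
  if (object$mean == "quadratic") mu <- mu + 0.25 * rowSums(Xn^2)
  data.frame(mean = mu, variance = v)
}

#' Minimise the predicted surface inside a design-space box
#'
#' Seeded multi-start bounded minimisation (L-BFGS-B over the coded image
#' of the box) of the kriging predicted mean. Inputs to the GP are assumed
#' to be on the coded scale of `factors`.
#'
#' @param gp A `gp_model` trained on coded continuous-factor inputs.
#' @param box A [factor_box()] (natural units) to search within.
#' @param factors The `factor_space` for coding; defaults to the box's.
#' @param n_starts Multi-start count, default 20.
#' @param seed RNG seed.
#' @return List with `settings` (one-row natural-unit data frame, the box
#'   level attached when present), `coded` (optimal coded point) and
#'   `predicted` (kriging mean there).
#' @export
gp_minimize <- function(gp, box, factors = box$factors, n_starts = 20L,
                        seed = 1L) {
  stopifnot(inherits(gp, "gp_model"), inherits(box, "factor_box"))
  cont <- continuous_factors(factors)
  nms <- names(cont)
  lower <- vapply(nms, function(nm) code_value(cont[[nm]], box$intervals[[nm]][1]),
                  numeric(1))
  upper <- vapply(nms, function(nm) code_value(cont[[nm]], box$intervals[[nm]][2]),
                  numeric(1))
  if (any(lower < -1 - 1e-9) || any(upper > 1 + 1e-9))
    stop("box outside the factor ranges", call. = FALSE)
  K <- length(nms)
  obj <- function(z) predict(gp, matrix(z, 1L))$mean
  if (all(upper - lower < 1e-12)) {
    z_best <- lower
  } else {
    starts <- with_seed(seed, {
      s <- lhs::maximinLHS(n_starts, K)
      sweep(sweep(s, 2L, upper - lower, "*"), 2L, lower, "+")
    })
    best <- NULL
    for (i in seq_len(n_starts)) {
      opt <- stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                          lower = lower, upper = upper)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    z_best <- best$par
  }
  settings <- as.data.frame(lapply(seq_len(K), function(j)
    decode_value(cont[[j]], z_best[j])))
  names(settings) <- nms
  cat_f <- categorical_factor(factors)
  if (!is.null(cat_f))
    settings[[cat_f$name]] <- box$level %||% cat_f$levels[2L]
  list(settings = settings, coded = stats::setNames(z_best, nms),
       predicted = obj(z_best))
}

#' Serialize a GP model as JSON
#'
#' @param gp A `gp_model`.
#' @param path File path.
#' @return `read_gp_json()` returns the refitted-free reconstructed model.
#' @export
write_gp_json <- function(gp, path) {
  out <- list(theta = as.list(gp$theta), sigma2 = gp$sigma2, beta = gp$beta,
              nugget = gp$nugget, mean = gp$mean,
              X = apply(gp$X, 1L, as.list), y = gp$y)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gp_json
#' @export
read_gp_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  X <- as.matrix(doc$X)
  if (is.list(doc$X)) X <- do.call(rbind, lapply(doc$X, unlist))
  y <- as.numeric(doc$y)
  theta <- unlist(doc$theta)
  n <- length(y)
  y_fit <- y
  if (doc$mean == "quadratic") y_fit <- y - 0.25 * rowSums(X^2)
  R <- corr_matrix(X, theta) + diag(doc$nugget, n)
  L <- chol(R)
  resid <- y_fit - doc$beta
  structure(list(theta = theta, sigma2 = doc$sigma2, beta = doc$beta,
                 nugget = doc$nugget, X = X, y = y, mean = doc$mean,
                 chol = L,
                 Ri_r = backsolve(L, forwardsolve(t(L), resid)),
                 Ri_1 = backsolve(L, forwardsolve(t(L), rep(1, n))),
                 log_lik = NA_real_),
            class = "gp_model")
}
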