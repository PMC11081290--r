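test_that("the Gaussian correlation kernel evaluates and orders as expected", {
  expect_equal(gp_correlation(c(1, 2), c(1, 2), c(1, 1)), 1)
  expect_equal(gp_correlation(0, 1, 1), exp(-1))
  expect_equal(gp_correlation(c(0, 0), c(1, 2), c(0.5, 0.25)),
               exp(-(0.5 * 1 + 0.25 * 4)))
  # strictly decreasing in any theta at fixed nonzero distance
  r <- vapply(c(0.5, 1, 2, 4), function(th) gp_correlation(0, 0.7, th),
              numeric(1))
  expect_true(all(diff(r) < 0))
  expect_error(gp_correlation(c(0, 0), 1, 1), "dimension")
  expect_error(gp_correlation(0, 1, -1), "positive")
})

test_that("kriging interpolates noiseless training data to 1e-6", {
  x <- matrix(seq(0, 2 * pi, length.out = 10), ncol = 1)
  y <- sin(x[, 1])
  gp <- gp_fit(x, y, nugget = 1e-10, seed = 1)
  pred <- predict(gp, x)
  expect_lt(max(abs(pred$mean - y)), 1e-6)
  expect_true(all(pred$variance >= 0))
  expect_lt(max(pred$variance), 1e-6 * gp$sigma2 + 1e-10)
})

test_that("a constant response collapses the process variance", {
  x <- matrix(seq(-1, 1, length.out = 8), ncol = 1)
  gp <- gp_fit(x, rep(3.5, 8), nugget = 1e-8, seed = 1)
  expect_lt(gp$sigma2, 1e-10)
  pred <- predict(gp, matrix(c(-0.5, 0.33, 2), ncol = 1))
  expect_equal(pred$mean, rep(3.5, 3), tolerance = 1e-6)
})

test_that("far from the data the prediction reverts to the constant mean", {
  x <- matrix(seq(-1, 1, length.out = 12), ncol = 1)
  y <- sin(2 * x[, 1])
  gp <- gp_fit(x, y, nugget = 1e-8, seed = 2)
  far <- predict(gp, matrix(1e4, ncol = 1))
  expect_equal(far$mean, gp$beta, tolerance = 1e-8)
  expect_equal(far$variance, gp$sigma2 * (1 + 1 / sum(gp$Ri_1)),
               tolerance = 1e-6)
  # variance never exceeds sigma2 (+ mean-estimation term + nugget)
  grid <- predict(gp, matrix(seq(-2, 2, length.out = 50), ncol = 1))
  expect_true(all(grid$variance <=
                    gp$sigma2 * (1 + 1 / sum(gp$Ri_1)) + 1e-8))
})

test_that("symmetric training points predict their common target at the midpoint", {
  # two symmetric points with equal targets: the GLS constant mean equals
  # the common target, so the kriging mean at the midpoint is that target
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c(2.2, 2.2)
  theta <- 0.8
  R <- outer(x[, 1], x[, 1], function(a, b) exp(-theta * (a - b)^2)) +
    diag(1e-10, 2)
  L <- chol(R)
  solve_R <- function(b) backsolve(L, forwardsolve(t(L), b))
  beta <- sum(solve_R(y)) / sum(solve_R(rep(1, 2)))
  gp <- structure(list(theta = theta, sigma2 = 0.5, beta = beta,
                       nugget = 1e-10, X = x, y = y, mean = "constant",
                       chol = L, Ri_r = solve_R(y - beta),
                       Ri_1 = solve_R(rep(1, 2)), log_lik = NA_real_),
                  class = "gp_model")
  expect_equal(predict(gp, matrix(0, ncol = 1))$mean, 2.2, tolerance = 1e-10)
})

test_that("kriging predictions are invariant to affine input rescaling", {
  set.seed(7)
  x <- matrix(runif(20, -1, 1), ncol = 2)
  y <- x[, 1]^2 - 0.5 * x[, 2] + rnorm(10, 0, 0.01)
  gp1 <- gp_fit(x, y, nugget = 1e-8, seed = 3)
  # rescale inputs by c and theta by 1/c^2: identical correlations
  c_ <- 4
  gp2 <- gp1
  gp2$X <- x * c_
  gp2$theta <- gp1$theta / c_^2
  new1 <- matrix(runif(6, -1, 1), ncol = 2)
  p1 <- predict(gp1, new1)
  p2 <- predict(gp2, new1 * c_)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_equal(p1$variance, p2$variance, tolerance = 1e-10)
})

test_that("the fitted length-scale beats random draws in likelihood", {
  set.seed(19)
  x <- matrix(runif(30, -2, 2), ncol = 1)
  theta_true <- 1.5
  R <- outer(x[, 1], x[, 1], function(a, b) exp(-theta_true * (a - b)^2)) +
    diag(1e-8, 30)
  y <- drop(t(chol(R)) %*% rnorm(30))
  gp <- gp_fit(x, y, nugget = 1e-8, seed = 4)
  nll_hat <- rheodsd:::gp_nll(log(gp$theta), x, y, 1e-8)
  draws <- withr::with_seed(99, exp(runif(100, log(0.01), log(50))))
  nll_draws <- vapply(draws, function(th)
    rheodsd:::gp_nll(log(th), x, y, 1e-8), numeric(1))
  expect_lte(nll_hat, min(nll_draws) + 1e-6)
})

test_that("length-scale recovery from GP draws lands within a factor of two", {
  theta_true <- 2
  n <- 60L
  n_rep <- 50L
  hits <- 0L
  for (r in seq_len(n_rep)) {
    x <- matrix(withr::with_seed(5000 + r, runif(n, -2, 2)), ncol = 1)
    R <- outer(x[, 1], x[, 1],
               function(a, b) exp(-theta_true * (a - b)^2)) + diag(1e-8, n)
    y <- drop(t(chol(R)) %*% withr::with_seed(6000 + r, rnorm(n)))
    gp <- gp_fit(x, y, nugget = 1e-8, n_starts = 6L, seed = r)
    if (gp$theta >= theta_true / 2 && gp$theta <= theta_true * 2)
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.80)
})

test_that("surface minimisation finds the vertex of a convex paraboloid", {
  set.seed(77)
  fs <- small_space(2)
  Xc <- as.matrix(expand.grid(x1 = seq(-1, 1, length.out = 7),
                              x2 = seq(-1, 1, length.out = 7)))
  y <- (Xc[, 1] - 0.2)^2 + 2 * (Xc[, 2] + 0.3)^2
  gp <- gp_fit(Xc, y, nugget = 1e-8, seed = 5)
  box <- factor_box(list(x1 = c(-10, 10), x2 = c(-10, 10)), fs)
  opt <- gp_minimize(gp, box, fs, n_starts = 10L, seed = 6)
  # natural units: decode is 10 * coded
  expect_equal(unname(opt$coded["x1"]), 0.2, tolerance = 0.05)
  expect_equal(unname(opt$coded["x2"]), -0.3, tolerance = 0.05)
  # collapsed box returns its single point
  pt_box <- factor_box(list(x1 = c(5, 5), x2 = c(-3, -3)), fs)
  opt_pt <- gp_minimize(gp, pt_box, fs, seed = 1)
  expect_equal(opt_pt$settings$x1, 5)
  expect_equal(opt_pt$settings$x2, -3)
  out_box <- factor_box(list(x1 = c(-20, 0), x2 = c(0, 1)), fs)
  out_box$intervals$x1 <- c(-30, 0) # force out of range
  expect_error(gp_minimize(gp, out_box, fs), "outside")
})

test_that("GP models round-trip through JSON with identical predictions", {
  set.seed(13)
  x <- matrix(runif(24, -1, 1), ncol = 2)
  y <- x[, 1] - x[, 2]^2 + rnorm(12, 0, 0.05)
  gp <- gp_fit(x, y, nugget = 1e-8, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_gp_json(gp, path)
  gp2 <- read_gp_json(path)
  new1 <- matrix(runif(10, -1, 1), ncol = 2)
  expect_equal(predict(gp2, new1)$mean, predict(gp, new1)$mean,
               tolerance = 1e-10)
})
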