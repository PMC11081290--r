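test_that("radial layers are contiguous and follow the cyclic assignment rule", {
  sch <- radial_scheme(4L, d = 0.5)
  expect_equal(sch$bounds[, "inner"], c(0, 0.5, 1.5, 2.5))
  expect_equal(sch$bounds[, "outer"], c(0.5, 1.5, 2.5, 3.5))
  # contiguous and non-overlapping
  expect_equal(sch$bounds[-1, "inner"], sch$bounds[-4, "outer"])
  expect_error(radial_scheme(3L, d = -1), "positive")
  # default d maps the outermost radius to the coded-box corner
  sch5 <- radial_scheme(4L, dims = 5)
  expect_equal(max(sch5$bounds), sqrt(5))

  pts <- sample_radial(3L, radial_scheme(4L, dims = 3), n = 24L, seed = 9)
  layer <- attr(pts, "layer")
  # run i sits in layer (i - 1) mod layers: run 6 -> layer 1
  expect_equal(layer[6], 1L)
  expect_equal(layer, (seq_len(24L) - 1L) %% 4L)
  # n = 4k runs spread exactly k per layer
  expect_equal(unname(table(layer)), rep(6L, 4L), ignore_attr = TRUE)
})

test_that("layer-0 radial points stay within the base distance", {
  sch <- radial_scheme(4L, dims = 4)
  pts <- sample_radial(4L, sch, n = 400L, seed = 1)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r[attr(pts, "layer") == 0L] <= sch$d + 1e-12))
  expect_true(all(abs(pts) <= 1)) # clamped to the coded box
})

test_that("defect rates reproduce analytic normal-tail cases", {
  # a single synthetic response y ~ N(mu, sd) against a window
  fs <- factor_space(qbd_factor("x", low = -1, high = 1))
  m <- response_model("y", intercept = 10, coef = c(x = 0), factors = fs)
  n <- 100000L
  # zero noise, prediction strictly inside: defect exactly 0
  lim0 <- spec_limits(list(y = c(5, 15)))
  r0 <- defect_rate(list(y = m), data.frame(x = 0), lim0, noise_model(),
                    n = 1000L, seed = 1)
  expect_equal(r0$overall, 0)
  expect_equal(r0$log10_overall, log10(1 / 1000))
  # upper limit at the mean: defect 0.5 within 3 binomial SEs
  lim_half <- spec_limits(list(y = c(-1e9, 10)))
  r_half <- defect_rate(list(y = m), data.frame(x = 0), lim_half,
                        noise_model(response_sd = c(y = 2)), n = n, seed = 2)
  expect_lt(abs(r_half$overall - 0.5), 3 * sqrt(0.25 / n))
  # +/- 1.96 sd window: defect ~ 0.05
  lim_95 <- spec_limits(list(y = c(10 - 1.96 * 2, 10 + 1.96 * 2)))
  r95 <- defect_rate(list(y = m), data.frame(x = 0), lim_95,
                     noise_model(response_sd = c(y = 2)), n = n, seed = 3)
  expect_lt(abs(r95$overall - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("defect reports satisfy their structural bounds", {
  r <- defect_rate(study_models, optimal_settings(), study_limits,
                   default_noise_model(study_models), n = 20000L, seed = 5)
  expect_true(all(r$per_response >= 0 & r$per_response <= 1))
  expect_lte(r$overall, sum(r$per_response) + 1e-12)
  expect_gte(r$overall, max(r$per_response) - 1e-12)
  expect_equal(r$log10_overall, log10(max(r$overall, 1 / r$n)))
  expect_error(defect_rate(study_models[-1], optimal_settings(), study_limits,
                           n = 10L), "no model")
})

test_that("stratified radial sampling agrees with the iid oracle within 3 MC SEs", {
  # toy configurations: a linear response over a 3-factor space; the
  # estimand is the out-of-window probability under the radial measure
  # (uniform radius x uniform direction). The iid oracle is the same
  # measure sampled with a single all-covering layer.
  fs <- small_space(3)
  m <- response_model("y", intercept = 0,
                      coef = c(x1 = 1, x2 = 0.5, x3 = 0.25), factors = fs)
  n <- 20000L
  r_max <- sqrt(3)
  eval_defect <- function(pts, lim) {
    nat <- as.data.frame(10 * pts) # decode for this space is 10 * coded
    names(nat) <- c("x1", "x2", "x3")
    yy <- predict(m, nat)
    bad <- yy < lim$y[1] | yy > lim$y[2]
    w <- attr(pts, "weight")
    list(est = sum(w * bad), se = sqrt(sum(w^2 * stats::var(bad))))
  }
  for (cfg in 1:10) {
    lim <- spec_limits(list(y = c(-1, 0.3 + 0.12 * cfg)))
    strat <- eval_defect(sample_radial(3L, radial_scheme(4L, dims = 3),
                                       n = n, seed = 100 + cfg), lim)
    iid <- eval_defect(sample_radial(3L, radial_scheme(1L, d = r_max),
                                     n = n, seed = 200 + cfg), lim)
    se <- sqrt(strat$se^2 + iid$se^2)
    expect_lt(abs(strat$est - iid$est), 3 * se, label = paste("config", cfg))
  }
})

test_that("Monte Carlo standard error shrinks like one over root n", {
  fs <- factor_space(qbd_factor("x", low = -1, high = 1))
  m <- response_model("y", intercept = 0, coef = c(x = 0), factors = fs)
  lim <- spec_limits(list(y = c(-1.5, 1.5)))
  nm <- noise_model(response_sd = c(y = 1))
  est <- function(n, seeds) vapply(seeds, function(s)
    defect_rate(list(y = m), data.frame(x = 0), lim, nm, n = n, seed = s)$overall,
    numeric(1))
  e_small <- est(500L, 1:50)
  e_big <- est(2000L, 101:150)
  ratio <- stats::sd(e_small) / stats::sd(e_big)
  # quadrupling n should halve the SE (allowing sampling slack)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)
})

test_that("widening any specification window never increases the overall defect", {
  nm <- default_noise_model(study_models)
  base <- defect_rate(study_models, optimal_settings(), study_limits,
                      nm, n = 20000L, seed = 11)
  for (widen in names(study_limits)) {
    w <- unclass(study_limits)
    w[[widen]] <- w[[widen]] + c(-0.5, 0.5) * diff(w[[widen]])
    wider <- defect_rate(study_models, optimal_settings(),
                         spec_limits(w), nm, n = 20000L, seed = 11)
    expect_lte(wider$overall, base$overall + 1e-12, label = widen)
  }
})

test_that("defect surfaces are deterministic with per-point derived seeds", {
  pts <- rbind(optimal_settings(), optimal_settings(),
               optimal_settings(rounded = TRUE))
  surf <- defect_surface(study_models, pts, study_limits,
                         default_noise_model(study_models),
                         n_inner = 5000L, seed = 4)
  expect_equal(nrow(surf), 3L)
  # identical rows with identical derived seeds give identical results
  surf12 <- defect_surface(study_models, pts[1:2, ], study_limits,
                           default_noise_model(study_models),
                           n_inner = 5000L, seed = 4)
  expect_equal(surf$defect[1:2], surf12$defect)
  # log10 column is consistent with the defect column
  pos <- surf$defect > 0
  expect_equal(surf$log10_defect[pos], log10(surf$defect[pos]))
})
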