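test_that("the shipped case-study models reproduce the printed optimum predictions", {
  preds <- vapply(study_models, predict, numeric(1), newdata = printed_optimum)
  for (nm in names(printed_predictions)) {
    expect_lt(abs(preds[[nm]] - printed_predictions[[nm]]) /
                printed_predictions[[nm]], 0.005, label = nm)
  }
})

test_that("model evaluation matches hand arithmetic at the design centre", {
  centre <- data.frame(drug_ratio = 35, mixing_time = 25, mixing_speed = 1050,
                       petroleum = 77.5, liquid_paraffin = 7.5, method = "B")
  # at coded zeros only intercept + method match value survive
  expect_equal(predict(study_models$yield_stress, centre), 42.00 + 2.33)
  centre$method <- "A"
  expect_equal(predict(study_models$yield_stress, centre), 42.00 - 2.33)
  expect_error(predict(study_models$yield_stress, centre[-1]), "lack")
  centre$method <- "C"
  expect_error(predict(study_models$yield_stress, centre), "unknown level")
})

test_that("method A and B predictions differ by twice the summed match values", {
  settings <- data.frame(drug_ratio = 28, mixing_time = 12, mixing_speed = 900,
                         petroleum = 80, liquid_paraffin = 6, method = "B")
  coded <- data.frame(drug_ratio = (28 - 35) / 15, mixing_time = (12 - 25) / 20,
                      mixing_speed = (900 - 1050) / 750, petroleum = (80 - 77.5) / 7.5,
                      liquid_paraffin = (6 - 7.5) / 2.5)
  for (m in study_models) {
    yb <- predict(m, settings)
    settings_a <- settings; settings_a$method <- "A"
    ya <- predict(m, settings_a)
    mv <- match_values(m)
    # every match term's level values sum to zero
    for (v in mv) expect_equal(sum(v), 0)
    # difference = 2 * sum of (B match value x partner term value)
    delta <- 0
    for (lab in names(mv)) {
      partners <- setdiff(strsplit(lab, ":")[[1]], "method")
      x <- if (length(partners)) coded[[partners]] else 1
      delta <- delta + 2 * mv[[lab]][["B"]] * x
    }
    expect_equal(yb - ya, delta, tolerance = 1e-10, label = m$response)
  }
})

test_that("stepwise selection recovers a noiseless sparse model exactly", {
  d <- dsd_design(ointment_space)
  X <- model_matrix(d)
  y <- 10 + 4 * X[, "petroleum"] - 2 * X[, "liquid_paraffin"]
  f <- stepwise_rsm(d, y, criterion = "aicc")
  expect_setequal(f$terms, c("petroleum", "liquid_paraffin"))
  expect_equal(unname(coef(f)[c("petroleum", "liquid_paraffin")]), c(4, -2),
               tolerance = 1e-9)
  expect_equal(f$stats$r_squared, 1, tolerance = 1e-12)
})

test_that("stepwise recovers a dominant single effect against the OLS oracle", {
  d <- dsd_design(ointment_space)
  X <- model_matrix(d)
  y <- withr::with_seed(11, 2 + 3 * X[, "drug_ratio"] + rnorm(14, 0, 0.01))
  f <- stepwise_rsm(d, y, criterion = "aicc")
  expect_true("drug_ratio" %in% f$terms)
  # oracle: OLS on the true term set
  oracle <- stats::lm.fit(X[, c("(Intercept)", "drug_ratio")], y)$coefficients
  expect_lt(abs(coef(f)[["drug_ratio"]] - 3), 0.05)
  expect_lt(abs(coef(f)[["drug_ratio"]] - oracle[["drug_ratio"]]), 0.05)
})

test_that("effect heredity gates second-order entry and exit", {
  d <- dsd_design(ointment_space)
  X <- model_matrix(d)
  # pure quadratic signal: without its parent main in the model the
  # quadratic may not enter under heredity
  y <- withr::with_seed(5, 6 + 8 * X[, "mixing_speed^2"] + rnorm(14, 0, 0.05))
  f_on <- stepwise_rsm(d, y, criterion = "aicc", heredity = TRUE)
  if ("mixing_speed^2" %in% f_on$terms)
    expect_true("mixing_speed" %in% f_on$terms)
  f_off <- stepwise_rsm(d, y, criterion = "aicc", heredity = FALSE)
  expect_true("mixing_speed^2" %in% f_off$terms)
})

test_that("t-ratios follow the closed form on an orthogonal single-term design", {
  d <- dsd_design(ointment_space)
  X <- model_matrix(d)[, c("(Intercept)", "petroleum")]
  y <- withr::with_seed(3, 1 + 2 * X[, "petroleum"] + rnorm(14, 0, 0.3))
  tt <- t_ratios(X, y)
  fit <- stats::lm.fit(X, y)
  s <- sqrt(sum(fit$residuals^2) / (14 - 2))
  # orthogonal columns: se = s / sqrt(sum x^2)
  expect_equal(tt$t_ratio[tt$term == "petroleum"],
               unname(fit$coefficients["petroleum"]) /
                 (s / sqrt(sum(X[, "petroleum"]^2))),
               tolerance = 1e-10)
  dup <- cbind(X, petroleum2 = X[, "petroleum"])
  expect_error(t_ratios(dup, y), "rank deficient")
  expect_error(t_ratios(X[1:2, ], y[1:2]), "degrees of freedom")
})

test_that("stepwise refits of synthetic study data are faithful and well-fitting", {
  d <- dsd_design(ointment_space)
  # the permissive classic screening entry threshold favours fit quality
  # over parsimony, which is what the goodness-of-fit claim is about
  n_rep <- 20L
  all_good <- 0L
  for (r in seq_len(n_rep)) {
    resp <- gen_doe_responses(d, study_models, seed = 100 + r)
    fits <- suppressWarnings(
      fit_all_responses(d, resp, p_enter = 0.25, p_remove = 0.25))
    r2 <- vapply(fits, function(f) f$stats$r_squared, numeric(1))
    if (all(r2 > 0.9)) all_good <- all_good + 1L
  }
  expect_gte(all_good / n_rep, 0.7)
  # the dominant printed coefficient makes drug ratio the top |t| term
  # for storage modulus
  resp <- gen_doe_responses(d, study_models, seed = 7)
  fit_sm <- stepwise_rsm(d, resp$storage_modulus, p_enter = 0.25,
                         p_remove = 0.25)
  tt <- t_ratios(fit_sm)
  expect_equal(tt$term[1], "drug_ratio")
})

test_that("desirability values and the joint optimum behave as specified", {
  dspec <- desirability_spec(study_limits)
  # exact window midpoints give overall desirability 1
  mids <- vapply(study_limits, mean, numeric(1))
  expect_equal(overall_desirability(as.list(mids), dspec), 1)
  # any response outside its window zeroes the overall desirability
  bad <- as.list(mids); bad$yield_stress <- 60
  expect_equal(overall_desirability(bad, dspec), 0)
  on_edge <- as.list(mids); on_edge$yield_stress <- 55
  expect_equal(overall_desirability(on_edge, dspec), 0)
  opt <- desirability_optimize(study_models, dspec, seed = 2)
  # optimiser's predictions all inside the four windows
  for (nm in names(study_limits)) {
    w <- study_limits[[nm]]
    expect_gt(opt$predictions[[nm]], w[1], label = nm)
    expect_lt(opt$predictions[[nm]], w[2], label = nm)
  }
  expect_gt(opt$desirability, 0)
  # infeasible windows are reported explicitly
  tight <- spec_limits(list(yield_stress = c(4000, 4001),
                            high_shear_visc = c(0, 7),
                            low_shear_visc = c(11000, 18000),
                            storage_modulus = c(200, 1000)))
  expect_error(
    desirability_optimize(study_models, desirability_spec(tight),
                          n_starts = 8L, seed = 2),
    "empty feasible region")
})

test_that("active-set recovery on sparse study-scale signals exceeds 90 percent", {
  d <- dsd_design(ointment_space)
  X <- model_matrix(d)
  # sparse truth: the three main effects of the printed yield-stress model
  truth <- c(petroleum = 8.83, liquid_paraffin = -6.96, mixing_time = 2.23)
  mu <- 42 + as.vector(X[, names(truth)] %*% truth)
  sigma <- 0.05 * stats::sd(mu)
  n_rep <- 200L
  exact <- 0L
  for (r in seq_len(n_rep)) {
    y <- withr::with_seed(4000 + r, mu + rnorm(14, 0, sigma))
    # Bonferroni-style entry (0.05 over ~25 candidates) controls the
    # best-of-many selection bias that exact set recovery needs
    f <- stepwise_rsm(d, y, p_enter = 0.002, p_remove = 0.002)
    if (setequal(f$terms, names(truth))) exact <- exact + 1L
  }
  expect_gte(exact / n_rep, 0.90)
})
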