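#' Case-study configuration
#'
#' Bundles every tunable of the end-to-end pipeline with validated
#' defaults: the factor space and specification windows of the ointment
#' study, the perturbation model, Monte Carlo sizes, tree and GP settings.
#'
#' @param factors `factor_space`, default [ointment_factors()].
#' @param limits [spec_limits()], default the study windows.
#' @param models Ground-truth/fitted models used for simulation; default
#'   the printed fixture models ("fixture mode"). Set `refit = TRUE` in
#'   [run_case_study()] to refit them from synthetic responses instead.
#' @param noise [noise_model()]; default [default_noise_model()].
#' @param n_mc Monte Carlo batches per defect estimate, default 100000.
#' @param n_tree_points Labelled points for the tree, default 6000.
#' @param max_splits,lambda,min_pass_prob Tree settings (15 splits,
#'   lambda 0.5, best leaf unconstrained by default).
#' @param n_surface,n_inner GP training design size (128 points) and Monte
#'   Carlo runs per surface point (default 20000).
#' @param plateau Desirability plateau fraction, default 0.5.
#' @return A validated list of class `case_study_config`.
#' @export
case_study_config <- function(factors = ointment_factors(),
                              limits = spec_limits(),
                              models = ointment_models(),
                              noise = NULL,
                              n_mc = 100000L, n_tree_points = 6000L,
                              max_splits = 15L, lambda = 0.5,
                              min_pass_prob = 0,
                              n_surface = 128L, n_inner = 20000L,
                              plateau = 0.5) {
  if (is.null(noise)) noise <- default_noise_model(models)
  stopifnot(inherits(factors, "factor_space"), inherits(limits, "spec_limits"),
            inherits(noise, "noise_model"), n_mc >= 1L, n_tree_points >= 10L,
            max_splits >= 0L, lambda >= 0, lambda <= 1, n_surface >= 2L,
            n_inner >= 1L)
  missing <- setdiff(names(limits), names(models))
  if (length(missing))
    stop("no model for response(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(factors = factors, limits = limits, models = models,
                 noise = noise, n_mc = as.integer(n_mc),
                 n_tree_points = as.integer(n_tree_points),
                 max_splits = as.integer(max_splits), lambda = lambda,
                 min_pass_prob = min_pass_prob,
                 n_surface = as.integer(n_surface),
                 n_inner = as.integer(n_inner), plateau = plateau),
            class = "case_study_config")
}

#' Run the end-to-end quality-by-design case study
#'
#' Executes the full optimisation chain: definitive screening design,
#' synthetic response generation, (optionally) stepwise model refits,
#' desirability optimisation, Monte Carlo defect estimation, decision-tree
#' design-space extraction, Gaussian-process surface fit and constrained
#' optimisation. All randomness derives from `seed`; rerunning with the
#' same configuration and seed reproduces the report exactly.
#'
#' The report's `reference_predictions` block evaluates the four shipped
#' response models at the study's reported optimal settings
#' ([optimal_settings()]); the `defect` block compares the overall defect
#' rate at the desirability optimum, averaged over the tree box, and at
#' the GP optimum (common random numbers across the three).
#'
#' @param config A [case_study_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param refit Refit the four models from synthetic DSD responses by
#'   [stepwise_rsm()] instead of simulating from the shipped fixture
#'   models.
#' @param json Optional path: write the report as JSON.
#' @return A list of class `case_study_report`.
#' @export
run_case_study <- function(config = case_study_config(), seed = 1L,
                           refit = FALSE, json = NULL) {
  stopifnot(inherits(config, "case_study_config"))
  seed <- as.integer(seed)
  stage_seed <- function(k) (seed * 101L + k * 7919L) %% .Machine$integer.max

  design <- dsd_design(config$factors)
  responses <- gen_doe_responses(design, config$models,
                                 seed = stage_seed(1L))
  models <- config$models
  fits <- NULL
  if (refit) {
    fits <- fit_all_responses(design, responses, p_enter = 0.25,
                              p_remove = 0.25)
    models <- lapply(fits, `[[`, "model")
  }

  dspec <- desirability_spec(config$limits, plateau = config$plateau)
  opt_des <- desirability_optimize(models, dspec, n_starts = 32L,
                                   seed = stage_seed(2L))
  mc_seed <- stage_seed(3L) # shared: common random numbers across points
  defect_des <- defect_rate(models, opt_des$settings, config$limits,
                            config$noise, n = config$n_mc, seed = mc_seed)

  labeled <- gen_labeled_points(models, config$limits, config$noise,
                                n = config$n_tree_points,
                                level = box_level(config$factors),
                                seed = stage_seed(4L))
  feat <- labeled[setdiff(names(labeled), c("pass", cat_name(config$factors)))]
  tree <- grow_tree(feat, labeled$pass, max_splits = config$max_splits,
                    lambda = config$lambda)
  auc <- roc_auc(predict(tree, feat), labeled$pass)
  box <- extract_box(tree, config$factors, config$min_pass_prob)
  box$level <- box$level %||% box_level(config$factors)
  defect_box <- defect_rate(models, box, config$limits, config$noise,
                            n = config$n_mc, seed = mc_seed)

  # GP surface over the box: maximin LHS in the box's coded image
  cont <- continuous_factors(config$factors)
  nms <- names(cont)
  lower <- vapply(nms, function(nm) code_value(cont[[nm]], box$intervals[[nm]][1]),
                  numeric(1))
  upper <- vapply(nms, function(nm) code_value(cont[[nm]], box$intervals[[nm]][2]),
                  numeric(1))
  Xc <- with_seed(stage_seed(5L), {
    s <- lhs::maximinLHS(config$n_surface, length(nms))
    sweep(sweep(s, 2L, upper - lower, "*"), 2L, lower, "+")
  })
  colnames(Xc) <- nms
  pts <- as.data.frame(lapply(seq_along(nms), function(j)
    decode_value(cont[[j]], Xc[, j])))
  names(pts) <- nms
  if (!is.null(cat_name(config$factors)))
    pts[[cat_name(config$factors)]] <- box$level
  surface <- defect_surface(models, pts, config$limits, config$noise,
                            n_inner = config$n_inner, seed = stage_seed(6L))
  gp <- gp_fit(Xc, surface$log10_defect, seed = stage_seed(7L))
  opt_gp <- gp_minimize(gp, box, config$factors, seed = stage_seed(8L))
  defect_gp <- defect_rate(models, opt_gp$settings, config$limits,
                           config$noise, n = config$n_mc, seed = mc_seed)
  pred_gp <- vapply(models[names(config$limits)], predict, numeric(1),
                    newdata = opt_gp$settings)

  ref <- vapply(ointment_models()[names(config$limits)], predict, numeric(1),
                newdata = optimal_settings())

  report <- structure(list(
    seed = seed,
    design = design,
    responses = responses,
    fits = fits,
    desirability = list(settings = opt_des$settings,
                        predictions = opt_des$predictions,
                        desirability = opt_des$desirability),
    tree = list(auc = auc, n_splits = tree$n_splits, box = box),
    gp = list(model = gp, settings = opt_gp$settings,
              predicted_log10_defect = opt_gp$predicted,
              predictions = pred_gp),
    defect = list(desirability_optimum = defect_des$overall,
                  tree_box = defect_box$overall,
                  gp_optimum = defect_gp$overall,
                  reports = list(desirability = defect_des,
                                 box = defect_box, gp = defect_gp)),
    reference_predictions = ref),
    class = "case_study_report")
  if (!is.null(json)) write_report_json(report, json)
  report
}

cat_name <- function(factors) {
  f <- categorical_factor(factors)
  if (is.null(f)) NULL else f$name
}

# categorical level the optimisation stages work at (second level,
# the study's preferred drug-addition method)
box_level <- function(factors) {
  f <- categorical_factor(factors)
  if (is.null(f)) NULL else f$levels[2L]
}

#' @export
print.case_study_report <- function(x, ...) {
  cat("Quality-by-design case-study report (seed ", x$seed, ")\n", sep = "")
  cat("\nReference predictions at the reported optimum:\n")
  for (nm in names(x$reference_predictions))
    cat(sprintf("  %-16s %.2f\n", nm, x$reference_predictions[[nm]]))
  cat("\nDesirability optimum (overall desirability ",
      sprintf("%.3f", x$desirability$desirability), "):\n", sep = "")
  print(x$desirability$settings, row.names = FALSE)
  cat("\nTree: ", x$tree$n_splits, " splits, AUC ",
      sprintf("%.4f", x$tree$auc), "\n", sep = "")
  print(x$tree$box)
  cat("\nGP optimum:\n")
  print(x$gp$settings, row.names = FALSE)
  cat("\nOverall defect rates:\n")
  cat(sprintf("  desirability optimum  %.4f\n", x$defect$desirability_optimum))
  cat(sprintf("  tree box (uniform)    %.4f\n", x$defect$tree_box))
  cat(sprintf("  GP optimum            %.4f\n", x$defect$gp_optimum))
  invisible(x)
}

#' Write a case-study report as JSON
#'
#' Serialises the numeric content of a [run_case_study()] report (settings,
#' predictions, defect rates, box, AUC); model objects are omitted.
#'
#' @param report A `case_study_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    seed = report$seed,
    reference_predictions = as.list(report$reference_predictions),
    desirability = list(settings = as.list(report$desirability$settings),
                        predictions = as.list(report$desirability$predictions),
                        desirability = report$desirability$desirability),
    tree = list(auc = report$tree$auc, n_splits = report$tree$n_splits,
                box = lapply(report$tree$box$intervals, as.list)),
    gp = list(settings = as.list(report$gp$settings),
              predicted_log10_defect = report$gp$predicted_log10_defect,
              predictions = as.list(report$gp$predictions)),
    defect = report$defect[c("desirability_optimum", "tree_box",
                             "gp_optimum")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validation-batch deviations from target
#'
#' Percentage deviation of each validation-batch mean from its target,
#' `100 * (mean - target) / target`, computed from a validation summary
#' table (default: the shipped case-study fixture with the three
#' verification batches at the optimal settings).
#'
#' @param path CSV with columns `response`, `target`, `validation_mean`
#'   (and optionally `validation_sd`, `n`).
#' @return The table with columns `deviation_pct` (rounded to 2 decimals)
#'   and `rsd_pct` (validation SD as percent of the mean) appended.
#' @export
validation_deviations <- function(path = system.file("extdata",
                                                     "validation_batches.csv",
                                                     package = "rheodsd",
                                                     mustWork = TRUE)) {
  df <- utils::read.csv(path)
  stopifnot(all(c("response", "target", "validation_mean") %in% names(df)))
  df$deviation_pct <- round(100 * (df$validation_mean - df$target) / df$target, 2)
  if (!is.null(df$validation_sd))
    df$rsd_pct <- round(100 * df$validation_sd / df$validation_mean, 2)
  df
}

#' Summarise a yield-stress batch table
#'
#' Mean, SD and range of per-run yield stresses, as reported for a
#' screening campaign. The shipped default is a synthetic stand-in table
#' (the study's supplementary per-run data are not redistributable)
#' constructed to be consistent with the published summary statistics.
#'
#' @param path CSV with columns `run_id`, `yield_stress_Pa`.
#' @return List with `n`, `mean`, `sd`, `min`, `max`.
#' @export
yield_stress_summary <- function(path = system.file("extdata",
                                                    "yield_stress_batches_synthetic.csv",
                                                    package = "rheodsd",
                                                    mustWork = TRUE)) {
  df <- utils::read.csv(path)
  stopifnot("yield_stress_Pa" %in% names(df))
  y <- df$yield_stress_Pa
  list(n = length(y), mean = mean(y), sd = stats::sd(y),
       min = min(y), max = max(y))
}

#' Read and write factor-space and limits configuration YAML
#'
#' Factor YAML: a list of entries with `name` and either `low`/`high`
#' (optional `mid`, `unit`) or `levels`. Limits YAML: `response: [lower,
#' upper]` pairs.
#'
#' @param path File path.
#' @param factors `factor_space` to write.
#' @param limits `spec_limits` to write.
#' @return Readers return the reconstructed object.
#' @export
read_factors_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  factor_space(lapply(doc, function(f) {
    if (!is.null(f$levels)) qbd_factor(f$name, levels = unlist(f$levels))
    else qbd_factor(f$name, low = f$low, high = f$high,
                    mid = f$mid %||% NULL, unit = f$unit %||% NULL)
  }))
}

#' @rdname read_factors_yaml
#' @export
write_factors_yaml <- function(factors, path) {
  out <- lapply(unname(factors), function(f) {
    if (f$kind == "categorical") list(name = f$name, levels = as.list(f$levels))
    else Filter(Negate(is.null),
                list(name = f$name, low = f$low, mid = f$mid, high = f$high,
                     unit = f$unit))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname read_factors_yaml
#' @export
read_limits_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  spec_limits(lapply(doc, function(w) as.numeric(unlist(w))))
}

#' @rdname read_factors_yaml
#' @export
write_limits_yaml <- function(limits, path) {
  yaml::write_yaml(lapply(unclass(limits), as.list), path)
  invisible(path)
}
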