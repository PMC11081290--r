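#' Coded-factor response-surface model
#'
#' Represents a fitted second-order response model on the coded factor
#' scale: intercept plus named terms (main effects, pairwise interactions,
#' quadratics), with the two-level categorical factor entering as -1/+1 for
#' its first/second level. A term involving the categorical factor is the
#' usual "match" term: its coefficient is the additive value for the second
#' level, and the negated coefficient for the first, so the two level
#' values sum to zero.
#'
#' @param response Response name.
#' @param intercept Intercept on the response scale.
#' @param coef Named numeric vector of term coefficients. Labels follow the
#'   [model_matrix()] convention: `drug_ratio`, `drug_ratio^2`,
#'   `mixing_time:liquid_paraffin`, `drug_ratio:method`.
#' @param factors The `factor_space` the terms refer to.
#' @param units Response units (printing only).
#' @param stats Optional named list of fit statistics (`r_squared`,
#'   `p_value`, `rmse`).
#' @return An object of class `response_model`.
#' @export
response_model <- function(response, intercept, coef, factors,
                           units = NULL, stats = list()) {
  stopifnot(inherits(factors, "factor_space"),
            is.numeric(intercept), length(intercept) == 1L)
  coef <- unlist(coef)
  if (length(coef) && is.null(names(coef)))
    stop("coef must be a named vector", call. = FALSE)
  for (lab in names(coef)) {
    for (part in term_parts(lab)$factors) {
      if (!part %in% names(factors))
        stop("term '", lab, "' references unknown factor '", part, "'",
             call. = FALSE)
    }
  }
  structure(list(response = response, units = units, intercept = intercept,
                 coef = coef, factors = factors, stats = stats),
            class = "response_model")
}

# split a term label into factor names and powers
term_parts <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1L]]
  pow <- ifelse(grepl("\\^2$", parts), 2L, 1L)
  list(factors = sub("\\^2$", "", parts), powers = pow)
}

#' @export
print.response_model <- function(x, digits = 4, ...) {
  cat(sprintf("Response model: %s%s\n", x$response,
              if (is.null(x$units)) "" else paste0(" (", x$units, ")")))
  cat(sprintf("  intercept %s + %d terms\n",
              format(x$intercept, digits = digits), length(x$coef)))
  if (length(x$coef)) {
    for (i in seq_along(x$coef))
      cat(sprintf("  %+.*g * %s\n", digits, x$coef[i], names(x$coef)[i]))
  }
  if (!is.null(x$stats$r_squared))
    cat(sprintf("  R-squared %.4f", x$stats$r_squared))
  if (!is.null(x$stats$p_value))
    cat(sprintf(", p = %.4g", x$stats$p_value))
  cat("\n")
  invisible(x)
}

#' @export
coef.response_model <- function(object, ...) {
  c("(Intercept)" = unname(object$intercept), object$coef)
}

# settings (natural units, data.frame or named list) -> coded data.frame
# with one column per continuous factor plus the categorical as -1/+1
coded_settings <- function(factors, settings) {
  if (!is.data.frame(settings)) settings <- as.data.frame(settings)
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  out <- list()
  for (nm in names(cont)) {
    if (is.null(settings[[nm]]))
      stop("settings lack factor '", nm, "'", call. = FALSE)
    out[[nm]] <- code_value(cont[[nm]], settings[[nm]])
  }
  if (!is.null(cat_f)) {
    lev <- settings[[cat_f$name]]
    if (is.null(lev))
      stop("settings lack factor '", cat_f$name, "'", call. = FALSE)
    lev <- as.character(lev)
    if (!all(lev %in% cat_f$levels))
      stop("unknown level(s) for '", cat_f$name, "': ",
           paste(setdiff(lev, cat_f$levels), collapse = ", "), call. = FALSE)
    out[[cat_f$name]] <- ifelse(lev == cat_f$levels[2L], 1, -1)
  }
  as.data.frame(out)
}

term_column <- function(label, coded) {
  tp <- term_parts(label)
  val <- rep(1, nrow(coded))
  for (i in seq_along(tp$factors))
    val <- val * coded[[tp$factors[i]]]^tp$powers[i]
  val
}

#' Evaluate a response model at natural-unit settings
#'
#' Codes each continuous factor, maps the categorical level to -1/+1, and
#' returns intercept + sum of coefficient x term value. Vectorised over the
#' rows of `newdata`.
#'
#' @param object A `response_model`.
#' @param newdata Data frame (or named list) with one column per model
#'   factor in natural units; categorical levels as text.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @examples
#' m <- ointment_models()$yield_stress
#' predict(m, list(drug_ratio = 35, mixing_time = 25, mixing_speed = 1050,
#'                 petroleum = 77.5, liquid_paraffin = 7.5, method = "B"))
#' @export
predict.response_model <- function(object, newdata, ...) {
  coded <- coded_settings(object$factors, newdata)
  y <- rep(object$intercept, nrow(coded))
  for (lab in names(object$coef))
    y <- y + object$coef[[lab]] * term_column(lab, coded)
  y
}

#' Categorical match values of a model
#'
#' Returns, per term involving the categorical factor, the additive value
#' for each level (second level +coef, first level -coef; they sum to zero).
#'
#' @param object A `response_model`.
#' @return Named list of two-element numeric vectors, or an empty list.
#' @export
match_values <- function(object) {
  stopifnot(inherits(object, "response_model"))
  cat_f <- categorical_factor(object$factors)
  if (is.null(cat_f)) return(list())
  out <- list()
  for (lab in names(object$coef)) {
    if (cat_f$name %in% term_parts(lab)$factors) {
      v <- c(-object$coef[[lab]], object$coef[[lab]])
      names(v) <- cat_f$levels
      out[[lab]] <- v
    }
  }
  out
}

#' Read and write response-model collections as JSON
#'
#' The JSON layout stores, per model: response name, units, intercept, a
#' term list (label + coefficient) and fit statistics. The shipped fixture
#' `ointment_models.json` uses this layout.
#'
#' @param path File path.
#' @param factors `factor_space` the term labels refer to.
#' @param models Named list of `response_model` objects.
#' @return `read_models_json()` returns a named list of `response_model`s.
#' @export
read_models_json <- function(path, factors = ointment_factors()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (m in doc$models) {
    coefs <- vapply(m$terms, `[[`, numeric(1), "coef")
    names(coefs) <- vapply(m$terms, `[[`, character(1), "term")
    out[[m$response]] <- response_model(
      response = m$response, intercept = m$intercept, coef = coefs,
      factors = factors, units = m$units,
      stats = list(r_squared = m$r_squared, p_value = m$p_value,
                   rmse = m$rmse))
  }
  out
}

#' @rdname read_models_json
#' @export
write_models_json <- function(models, path) {
  doc <- list(version = 1L, models = lapply(unname(models), function(m) {
    terms <- lapply(seq_along(m$coef), function(i)
      list(term = names(m$coef)[i], coef = m$coef[[i]]))
    c(list(response = m$response, units = m$units, intercept = m$intercept,
           terms = terms), m$stats)
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' The four printed case-study response models
#'
#' The stepwise-regression equations of the ointment study (high/low shear
#' viscosity, storage modulus, yield stress) as `response_model` objects,
#' loaded from the shipped JSON fixture.
#'
#' @return Named list of four `response_model`s over [ointment_factors()].
#' @export
ointment_models <- function() {
  path <- system.file("extdata", "ointment_models.json", package = "rheodsd",
                      mustWork = TRUE)
  read_models_json(path, ointment_factors())
}

#' The printed optimal settings of the case study
#'
#' Factor settings at the surrogate-optimised operating point reported in
#' the study, used by the validation and reporting helpers.
#'
#' @param rounded Return the practically rounded values instead of the full
#'   precision ones.
#' @return One-row data frame of natural-unit settings with `method = "B"`.
#' @export
optimal_settings <- function(rounded = FALSE) {
  if (rounded) {
    data.frame(drug_ratio = 24.5, mixing_time = 8, mixing_speed = 1175,
               petroleum = 79, liquid_paraffin = 6.7, method = "B")
  } else {
    data.frame(drug_ratio = 24.498709, mixing_time = 7.769771,
               mixing_speed = 1175.417, petroleum = 78.855153,
               liquid_paraffin = 6.7251419, method = "B")
  }
}
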