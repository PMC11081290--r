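#' Define a process factor
#'
#' A continuous factor is described by its low, mid and high natural-unit
#' levels; a categorical factor by exactly two level labels. Continuous
#' factors are coded as `(x - mid) / half_range` so that low/mid/high map to
#' -1/0/+1.
#'
#' @param name Factor name (unique within a factor space).
#' @param low,mid,high Natural-unit levels of a continuous factor. `mid`
#'   defaults to the arithmetic centre `(low + high) / 2`.
#' @param levels Character vector of length 2 for a categorical factor.
#' @param unit Optional unit string, carried for printing only.
#' @return An object of class `qbd_factor`.
#' @examples
#' qbd_factor("drug_ratio", low = 20, high = 50, unit = "%")
#' qbd_factor("method", levels = c("A", "B"))
#' @export
qbd_factor <- function(name, low = NULL, high = NULL, mid = NULL,
                       levels = NULL, unit = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(levels)) {
    if (length(levels) != 2L || anyDuplicated(levels))
      stop("a categorical factor needs exactly 2 distinct levels", call. = FALSE)
    out <- list(name = name, kind = "categorical",
                levels = as.character(levels), unit = unit)
  } else {
    if (is.null(low) || is.null(high))
      stop("continuous factor '", name, "' needs low and high", call. = FALSE)
    if (is.null(mid)) mid <- (low + high) / 2
    if (!(low < mid && mid < high))
      stop("factor '", name, "' must satisfy low < mid < high", call. = FALSE)
    out <- list(name = name, kind = "continuous",
                low = low, mid = mid, high = high, unit = unit)
  }
  class(out) <- "qbd_factor"
  out
}

#' @export
print.qbd_factor <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("Factor %s [%s]: %g / %g / %g (low/mid/high)\n",
                x$name, x$unit %||% "-", x$low, x$mid, x$high))
  } else {
    cat(sprintf("Factor %s: categorical {%s}\n", x$name,
                paste(x$levels, collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect factors into a factor space
#'
#' @param ... `qbd_factor` objects (or a single list of them).
#' @return An object of class `factor_space`: a named list of factors with
#'   helpers for the continuous/categorical split.
#' @export
factor_space <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "qbd_factor")) fs <- fs[[1L]]
  if (!all(vapply(fs, inherits, logical(1), "qbd_factor")))
    stop("all arguments must be qbd_factor objects", call. = FALSE)
  nm <- vapply(fs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate factor names", call. = FALSE)
  names(fs) <- nm
  n_cat <- sum(vapply(fs, function(f) f$kind == "categorical", logical(1)))
  if (n_cat > 1L)
    stop("at most one categorical factor is supported", call. = FALSE)
  structure(fs, class = "factor_space")
}

#' @export
print.factor_space <- function(x, ...) {
  cat("Factor space (", length(x), " factors)\n", sep = "")
  for (f in x) print(f)
  invisible(x)
}

continuous_factors <- function(space) {
  space[vapply(space, function(f) f$kind == "continuous", logical(1))]
}

categorical_factor <- function(space) {
  cat <- space[vapply(space, function(f) f$kind == "categorical", logical(1))]
  if (length(cat)) cat[[1L]] else NULL
}

#' Code and decode natural-unit factor values
#'
#' `code_value()` maps a natural-unit value of a continuous factor to the
#' coded scale `(x - mid) / half_range`; `decode_value()` is its inverse.
#'
#' @param factor A continuous `qbd_factor`.
#' @param x Natural-unit value(s).
#' @param z Coded value(s).
#' @return Numeric vector.
#' @examples
#' f <- qbd_factor("mixing_speed", low = 300, high = 1800, unit = "rpm")
#' code_value(f, 1050)   # 0
#' decode_value(f, -1)   # 300
#' @export
code_value <- function(factor, x) {
  stopifnot(inherits(factor, "qbd_factor"))
  if (factor$kind != "continuous")
    stop("cannot code a categorical factor", call. = FALSE)
  (x - factor$mid) / ((factor$high - factor$low) / 2)
}

#' @rdname code_value
#' @export
decode_value <- function(factor, z) {
  stopifnot(inherits(factor, "qbd_factor"))
  if (factor$kind != "continuous")
    stop("cannot decode a categorical factor", call. = FALSE)
  factor$mid + z * (factor$high - factor$low) / 2
}

#' The ointment case-study factor space
#'
#' The five continuous preparation factors (drug ratio, mixing time, mixing
#' speed, petroleum dosage, liquid-paraffin dosage) at their study levels,
#' plus the two-level drug-addition method factor (A: drug added to the
#' molten base; B: drug added after the base has set).
#'
#' @return A `factor_space` with six factors.
#' @export
ointment_factors <- function() {
  factor_space(
    qbd_factor("drug_ratio",      low = 20,  high = 50,   unit = "%"),
    qbd_factor("mixing_time",     low = 5,   high = 45,   unit = "min"),
    qbd_factor("mixing_speed",    low = 300, high = 1800, unit = "rpm"),
    qbd_factor("petroleum",       low = 70,  high = 85,   unit = "g"),
    qbd_factor("liquid_paraffin", low = 5,   high = 10,   unit = "g"),
    qbd_factor("method", levels = c("A", "B"))
  )
}

#' Specification windows for the four rheological responses
#'
#' Acceptance windows defining a "defect": a simulated batch is defective
#' when any response falls outside its window. Defaults are the case-study
#' settings: yield stress 40--55 Pa, high-shear viscosity 0--7 Pa.s,
#' low-shear viscosity 11000--18000 Pa.s, storage modulus 200--1000 Pa.
#'
#' @param windows Named list of `c(lower, upper)` numeric pairs.
#' @return An object of class `spec_limits`.
#' @export
spec_limits <- function(windows = list(
                          yield_stress    = c(40, 55),
                          high_shear_visc = c(0, 7),
                          low_shear_visc  = c(11000, 18000),
                          storage_modulus = c(200, 1000))) {
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2L || !is.numeric(w) || !(w[1] < w[2]))
      stop("window for '", nm, "' must be c(lower, upper) with lower < upper",
           call. = FALSE)
  }
  structure(windows, class = "spec_limits")
}

#' @export
print.spec_limits <- function(x, ...) {
  cat("Specification windows:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}
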