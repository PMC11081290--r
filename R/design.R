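#' Build a definitive screening design
#'
#' Constructs a three-level definitive screening design (DSD) for the
#' continuous factors in `factors`, optionally carrying one two-level
#' categorical factor. For an odd number `m` of continuous factors the
#' `(m+1) x (m+1)` conference matrix is used with its last column dropped
#' (that column slot carries the categorical factor when present); for even
#' `m` the `m x m` conference matrix is used directly. The half-fraction is
#' folded over (every run gains a mirror run with all continuous coded
#' values negated and the categorical level flipped) and centre runs are
#' appended last: two for odd `m`, one for even `m` (two when a categorical
#' factor is present, one per level).
#'
#' Run counts: `2m + 4` for odd `m`; `2m + 1` for even `m` (`2m + 2` with a
#' categorical factor). Mirror pairs are interleaved (each run is followed
#' by its mirror); an optional seeded shuffle permutes the run order.
#'
#' @param factors A `factor_space` with 3--10 continuous factors and at most
#'   one two-level categorical factor.
#' @param seed Optional integer; when given, run order is shuffled
#'   reproducibly (structure metadata is permuted consistently).
#' @return An object of class `dsd_design` with elements `runs` (natural-unit
#'   data frame with `run_id`), `coded` (runs x continuous-factors matrix),
#'   `cat_level` (character or `NULL`), `mirror_of` (index of each run's
#'   mirror, `NA` for centre runs) and `is_center`.
#' @examples
#' d <- dsd_design(ointment_factors())
#' nrow(d$runs) # 14
#' @export
dsd_design <- function(factors, seed = NULL) {
  stopifnot(inherits(factors, "factor_space"))
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  m <- length(cont)
  if (m < 3L || m > 10L)
    stop("between 3 and 10 continuous factors are supported", call. = FALSE)

  if (m %% 2L == 1L) {
    C <- conference_matrix(m + 1L)
    half <- unclass(C)[, seq_len(m), drop = FALSE]
    spare <- unclass(C)[, m + 1L] # carries the categorical factor
  } else {
    C <- conference_matrix(m)
    half <- unclass(C)
    spare <- rep(1L, m) # even m: no spare column, alternate by pair
  }
  k <- nrow(half)

  # interleave each half-fraction row with its fold-over mirror
  coded <- matrix(0L, 2L * k, m)
  coded[seq(1L, 2L * k, by = 2L), ] <- half
  coded[seq(2L, 2L * k, by = 2L), ] <- -half
  mirror_of <- as.integer(seq_len(2L * k) + c(1L, -1L))

  n_center <- if (m %% 2L == 1L) 2L else if (is.null(cat_f)) 1L else 2L
  coded <- rbind(coded, matrix(0L, n_center, m))
  mirror_of <- c(mirror_of, rep(NA_integer_, n_center))
  is_center <- c(rep(FALSE, 2L * k), rep(TRUE, n_center))
  n <- nrow(coded)

  cat_level <- NULL
  if (!is.null(cat_f)) {
    # dropped-column convention: sign +1 -> second level, -1 -> first level,
    # the zero-entry row -> first level; fold-over flips the level
    sgn <- ifelse(spare == 0L, -1L, spare)
    lev <- integer(n)
    lev[seq(1L, 2L * k, by = 2L)] <- sgn
    lev[seq(2L, 2L * k, by = 2L)] <- -sgn
    lev[is_center] <- c(-1L, 1L)[seq_len(n_center)]
    cat_level <- cat_f$levels[(lev + 3L) / 2L]
  }

  if (!is.null(seed)) {
    ord <- local({
      old <- get_rng_state()
      on.exit(restore_rng_state(old))
      set.seed(as.integer(seed))
      sample.int(n)
    })
    coded <- coded[ord, , drop = FALSE]
    inv <- order(ord)
    mirror_of <- inv[mirror_of[ord]]
    is_center <- is_center[ord]
    if (!is.null(cat_level)) cat_level <- cat_level[ord]
  }

  colnames(coded) <- names(cont)
  natural <- as.data.frame(lapply(seq_len(m), function(j)
    decode_value(cont[[j]], coded[, j])))
  names(natural) <- names(cont)
  runs <- cbind(data.frame(run_id = paste0("run", seq_len(n))), natural)
  if (!is.null(cat_level)) runs[[cat_f$name]] <- cat_level

  structure(list(factors = factors, runs = runs, coded = coded,
                 cat_level = cat_level, mirror_of = mirror_of,
                 is_center = is_center),
            class = "dsd_design")
}

#' @export
print.dsd_design <- function(x, ...) {
  m <- ncol(x$coded)
  cat(sprintf("Definitive screening design: %d runs, %d continuous factors%s\n",
              nrow(x$runs), m,
              if (is.null(x$cat_level)) "" else " + 1 categorical"))
  cat(sprintf("  %d mirror pairs, %d centre run(s)\n",
              sum(!x$is_center) / 2L, sum(x$is_center)))
  print(x$runs, ...)
  invisible(x)
}

#' Reconstruct a design object from a natural-unit run table
#'
#' Codes each continuous factor, flags centre runs (all continuous coded
#' values zero) and matches mirror pairs (all continuous coded values
#' negated, categorical level flipped when present). Used to ingest
#' externally produced design tables such as the printed case-study design.
#'
#' @param runs Data frame with a `run_id` column, one natural-unit column
#'   per continuous factor and one column per categorical factor.
#' @param factors The `factor_space` the columns refer to.
#' @return A `dsd_design`.
#' @export
as_dsd_design <- function(runs, factors) {
  stopifnot(is.data.frame(runs), inherits(factors, "factor_space"))
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  missing <- setdiff(names(factors), names(runs))
  if (length(missing))
    stop("design table lacks factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"run_id" %in% names(runs))
    runs <- cbind(data.frame(run_id = paste0("run", seq_len(nrow(runs)))), runs)
  coded <- vapply(names(cont), function(nm) code_value(cont[[nm]], runs[[nm]]),
                  numeric(nrow(runs)))
  coded <- matrix(coded, nrow = nrow(runs),
                  dimnames = list(NULL, names(cont)))
  is_center <- apply(abs(coded) < 1e-9, 1L, all)
  cat_level <- if (is.null(cat_f)) NULL else as.character(runs[[cat_f$name]])
  mirror_of <- rep(NA_integer_, nrow(runs))
  for (i in which(!is_center)) {
    for (j in which(!is_center)) {
      if (i == j) next
      if (all(abs(coded[i, ] + coded[j, ]) < 1e-9) &&
          (is.null(cat_level) || cat_level[i] != cat_level[j])) {
        mirror_of[i] <- j
        break
      }
    }
  }
  structure(list(factors = factors, runs = runs, coded = coded,
                 cat_level = cat_level, mirror_of = mirror_of,
                 is_center = is_center),
            class = "dsd_design")
}

#' Validate the structural invariants of a DSD
#'
#' Checks that coded values lie in \{-1, 0, +1\}, centre runs have all
#' continuous coded values zero, and every non-centre run has a mirror run
#' with all continuous coded values negated (categorical level flipped when
#' present).
#'
#' @param design A `dsd_design`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "dsd_design"))
  coded <- design$coded
  if (!all(abs(abs(coded) - 1) < 1e-9 | abs(coded) < 1e-9))
    stop("coded values outside {-1, 0, +1}", call. = FALSE)
  if (any(abs(coded[design$is_center, , drop = FALSE]) > 1e-9))
    stop("centre run with non-zero continuous coded value", call. = FALSE)
  nc <- which(!design$is_center)
  mir <- design$mirror_of[nc]
  if (anyNA(mir))
    stop("non-centre run without a mirror run", call. = FALSE)
  for (i in nc) {
    j <- design$mirror_of[i]
    if (design$mirror_of[j] != i)
      stop("mirror mapping is not an involution", call. = FALSE)
    if (!all(abs(coded[i, ] + coded[j, ]) < 1e-9))
      stop("mirror pair with non-negated coded values (runs ", i, ", ", j, ")",
           call. = FALSE)
    if (!is.null(design$cat_level) &&
        design$cat_level[i] == design$cat_level[j])
      stop("mirror pair without flipped categorical level", call. = FALSE)
  }
  invisible(TRUE)
}

#' Expand a design into a second-order coded model matrix
#'
#' Builds the coded model matrix whose columns are the intercept, all main
#' effects (continuous factors on the coded scale, the categorical factor
#' as -1/+1 for its first/second level), all pairwise interactions and the
#' quadratics of the continuous factors. Quadratic columns are element-wise
#' squares of the main columns.
#'
#' @param design A `dsd_design`.
#' @param term_set `"full_quadratic"` (default) or a character vector of
#'   column labels selecting a subset (intercept always kept). Labels follow
#'   the naming `drug_ratio`, `drug_ratio:method`, `drug_ratio^2`.
#' @return Numeric matrix with named columns and attribute `"terms"` (a data
#'   frame describing each column's factors and orders).
#' @export
model_matrix <- function(design, term_set = "full_quadratic") {
  stopifnot(inherits(design, "dsd_design"))
  if (nrow(design$coded) == 0L) stop("empty design", call. = FALSE)
  cont <- continuous_factors(design$factors)
  cat_f <- categorical_factor(design$factors)
  cols <- list(`(Intercept)` = rep(1, nrow(design$coded)))
  for (nm in names(cont)) cols[[nm]] <- design$coded[, nm]
  if (!is.null(cat_f))
    cols[[cat_f$name]] <- ifelse(design$cat_level == cat_f$levels[2L], 1, -1)
  main_names <- setdiff(names(cols), "(Intercept)")
  for (a in seq_along(main_names)) {
    for (b in seq_along(main_names)) {
      if (b <= a) next
      lab <- paste0(main_names[a], ":", main_names[b])
      cols[[lab]] <- cols[[main_names[a]]] * cols[[main_names[b]]]
    }
  }
  for (nm in names(cont)) cols[[paste0(nm, "^2")]] <- cols[[nm]]^2
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!identical(term_set, "full_quadratic")) {
    unknown <- setdiff(term_set, colnames(X))
    if (length(unknown))
      stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    X <- X[, unique(c("(Intercept)", term_set)), drop = FALSE]
  }
  X
}

#' Read and write design tables
#'
#' Design tables are plain CSV with a header: `run_id`, one natural-unit
#' column per factor (categorical levels as text). `write_design_csv()` can
#' also emit the parallel coded table.
#'
#' @param design A `dsd_design`.
#' @param path File path.
#' @param coded Write coded instead of natural values (continuous factors).
#' @param factors `factor_space` used to re-interpret the columns.
#' @return `read_design_csv()` returns a `dsd_design`.
#' @export
write_design_csv <- function(design, path, coded = FALSE) {
  stopifnot(inherits(design, "dsd_design"))
  out <- design$runs
  if (coded) {
    for (nm in colnames(design$coded)) out[[nm]] <- design$coded[, nm]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cont <- continuous_factors(factors)
  for (nm in names(cont)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   nm, bad, path), call. = FALSE)
    }
  }
  as_dsd_design(df, factors)
}

#' The printed case-study design table
#'
#' The 14-run definitive screening design of the ointment study (five
#' continuous factors plus the drug-addition method), shipped as a fixture
#' and re-ingested through [as_dsd_design()].
#'
#' @return A `dsd_design` with the printed run order and IDs.
#' @export
ointment_design <- function() {
  path <- system.file("extdata", "ointment_design.csv", package = "rheodsd",
                      mustWork = TRUE)
  read_design_csv(path, ointment_factors())
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# run a block with a local, seeded RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}
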