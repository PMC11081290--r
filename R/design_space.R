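#' Gini impurity
#'
#' `1 - sum(p_i^2)` for a vector of class proportions.
#'
#' @param p Numeric vector of class proportions summing to 1.
#' @return Impurity in `[0, 1 - 1/m]`.
#' @examples
#' gini(c(0.5, 0.5)) # 0.5
#' @export
gini <- function(p) {
  if (any(p < 0)) stop("negative class proportions", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  1 - sum(p^2)
}

#' Prior-weighted node posterior probabilities
#'
#' Blends the parent node's prior and posterior into this node's prior,
#' `Prior_i = lambda * p_i + (1 - lambda) * P_i`, then combines it with the
#' node's class counts into posterior probabilities
#' `Prob_i = (n_i + Prior_i) / sum(n_i + Prior_i)`.
#'
#' @param n Non-negative class counts at the node.
#' @param parent_prior,parent_posterior Parent's prior/posterior vectors
#'   (each summing to 1).
#' @param lambda Blending weight in `[0, 1]`; `lambda = 1` keeps the parent
#'   prior unchanged.
#' @return List with `prior` and `prob` vectors.
#' @examples
#' node_posterior(c(8, 2), c(0.5, 0.5), c(0.5, 0.5), 0.5)$prob # 8.5/11, 2.5/11
#' @export
node_posterior <- function(n, parent_prior, parent_posterior, lambda = 0.5) {
  stopifnot(all(n >= 0), lambda >= 0, lambda <= 1)
  for (v in list(parent_prior, parent_posterior)) {
    if (abs(sum(v) - 1) > 1e-8)
      stop("priors must sum to 1", call. = FALSE)
  }
  prior <- lambda * parent_prior + (1 - lambda) * parent_posterior
  prob <- (n + prior) / sum(n + prior)
  list(prior = prior, prob = prob)
}

# best axis-aligned split of (x, y01) by Gini decrease; deterministic
# tie-break: lowest feature index, then lowest threshold
best_split <- function(x, y01, min_leaf) {
  n <- length(y01)
  parent_g <- gini(c(mean(y01), 1 - mean(y01)))
  best <- NULL
  for (j in seq_along(x)) {
    v <- x[[j]]
    ord <- order(v)
    vs <- v[ord]
    ys <- y01[ord]
    cum1 <- cumsum(ys)
    tot1 <- cum1[n]
    distinct <- which(diff(vs) > 0) # split after position i
    for (i in distinct) {
      nl <- i; nr <- n - i
      if (nl < min_leaf || nr < min_leaf) next
      p1l <- cum1[i] / nl
      p1r <- (tot1 - cum1[i]) / nr
      child_g <- (nl * (2 * p1l * (1 - p1l)) + nr * (2 * p1r * (1 - p1r))) / n
      dec <- parent_g - child_g
      if (dec <= 0) next
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature = names(x)[j], j = j,
                     threshold = (vs[i] + vs[i + 1L]) / 2,
                     decrease = dec)
      }
    }
  }
  best
}

#' Grow a prior-weighted classification tree
#'
#' Greedy binary CART on continuous features for a pass/fail label,
#' maximising the Gini decrease weighted by child sizes. Growth is
#' best-first: among all current leaves the split with the largest
#' size-weighted Gini decrease is applied next, until `max_splits` splits
#' have been made or no admissible split remains (`min_leaf` observations
#' per child). Node class probabilities are the prior-weighted posteriors
#' of [node_posterior()], with the root prior equal to the observed class
#' proportions. Deterministic given the input order; ties break towards
#' the lowest feature index, then the lowest threshold.
#'
#' @param data Data frame of numeric features (a two-level categorical
#'   factor should be supplied as a 0/1 column).
#' @param pass Logical (or 0/1) vector: `TRUE` for an in-specification
#'   point.
#' @param max_splits Total number of splits, default 15.
#' @param min_leaf Minimum observations per leaf; default 5 percent of the
#'   points.
#' @param lambda Prior blending weight of [node_posterior()], default 0.5.
#' @return An object of class `qbd_tree` (nested node list; classes are
#'   ordered `c("fail", "pass")`).
#' @export
grow_tree <- function(data, pass, max_splits = 15L,
                      min_leaf = max(1L, ceiling(0.05 * nrow(data))),
                      lambda = 0.5) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L)
  y01 <- as.integer(as.logical(pass)) # 1 = pass
  stopifnot(length(y01) == nrow(data), !anyNA(y01))
  counts <- function(idx) c(fail = sum(y01[idx] == 0L), pass = sum(y01[idx] == 1L))
  root_prop <- counts(seq_len(nrow(data))) / nrow(data)

  make_node <- function(idx, parent_prior, parent_posterior, constraints) {
    np <- node_posterior(counts(idx), parent_prior, parent_posterior, lambda)
    list(idx = idx, n = counts(idx), prior = np$prior, posterior = np$prob,
         constraints = constraints, split = NULL,
         children = NULL)
  }
  root <- make_node(seq_len(nrow(data)), root_prop, root_prop, list())
  leaves <- list(root)
  n_splits <- 0L
  both_classes <- function(nd) all(nd$n > 0L)
  while (n_splits < max_splits) {
    # best candidate split across all leaves, weighted by leaf size
    cand <- NULL
    for (li in seq_along(leaves)) {
      nd <- leaves[[li]]
      if (!both_classes(nd) || length(nd$idx) < 2L * min_leaf) next
      sp <- best_split(data[nd$idx, , drop = FALSE], y01[nd$idx], min_leaf)
      if (is.null(sp)) next
      w_dec <- sp$decrease * length(nd$idx)
      if (is.null(cand) || w_dec > cand$w_dec + 1e-12)
        cand <- list(li = li, sp = sp, w_dec = w_dec)
    }
    if (is.null(cand)) break
    nd <- leaves[[cand$li]]
    sp <- cand$sp
    go_left <- data[[sp$feature]][nd$idx] <= sp$threshold
    cl <- nd$constraints
    cl_left <- c(cl, list(list(feature = sp$feature, op = "<=",
                               threshold = sp$threshold)))
    cl_right <- c(cl, list(list(feature = sp$feature, op = ">",
                                threshold = sp$threshold)))
    left <- make_node(nd$idx[go_left], nd$prior, nd$posterior, cl_left)
    right <- make_node(nd$idx[!go_left], nd$prior, nd$posterior, cl_right)
    leaves[[cand$li]] <- NULL
    leaves <- c(leaves, list(left, right))
    n_splits <- n_splits + 1L
  }
  structure(list(leaves = lapply(leaves, function(nd)
                   nd[c("n", "prior", "posterior", "constraints")]),
                 n_splits = n_splits, lambda = lambda, min_leaf = min_leaf,
                 features = names(data), root_prior = root_prop,
                 n = nrow(data)),
            class = "qbd_tree")
}

#' @export
print.qbd_tree <- function(x, ...) {
  cat(sprintf("Classification tree: %d splits, %d leaves (lambda = %g, min_leaf = %d, n = %d)\n",
              x$n_splits, length(x$leaves), x$lambda, x$min_leaf, x$n))
  for (i in seq_along(x$leaves)) {
    lf <- x$leaves[[i]]
    rule <- if (!length(lf$constraints)) "<root>" else
      paste(vapply(lf$constraints, function(cn)
        sprintf("%s %s %.4g", cn$feature, cn$op, cn$threshold),
        character(1)), collapse = " & ")
    cat(sprintf("  leaf %d: n = %d/%d (fail/pass), P(pass) = %.3f  [%s]\n",
                i, lf$n["fail"], lf$n["pass"], lf$posterior["pass"], rule))
  }
  invisible(x)
}

leaf_of <- function(tree, row) {
  for (i in seq_along(tree$leaves)) {
    lf <- tree$leaves[[i]]
    ok <- TRUE
    for (cn in lf$constraints) {
      v <- row[[cn$feature]]
      if (cn$op == "<=" && !(v <= cn$threshold)) { ok <- FALSE; break }
      if (cn$op == ">" && !(v > cn$threshold)) { ok <- FALSE; break }
    }
    if (ok) return(i)
  }
  stop("no leaf matches the point", call. = FALSE) # cannot happen: leaves partition
}

#' Pass probability predicted by the tree
#'
#' @param object A `qbd_tree`.
#' @param newdata Data frame with the tree's feature columns.
#' @param ... Unused.
#' @return Numeric vector of leaf pass posteriors.
#' @export
predict.qbd_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    object$leaves[[leaf_of(object, newdata[i, , drop = FALSE])]]$posterior[["pass"]],
    numeric(1))
}

#' Axis-aligned design-space box from the best tree leaf
#'
#' Intersects the split constraints of the leaf with the highest pass
#' posterior (at or above `min_pass_prob`) and clips the resulting
#' intervals to the factor ranges, reporting each factor as
#' centre +/- half-width.
#'
#' @param tree A `qbd_tree` grown on natural-unit factor columns.
#' @param factors The `factor_space` giving each factor's full range.
#' @param min_pass_prob Minimum acceptable leaf pass posterior, default 0.
#' @return An object of class `factor_box`: named list `intervals`
#'   (`c(lower, upper)` per continuous factor), `center`, `half_width`,
#'   `pass_prob`, and `level` (categorical level when the tree constrains
#'   the 0/1 categorical feature, else `NULL`).
#' @export
extract_box <- function(tree, factors, min_pass_prob = 0) {
  stopifnot(inherits(tree, "qbd_tree"), inherits(factors, "factor_space"))
  pp <- vapply(tree$leaves, function(lf) lf$posterior[["pass"]], numeric(1))
  ok <- which(pp >= min_pass_prob)
  if (!length(ok))
    stop("no leaf reaches pass probability ", min_pass_prob, call. = FALSE)
  lf <- tree$leaves[[ok[which.max(pp[ok])]]]
  cont <- continuous_factors(factors)
  cat_f <- categorical_factor(factors)
  intervals <- lapply(cont, function(f) c(f$low, f$high))
  level <- NULL
  for (cn in lf$constraints) {
    if (!is.null(cat_f) && cn$feature == cat_f$name) {
      # 0/1 feature: <= t keeps level 1 (0), > t keeps level 2 (1)
      level <- if (cn$op == "<=") cat_f$levels[1L] else cat_f$levels[2L]
      next
    }
    iv <- intervals[[cn$feature]]
    if (is.null(iv)) next
    if (cn$op == "<=") iv[2] <- min(iv[2], cn$threshold)
    else iv[1] <- max(iv[1], cn$threshold)
    intervals[[cn$feature]] <- iv
  }
  center <- vapply(intervals, mean, numeric(1))
  half <- vapply(intervals, function(iv) diff(iv) / 2, numeric(1))
  structure(list(intervals = intervals, center = center, half_width = half,
                 pass_prob = lf$posterior[["pass"]], level = level,
                 factors = factors),
            class = "factor_box")
}

#' @export
print.factor_box <- function(x, ...) {
  cat(sprintf("Design-space box (leaf pass probability %.3f%s)\n",
              x$pass_prob,
              if (is.null(x$level)) "" else paste0(", level ", x$level)))
  for (nm in names(x$intervals))
    cat(sprintf("  %-16s %.4g +/- %.4g  [%.4g, %.4g]\n", nm,
                x$center[[nm]], x$half_width[[nm]],
                x$intervals[[nm]][1], x$intervals[[nm]][2]))
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann--Whitney AUC with ties averaged.
#'
#' @param scores Numeric scores (higher = more likely pass).
#' @param labels Logical (or 0/1): the true pass labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize trees and boxes
#'
#' Trees are written as JSON (leaf constraints, counts, priors,
#' posteriors); boxes as YAML (`factor: [center, half_width]`).
#'
#' @param tree A `qbd_tree`.
#' @param box A `factor_box`.
#' @param path File path.
#' @param factors `factor_space` for re-reading a box.
#' @return Read functions return the reconstructed object.
#' @export
write_tree_json <- function(tree, path) {
  out <- unclass(tree)
  # named vectors must travel as objects, not bare arrays
  out$leaves <- lapply(out$leaves, function(lf) {
    lf$n <- as.list(lf$n)
    lf$prior <- as.list(lf$prior)
    lf$posterior <- as.list(lf$posterior)
    lf
  })
  out$root_prior <- as.list(out$root_prior)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$leaves <- lapply(doc$leaves, function(lf) {
    lf$n <- unlist(lf$n)
    lf$prior <- unlist(lf$prior)
    lf$posterior <- unlist(lf$posterior)
    lf
  })
  doc$root_prior <- unlist(doc$root_prior)
  doc$features <- unlist(doc$features)
  structure(doc, class = "qbd_tree")
}

#' @rdname write_tree_json
#' @export
write_box_yaml <- function(box, path) {
  out <- list(pass_prob = box$pass_prob, level = box$level,
              factors = lapply(names(box$intervals), function(nm)
                list(name = nm, center = box$center[[nm]],
                     half_width = box$half_width[[nm]])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_box_yaml <- function(path, factors) {
  doc <- yaml::read_yaml(path)
  intervals <- list()
  center <- numeric(0); half <- numeric(0)
  for (f in doc$factors) {
    intervals[[f$name]] <- c(f$center - f$half_width, f$center + f$half_width)
    center[f$name] <- f$center
    half[f$name] <- f$half_width
  }
  structure(list(intervals = intervals, center = center, half_width = half,
                 pass_prob = doc$pass_prob, level = doc$level,
                 factors = factors),
            class = "factor_box")
}

#' Construct a design-space box directly
#'
#' @param intervals Named list of `c(lower, upper)` per continuous factor.
#' @param factors The `factor_space`.
#' @param level Optional categorical level.
#' @param pass_prob Optional pass probability to record.
#' @return A `factor_box`.
#' @export
factor_box <- function(intervals, factors, level = NULL, pass_prob = NA_real_) {
  cont <- continuous_factors(factors)
  for (nm in names(intervals)) {
    if (!nm %in% names(cont))
      stop("unknown continuous factor '", nm, "'", call. = FALSE)
    iv <- intervals[[nm]]
    stopifnot(length(iv) == 2L, iv[1] <= iv[2])
  }
  # fill unconstrained factors with their full range
  for (nm in setdiff(names(cont), names(intervals)))
    intervals[[nm]] <- c(cont[[nm]]$low, cont[[nm]]$high)
  intervals <- intervals[names(cont)]
  center <- vapply(intervals, mean, numeric(1))
  half <- vapply(intervals, function(iv) diff(iv) / 2, numeric(1))
  structure(list(intervals = intervals, center = center, half_width = half,
                 pass_prob = pass_prob, level = level, factors = factors),
            class = "factor_box")
}
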