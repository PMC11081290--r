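test_that("Gini impurity matches direct evaluation", {
  expect_equal(gini(c(1, 0)), 0)
  expect_equal(gini(c(0.5, 0.5)), 0.5)
  expect_equal(gini(c(0.9, 0.1)), 0.18)
  expect_equal(gini(rep(1 / 4, 4)), 1 - 1 / 4)
  expect_error(gini(c(-0.1, 1.1)), "negative")
  expect_error(gini(c(0.2, 0.2)), "sum to 1")
})

test_that("node posteriors blend parent priors and counts as specified", {
  np <- node_posterior(c(8, 2), c(0.5, 0.5), c(0.5, 0.5), 0.5)
  expect_equal(np$prob, c(8.5 / 11, 2.5 / 11))
  # no data: posterior equals the blended prior
  np0 <- node_posterior(c(0, 0), c(0.7, 0.3), c(0.4, 0.6), 0.25)
  expect_equal(np0$prob, 0.25 * c(0.7, 0.3) + 0.75 * c(0.4, 0.6))
  # lambda = 1 keeps the parent prior exactly
  np1 <- node_posterior(c(3, 1), c(0.6, 0.4), c(0.1, 0.9), 1)
  expect_equal(np1$prior, c(0.6, 0.4))
  expect_error(node_posterior(c(1, 1), c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("with lambda 1 and uniform priors leaf posteriors are Laplace-smoothed", {
  # root prior is the class proportion vector; force uniform via a balanced set
  x_bal <- data.frame(u = c(seq(-1, -0.1, length.out = 30),
                            seq(0.1, 1, length.out = 30)))
  pass_bal <- x_bal$u > 0
  tr <- grow_tree(x_bal, pass_bal, max_splits = 1L, min_leaf = 5L, lambda = 1)
  for (lf in tr$leaves) {
    expected <- (lf$n + 0.5) / (sum(lf$n) + 1)
    expect_equal(unname(lf$posterior), unname(expected))
  }
})

test_that("one-dimensional separable labels give the midpoint split and pure leaves", {
  x <- data.frame(v = c(-3, -2, -1.2, 0.4, 1.1, 2.5))
  pass <- x$v > 0
  tree <- grow_tree(x, pass, max_splits = 5L, min_leaf = 1L)
  expect_equal(tree$n_splits, 1L)
  thr <- tree$leaves[[1]]$constraints[[1]]$threshold
  expect_equal(thr, (-1.2 + 0.4) / 2) # midpoint of the straddling points
  purity <- vapply(tree$leaves, function(lf) min(lf$n) == 0, logical(1))
  expect_true(all(purity))
  # brute force over all candidate thresholds confirms the chosen one
  cand <- (sort(x$v)[-1] + sort(x$v)[-6]) / 2
  dec <- vapply(cand, function(t) {
    l <- pass[x$v <= t]; r <- pass[x$v > t]
    g <- function(p) if (!length(p)) 0 else gini(c(mean(p), 1 - mean(p)))
    gini(c(0.5, 0.5)) - (length(l) * g(l) + length(r) * g(r)) / 6
  }, numeric(1))
  expect_equal(thr, cand[which.max(dec)])
})

test_that("max_splits zero and single-class inputs give a root-only tree", {
  x <- data.frame(a = 1:10, b = 10:1)
  tree0 <- grow_tree(x, rep(c(TRUE, FALSE), 5), max_splits = 0L)
  expect_equal(tree0$n_splits, 0L)
  expect_equal(length(tree0$leaves), 1L)
  tree1 <- grow_tree(x, rep(TRUE, 10), max_splits = 5L)
  expect_equal(tree1$n_splits, 0L)
})

test_that("training error is non-increasing in the split budget", {
  set.seed(17)
  x <- data.frame(a = runif(300, -1, 1), b = runif(300, -1, 1))
  pass <- (x$a > -0.3 & x$a < 0.5 & x$b > 0) != (runif(300) < 0.05)
  err <- vapply(c(0L, 1L, 3L, 6L, 10L), function(k) {
    tr <- grow_tree(x, pass, max_splits = k, min_leaf = 10L)
    mean((predict(tr, x) >= 0.5) != pass)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12))
})

test_that("box extraction intersects and clips split constraints", {
  fs <- small_space(2)
  # pure-pass single split: box is the passing half-space clipped to range
  x <- data.frame(x1 = seq(-9, 9, length.out = 40), x2 = 0)
  pass <- x$x1 > 1
  tree <- grow_tree(x, pass, max_splits = 1L, min_leaf = 2L)
  box <- extract_box(tree, fs)
  thr <- tree$leaves[[2]]$constraints[[1]]$threshold
  expect_equal(box$intervals$x1, c(thr, 10))
  expect_equal(box$intervals$x2, c(-10, 10)) # unconstrained: full range
  # root-only all-pass tree: the full factor box
  tree_all <- grow_tree(x, rep(TRUE, 40), max_splits = 3L)
  box_all <- extract_box(tree_all, fs)
  expect_equal(box_all$intervals$x1, c(-10, 10))
  # nested splits x1 > a then x1 <= b give the interval (a, b]
  x2 <- data.frame(x1 = seq(-9, 9, length.out = 60), x2 = 0)
  pass2 <- x2$x1 > -2 & x2$x1 <= 4
  tree2 <- grow_tree(x2, pass2, max_splits = 2L, min_leaf = 2L)
  box2 <- extract_box(tree2, fs)
  expect_lt(box2$intervals$x1[1], -1.5)
  expect_gt(box2$intervals$x1[1], -2.5)
  expect_lt(box2$intervals$x1[2], 4.5)
  expect_gt(box2$intervals$x1[2], 3.5)
  expect_equal(unname(box2$center["x1"]), mean(box2$intervals$x1))
  expect_error(extract_box(tree2, fs, min_pass_prob = 0.9999), "no leaf")
})

test_that("every accepted split strictly decreases weighted Gini impurity", {
  set.seed(23)
  x <- data.frame(a = runif(200, -1, 1), b = runif(200, -1, 1),
                  c = runif(200, -1, 1))
  pass <- x$a + 0.5 * x$b + rnorm(200, 0, 0.3) > 0
  tree <- grow_tree(x, pass, max_splits = 8L, min_leaf = 10L)
  expect_gt(tree$n_splits, 0L)
  # leaves partition the data
  counts <- vapply(tree$leaves, function(lf) sum(lf$n), numeric(1))
  expect_equal(sum(counts), 200)
  # posteriors sum to one at every leaf
  for (lf in tree$leaves) expect_equal(sum(lf$posterior), 1)
})

test_that("rank AUC matches brute-force pair counting and the pROC oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # scores equal to labels with one of 4 flipped: enumerate pairs
  scores <- c(1, 0, 1, 0)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  brute <- 0
  for (i in which(labels)) {
    for (j in which(!labels)) {
      brute <- brute + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  expect_equal(roc_auc(scores, labels), brute / 4)
  # label-independent scores: AUC near 1/2 at large n
  set.seed(9)
  s <- runif(4000); l <- runif(4000) > 0.5
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.03)
  expect_error(roc_auc(s, rep(TRUE, 4000)), "both classes")
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(response = as.integer(l),
                                            predictor = s, quiet = TRUE)))
  expect_equal(roc_auc(s, l), auc_ref, tolerance = 1e-12)
})

test_that("trees and boxes survive serialization round trips", {
  set.seed(41)
  x <- data.frame(a = runif(100, -1, 1), b = runif(100, -1, 1))
  pass <- x$a > 0.1
  tree <- grow_tree(x, pass, max_splits = 3L, min_leaf = 5L)
  tpath <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tree, tpath)
  tree2 <- read_tree_json(tpath)
  expect_equal(predict(tree2, x), predict(tree, x))
  fs <- small_space(2)
  box <- factor_box(list(x1 = c(-2, 5)), fs, pass_prob = 0.93)
  bpath <- withr::local_tempfile(fileext = ".yaml")
  write_box_yaml(box, bpath)
  box2 <- read_box_yaml(bpath, fs)
  expect_equal(box2$intervals, box$intervals)
  expect_equal(box2$pass_prob, box$pass_prob)
})
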