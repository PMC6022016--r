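# Gain-ratio trees and AdaBoost: entropy/split-info arithmetic, split
# search against an exhaustive oracle, tree consistency, boosting weight
# dynamics, prediction arithmetic and model serialization.

test_that("entropy matches hand values and the direct formula", {
  expect_equal(entropy(c(4, 4)), 1)
  expect_equal(entropy(c(8, 0)), 0)
  p <- c(2, 3, 5) / 10
  expect_equal(entropy(c(2, 3, 5)), -sum(p * log2(p)), tolerance = 1e-12)
  expect_error(entropy(numeric(0)), "empty")
  expect_error(entropy(c(0, 0)), "empty")
})

test_that("split info is the entropy of the partition proportions", {
  expect_equal(split_info(c(50, 50)), 1)
  expect_equal(split_info(c(10, 90)), -(0.1 * log2(0.1) + 0.9 * log2(0.9)))
  expect_equal(split_info(c(1, 1, 1)), log2(3))
  expect_error(split_info(c(5, 0)), "positive")
})

test_that("the balanced perfect split has gain ratio exactly 1", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c("pos", "pos", "neg", "neg")
  s <- best_split(X, y)
  expect_equal(s$attribute, 1)
  expect_equal(s$threshold, 2.5)
  expect_identical(s$gain, 1)
  expect_identical(s$split_info, 1)
  expect_identical(s$gain_ratio, 1)
})

test_that("pure or constant nodes admit no split", {
  expect_null(best_split(matrix(1:6, ncol = 1), rep("a", 6)))
  expect_null(best_split(matrix(rep(2, 6), ncol = 1), rep(c("a", "b"), 3)))
})

test_that("best_split agrees with exhaustive enumeration on random tables", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(round(runif(n * p, 0, 10), 1), n, p)
    y <- sample(c("fall", "no_fall", "sitting")[seq_len(sample(2:3, 1))],
                n, replace = TRUE)
    if (length(unique(y)) < 2) next
    w <- runif(n)
    got <- best_split(X, y, w)
    want <- oracle_best_split(X, y, w)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$attribute, want$attribute)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain_ratio, want$gain_ratio, tolerance = 1e-9)
    }
  }
})

test_that("trees separate separable data and fit consistent data exactly", {
  X <- matrix(c(1:5, 11:15), ncol = 1)
  y <- rep(c("a", "b"), each = 5)
  tr <- grow_tree(X, y)
  expect_false(tr$node$leaf)
  expect_true(tr$node$left$leaf && tr$node$right$leaf)  # depth 1
  expect_equal(predict_tree(tr, X), y)

  set.seed(5)
  Xr <- matrix(runif(40 * 3), 40, 3)
  yr <- sample(c("fall", "no_fall", "sitting"), 40, TRUE)
  trr <- grow_tree(Xr, yr)
  expect_equal(predict_tree(trr, Xr), yr)  # consistency: no duplicate x
})

# XOR-like quadrant data with unequal cluster sizes: a perfectly balanced
# XOR gives zero gain to every axis split, so the clusters are skewed (3/2)
# to give the root split positive gain while still requiring depth 2.
xor_data <- function() {
  quad <- function(x1, x2, n, lab)
    cbind(matrix(rep(c(x1, x2), each = n), n), rep(lab, n))
  pts <- rbind(quad(0.25, 0.25, 3, "neg"), quad(0.25, 0.75, 2, "pos"),
               quad(0.75, 0.25, 3, "pos"), quad(0.75, 0.75, 2, "neg"))
  jitter <- seq(-0.05, 0.05, length.out = nrow(pts))
  X <- cbind(as.numeric(pts[, 1]) + jitter, as.numeric(pts[, 2]) - jitter)
  list(X = X, y = pts[, 3])
}

test_that("a depth-2 tree solves the XOR pattern", {
  d <- xor_data()
  tr <- grow_tree(d$X, d$y, max_depth = 2)
  expect_equal(predict_tree(tr, d$X), d$y)
})

test_that("max_depth = 1 yields a stump", {
  d <- xor_data()
  st <- grow_tree(d$X, d$y, max_depth = 1)
  expect_true(st$node$left$leaf && st$node$right$leaf)
})

test_that("boosting on separable data stops after one perfect round", {
  X <- matrix(c(1:6, 21:26), ncol = 1)
  y <- rep(c("fall", "no_fall"), each = 6)
  ens <- train_boosted(X, y, K = 10, base = "tree")
  expect_equal(length(ens$alphas), 1)
  expect_equal(predict(ens, X)$label, y)
})

test_that("boosted stumps beat every individual stump on XOR-like data", {
  d <- xor_data()
  ens <- train_boosted(d$X, d$y, K = 10, base = "stump")
  expect_gt(length(ens$alphas), 1)
  ens_err <- mean(predict(ens, d$X)$label != d$y)
  single_errs <- vapply(ens$trees, function(tr)
    mean(predict_tree(tr, d$X) != d$y), numeric(1))
  expect_lt(ens_err, min(single_errs))
})

test_that("boosting weight dynamics follow the AdaBoost update", {
  feats <- cached_features("fall", 1:3)
  featw <- cached_features("walk", 101:103)
  df <- rbind(feats, featw)
  X <- feature_matrix(df); y <- df$label
  ens <- train_boosted(X, y, K = 8, base = "stump")
  # replay the weight recursion independently and check each round
  n <- nrow(X); w <- rep(1 / n, n)
  for (k in seq_along(ens$alphas)) {
    miss <- predict_tree(ens$trees[[k]], X) != y
    eps <- sum(w[miss])
    expect_lt(eps, 0.5)
    expect_equal(ens$alphas[k], 0.5 * log((1 - max(eps, 1e-10)) / max(eps, 1e-10)),
                 tolerance = 1e-9)
    w <- w * exp(ens$alphas[k] * miss)
    w <- w / sum(w)
  }
  # deterministic retrain
  ens2 <- train_boosted(X, y, K = 8, base = "stump")
  expect_identical(ens$alphas, ens2$alphas)
  expect_identical(predict(ens, X), predict(ens2, X))
})

test_that("ensemble vote arithmetic matches the weighted-sum definition", {
  leaf_tree <- function(label_idx)
    structure(list(node = list(leaf = TRUE, label = label_idx,
                               probs = c(0, 0)),
                   classes = c("neg", "pos"), feature_names = NULL),
              class = "gain_ratio_tree")
  ens <- structure(list(alphas = c(0.4, 0.7),
                        trees = list(leaf_tree(2), leaf_tree(1)),
                        classes = c("neg", "pos"), positive = "pos",
                        base = "stump", feature_names = NULL),
                   class = "boosted_ensemble")
  p <- predict(ens, matrix(0, 1, 1))
  expect_equal(p$margin, 0.4 - 0.7)
  expect_equal(p$label, "neg")
  # single member: the ensemble is that tree
  ens1 <- ens; ens1$alphas <- 0.4; ens1$trees <- list(leaf_tree(2))
  expect_equal(predict(ens1, matrix(0, 1, 1))$label, "pos")
  # random ensembles vs the literal sum
  set.seed(2)
  for (i in 1:10) {
    K <- sample(1:5, 1)
    labs <- sample(1:2, K, TRUE)
    al <- runif(K)
    e <- ens
    e$alphas <- al
    e$trees <- lapply(labs, leaf_tree)
    F_val <- sum(al * ifelse(labs == 2, 1, -1))
    p <- predict(e, matrix(0, 1, 1))
    expect_equal(p$margin, F_val)
    expect_equal(p$label, if (F_val >= 0) "pos" else "neg")
  }
})

test_that("models serialize to JSON and back with identical predictions", {
  feats <- cached_features("fall", 1:2)
  featw <- cached_features("walk", 101:102)
  df <- rbind(feats, featw)
  X <- feature_matrix(df); y <- df$label
  ens <- train_boosted(X, y, K = 5, base = "tree")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(ens, path, metadata = list(k = 30))
  back <- read_model(path)
  expect_identical(predict(back, X), predict(ens, X))
  expect_identical(back$alphas, ens$alphas)
  expect_equal(attr(back, "metadata")$k, 30)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(1:4, ncol = 1)
  expect_error(train_boosted(X, rep("a", 4)), "single class")
  expect_error(train_boosted(X, c("a", "a", "b", "b"), K = 0), "K must be")
})
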