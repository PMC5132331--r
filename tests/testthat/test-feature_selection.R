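test_that("mean-sigma discretisation produces the expected states", {
  set.seed(71)
  # standard-normal column: roughly 16/68/16% state occupancy
  x <- data.frame(z = rnorm(10000))
  d <- discretize_features(x)
  occ <- table(factor(d$z, levels = 1:3)) / 10000
  expect_equal(unname(occ[1]), 0.16, tolerance = 0.03)
  expect_equal(unname(occ[2]), 0.68, tolerance = 0.03)
  expect_equal(unname(occ[3]), 0.16, tolerance = 0.03)

  # constant column collapses to one state with a warning
  expect_warning(dc <- discretize_features(data.frame(c1 = rep(4, 10))),
                 "constant")
  expect_equal(unique(dc$c1), 1L)
  expect_equal(attr(dc, "constant_features"), "c1")

  # unbalanced binary column keeps two states
  b <- data.frame(b = rep(c(0, 1), c(70, 30)))
  db <- discretize_features(b)
  expect_equal(length(unique(db$b)), 2L)
})

test_that("mutual information matches entropy arithmetic", {
  # identical uniform binary variables share 1 bit
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x), 1)
  # a constant is independent of anything
  expect_equal(mutual_information(rep(1, 100), x), 0)
  # 2x2 joint with counts (40, 10; 10, 40) via the entropy identity
  xx <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  yy <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  want <- 2 - (-2 * 0.4 * log2(0.4) - 2 * 0.1 * log2(0.1))
  expect_equal(mutual_information(xx, yy), want)
  # against the oracle on random discrete pairs
  set.seed(72)
  for (rep in 1:100) {
    a <- sample(1:3, 60, TRUE)
    b <- sample(1:4, 60, TRUE)
    expect_equal(mutual_information(a, b), oracle_mi(a, b),
                 tolerance = 1e-9)
    expect_gte(mutual_information(a, b), -1e-12)
  }
})

test_that("mRMR ranking prefers informative features and is a
           permutation", {
  set.seed(73)
  labels <- rep(c("positive", "negative"), each = 100)
  informative <- ifelse(labels == "positive", 3L, 1L)
  feats <- data.frame(noise1 = sample(1:3, 200, TRUE),
                      signal = informative,
                      noise2 = sample(1:3, 200, TRUE))
  rk <- mrmr_rank(feats, labels)
  expect_equal(rk[1], "signal")
  expect_setequal(rk, names(feats))
  expect_equal(anyDuplicated(rk), 0L)

  # identical features: tie-break by original column order
  same <- data.frame(a = feats$signal, b = feats$signal, c = feats$signal)
  expect_equal(mrmr_rank(same, labels), c("a", "b", "c"))

  # the first pick always maximises relevance
  rel <- vapply(feats, mutual_information, numeric(1), y = labels)
  expect_equal(rk[1], names(which.max(rel)))
})

test_that("mRMR penalises redundant copies of the top feature", {
  set.seed(74)
  n <- 400
  labels <- rep(c("positive", "negative"), each = n / 2)
  cls <- ifelse(labels == "positive", 3L, 1L)
  # strong: a 90% noisy channel of the class; copy: identical to strong;
  # weak: an independent 75% channel, informative but far less redundant
  strong <- ifelse(runif(n) < 0.9, cls, 4L - cls)
  weak <- ifelse(runif(n) < 0.75, cls, 4L - cls)
  feats <- data.frame(strong = strong, copy = strong, weak = weak)
  rk <- mrmr_rank(feats, labels, criterion = "mid")
  expect_equal(rk[1], "strong")
  expect_equal(rk[2], "weak")  # the copy is pushed behind by redundancy
})

test_that("incremental selection picks the smallest prefix at peak MCC", {
  # stub evaluator injecting a fixed curve: peak 0.5 first reached at k=2
  curve <- c(0.2, 0.5, 0.5, 0.4)
  feats <- as.data.frame(matrix(rnorm(40), 10, 4))
  names(feats) <- paste0("f", 1:4)
  labels <- rep(c("positive", "negative"), 5)
  stub <- function(f, l, s) {
    k <- ncol(f)
    list(acc = 0.5, se = 0.5, sp = 0.5, mcc = curve[k])
  }
  tr <- ifs_select(feats, labels, names(feats), evaluator = stub, seed = 1)
  expect_equal(tr$optimal_k, 2L)
  expect_equal(tr$optimal_features, c("f1", "f2"))
  expect_equal(tr$curve$mcc, curve)

  # a single feature trivially yields k = 1
  tr1 <- ifs_select(feats[, 1, drop = FALSE], labels, "f1",
                    evaluator = stub, seed = 1)
  expect_equal(tr1$optimal_k, 1L)

  # ranking must cover the features exactly
  expect_error(ifs_select(feats, labels, c("f1", "f2"), evaluator = stub),
               "permutation")
})

test_that("incremental selection recovers informative features on
           synthetic data", {
  set.seed(75)
  n <- 60
  labels <- rep(c("positive", "negative"), each = n / 2)
  shift <- ifelse(labels == "positive", 1.5, 0)
  feats <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(feats) <- paste0("f", 1:10)
  feats$f1 <- feats$f1 + shift
  feats$f2 <- feats$f2 + shift
  rk <- mrmr_rank(discretize_features(feats), labels)
  expect_true(all(c("f1", "f2") %in% rk[1:4]))
  tr <- ifs_select(feats, labels, rk, folds = 5, ntree = 200, stride = 2,
                   seed = 7)
  expect_lte(tr$optimal_k, 8L)
  expect_true(any(c("f1", "f2") %in% tr$optimal_features))
  # the curve records the four metrics for every evaluated prefix
  expect_true(all(c("k", "acc", "se", "sp", "mcc") %in% names(tr$curve)))
  # determinism: the same inputs and seed reproduce the trace
  tr2 <- ifs_select(feats, labels, rk, folds = 5, ntree = 200, stride = 2,
                    seed = 7)
  expect_identical(tr$curve, tr2$curve)
})

test_that("the recorded MCC at the full prefix equals a direct
           cross-validation", {
  set.seed(76)
  n <- 40
  labels <- rep(c("positive", "negative"), each = n / 2)
  feats <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(feats) <- paste0("f", 1:5)
  feats$f1 <- feats$f1 + ifelse(labels == "positive", 2, 0)
  rk <- mrmr_rank(discretize_features(feats), labels)
  tr <- ifs_select(feats, labels, rk, folds = 4, ntree = 150, stride = 2,
                   seed = 3)
  direct <- cross_validate(feats[, rk, drop = FALSE], labels, folds = 4,
                           ntree = 150, seed = 3)
  expect_equal(tr$curve$mcc[nrow(tr$curve)], direct$mcc)
})
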