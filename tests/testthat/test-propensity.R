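test_that("first-order propensity matches hand-computed cases", {
  # no residues of the target call -> 0
  tr <- binding_track(1:4, rep("A", 4), rep("non-binding", 4), rep(5, 4))
  expect_equal(bp1(tr, "binding"), 0)
  # all residues carry the call with maximal reliability -> 1
  tr2 <- binding_track(1:6, rep("K", 6), rep("binding", 6), rep(10, 6))
  expect_equal(bp1(tr2, "binding"), 1)
  # N = 10, one binding residue with RI 7 -> 7 / 100
  lab <- c("binding", rep("non-binding", 9))
  tr3 <- binding_track(1:10, rep("A", 10), lab, c(7, rep(3, 9)))
  expect_equal(bp1(tr3, "binding"), 0.07)
  # complementary call counts the other residues
  expect_equal(bp1(tr3, "non-binding"), 9 * 3 / 100)
})

test_that("first-order propensity is bounded and monotone in reliability", {
  set.seed(31)
  for (rep in 1:20) {
    tr <- random_track(sample(5:60, 1))
    v <- bp1(tr, "binding")
    expect_gte(v, 0)
    expect_lte(v, 1)
    # raising one target residue's RI cannot decrease the statistic
    hit <- which(tr$label == "binding" & tr$ri < 10)
    if (length(hit)) {
      tr2 <- tr
      tr2$ri[hit[1]] <- tr2$ri[hit[1]] + 1L
      expect_gte(bp1(tr2, "binding"), v)
    }
  }
})

test_that("pair-distance counts enumerate unordered target pairs", {
  lab <- rep("non-binding", 6)
  lab[c(1, 3, 5)] <- "binding"
  tr <- binding_track(1:6, rep("A", 6), lab, rep(10, 6))
  pd <- pair_distances(tr, "binding")
  expect_equal(pd$distance, c(2L, 4L))
  expect_equal(pd$n, c(2L, 1L))
  # all RI = 10 -> summed pair reliability is 10 * n(i)
  expect_equal(pd$ri_sum, 10 * pd$n)
  # zero or one target residue -> no pairs
  tr1 <- binding_track(1:5, rep("A", 5),
                       c("binding", rep("non-binding", 4)), rep(8, 5))
  expect_equal(nrow(pair_distances(tr1, "binding")), 0L)
  expect_equal(nrow(pair_distances(tr1, "binding")), 0L)
  # reliability sum bounded by 10 * n(i) in general
  set.seed(13)
  for (rep in 1:10) {
    tr <- random_track(sample(5:50, 1))
    pd <- pair_distances(tr, "binding")
    expect_true(all(pd$ri_sum <= 10 * pd$n + 1e-12))
    expect_true(all(pd$distance >= 1 & pd$distance <= nrow(tr) - 1))
  }
})

test_that("second-order propensity matches hand and brute-force values", {
  # no target residues -> 0 by the q = 0 convention
  tr0 <- binding_track(1:5, rep("A", 5), rep("non-binding", 5), rep(5, 5))
  expect_equal(bp2(tr0, "binding"), 0)
  # N = 5, binding at 1 and 3 with RI 10: single nonzero term at i = 2
  lab <- c("binding", "non-binding", "binding", "non-binding", "non-binding")
  tr <- binding_track(1:5, rep("A", 5), lab, c(10, 0, 10, 0, 0))
  q <- 0.4; p <- 1 / 3; d <- p - q^2
  expect_equal(bp2(tr, "binding"), (d + d^2 / q^2) / log(2))
  expect_equal(bp2(tr, "binding"), 0.5210, tolerance = 1e-4)
  # every residue bound with RI 10: each bracket cancels exactly
  trF <- binding_track(1:8, rep("A", 8), rep("binding", 8), rep(10, 8))
  expect_equal(bp2(trF, "binding"), 0)
  # degenerate single-residue track is an error
  tr1 <- binding_track(1, "A", "binding", 9)
  expect_error(bp2(tr1, "binding"), "at least 2")
})

test_that("second-order propensity agrees with the brute-force
           transcription on random tracks", {
  set.seed(41)
  for (rep in 1:25) {
    tr <- random_track(sample(4:40, 1))
    for (target in c("binding", "non-binding")) {
      expect_equal(bp2(tr, target, form = "taylor"),
                   oracle_bp2_taylor(tr$position, tr$label, tr$ri, target),
                   tolerance = 1e-9)
      expect_equal(bp2(tr, target, form = "exact"),
                   oracle_bp2_exact(tr$position, tr$label, tr$ri, target),
                   tolerance = 1e-9)
    }
  }
})

test_that("second-order propensity is invariant under sequence reversal", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(6:50, 1)
    tr <- random_track(n)
    rev_tr <- binding_track(n + 1L - tr$position, tr$residue, tr$label,
                            tr$ri)
    expect_equal(bp2(tr, "binding"), bp2(rev_tr, "binding"))
    expect_equal(bp1(tr, "binding"), bp1(rev_tr, "binding"))
  }
})

test_that("the Taylor form approaches the exact form quadratically", {
  # term-level check: for p = q^2 (1 + eps) the gap between the exact
  # term p log2(p/q^2) and the implemented bracket is O(eps^2); halving
  # eps must shrink the gap by about 4.
  q <- 0.6
  eps <- c(0.1, 0.05, 0.025)
  gaps <- sapply(eps, function(e) {
    p <- q^2 * (1 + e)
    abs(dnabindR:::bp2_terms(p, q, "exact") -
          dnabindR:::bp2_terms(p, q, "taylor"))
  })
  expect_true(all(diff(gaps) < 0))
  ratios <- gaps[-length(gaps)] / gaps[-1]
  expect_true(all(ratios > 3 & ratios < 5))

  # track-level: dense high-reliability tracks sit near the p = q^2
  # regime and the two forms agree closely there
  trA <- binding_track(1:40, rep("A", 40), rep("binding", 40), rep(10, 40))
  expect_equal(bp2(trA, "binding", "taylor"), bp2(trA, "binding", "exact"))
})
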