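test_that("pairwise asymmetry averages strong/weak magnitude ratios", {
  m <- matrix(0, 4, 4); diag(m) <- -1
  m[1, 2] <- -0.9; m[2, 1] <- -0.1
  m[3, 4] <- -0.4; m[4, 3] <- -0.2
  expect_equal(as.numeric(pairwise_asymmetry(m)), mean(c(9, 2)))

  single <- matrix(c(-1, -0.3, -0.6, -1), 2, 2)
  expect_equal(as.numeric(pairwise_asymmetry(single)), 2)

  sym <- matrix(-0.4, 3, 3); diag(sym) <- -1
  expect_equal(as.numeric(pairwise_asymmetry(sym)), 1)

  # one-sided links are excluded but tallied
  m2 <- m; m2[1, 3] <- -0.5
  pa <- pairwise_asymmetry(m2)
  expect_equal(as.numeric(pa), 5.5)
  expect_equal(attr(pa, "excluded"), 1)

  expect_error(pairwise_asymmetry(diag(c(-1, -1))), "reciprocal")
})

test_that("both asymmetry indices are scale invariant", {
  set.seed(3)
  for (r in 1:10) {
    m <- random_jacobian(5)
    k <- runif(1, 0.1, 20)
    expect_equal(as.numeric(pairwise_asymmetry(m)),
                 as.numeric(pairwise_asymmetry(k * m)))
    expect_equal(community_asymmetry(m)$ratio,
                 community_asymmetry(k * m)$ratio, tolerance = 1e-12)
  }
})

test_that("community asymmetry maximises the below/above ratio over orders", {
  # perfect 3-species hierarchy: strong effects below the diagonal in rank
  # order, weak above
  m <- matrix(0, 3, 3); diag(m) <- -1
  m[lower.tri(m)] <- -0.9
  m[upper.tri(m)] <- -0.1
  ca <- community_asymmetry(m)
  expect_equal(ca$ratio, 9)
  expect_equal(ca$method, "exact")
  expect_equal(ca$best_order, c("1", "2", "3"))

  sym <- matrix(-0.4, 3, 3); diag(sym) <- -1
  expect_equal(community_asymmetry(sym)$ratio, 1)

  two <- matrix(c(-1, -0.2, -0.8, -1), 2, 2)
  expect_equal(community_asymmetry(two)$ratio, 4)
})

test_that("hill-climb heuristic finds the exact optimum on small instances", {
  set.seed(41)
  hits <- 0
  n <- 60
  for (r in seq_len(n)) {
    m <- random_jacobian(sample(4:6, 1), C = runif(1, 0.6, 1))
    ex <- community_asymmetry(m)
    he <- community_asymmetry(m, exact_limit = 0, restarts = 50)
    expect_equal(he$method, "heuristic")
    expect_lte(he$ratio, ex$ratio + 1e-9)   # heuristic is a lower bound
    if (abs(he$ratio - ex$ratio) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("win index measures the polarisation of decisive outcomes", {
  sp <- c("A", "B")
  w <- matrix(0, 2, 2); w[1, 2] <- 3; w[2, 1] <- 1
  d <- matrix(0, 2, 2)
  expect_equal(as.numeric(win_index(contact_data(sp, w, d, c(1, 1)))), 0.75)

  w2 <- matrix(0, 2, 2); w2[1, 2] <- 5
  expect_equal(as.numeric(win_index(contact_data(sp, w2, d, c(1, 1)))), 1)

  w3 <- matrix(0, 2, 2); w3[1, 2] <- w3[2, 1] <- 4
  expect_equal(as.numeric(win_index(contact_data(sp, w3, d, c(1, 1)))), 0.5)

  # draws-only pair is excluded from the index but tallied
  sp3 <- c("A", "B", "C")
  w4 <- matrix(0, 3, 3); w4[1, 2] <- 3; w4[2, 1] <- 1
  d4 <- matrix(0, 3, 3); d4[1, 3] <- d4[3, 1] <- 2
  wi <- win_index(contact_data(sp3, w4, d4, rep(1, 3)))
  expect_equal(as.numeric(wi), 0.75)
  expect_equal(attr(wi, "excluded"), 1)

  d0 <- matrix(0, 2, 2); d0[1, 2] <- d0[2, 1] <- 1
  expect_error(win_index(contact_data(sp, matrix(0, 2, 2), d0, c(1, 1))),
               "decisive")
})

test_that("triad census separates hierarchy from rock-paper-scissors", {
  # strict hierarchy 1 > 2 > 3: |a_ij| > |a_ji| whenever j outranks i
  h <- matrix(0, 3, 3); diag(h) <- -1
  h[lower.tri(h)] <- -0.9
  h[upper.tri(h)] <- -0.1
  expect_equal(as.numeric(intransitivity_index(h)), -1)

  # rock-paper-scissors: 1 beats 2 beats 3 beats 1
  r <- matrix(0, 3, 3); diag(r) <- -1
  r[2, 1] <- -0.9; r[1, 2] <- -0.1   # 1 beats 2
  r[3, 2] <- -0.9; r[2, 3] <- -0.1   # 2 beats 3
  r[1, 3] <- -0.9; r[3, 1] <- -0.1   # 3 beats 1
  expect_equal(as.numeric(intransitivity_index(r)), 1)

  expect_error(intransitivity_index(matrix(c(-1, -0.2, -0.4, -1), 2, 2)),
               "3 species")
  # no complete triad -> absent
  tied <- matrix(-0.5, 3, 3); diag(tied) <- -1
  expect_true(is.na(intransitivity_index(tied)))
})
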