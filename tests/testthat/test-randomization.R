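manip_funs <- list(
  full = full_randomize,
  weak = weak_randomize,
  minimal = minimal_randomize,
  restore_pairwise = restore_pairwise_asymmetry,
  restore_community = function(N) restore_community_asymmetry(
    restore_pairwise_asymmetry(N)))

test_that("every manipulation preserves multiset, topology and diagonal", {
  set.seed(11)
  for (r in 1:20) {
    m <- random_jacobian(sample(4:8, 1), C = runif(1, 0.5, 1),
                         uniform_diag = TRUE)
    off <- row(m) != col(m)
    for (kind in names(manip_funs)) {
      out <- manip_funs[[kind]](m)
      expect_true(same_multiset(m[off & m != 0], out[off & out != 0]),
                  label = paste(kind, "value multiset"))
      expect_identical(unname(out != 0), unname(m != 0),
                       label = paste(kind, "topology"))
      expect_equal(diag(out), diag(m), label = paste(kind, "diagonal"))
    }
  }
})

test_that("pair-preserving manipulations keep all 2-link loops intact", {
  set.seed(19)
  for (r in 1:20) {
    m <- random_jacobian(6, C = 0.8, uniform_diag = TRUE)
    ref <- two_link_multiset(m)
    expect_equal(two_link_multiset(weak_randomize(m)), ref, tolerance = 1e-12)
    expect_equal(two_link_multiset(minimal_randomize(m)), ref,
                 tolerance = 1e-12)
    # pairwise asymmetry is position independent, so weak preserves it
    expect_equal(as.numeric(pairwise_asymmetry(weak_randomize(m))),
                 as.numeric(pairwise_asymmetry(m)), tolerance = 1e-12)
  }
})

test_that("minimal randomisation preserves the below/above value multisets", {
  set.seed(29)
  for (r in 1:10) {
    m <- random_jacobian(6, C = 0.9, uniform_diag = TRUE)
    out <- minimal_randomize(m)
    expect_true(same_multiset(m[lower.tri(m)], out[lower.tri(out)]))
    expect_true(same_multiset(m[upper.tri(m)], out[upper.tri(out)]))
  }
})

test_that("manipulations needing pairs reject one-sided links", {
  m <- matrix(0, 3, 3); diag(m) <- -1
  m[1, 2] <- -0.5   # unreciprocated
  m[2, 3] <- -0.3; m[3, 2] <- -0.4
  expect_error(weak_randomize(m), "one-sided")
  expect_error(minimal_randomize(m), "one-sided")
  # full randomisation has no pairing requirement
  expect_silent(full_randomize(m))
})

test_that("strongest-with-weakest pairing minimises the heaviest 2-link loop", {
  # magnitudes {0.9, 0.7, 0.3, 0.1} must pair as (0.9, 0.1) and (0.7, 0.3)
  m <- matrix(0, 4, 4); diag(m) <- -1
  m[1, 2] <- -0.9; m[2, 1] <- -0.7
  m[3, 4] <- -0.3; m[4, 3] <- -0.1
  set.seed(1)
  out <- restore_pairwise_asymmetry(m)
  prods <- sort(sapply(list(c(1, 2), c(3, 4)), function(p)
    abs(out[p[1], p[2]] * out[p[2], p[1]])))
  expect_equal(prods, sort(c(0.9 * 0.1, 0.7 * 0.3)))

  # brute force over all pairings of 6 values: no pairing has a smaller
  # maximum product than strongest-with-weakest
  vals <- c(0.95, 0.8, 0.6, 0.45, 0.2, 0.05)
  pairings <- list()
  perm3 <- function(v) {
    if (length(v) == 0) return(list(list()))
    out <- list()
    for (j in 2:length(v)) {
      rest <- perm3(v[-c(1, j)])
      out <- c(out, lapply(rest, function(p) c(list(c(v[1], v[j])), p)))
    }
    out
  }
  maxprod <- sapply(perm3(vals), function(p)
    max(sapply(p, prod)))
  rule <- max(0.95 * 0.05, 0.8 * 0.2, 0.6 * 0.45)
  expect_equal(min(maxprod), rule)   # the stated rule attains the optimum
})

test_that("community restoration puts every stronger value below the diagonal", {
  set.seed(2)
  m <- random_jacobian(6, C = 0.9, uniform_diag = TRUE)
  rp <- restore_pairwise_asymmetry(m)
  rc <- restore_community_asymmetry(rp)
  low <- which(lower.tri(rc), arr.ind = TRUE)
  nz <- rc[low] != 0
  expect_true(all(abs(rc[low][nz]) >=
                    abs(rc[cbind(low[, 2], low[, 1])][nz])))
  expect_equal(two_link_multiset(rc), two_link_multiset(rp), tolerance = 1e-12)
})

test_that("random competition matrices honour topology, sign and pairing", {
  set.seed(6)
  m <- random_competition_matrix(3, C = 1)
  expect_true(all(m[row(m) != col(m)] != 0))
  expect_true(all(m <= 0))
  expect_equal(unname(diag(m)), rep(-1, 3))

  expect_error(random_competition_matrix(3, C = 0), "C must")
  expect_error(random_competition_matrix(3, C = 0.5, sigma = -1), "sigma")

  # pairing of sorted magnitudes {m1 >= m2 >= m3 >= m4}:
  # asymmetric -> {(m1, m4), (m2, m3)}; symmetric -> {(m1, m2), (m3, m4)}
  for (pairing in c("asymmetric", "symmetric")) {
    found <- FALSE
    for (rep in 1:50) {
      m <- random_competition_matrix(4, C = 0.5, pairing = pairing)
      pr <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
      if (nrow(pr) != 2) next
      found <- TRUE
      v <- sort(abs(c(m[pr], m[cbind(pr[, 2], pr[, 1])])), decreasing = TRUE)
      prods <- sort(abs(c(m[pr[1, 1], pr[1, 2]] * m[pr[1, 2], pr[1, 1]],
                          m[pr[2, 1], pr[2, 2]] * m[pr[2, 2], pr[2, 1]])))
      want <- if (pairing == "asymmetric") {
        sort(c(v[1] * v[4], v[2] * v[3]))
      } else {
        sort(c(v[1] * v[2], v[3] * v[4]))
      }
      expect_equal(prods, want, tolerance = 1e-12)
    }
    expect_true(found)
  }
})

test_that("drawn magnitudes follow the half-normal mean", {
  set.seed(14)
  sigma <- 0.8
  m <- random_competition_matrix(100, C = 1, sigma = sigma)
  x <- abs(m[row(m) != col(m)])
  n <- length(x)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mean(x) - sigma * sqrt(2 / pi)), 3 * se)
})

test_that("threshold curve scans connectance for the stable region", {
  set.seed(21)
  # 2 species with weak links: diagonal -1 dominates, nearly always stable
  res <- stability_threshold_curve(2, c(0.5, 1), reps = 30, sigma = 0.1)
  expect_true(all(res$grid$stable_fraction > 0.9))
  expect_equal(res$thresholds$C_threshold, 1)

  expect_error(stability_threshold_curve(integer(0), 0.5), "empty")
  expect_error(stability_threshold_curve(3, 0.5, reps = 5), "reps")
})
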