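test_that("loop weight is the scaled geometric mean of cycle links", {
  m <- matrix(c(-1, -0.1, -0.9, -1), 2, 2)
  w <- loop_weight(m, c(1, 2))
  expect_equal(as.numeric(w), sqrt(0.09))
  expect_equal(attr(w, "sign"), 1)

  m3 <- matrix(-0.5, 3, 3); diag(m3) <- -1
  w3 <- loop_weight(m3, c(1, 2, 3))
  expect_equal(as.numeric(w3), 0.125^(1 / 3))
  expect_equal(attr(w3, "sign"), -1)

  expect_error(loop_weight(m3, c(1, 1, 2)), "repeated")
  z <- m3; z[1, 2] <- 0
  expect_error(loop_weight(z, c(1, 2, 3)), "zero link")
})

test_that("heaviest 2-link loop scans all reciprocal pairs", {
  m <- matrix(0, 3, 3); diag(m) <- -1
  m[1, 2] <- -0.9; m[2, 1] <- -0.1
  m[2, 3] <- -0.5; m[3, 2] <- -0.5
  expect_equal(max_two_link_loop_weight(m), 0.5)
  expect_equal(max_two_link_loop_weight(diag(c(-1, -2, -3))), 0)
})

test_that("for 2 species the heaviest 2-link loop equals s*", {
  set.seed(5)
  for (r in 1:20) {
    m <- random_jacobian(2, C = 1, uniform_diag = TRUE)
    expect_equal(max_two_link_loop_weight(m),
                 critical_self_regulation_normalized(m)$s_star,
                 tolerance = 1e-10)
  }
})

test_that("spectrum handles single-cycle and uniform matrices exactly", {
  # one directed 3-cycle only, no reciprocal pair
  m <- matrix(0, 3, 3); diag(m) <- -1
  m[1, 2] <- -0.2; m[2, 3] <- -0.4; m[3, 1] <- -0.5
  sp <- max_loop_weight_per_length(m)
  expect_equal(sp$k, 3)
  expect_equal(sp$max_weight, 0.04^(1 / 3))
  expect_equal(sp$cycle, "1;2;3")

  # fully reciprocal uniform matrix: w^(k) = c at every length
  u <- matrix(-0.3, 4, 4); diag(u) <- -1
  spu <- max_loop_weight_per_length(u)
  expect_equal(spu$k, 2:4)
  expect_equal(spu$max_weight, rep(0.3, 3))
  expect_equal(spu$sign, c(1, -1, 1))
})

test_that("subset DP agrees with DFS enumeration on random matrices", {
  set.seed(12)
  for (r in 1:60) {
    S <- sample(3:6, 1)
    m <- random_jacobian(S, C = runif(1, 0.4, 1))
    dp <- max_loop_weight_per_length(m)
    bf <- max_loop_weight_brute(m)
    expect_equal(dp$k, bf$k)
    expect_equal(dp$max_weight, bf$max_weight, tolerance = 1e-12)
    # the reported argmax cycle must itself attain the reported weight
    for (i in seq_len(nrow(dp))) {
      cyc <- as.integer(strsplit(dp$cycle[i], ";")[[1]])
      expect_equal(as.numeric(loop_weight(m, cyc)), dp$max_weight[i],
                   tolerance = 1e-12)
    }
  }
})

test_that("DP agrees with igraph's independent cycle enumeration", {
  skip_if_not_installed("igraph")
  # enumerate every simple directed cycle by anchoring at its lowest-index
  # vertex: in the subgraph induced on vertices >= a, a simple path from a
  # that closes back to a is a cycle, found via igraph's path enumeration
  set.seed(77)
  for (r in 1:10) {
    S <- 5
    m <- random_jacobian(S, C = 0.8)
    N <- normalize_community(m)$abar
    adj <- (N != 0) * 1; diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    best <- rep(-Inf, S)
    for (a in seq_len(S - 1)) {
      keepv <- a:S
      sub <- igraph::induced_subgraph(g, keepv)
      paths <- igraph::all_simple_paths(sub, from = 1,
                                        mode = "out")
      for (p in paths) {
        v <- keepv[as.integer(p)]
        k <- length(v)
        if (k >= 2 && N[v[k], v[1]] != 0) {
          w <- prod(abs(N[cbind(v, c(v[-1], v[1]))]))^(1 / k)
          if (w > best[k]) best[k] <- w
        }
      }
    }
    dp <- max_loop_weight_per_length(m)
    expect_equal(dp$max_weight, best[dp$k], tolerance = 1e-12)
    expect_true(all(!is.finite(best[setdiff(2:S, dp$k)])))
  }
})

test_that("loop weights are invariant under normalisation", {
  set.seed(9)
  for (r in 1:10) {
    m <- random_jacobian(sample(4:7, 1))
    a <- max_loop_weight_per_length(m)
    b <- max_loop_weight_per_length(normalize_community(m))
    expect_equal(a$max_weight, b$max_weight, tolerance = 1e-12)
  }
})

test_that("hierarchical sources carry lighter loops than randomised versions", {
  set.seed(5)
  lower_everywhere <- 0
  n_draw <- 40
  for (r in seq_len(n_draw)) {
    cd <- generate_assemblage(synthetic_spec(S = 7, beta = 4, seed = 3000 + r))
    N <- normalize_community(jacobian(energy_loss_web(cd), cd$abundance))
    sN <- max_loop_weight_per_length(N)
    sF <- max_loop_weight_per_length(full_randomize(N))
    kk <- intersect(sN$k, sF$k)
    if (all(sN$max_weight[match(kk, sN$k)] < sF$max_weight[match(kk, sF$k)])) {
      lower_everywhere <- lower_everywhere + 1
    }
  }
  expect_gte(lower_everywhere / n_draw, 0.9)
})

test_that("large systems fall back to sampling, flagged as such", {
  set.seed(2)
  m <- random_jacobian(8, C = 0.9)
  sampled <- max_loop_weight_per_length(m, exact_limit = 5, n_samples = 5000)
  exact <- max_loop_weight_per_length(m)
  expect_true(all(sampled$method == "sampled"))
  kk <- intersect(sampled$k, exact$k)
  # sampling reports a lower bound on the true maxima
  expect_true(all(sampled$max_weight[match(kk, sampled$k)] <=
                    exact$max_weight[match(kk, exact$k)] + 1e-12))
})
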