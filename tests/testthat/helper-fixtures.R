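# fixture builders shared across the suite

# the 3-species worked example used throughout: A beats B, B beats C,
# A and C interact weakly
toy_contacts <- function() {
  sp <- c("A", "B", "C")
  w <- matrix(0, 3, 3, dimnames = list(sp, sp))
  d <- matrix(0, 3, 3, dimnames = list(sp, sp))
  w["A", "B"] <- 3; w["B", "A"] <- 1
  w["B", "C"] <- 5; w["C", "B"] <- 0
  w["A", "C"] <- 2; w["C", "A"] <- 1
  d["A", "B"] <- d["B", "A"] <- 2
  d["B", "C"] <- d["C", "B"] <- 1
  w["A", "A"] <- 2; d["A", "A"] <- 1
  contact_data(sp, w, d, c(8, 5, 12), assemblage_id = "toy")
}

# random Jacobian-like matrix: strictly negative diagonal, non-positive
# off-diagonals, reciprocal topology with connectance C
random_jacobian <- function(S, C = 0.9, sigma = 0.8, uniform_diag = FALSE) {
  m <- matrix(0, S, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (stats::runif(1) < C) {
      m[i, j] <- -abs(stats::rnorm(1, 0, sigma))
      m[j, i] <- -abs(stats::rnorm(1, 0, sigma))
    }
  }
  diag(m) <- if (uniform_diag) -1 else -stats::runif(S, 0.2, 2)
  m
}

# multiset comparison helper
same_multiset <- function(a, b, tol = 1e-12) {
  length(a) == length(b) && all(abs(sort(a) - sort(b)) < tol)
}

# 2-link loop-weight multiset over reciprocal pairs of a uniform-diagonal
# matrix (used to check that pair-preserving manipulations keep it intact)
two_link_multiset <- function(m) {
  S <- nrow(m)
  out <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (m[i, j] != 0 && m[j, i] != 0) {
      out <- c(out, sqrt(abs(m[i, j] * m[j, i]) / abs(m[i, i] * m[j, j])))
    }
  }
  sort(out)
}
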