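# Null-model manipulations of community matrices. All of them preserve the
# zero pattern (topology), the diagonal, and the multiset of non-zero
# off-diagonal values; they differ in how much of the empirical patterning
# of those values survives. Randomness comes from R's global RNG: call
# set.seed() for reproducibility.

#' Full randomisation
#'
#' Randomly permutes all non-zero interspecific interaction strengths among
#' the non-zero off-diagonal positions. Destroys the loop-weight structure
#' of every feedback loop of length > 1 while preserving topology,
#' complexity and the value multiset.
#'
#' @param N a `normalized_matrix` (the usual case), `jacobian_matrix` or
#'   square matrix; the diagonal is untouched.
#' @return A manipulated object of the same class as `N`.
#' @export
full_randomize <- function(N) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  idx <- offdiag_nonzero(m)
  m[idx] <- m[idx][sample.int(nrow(idx))]
  comp_rewrap(N, m)
}

# decompose the off-diagonal structure into unordered reciprocal pairs:
# positions (upper = (i, j) with i < j; lower = (j, i)) and their two values
extract_pairs <- function(m) {
  pr <- reciprocal_pairs(m, require_all_paired = TRUE)
  list(upper = pr,
       lower = cbind(pr[, 2], pr[, 1]),
       v_upper = m[pr],
       v_lower = m[cbind(pr[, 2], pr[, 1])])
}

#' Weak randomisation
#'
#' Reshuffles the coupled pairs of interaction strengths as units: every
#' 2-link loop stays intact (its two values remain coupled), but the pairs
#' are reassigned to the reciprocal position-pairs uniformly at random and
#' the side of the diagonal each member lands on is also random. Disrupts
#' the patterning of feedback loops of length > 2 only. Requires every
#' non-zero link to be reciprocated.
#'
#' @inheritParams full_randomize
#' @return A manipulated object of the same class as `N`.
#' @export
weak_randomize <- function(N) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  p <- extract_pairs(m)
  n <- nrow(p$upper)
  if (n == 0) return(N)
  assign <- sample.int(n)
  flip <- stats::runif(n) < 0.5
  vu <- ifelse(flip, p$v_lower, p$v_upper)[assign]
  vl <- ifelse(flip, p$v_upper, p$v_lower)[assign]
  m[p$upper] <- vu
  m[p$lower] <- vl
  comp_rewrap(N, m)
}

#' Minimal randomisation
#'
#' Identical to [weak_randomize()] except that every pair keeps its stronger
#' member on the same side of the diagonal as in the source matrix. This
#' preserves the below/above-diagonal value multisets (hence community
#' asymmetry at the source ordering) while still relocating the pairs.
#'
#' @inheritParams full_randomize
#' @return A manipulated object of the same class as `N`.
#' @export
minimal_randomize <- function(N) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  p <- extract_pairs(m)
  n <- nrow(p$upper)
  if (n == 0) return(N)
  assign <- sample.int(n)
  # orient each relocated pair so its stronger member stays on its source side
  src_strong_lower <- abs(p$v_lower) >= abs(p$v_upper)
  strong <- ifelse(src_strong_lower, p$v_lower, p$v_upper)[assign]
  weakv <- ifelse(src_strong_lower, p$v_upper, p$v_lower)[assign]
  to_lower <- src_strong_lower[assign]
  m[p$lower] <- ifelse(to_lower, strong, weakv)
  m[p$upper] <- ifelse(to_lower, weakv, strong)
  comp_rewrap(N, m)
}

#' Restore maximal pairwise asymmetry
#'
#' Re-pairs the non-zero off-diagonal values so that the strongest is
#' coupled with the weakest, the second strongest with the second weakest,
#' and so on (stable sort, so ties keep their first-appearance order); the
#' re-formed pairs are then placed at randomly chosen reciprocal
#' position-pairs with random orientation, so strong links can appear on
#' either side of the diagonal. This maximises pairwise asymmetry — and
#' minimises the heaviest 2-link loop — for the given value multiset.
#'
#' @inheritParams full_randomize
#' @return A manipulated object of the same class as `N`.
#' @export
restore_pairwise_asymmetry <- function(N) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  p <- extract_pairs(m)
  n <- nrow(p$upper)
  if (n == 0) return(N)
  vals <- c(p$v_upper, p$v_lower)
  if (length(vals) %% 2 != 0) stop("domain error: odd number of values")
  srt <- vals[order(abs(vals), decreasing = TRUE)]   # stable in ties
  strong <- srt[seq_len(n)]
  weakv <- rev(srt)[seq_len(n)]                      # weakest first-to-last
  assign <- sample.int(n)
  flip <- stats::runif(n) < 0.5
  m[p$upper[assign, , drop = FALSE]] <- ifelse(flip, weakv, strong)
  m[p$lower[assign, , drop = FALSE]] <- ifelse(flip, strong, weakv)
  comp_rewrap(N, m)
}

#' Restore community asymmetry on top of pairwise asymmetry
#'
#' Flips the orientation of every reciprocal pair so that its stronger
#' member lies below the diagonal; pair membership and positions are
#' unchanged (2-link loop weights are unaffected). Applied to the output of
#' [restore_pairwise_asymmetry()], this maximises community asymmetry for
#' the given pairing.
#'
#' @inheritParams full_randomize
#' @return A manipulated object of the same class as `N`.
#' @export
restore_community_asymmetry <- function(N) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  p <- extract_pairs(m)
  if (nrow(p$upper) == 0) return(N)
  strong_up <- abs(p$v_upper) > abs(p$v_lower)
  m[p$lower] <- ifelse(strong_up, p$v_upper, p$v_lower)
  m[p$upper] <- ifelse(strong_up, p$v_lower, p$v_upper)
  comp_rewrap(N, m)
}

#' Random competition matrix (May-style)
#'
#' Builds an S x S competition matrix with random topology and interaction
#' strengths: the diagonal is fixed (default -1), each unordered species
#' pair is activated independently with probability `C`, and the strengths
#' are the negated magnitudes of draws from `Normal(0, sigma)` so that all
#' interactions are competitive (-/-). The `pairing` argument controls how
#' the drawn values are coupled into reciprocal pairs:
#' \describe{
#'   \item{independent}{each of the two link values is drawn separately;}
#'   \item{asymmetric}{the 2n draws are sorted by magnitude and the
#'     strongest is paired with the weakest, the second strongest with the
#'     second weakest, etc.;}
#'   \item{symmetric}{the sorted draws are paired adjacent-in-order
#'     (strongest with second strongest, and so on).}
#' }
#' Pairs are assigned to the active position-pairs in random order with
#' random orientation.
#'
#' @param S number of species (>= 2).
#' @param C connectance target in (0, 1]: pair-activation probability.
#' @param sigma standard deviation of the sampling distribution (> 0,
#'   default 0.8).
#' @param pairing `"independent"`, `"asymmetric"` or `"symmetric"`.
#' @param diagonal fixed self-regulation value (default -1).
#' @return An S x S matrix with non-positive entries.
#' @export
random_competition_matrix <- function(S, C, sigma = 0.8,
                                      pairing = c("independent", "asymmetric",
                                                  "symmetric"),
                                      diagonal = -1) {
  pairing <- match.arg(pairing)
  if (S < 2) stop("validation error: S must be >= 2")
  if (!is.finite(C) || C <= 0 || C > 1) {
    stop("validation error: C must be in (0, 1]")
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("validation error: sigma must be positive")
  }
  m <- matrix(0, S, S)
  diag(m) <- diagonal
  up <- which(upper.tri(m), arr.ind = TRUE)
  active <- up[stats::runif(nrow(up)) < C, , drop = FALSE]
  n <- nrow(active)
  if (n == 0) return(m)
  lower <- cbind(active[, 2], active[, 1])
  draws <- -abs(stats::rnorm(2 * n, 0, sigma))
  if (pairing == "independent") {
    m[active] <- draws[seq_len(n)]
    m[lower] <- draws[n + seq_len(n)]
    return(m)
  }
  srt <- draws[order(abs(draws), decreasing = TRUE)]
  if (pairing == "asymmetric") {
    first <- srt[seq_len(n)]
    second <- rev(srt)[seq_len(n)]
  } else {
    first <- srt[seq(1, 2 * n, by = 2)]
    second <- srt[seq(2, 2 * n, by = 2)]
  }
  assign <- sample.int(n)
  flip <- stats::runif(n) < 0.5
  m[active[assign, , drop = FALSE]] <- ifelse(flip, second, first)
  m[lower[assign, , drop = FALSE]] <- ifelse(flip, first, second)
  m
}

#' Stability-threshold curve over (S, C) for random competition matrices
#'
#' For every combination of species number and connectance, draws an
#' ensemble of [random_competition_matrix()] systems and records the
#' fraction that is locally stable (dominant eigenvalue with negative real
#' part). For each S, the threshold connectance is the largest C — scanning
#' C in ascending order — up to which the stable fraction stays at or above
#' `stable_fraction_cutoff`; systems above the curve are predominantly
#' unstable.
#'
#' @param S_values,C_values grids of species numbers and connectances.
#' @param reps ensemble size per cell (>= 20).
#' @param stable_fraction_cutoff fraction in (0, 1) defining the threshold
#'   (default 0.05).
#' @param pairing,sigma,diagonal passed to [random_competition_matrix()].
#' @return A list with `thresholds` (data.frame: S, C_threshold) and `grid`
#'   (data.frame: S, C, stable_fraction).
#' @export
stability_threshold_curve <- function(S_values, C_values, reps = 100,
                                      stable_fraction_cutoff = 0.05,
                                      pairing = "asymmetric", sigma = 0.8,
                                      diagonal = -1) {
  if (length(S_values) == 0 || length(C_values) == 0) {
    stop("validation error: empty S or C grid")
  }
  if (reps < 20) stop("validation error: reps must be >= 20")
  if (stable_fraction_cutoff <= 0 || stable_fraction_cutoff >= 1) {
    stop("validation error: cutoff must be in (0, 1)")
  }
  C_values <- sort(C_values)
  grid <- expand.grid(S = S_values, C = C_values)
  grid$stable_fraction <- mapply(function(S, C) {
    stable <- vapply(seq_len(reps), function(r) {
      m <- random_competition_matrix(S, C, sigma, pairing, diagonal)
      dominant_eigenvalue(m) < 0
    }, logical(1))
    mean(stable)
  }, grid$S, grid$C)
  thresholds <- do.call(rbind, lapply(S_values, function(S) {
    fr <- grid$stable_fraction[grid$S == S]
    drop <- which(fr < stable_fraction_cutoff)
    C_thr <- if (length(drop) == 0) {
      max(C_values)
    } else if (drop[1] == 1) {
      NA_real_
    } else {
      C_values[drop[1] - 1]
    }
    data.frame(S = S, C_threshold = C_thr)
  }))
  list(thresholds = thresholds, grid = grid)
}
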