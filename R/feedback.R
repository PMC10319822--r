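#' Weight of a single feedback loop
#'
#' The loop weight of a length-k directed cycle is the geometric mean of the
#' magnitudes of its links, scaled by the self-regulation terms of its
#' members:
#' `w^(k) = |a[i1,i2] * a[i2,i3] * ... * a[ik,i1] / (a[i1,i1] * ... * a[ik,ik])|^(1/k)`.
#' Because all links in a competition network are negative, loops with an
#' even number of links are positive (self-reinforcing) and loops with an
#' odd number are negative (self-dampening); the weight itself is >= 0 and
#' dimensionless, comparable across loop lengths and with s*.
#'
#' @param J a `jacobian_matrix`, `normalized_matrix` or square matrix with
#'   strictly negative diagonal.
#' @param cycle species labels or indices, in traversal order, each visited
#'   once (k >= 2); the closing link from the last back to the first is
#'   implied.
#' @return The loop weight, a non-negative scalar with attribute `sign`
#'   (+1 for even k, -1 for odd k).
#' @export
loop_weight <- function(J, cycle) {
  m <- comp_matrix(J)
  stopifnot_square(m)
  if (any(diag(m) >= 0)) stop("domain error: diagonal must be strictly negative")
  sp <- comp_species(J)
  idx <- if (is.character(cycle)) match(cycle, sp) else as.integer(cycle)
  if (any(is.na(idx)) || any(idx < 1 | idx > nrow(m))) {
    stop("unknown species in cycle")
  }
  k <- length(idx)
  if (k < 2) stop("domain error: a feedback loop needs at least 2 species")
  if (anyDuplicated(idx)) stop("domain error: repeated species in cycle")
  links <- m[cbind(idx, c(idx[-1], idx[1]))]
  if (any(links == 0)) stop("domain error: cycle traverses a zero link")
  w <- exp((sum(log(abs(links))) - sum(log(abs(diag(m)[idx])))) / k)
  structure(w, sign = if (k %% 2 == 0) 1 else -1)
}

#' Maximum 2-link loop weight
#'
#' The heaviest pairwise positive feedback,
#' `w2_max = max over pairs of sqrt(a_ij * a_ji / |a_ii * a_jj|)`,
#' which in a 2-species system fully determines stability (it equals both
#' s* of the normalised system and Chesson's niche overlap).
#'
#' @param J as in [loop_weight()].
#' @return The maximum over reciprocally interacting pairs, or 0 if no pair
#'   interacts in both directions.
#' @export
max_two_link_loop_weight <- function(J) {
  m <- comp_matrix(J)
  stopifnot_square(m)
  if (any(diag(m) >= 0)) stop("domain error: diagonal must be strictly negative")
  pr <- reciprocal_pairs(m)
  if (nrow(pr) == 0) return(0)
  w <- sqrt(abs(m[pr] * m[cbind(pr[, 2], pr[, 1])]) /
              abs(diag(m)[pr[, 1]] * diag(m)[pr[, 2]]))
  max(w)
}

#' Maximum loop weight per loop length
#'
#' For each length k from 2 up to `k_max`, the maximum loop weight over all
#' simple directed cycles of exactly k links. Loop weights are invariant
#' under row-normalisation, so the search runs on the log-magnitudes of the
#' normalised matrix: a dynamic programme over vertex subsets (anchored at
#' each cycle's lowest-index member) finds, for every subset size, the
#' heaviest closing path — exact up to `exact_limit` species. Larger systems
#' fall back to uniform random simple-cycle sampling, flagged `sampled` and
#' interpretable as a lower bound.
#'
#' @param J as in [loop_weight()].
#' @param k_max longest loop length to report (default: number of species).
#' @param exact_limit largest S for the exact subset DP (default 14).
#' @param n_samples random cycles drawn in the sampling fallback.
#' @return A data.frame of class `loop_weight_spectrum` with columns `k`,
#'   `max_weight`, `sign` (+1 even k, -1 odd k), `cycle` (semicolon-joined
#'   species labels attaining the maximum; empty for sampled results) and
#'   `method`. Lengths with no simple cycle are absent.
#' @export
max_loop_weight_per_length <- function(J, k_max = NULL, exact_limit = 14,
                                       n_samples = 20000) {
  N <- normalize_community(J)
  m <- N$abar
  sp <- N$species
  S <- nrow(m)
  k_max <- min(k_max %||% S, S)
  if (k_max < 2) stop("k_max must be at least 2")
  L <- log(abs(m))          # -Inf marks absent links
  L[row(L) == col(L)] <- -Inf
  if (S <= exact_limit) {
    res <- loop_dp_max(L, k_max)
    method <- "exact"
  } else {
    res <- loop_sample_max(L, k_max, n_samples)
    method <- "sampled"
  }
  keep <- which(is.finite(res$logsum))
  out <- data.frame(
    k = res$k[keep],
    max_weight = exp(res$logsum[keep] / res$k[keep]),
    sign = ifelse(res$k[keep] %% 2 == 0, 1, -1),
    cycle = vapply(keep, function(i) {
      if (is.null(res$cycles[[i]])) "" else
        paste(sp[res$cycles[[i]]], collapse = ";")
    }, character(1)),
    method = rep(method, length(keep)),
    stringsAsFactors = FALSE)
  class(out) <- c("loop_weight_spectrum", "data.frame")
  out
}

# subset DP: for each anchor a (lowest-index vertex of the cycle), dp[mask, v]
# holds the best log-weight of a simple path from a to v visiting exactly the
# vertices in mask (all >= a). Closing edge v->a yields a cycle of length
# |mask|. Parent pointers give the argmax cycle.
loop_dp_max <- function(L, k_max) {
  S <- nrow(L)
  best <- rep(-Inf, k_max)
  best_cycle <- vector("list", k_max)
  for (a in seq_len(S - 1)) {
    verts <- a:S
    nm <- length(verts)
    nmask <- bitwShiftL(1L, nm)
    bits <- bitwShiftL(1L, 0:(nm - 1))
    # dp row index = mask value + 1
    dp <- matrix(-Inf, nrow = nmask, ncol = nm)
    parent <- matrix(0L, nrow = nmask, ncol = nm)
    dp[2L, 1L] <- 0   # mask {a} (value 1), ending at a
    for (maskval in seq(1L, nmask - 1L, by = 2L)) {  # masks containing a
      row <- maskval + 1L
      ends <- which(is.finite(dp[row, ]))
      if (length(ends) == 0) next
      size <- sum(bitwAnd(maskval, bits) > 0)
      for (e in ends) {
        base <- dp[row, e]
        # close the cycle (length >= 2)
        if (size >= 2 && size <= k_max) {
          cl <- base + L[verts[e], a]
          if (is.finite(cl) && cl > best[size]) {
            best[size] <- cl
            best_cycle[[size]] <- verts[trace_path(parent, maskval, e)]
          }
        }
        if (size >= k_max) next
        for (u in seq_len(nm)[-1]) {
          bit <- bits[u]
          if (bitwAnd(maskval, bit) > 0) next
          step <- L[verts[e], verts[u]]
          if (!is.finite(step)) next
          val <- base + step
          row2 <- maskval + bit + 1L
          if (val > dp[row2, u]) {
            dp[row2, u] <- val
            parent[row2, u] <- e
          }
        }
      }
    }
  }
  list(k = seq_len(k_max), logsum = best, cycles = best_cycle)
}

# walk parent pointers back from (maskval, end) to the anchor (local index 1)
trace_path <- function(parent, maskval, e) {
  path <- integer(0)
  while (e != 1L) {
    path <- c(e, path)
    p <- parent[maskval + 1L, e]
    maskval <- maskval - bitwShiftL(1L, e - 1L)
    e <- p
  }
  c(1L, path)
}

# sampling fallback: random simple walks that close back to their start
loop_sample_max <- function(L, k_max, n_samples) {
  S <- nrow(L)
  best <- rep(-Inf, k_max)
  nbrs <- lapply(seq_len(S), function(i) which(is.finite(L[i, ])))
  for (iter in seq_len(n_samples)) {
    start <- sample.int(S, 1)
    path <- start
    v <- start
    klim <- sample.int(k_max - 1, 1) + 1
    while (length(path) < klim) {
      cand <- setdiff(nbrs[[v]], path)
      if (length(cand) == 0) break
      v <- cand[sample.int(length(cand), 1)]
      path <- c(path, v)
    }
    k <- length(path)
    if (k >= 2 && is.finite(L[v, start])) {
      lw <- sum(L[cbind(path, c(path[-1], start))])
      if (lw > best[k]) best[k] <- lw
    }
  }
  list(k = seq_len(k_max), logsum = best, cycles = vector("list", k_max))
}

#' Brute-force maximum loop weight (enumeration oracle)
#'
#' Exhaustively enumerates all simple directed cycles by depth-first search
#' (each cycle anchored at its lowest-index vertex) and returns the maximum
#' loop weight per length. Exponential in S; intended as an independent
#' check of [max_loop_weight_per_length()] on small systems.
#'
#' @param J as in [loop_weight()].
#' @param k_max longest loop length (default: number of species).
#' @return A data.frame with columns `k`, `max_weight`, `cycle`.
#' @export
max_loop_weight_brute <- function(J, k_max = NULL) {
  N <- normalize_community(J)
  m <- N$abar
  sp <- N$species
  S <- nrow(m)
  if (S > 9) stop("brute-force enumeration is limited to S <= 9")
  k_max <- min(k_max %||% S, S)
  L <- log(abs(m))
  L[row(L) == col(L)] <- -Inf
  best <- rep(-Inf, k_max)
  best_cycle <- vector("list", k_max)
  dfs <- function(anchor, v, path, acc) {
    k <- length(path)
    if (k >= 2 && k <= k_max && is.finite(L[v, anchor])) {
      tot <- acc + L[v, anchor]
      if (tot > best[k]) {
        best[k] <<- tot
        best_cycle[[k]] <<- path
      }
    }
    if (k >= k_max) return()
    for (u in seq((anchor + 1), S)) {
      if (anchor + 1 > S) break
      if (u %in% path || !is.finite(L[v, u])) next
      dfs(anchor, u, c(path, u), acc + L[v, u])
    }
  }
  for (a in seq_len(max(S - 1, 1))) {
    if (a < S) dfs(a, a, a, 0)
  }
  keep <- which(is.finite(best))
  data.frame(
    k = keep,
    max_weight = exp(best[keep] / keep),
    cycle = vapply(keep, function(i) paste(sp[best_cycle[[i]]], collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}
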