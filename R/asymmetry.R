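#' Pairwise asymmetry of interaction strengths
#'
#' The mean, over all reciprocally non-zero pairs, of the ratio of the
#' stronger to the weaker interaction magnitude. A value of 1 means every
#' pair is perfectly symmetric; large values mean each interaction couples
#' a strong with a weak effect, as produced by a dominance hierarchy.
#' Pairs where one direction is zero have no defined ratio; they are
#' excluded and counted in the `excluded` attribute.
#'
#' @param M a square matrix of non-positive entries (or `jacobian_matrix`,
#'   `normalized_matrix`, `energy_loss_web`).
#' @return The mean strong/weak ratio (>= 1), with attributes `n_pairs` and
#'   `excluded`.
#' @export
pairwise_asymmetry <- function(M) {
  m <- comp_matrix(M)
  stopifnot_square(m)
  pr <- reciprocal_pairs(m)
  if (nrow(pr) == 0) {
    stop("domain error: no reciprocally non-zero pair")
  }
  x <- abs(m[pr])
  y <- abs(m[cbind(pr[, 2], pr[, 1])])
  ratios <- pmax(x, y) / pmin(x, y)
  up <- which(upper.tri(m), arr.ind = TRUE)
  one_sided <- sum(xor(m[up] != 0, m[cbind(up[, 2], up[, 1])] != 0))
  structure(mean(ratios), n_pairs = nrow(pr), excluded = one_sided)
}

# ratio of mean |below-diagonal| to mean |above-diagonal| non-zero entries
# under a given species ordering (position 1 = top of the hierarchy)
order_asymmetry_ratio <- function(absm, ord) {
  p <- absm[ord, ord]
  below <- p[lower.tri(p)]
  above <- p[upper.tri(p)]
  below <- below[below > 0]
  above <- above[above > 0]
  if (length(above) == 0 || length(below) == 0) return(NA_real_)
  mean(below) / mean(above)
}

#' Community asymmetry of interaction strengths
#'
#' When species are listed from the strongest to the weakest competitor,
#' "top-down" losses (effects of higher- on lower-ranked species) sit below
#' the matrix diagonal and "bottom-up" losses above it. Community asymmetry
#' is the ratio of the mean magnitude of non-zero below-diagonal entries to
#' the mean above-diagonal magnitude, maximised over all species orderings:
#' a strict hierarchy concentrates strong values below the diagonal and
#' drives the ratio far above 1.
#'
#' The maximisation is a linear-ordering problem: all `S!` orderings are
#' evaluated (vectorised over orderings) for `S <= exact_limit`; above that
#' a hill-climb over pairwise transpositions from `restarts` starts (the
#' first at the dominance-rank order, the rest random) returns a lower
#' bound flagged `heuristic`.
#'
#' @param M as in [pairwise_asymmetry()].
#' @param exact_limit largest S for exhaustive search (default 9).
#' @param restarts hill-climb restarts for the heuristic path (default 50).
#' @return A list with `ratio` (>= 1), `best_order` (species labels, top of
#'   the hierarchy first) and `method` (`"exact"` or `"heuristic"`).
#' @export
community_asymmetry <- function(M, exact_limit = 9, restarts = 50) {
  m <- comp_matrix(M)
  stopifnot_square(m)
  if (nrow(reciprocal_pairs(m)) == 0) {
    stop("domain error: no reciprocally non-zero pair")
  }
  sp <- comp_species(M)
  S <- nrow(m)
  absm <- abs(m)
  diag(absm) <- 0
  if (S <= exact_limit) {
    res <- ca_exact(absm)
    method <- "exact"
  } else {
    res <- ca_hillclimb(absm, restarts)
    method <- "heuristic"
  }
  list(ratio = res$ratio, best_order = sp[res$order], method = method)
}

# exhaustive search, vectorised across all permutations: for each ordered
# species pair (i, j) with absm[i, j] > 0, the entry lies below the diagonal
# exactly when pos(i) > pos(j); accumulate sums and counts per permutation
ca_exact <- function(absm) {
  S <- nrow(absm)
  perms <- all_permutations(S)            # rows: orderings (order -> species)
  pos <- matrix(0L, nrow(perms), S)       # pos[perm, species]
  for (k in seq_len(S)) {
    pos[cbind(seq_len(nrow(perms)), perms[, k])] <- k
  }
  nz <- which(absm > 0, arr.ind = TRUE)
  sum_below <- numeric(nrow(perms))
  cnt_below <- numeric(nrow(perms))
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]
    is_below <- pos[, i] > pos[, j]
    sum_below <- sum_below + absm[i, j] * is_below
    cnt_below <- cnt_below + is_below
  }
  tot_sum <- sum(absm)
  tot_cnt <- nrow(nz)
  ratio <- (sum_below / cnt_below) /
    ((tot_sum - sum_below) / (tot_cnt - cnt_below))
  ratio[!is.finite(ratio)] <- NA_real_
  bestp <- which.max(ratio)
  list(ratio = ratio[bestp], order = perms[bestp, ])
}

ca_hillclimb <- function(absm, restarts) {
  S <- nrow(absm)
  # dominance-rank start: strong competitors inflict much (large column sums)
  # and suffer little (small row sums)
  score <- colSums(absm) - rowSums(absm)
  starts <- c(list(order(score, decreasing = TRUE)),
              replicate(max(restarts - 1, 0), sample.int(S), simplify = FALSE))
  best_ratio <- -Inf
  best_order <- starts[[1]]
  for (ord in starts) {
    cur <- order_asymmetry_ratio(absm, ord)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        cand <- ord
        cand[c(i, j)] <- cand[c(j, i)]
        v <- order_asymmetry_ratio(absm, cand)
        if (!is.na(v) && v > cur + 1e-12) {
          ord <- cand; cur <- v; improved <- TRUE
        }
      }
    }
    if (!is.na(cur) && cur > best_ratio) {
      best_ratio <- cur
      best_order <- ord
    }
  }
  list(ratio = best_ratio, order = best_order)
}

#' Contest-polarisation (win) index
#'
#' The mean, over species pairs with at least one decisive contest, of the
#' dominant species' share of decisive outcomes,
#' `max(W_ij, W_ji) / (W_ij + W_ji)`. Ranges from 0.5 (every pair evenly
#' matched) to 1 (every pair fully one-sided). Draws do not enter the
#' denominator; pairs with only draws are excluded and counted in the
#' `excluded` attribute.
#'
#' @param contacts a [contact_data] object.
#' @return The index in \[0.5, 1\] with attributes `n_pairs` and `excluded`.
#' @export
win_index <- function(contacts) {
  stopifnot(inherits(contacts, "contact_data"))
  W <- contacts$wins
  up <- which(upper.tri(W), arr.ind = TRUE)
  w1 <- W[up]
  w2 <- W[cbind(up[, 2], up[, 1])]
  decisive <- (w1 + w2) > 0
  if (!any(decisive)) stop("domain error: no decisive contests in any pair")
  # pairs that interacted (draws only) but had no decisive outcome
  d <- contacts$draws[up]
  only_draws <- sum(!decisive & d > 0)
  idx <- pmax(w1, w2)[decisive] / (w1 + w2)[decisive]
  structure(mean(idx), n_pairs = sum(decisive), excluded = only_draws)
}

#' Triad-based intransitivity index (operational variant)
#'
#' Builds the dominance digraph in which species j beats species i when
#' species i loses more per capita to j than vice versa
#' (`|a_ij| > |a_ji|`), censuses all complete triads (all three pairs with a
#' strict dominance relation), and returns
#' `1 - 2 * (proportion of transitive triads)`: -1 for a fully transitive
#' hierarchy, +1 for fully cyclic (rock-paper-scissors) dominance. This is
#' an operational variant defined on Jacobian elements, not a reproduction
#' of any published competition-coefficient index.
#'
#' @param J a `jacobian_matrix`, `normalized_matrix` or square matrix of
#'   non-positive entries; at least 3 species.
#' @return The index in \[-1, 1\] with attributes `n_triads` and
#'   `variant = "operational_variant"`, or `NA` if no complete triad exists.
#' @export
intransitivity_index <- function(J) {
  m <- comp_matrix(J)
  stopifnot_square(m)
  S <- nrow(m)
  if (S < 3) stop("domain error: need at least 3 species")
  absm <- abs(m)
  diag(absm) <- 0
  # beats[j, i]: j beats i
  beats <- absm > t(absm)
  n_complete <- 0L
  n_trans <- 0L
  for (i in seq_len(S - 2)) for (j in (i + 1):(S - 1)) for (k in (j + 1):S) {
    trio <- c(i, j, k)
    b <- beats[trio, trio]
    if (sum(b) != 3L) next   # some pair without a strict dominance relation
    n_complete <- n_complete + 1L
    outdeg <- rowSums(b)
    # a transitive triad has out-degrees {2, 1, 0}; a cycle has {1, 1, 1}
    if (max(outdeg) == 2L) n_trans <- n_trans + 1L
  }
  if (n_complete == 0L) {
    return(structure(NA_real_, n_triads = 0L,
                     variant = "operational_variant"))
  }
  structure(1 - 2 * (n_trans / n_complete), n_triads = n_complete,
            variant = "operational_variant")
}
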