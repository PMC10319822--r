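#' Species-contact data for one assemblage
#'
#' Bundles the observed outcomes of pairwise overgrowth contests between
#' colonies of the species in one assemblage: a matrix of wins, a matrix of
#' draws, and per-species colony abundances. `wins[i, j]` counts the contests
#' in which a colony of species `i` overgrew a colony of species `j`; the
#' diagonal counts intraspecific overgrowth events. `draws[i, j]` counts tied
#' contests between species `i` and `j` (one record per contest, hence the
#' matrix is symmetric off the diagonal; the diagonal counts intraspecific
#' ties).
#'
#' @param species character vector of species labels (order is preserved
#'   through the whole pipeline).
#' @param wins S x S matrix of non-negative integer win counts.
#' @param draws S x S matrix of non-negative integer draw counts; must be
#'   symmetric off the diagonal.
#' @param abundance integer vector of colony counts per species, all >= 1.
#' @param assemblage_id label for the assemblage.
#' @return An object of class `contact_data`.
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- 3; w[2, 1] <- 1
#' d <- matrix(0, 2, 2); d[1, 2] <- d[2, 1] <- 2
#' cd <- contact_data(c("A", "B"), w, d, c(10, 5))
#' connectance(cd)
#' @export
contact_data <- function(species, wins, draws, abundance,
                         assemblage_id = "assemblage") {
  species <- as.character(species)
  S <- length(species)
  if (S < 1) stop("need at least one species")
  if (anyDuplicated(species)) stop("duplicated species labels")
  wins <- as.matrix(wins)
  draws <- as.matrix(draws)
  if (!all(dim(wins) == c(S, S))) stop("wins must be an S x S matrix")
  if (!all(dim(draws) == c(S, S))) stop("draws must be an S x S matrix")
  if (any(wins < 0) || any(draws < 0)) {
    stop("validation error: negative contest count")
  }
  if (any(wins != round(wins)) || any(draws != round(draws))) {
    stop("contest counts must be integers")
  }
  asym <- which(draws != t(draws) & upper.tri(draws), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    stop(sprintf(
      "validation error: draws matrix asymmetric for pair(s): %s",
      paste(apply(asym, 1, function(p)
        sprintf("(%s, %s)", species[p[1]], species[p[2]])), collapse = ", ")))
  }
  abundance <- as.numeric(abundance)
  if (length(abundance) != S) stop("abundance must have one entry per species")
  if (any(abundance < 1) || any(abundance != round(abundance))) {
    stop("validation error: abundance must be positive integers")
  }
  dimnames(wins) <- dimnames(draws) <- list(species, species)
  names(abundance) <- species
  structure(
    list(assemblage_id = as.character(assemblage_id), species = species,
         wins = wins, draws = draws, abundance = abundance),
    class = "contact_data")
}

#' @export
print.contact_data <- function(x, ...) {
  n_inter <- sum(total_contests(x)[upper.tri(x$wins)] > 0)
  cat(sprintf("Species-contact data '%s': %d species, %d interacting pairs\n",
              x$assemblage_id, length(x$species), n_inter))
  cat(sprintf("  colonies: %s\n",
              paste(sprintf("%s=%d", x$species, x$abundance), collapse = ", ")))
  invisible(x)
}

# S x S matrix of total contests N_ij = W_ij + W_ji + D_ij (i != j);
# diagonal: intraspecific contests W_ii + D_ii
total_contests <- function(contacts) {
  n <- contacts$wins + t(contacts$wins) + contacts$draws
  diag(n) <- diag(contacts$wins) + diag(contacts$draws)
  n
}

#' Connectance of a contact network
#'
#' Fraction of unordered interspecific species pairs with at least one
#' recorded contest of any kind (win, loss or draw).
#'
#' @param contacts a [contact_data] object with at least two species.
#' @return A fraction in \[0, 1\].
#' @export
connectance <- function(contacts) {
  stopifnot(inherits(contacts, "contact_data"))
  S <- length(contacts$species)
  if (S < 2) stop("connectance requires at least 2 species")
  n <- total_contests(contacts)
  sum(n[upper.tri(n)] > 0) / (S * (S - 1) / 2)
}

#' Per-pair summary of contest outcomes
#'
#' One row per unordered interacting interspecific pair, with the win counts
#' in both directions, draws, and the total number of confrontations.
#' Intraspecific contests (the matrix diagonals) are excluded here; see
#' [intraspecific_summary()].
#'
#' @param contacts a [contact_data] object.
#' @return A data.frame with columns `species_a`, `species_b`, `wins_a`,
#'   `wins_b`, `draws`, `total`.
#' @export
win_loss_summary <- function(contacts) {
  stopifnot(inherits(contacts, "contact_data"))
  sp <- contacts$species
  up <- which(upper.tri(contacts$wins), arr.ind = TRUE)
  w_ab <- contacts$wins[up]
  w_ba <- contacts$wins[cbind(up[, 2], up[, 1])]
  d <- contacts$draws[up]
  keep <- (w_ab + w_ba + d) > 0
  data.frame(
    species_a = sp[up[keep, 1]], species_b = sp[up[keep, 2]],
    wins_a = w_ab[keep], wins_b = w_ba[keep], draws = d[keep],
    total = (w_ab + w_ba + d)[keep],
    stringsAsFactors = FALSE)
}

#' Intraspecific contest summary
#'
#' Reports, per species, the number of within-species overgrowth events and
#' ties recorded on the diagonals of the contact matrices.
#'
#' @param contacts a [contact_data] object.
#' @return A data.frame with columns `species`, `overgrowths`, `ties`.
#' @export
intraspecific_summary <- function(contacts) {
  stopifnot(inherits(contacts, "contact_data"))
  data.frame(species = contacts$species,
             overgrowths = diag(contacts$wins),
             ties = diag(contacts$draws),
             row.names = NULL, stringsAsFactors = FALSE)
}
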