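#' Energy-cost parameters for contest outcomes
#'
#' Fixed proportions of energy lost per colony per unit time for winning,
#' losing and drawing a contest. All three are losses and must be <= 0.
#' The defaults (win -0.1, loss -0.9, draw -0.2) encode that overgrowing a
#' neighbour is much cheaper than being overgrown, with a draw in between;
#' the sensitivity sweep varies these to check that relative stability
#' conclusions do not hinge on the exact values.
#'
#' @param p_win,p_loss,p_draw energy loss per colony per time (<= 0).
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(p_win = -0.1, p_loss = -0.9, p_draw = -0.2) {
  vals <- c(p_win = p_win, p_loss = p_loss, p_draw = p_draw)
  if (any(!is.finite(vals))) stop("cost parameters must be finite")
  if (any(vals > 0)) {
    stop("validation error: cost parameters represent losses and must be <= 0")
  }
  structure(as.list(vals), class = "cost_parameters")
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat(sprintf("Contest costs: win %g, loss %g, draw %g (per colony per time)\n",
              x$p_win, x$p_loss, x$p_draw))
  invisible(x)
}

#' Build an energy-loss web from contest counts
#'
#' The total energy-loss rate of species i due to competition with species j
#' is the cost-weighted sum of observed outcomes,
#' `f_ij = p_win * W_ij + p_loss * L_ij + p_draw * D_ij`,
#' with `W_ij` wins of i over j, `L_ij = W_ji` losses, and `D_ij` draws.
#' On the diagonal every intraspecific overgrowth event is simultaneously a
#' win and a loss for the species, and the tied-outcome count is doubled
#' because a single recorded tie affects two colonies of the same species.
#' Colony biomass is taken as 1, so rates are in units of biomass per time.
#'
#' @param contacts a [contact_data] object.
#' @param costs a [cost_parameters] object.
#' @return An object of class `energy_loss_web` with fields `species`,
#'   `f` (S x S matrix of loss rates, all <= 0) and `costs`.
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- 3; w[2, 1] <- 1
#' d <- matrix(0, 2, 2); d[1, 2] <- d[2, 1] <- 2
#' cd <- contact_data(c("A", "B"), w, d, c(8, 8))
#' energy_loss_web(cd)$f["A", "B"]  # -0.3 - 0.9 - 0.4 = -1.6
#' @export
energy_loss_web <- function(contacts, costs = cost_parameters()) {
  stopifnot(inherits(contacts, "contact_data"),
            inherits(costs, "cost_parameters"))
  W <- contacts$wins
  D <- contacts$draws
  f <- costs$p_win * W + costs$p_loss * t(W) + costs$p_draw * D
  # diagonal: each overgrowth event is one win plus one loss within the
  # species; one recorded tie costs two colonies
  diag(f) <- (costs$p_win + costs$p_loss) * diag(W) +
    costs$p_draw * 2 * diag(D)
  structure(list(species = contacts$species, f = f, costs = costs),
            class = "energy_loss_web")
}

#' @export
print.energy_loss_web <- function(x, ...) {
  cat(sprintf("Energy-loss web: %d species, total loss rate %.3g biomass/time\n",
              length(x$species), sum(x$f)))
  invisible(x)
}

#' Jacobian community matrix from an energy-loss web
#'
#' Per-capita interaction strengths at the (assumed) steady state are
#' `a_ij = f_ij / B_j`: the loss rate of species i attributable to species j,
#' per colony of species j. Diagonal entries that are zero because no
#' intraspecific contest was observed (common for rare species) are filled
#' with `diag_fill_factor` times the mean Jacobian element, and flagged.
#'
#' @param web an [energy_loss_web].
#' @param abundance per-species colony counts in the species order of `web`
#'   (e.g. `contacts$abundance`). All entries must be >= 1.
#' @param diag_fill_factor proportionality constant for filling unobserved
#'   diagonals (default 0.1, the main-analysis configuration).
#' @param fill_mean `"nonzero"` (default) takes the fill mean over the
#'   non-zero pre-fill Jacobian entries; `"all"` over all S^2 entries
#'   including structural zeros. The two differ by a factor equal to the
#'   filled fraction of the matrix; the sensitivity sweep compares them.
#' @return An object of class `jacobian_matrix` with fields `species`, `a`,
#'   `diag_estimated` (logical, per species), `diag_fill_factor`, `fill_mean`.
#' @export
jacobian <- function(web, abundance, diag_fill_factor = 0.1,
                     fill_mean = c("nonzero", "all")) {
  stopifnot(inherits(web, "energy_loss_web"))
  fill_mean <- match.arg(fill_mean)
  if (diag_fill_factor <= 0) stop("diag_fill_factor must be positive")
  B <- as.numeric(abundance)
  if (length(B) != length(web$species)) {
    stop("domain error: abundance must have one entry per species")
  }
  if (any(!is.finite(B)) || any(B < 1)) {
    stop("domain error: zero or missing abundance")
  }
  a <- sweep(web$f, 2, B, "/")
  if (all(a == 0)) {
    stop("all-zero matrix: no contests anywhere, cannot define a fill mean")
  }
  m <- if (fill_mean == "nonzero") mean(a[a != 0]) else mean(a)
  diag_estimated <- diag(a) == 0
  diag(a)[diag_estimated] <- diag_fill_factor * m
  if (any(diag(a) >= 0)) {
    stop("diagonal filling produced a non-negative self-regulation term")
  }
  structure(
    list(species = web$species, a = a, diag_estimated = diag_estimated,
         diag_fill_factor = diag_fill_factor, fill_mean = fill_mean),
    class = "jacobian_matrix")
}

#' @export
print.jacobian_matrix <- function(x, ...) {
  cat(sprintf(
    "Jacobian community matrix: %d species, %d filled diagonal(s) (factor %g)\n",
    length(x$species), sum(x$diag_estimated), x$diag_fill_factor))
  invisible(x)
}

#' Row-normalise a Jacobian matrix
#'
#' Divides each row by the magnitude of its diagonal term, giving the
#' dimensionless community matrix with uniform diagonal -1. Normalisation
#' transfers the diagonal structure onto the off-diagonal elements, so that
#' manipulation experiments on the off-diagonals leave the self-regulation
#' structure untouched; it preserves the sign pattern, the feedback-loop
#' weights, and (for these matrices, very closely) the critical level of
#' self-regulation. Idempotent.
#'
#' @param J a `jacobian_matrix`, `normalized_matrix`, or plain square matrix
#'   with strictly negative diagonal.
#' @return An object of class `normalized_matrix` with fields `species` and
#'   `abar` (diagonal exactly -1).
#' @export
normalize_community <- function(J) {
  m <- comp_matrix(J)
  stopifnot_square(m, "Jacobian")
  if (any(diag(m) == 0)) {
    stop("domain error: zero diagonal entry; run diagonal filling first ",
         "(see jacobian())")
  }
  if (any(diag(m) > 0)) stop("domain error: positive self-regulation term")
  abar <- m / abs(diag(m))
  diag(abar) <- -1
  structure(list(species = comp_species(J), abar = abar),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Normalised community matrix: %d species, diagonal -1\n",
              length(x$species)))
  invisible(x)
}

#' Write a loss web or Jacobian as CSV with a JSON provenance sidecar
#'
#' The matrix goes to `path` as a headed CSV; the parameters that produced it
#' (cost parameters, fill factor, fill-mean convention) go to `<path>.json`.
#'
#' @param x an `energy_loss_web` or `jacobian_matrix`.
#' @param path output CSV path.
#' @return Invisibly, `x`.
#' @export
write_web_csv <- function(x, path) {
  m <- comp_matrix(x)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  meta <- if (inherits(x, "energy_loss_web")) {
    list(type = "energy_loss_web", costs = unclass(x$costs))
  } else if (inherits(x, "jacobian_matrix")) {
    list(type = "jacobian_matrix", diag_fill_factor = x$diag_fill_factor,
         fill_mean = x$fill_mean,
         diag_estimated = x$species[x$diag_estimated])
  } else {
    list(type = class(x)[1])
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(x)
}
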