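#' Real part of the dominant eigenvalue
#'
#' The dominant eigenvalue is the one with the largest real part; a negative
#' value means all perturbations of the steady state decay, i.e. local
#' asymptotic stability.
#'
#' @param M a square real matrix (or `jacobian_matrix` / `normalized_matrix`).
#' @return `max(Re(eigenvalues))`.
#' @export
dominant_eigenvalue <- function(M) {
  m <- comp_matrix(M)
  stopifnot_square(m)
  max(Re(eigen(m, only.values = TRUE)$values))
}

# Re(lambda_d) of M with its diagonal multiplied by s
scaled_diag_relambda <- function(m, s) {
  d <- diag(m)
  diag(m) <- s * d
  max(Re(eigen(m, only.values = TRUE)$values))
}

#' Critical level of self-regulation by bisection
#'
#' Finds the multiplier `s*` of the Jacobian diagonal at which the dominant
#' eigenvalue's real part crosses zero: the factor by which observed
#' intraspecific interaction strength must be multiplied to reach the
#' stability threshold. `s* > 1` means the observed self-damping is
#' insufficient (unstable system); `s* < 1` measures buffering capacity.
#'
#' The bracket is grown geometrically from `s = 1` (doubling or halving
#' until the stability indicator flips), then refined by bisection until
#' `|Re(lambda_d)| < tol`. The bisection assumes a single sign change along
#' the bracket; the converged root is cross-checked by evaluating the
#' indicator just below and above `s*`, and a fine grid scan locates the
#' smallest crossing if the check fails (the crossing need not be monotone
#' for arbitrary matrices).
#'
#' @param J a `jacobian_matrix`, `normalized_matrix` or square matrix with
#'   strictly negative diagonal.
#' @param tol convergence tolerance on `Re(lambda_d)` (default 1e-8).
#' @return An object of class `stability_result`: a list with
#'   `re_lambda_d` (at the observed matrix, s = 1), `s_star`, `method`,
#'   `tolerance`, `marginal`, and `agreement_gap` (`NA` here; filled when
#'   both routes are compared).
#' @export
critical_self_regulation <- function(J, tol = 1e-8) {
  m <- comp_matrix(J)
  stopifnot_square(m)
  if (any(diag(m) >= 0)) stop("domain error: diagonal must be strictly negative")
  if (tol <= 0) stop("tol must be positive")
  re1 <- scaled_diag_relambda(m, 1)

  if (all(m[row(m) != col(m)] == 0)) {
    # no interspecific feedback at all: any positive self-damping stabilises
    return(new_stability_result(re1, 0, "bisection", tol, marginal = FALSE))
  }
  if (abs(re1) < tol) {
    return(new_stability_result(re1, 1, "bisection", tol, marginal = TRUE))
  }

  # bracket [lo, hi] with g(lo) > 0 (unstable) and g(hi) < 0 (stable)
  if (re1 > 0) {
    lo <- 1; hi <- 2
    n <- 0
    while (scaled_diag_relambda(m, hi) > 0) {
      lo <- hi; hi <- hi * 2; n <- n + 1
      if (n > 60) {
        stop("failed to bracket s* within 60 doublings: the matrix cannot be ",
             "stabilised by diagonal scaling alone (Re(lambda_d) = ",
             signif(scaled_diag_relambda(m, hi / 2), 6), " at s = ", hi / 2, ")")
      }
    }
  } else {
    hi <- 1; lo <- 0.5
    n <- 0
    while (scaled_diag_relambda(m, lo) < 0) {
      hi <- lo; lo <- lo / 2; n <- n + 1
      if (n > 60) {
        # stable all the way down: s* is numerically zero
        return(new_stability_result(re1, 0, "bisection", tol, marginal = FALSE))
      }
    }
  }
  s_star <- bisect_root(m, lo, hi, tol)

  # verify instability just below and stability just above the root
  eps <- 10 * tol
  below <- scaled_diag_relambda(m, s_star * (1 - eps))
  above <- scaled_diag_relambda(m, s_star * (1 + eps))
  if (below < -tol || above > tol) {
    # non-monotone indicator: locate the smallest crossing on a fine grid
    grid <- seq(0, max(1, s_star) * 1.05, length.out = 2001)[-1]
    g <- vapply(grid, function(s) scaled_diag_relambda(m, s), numeric(1))
    flips <- which(g[-length(g)] > 0 & g[-1] <= 0)
    if (length(flips) > 0) {
      s_star <- bisect_root(m, grid[flips[1]], grid[flips[1] + 1], tol)
    }
  }
  new_stability_result(re1, s_star, "bisection", tol, marginal = FALSE)
}

bisect_root <- function(m, lo, hi, tol) {
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    g <- scaled_diag_relambda(m, mid)
    if (abs(g) < tol || (hi - lo) < tol * max(1, mid)) return(mid)
    if (g > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

new_stability_result <- function(re_lambda_d, s_star, method, tol,
                                 marginal = FALSE, agreement_gap = NA_real_) {
  structure(
    list(re_lambda_d = re_lambda_d, s_star = s_star, method = method,
         tolerance = tol, marginal = marginal, agreement_gap = agreement_gap),
    class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  state <- if (x$marginal) "marginal" else if (x$s_star > 1) "unstable" else "stable"
  cat(sprintf("s* = %s (%s, %s method)", signif(x$s_star, 6), state, x$method))
  if (!is.na(x$agreement_gap)) {
    cat(sprintf("; bisection/shortcut gap %.2g", x$agreement_gap))
  }
  cat("\n")
  invisible(x)
}

#' Critical self-regulation of a normalised matrix (eigenvalue shortcut)
#'
#' For a community matrix with uniform diagonal -1, `s*` equals the maximum
#' real part of the eigenvalues of the matrix with its diagonal set to zero.
#' When the source Jacobian is supplied, the shortcut is compared against
#' the bisection route on the Jacobian and the absolute gap is reported; a
#' warning is raised when the relative gap exceeds 1e-3. The two routes
#' agree exactly when the stability transition passes through a real
#' eigenvalue (always the case for a uniform diagonal); for strongly
#' heterogeneous diagonals the transition can be an imaginary-pair crossing
#' and the gap is then real information, not numerical error.
#'
#' @param N a `normalized_matrix` (or square matrix with diagonal all -1).
#' @param J optional source `jacobian_matrix` for the agreement check.
#' @param tol tolerance used for the bisection cross-check.
#' @return A `stability_result` with `method = "normalized_shortcut"`.
#' @export
critical_self_regulation_normalized <- function(N, J = NULL, tol = 1e-8) {
  m <- comp_matrix(N)
  stopifnot_square(m)
  if (any(abs(diag(m) + 1) > 1e-9)) {
    stop("domain error: diagonal must be uniformly -1 (normalise first)")
  }
  a0 <- m
  diag(a0) <- 0
  s_star <- max(Re(eigen(a0, only.values = TRUE)$values))
  re1 <- dominant_eigenvalue(m)
  gap <- NA_real_
  if (!is.null(J)) {
    bis <- critical_self_regulation(J, tol = tol)
    gap <- abs(bis$s_star - s_star)
    if (gap > 1e-3 * max(abs(bis$s_star), .Machine$double.eps)) {
      warning(sprintf(
        "normalised-shortcut s* (%.6g) and bisection s* (%.6g) disagree by %.3g (relative %.3g)",
        s_star, bis$s_star, gap, gap / abs(bis$s_star)))
    }
  }
  new_stability_result(re1, s_star, "normalized_shortcut", tol,
                       marginal = abs(re1) < tol, agreement_gap = gap)
}

#' Cost-scenario sensitivity sweep
#'
#' Recomputes the full chain (loss web, Jacobian, s*) for every assemblage
#' under every cost scenario and diagonal-fill factor, and checks whether the
#' scenarios agree on the relative stability of the assemblages: instability
#' counts per scenario and the Spearman rank correlation of s* between every
#' scenario pair are reported.
#'
#' @param contacts_list a list of [contact_data] objects (>= 1).
#' @param scenarios a list of >= 2 [cost_parameters] objects; names are used
#'   as scenario labels.
#' @param diag_fill_factors numeric vector of fill factors (default 0.1).
#' @param fill_mean fill-mean convention passed to [jacobian()]; may be a
#'   vector to compare both conventions.
#' @return A list with `results` (data.frame: assemblage_id, scenario,
#'   fill_factor, fill_mean, s_star, unstable), `instability_counts`, and
#'   `rank_agreement` (data.frame of Spearman correlations per scenario pair
#'   and fill configuration).
#' @export
sensitivity_sweep <- function(contacts_list, scenarios,
                              diag_fill_factors = 0.1,
                              fill_mean = "nonzero") {
  if (inherits(contacts_list, "contact_data")) contacts_list <- list(contacts_list)
  if (length(contacts_list) < 1) stop("need at least one assemblage")
  if (length(scenarios) < 2) stop("need at least two cost scenarios")
  for (sc in scenarios) {
    if (!inherits(sc, "cost_parameters")) {
      stop("validation error: every scenario must be a cost_parameters object")
    }
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  ids <- vapply(contacts_list, function(cd) cd$assemblage_id, character(1))
  if (anyDuplicated(ids)) {
    stop("assemblage_id values must be unique across the sweep")
  }
  grid <- expand.grid(scenario = names(scenarios),
                      fill_factor = diag_fill_factors,
                      fill_mean = fill_mean,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sc <- scenarios[[grid$scenario[g]]]
    s_star <- vapply(contacts_list, function(cd) {
      J <- jacobian(energy_loss_web(cd, sc), cd$abundance,
                    diag_fill_factor = grid$fill_factor[g],
                    fill_mean = grid$fill_mean[g])
      critical_self_regulation(J)$s_star
    }, numeric(1))
    data.frame(assemblage_id = ids, scenario = grid$scenario[g],
               fill_factor = grid$fill_factor[g], fill_mean = grid$fill_mean[g],
               s_star = s_star, unstable = s_star > 1,
               stringsAsFactors = FALSE)
  }))
  counts <- stats::aggregate(unstable ~ scenario + fill_factor + fill_mean,
                             data = res, FUN = sum)
  names(counts)[names(counts) == "unstable"] <- "n_unstable"

  # rank agreement of s* between scenario pairs within each fill configuration
  agreement <- NULL
  for (ff in unique(res$fill_factor)) for (fm in unique(res$fill_mean)) {
    sub <- res[res$fill_factor == ff & res$fill_mean == fm, ]
    wide <- stats::reshape(sub[, c("assemblage_id", "scenario", "s_star")],
                           idvar = "assemblage_id", timevar = "scenario",
                           direction = "wide")
    scen <- sub("^s_star\\.", "", names(wide)[-1])
    if (length(scen) >= 2) {
      for (i in seq_len(length(scen) - 1)) for (j in (i + 1):length(scen)) {
        rho <- stats::cor(wide[[i + 1]], wide[[j + 1]], method = "spearman")
        agreement <- rbind(agreement, data.frame(
          scenario_a = scen[i], scenario_b = scen[j], fill_factor = ff,
          fill_mean = fm, spearman_rho = rho, stringsAsFactors = FALSE))
      }
    }
  }
  list(results = res, instability_counts = counts, rank_agreement = agreement)
}
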