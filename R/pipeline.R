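#' Full stability analysis of a set of assemblages
#'
#' Runs the complete chain per assemblage — loss web, Jacobian with diagonal
#' filling, critical self-regulation s* by bisection (with the
#' normalised-shortcut agreement gap), the heaviest 2-link loop weight,
#' pairwise and community asymmetry of the interaction strengths, the win
#' index and the triad intransitivity index — and, when at least three
#' assemblages are supplied, fits the ordinary least-squares regression of
#' s* on w2_max that summarises how the strongest pairwise feedback governs
#' relative instability.
#'
#' @param contacts_list a [contact_data] object or list of them.
#' @param costs a [cost_parameters] object.
#' @param diag_fill_factor,fill_mean passed to [jacobian()].
#' @param exact_order_limit passed to [community_asymmetry()] as
#'   `exact_limit`.
#' @return An object of class `competition_analysis`: a list with `records`
#'   (one data.frame row per assemblage: assemblage_id, S, connectance,
#'   s_star, re_lambda_d, s_star_shortcut, agreement_gap, w2max,
#'   pairwise_asymmetry, community_asymmetry, win_index, intransitivity,
#'   n_diag_estimated) and `regression` (slope, intercept, r_squared, n; or
#'   NULL when n < 3).
#' @export
analyze <- function(contacts_list, costs = cost_parameters(),
                    diag_fill_factor = 0.1, fill_mean = "nonzero",
                    exact_order_limit = 9) {
  if (inherits(contacts_list, "contact_data")) contacts_list <- list(contacts_list)
  if (length(contacts_list) < 1) stop("need at least one assemblage")
  records <- do.call(rbind, lapply(contacts_list, function(cd) {
    tryCatch({
      J <- jacobian(energy_loss_web(cd, costs), cd$abundance,
                    diag_fill_factor = diag_fill_factor,
                    fill_mean = fill_mean)
      bis <- critical_self_regulation(J)
      short <- suppressWarnings(
        critical_self_regulation_normalized(normalize_community(J)))
      ca <- community_asymmetry(J, exact_limit = exact_order_limit)
      wi <- tryCatch(as.numeric(win_index(cd)), error = function(e) NA_real_)
      ii <- if (length(cd$species) >= 3) {
        as.numeric(intransitivity_index(J))
      } else NA_real_
      data.frame(
        assemblage_id = cd$assemblage_id,
        S = length(cd$species),
        connectance = connectance(cd),
        s_star = bis$s_star,
        re_lambda_d = bis$re_lambda_d,
        s_star_shortcut = short$s_star,
        agreement_gap = abs(bis$s_star - short$s_star),
        w2max = max_two_link_loop_weight(J),
        pairwise_asymmetry = as.numeric(pairwise_asymmetry(J)),
        community_asymmetry = ca$ratio,
        win_index = wi,
        intransitivity = ii,
        n_diag_estimated = sum(J$diag_estimated),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      stop(sprintf("assemblage '%s': %s", cd$assemblage_id,
                   conditionMessage(e)), call. = FALSE)
    })
  }))
  regression <- if (nrow(records) >= 3) {
    ols_summary(records$s_star, records$w2max)
  } else NULL
  structure(list(records = records, regression = regression),
            class = "competition_analysis")
}

ols_summary <- function(y, x) {
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(y))
}

#' @export
print.competition_analysis <- function(x, ...) {
  r <- x$records
  cat(sprintf("Competition-network analysis of %d assemblage(s)\n", nrow(r)))
  cat(sprintf("  unstable (s* > 1): %d of %d\n", sum(r$s_star > 1), nrow(r)))
  cat(sprintf("  s* range: %.3g - %.3g; w2max range: %.3g - %.3g\n",
              min(r$s_star), max(r$s_star), min(r$w2max), max(r$w2max)))
  if (!is.null(x$regression)) {
    cat(sprintf("  OLS s* ~ w2max: slope %.3g, intercept %.3g, R^2 %.3g (n = %d)\n",
                x$regression$slope, x$regression$intercept,
                x$regression$r_squared, x$regression$n))
  }
  invisible(x)
}

#' Randomisation experiment on one assemblage
#'
#' Normalises the assemblage's Jacobian and generates `reps` manipulated
#' matrices for each requested kind (`full`, `weak`, `minimal`,
#' `restore_pairwise`, `restore_community` — the last applies the pairwise
#' restoration first), computing s* (via the normalised shortcut, exact for
#' the uniform -1 diagonal), the heaviest 2-link loop, and both asymmetry
#' indices for every matrix. Across each kind's ensemble plus the source
#' matrix it fits the OLS regressions of s* on pairwise asymmetry, on
#' w2_max, and on community asymmetry, and summarises the loop-weight
#' spectrum per kind over a subsample of replicates.
#'
#' @param contacts a [contact_data] object (or a ready `normalized_matrix`).
#' @param kinds subset of `c("full", "weak", "minimal", "restore_pairwise",
#'   "restore_community")`.
#' @param reps replicates per kind (>= 2).
#' @param costs,diag_fill_factor passed down when `contacts` is contact data.
#' @param ca_restarts hill-climb restarts for per-replicate community
#'   asymmetry (heuristic mode is used for speed across ensembles).
#' @param spectrum_reps replicates per kind entering the loop-weight
#'   spectrum summary (default 20).
#' @param seed optional integer seed.
#' @return An object of class `randomization_experiment`: list with
#'   `source` (metrics of the unmanipulated matrix), `ensemble` (data.frame:
#'   kind, replicate, s_star, w2max, pairwise_asymmetry,
#'   community_asymmetry), `regressions` (per response, across source +
#'   all replicates of each kind), and `spectra` (data.frame: kind, k,
#'   median and max of the per-length maximum loop weight).
#' @export
randomization_experiment <- function(contacts,
                                     kinds = c("full", "weak", "minimal",
                                               "restore_pairwise",
                                               "restore_community"),
                                     reps = 100,
                                     costs = cost_parameters(),
                                     diag_fill_factor = 0.1,
                                     ca_restarts = 5,
                                     spectrum_reps = 20,
                                     seed = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (reps < 2) stop("reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  N <- if (inherits(contacts, "contact_data")) {
    normalize_community(jacobian(energy_loss_web(contacts, costs),
                                 contacts$abundance,
                                 diag_fill_factor = diag_fill_factor))
  } else if (inherits(contacts, "normalized_matrix")) {
    contacts
  } else {
    normalize_community(contacts)
  }
  # weak/minimal/restorations need fully reciprocal links; fail fast
  invisible(extract_pairs(comp_matrix(N)))

  metrics <- function(M, exact_ca = FALSE) {
    m <- comp_matrix(M)
    c(s_star = max(Re(eigen("diag<-"(m, 0), only.values = TRUE)$values)),
      w2max = max_two_link_loop_weight(M),
      pairwise_asymmetry = as.numeric(pairwise_asymmetry(M)),
      community_asymmetry = if (exact_ca) {
        community_asymmetry(M)$ratio
      } else {
        community_asymmetry(M, exact_limit = 0, restarts = ca_restarts)$ratio
      })
  }
  manipulate <- function(kind) {
    switch(kind,
           full = full_randomize(N),
           weak = weak_randomize(N),
           minimal = minimal_randomize(N),
           restore_pairwise = restore_pairwise_asymmetry(N),
           restore_community = restore_community_asymmetry(
             restore_pairwise_asymmetry(N)))
  }

  src <- metrics(N, exact_ca = TRUE)
  ensemble <- NULL
  spectra <- NULL
  for (kind in kinds) {
    mats <- lapply(seq_len(reps), function(r) manipulate(kind))
    met <- t(vapply(mats, metrics, numeric(4)))
    ensemble <- rbind(ensemble, data.frame(
      kind = kind, replicate = seq_len(reps), met, stringsAsFactors = FALSE))
    spec_sub <- mats[seq_len(min(spectrum_reps, reps))]
    sp <- do.call(rbind, lapply(spec_sub, function(m) {
      s <- max_loop_weight_per_length(m)
      data.frame(k = s$k, w = s$max_weight)
    }))
    agg_med <- stats::aggregate(w ~ k, sp, stats::median)
    agg_max <- stats::aggregate(w ~ k, sp, max)
    spectra <- rbind(spectra, data.frame(
      kind = kind, k = agg_med$k, median_max_weight = agg_med$w,
      max_max_weight = agg_max$w, stringsAsFactors = FALSE))
  }
  # per-kind regressions of s* on each structural metric, across that kind's
  # replicates plus the (one) source matrix
  regressions <- lapply(stats::setNames(kinds, kinds), function(kind) {
    sub <- ensemble[ensemble$kind == kind, ]
    lapply(c(pairwise_asymmetry = "pairwise_asymmetry", w2max = "w2max",
             community_asymmetry = "community_asymmetry"),
           function(v) {
             ols_summary(c(src[["s_star"]], sub$s_star),
                         c(src[[v]], sub[[v]]))
           })
  })
  src_spectrum <- max_loop_weight_per_length(N)
  structure(
    list(source = as.list(src), source_spectrum = src_spectrum,
         ensemble = ensemble, regressions = regressions, spectra = spectra,
         seed = seed),
    class = "randomization_experiment")
}

#' @export
print.randomization_experiment <- function(x, ...) {
  cat("Randomisation experiment\n")
  cat(sprintf("  source: s* = %.4g, w2max = %.4g\n",
              x$source$s_star, x$source$w2max))
  med <- stats::aggregate(s_star ~ kind, x$ensemble, stats::median)
  for (i in seq_len(nrow(med))) {
    cat(sprintf("  %-18s median s* = %.4g\n", med$kind[i], med$s_star[i]))
  }
  invisible(x)
}
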