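# internal helpers shared across modules

# coerce matrix-bearing objects to a plain numeric matrix
comp_matrix <- function(x) {
  if (inherits(x, "jacobian_matrix")) return(x$a)
  if (inherits(x, "normalized_matrix")) return(x$abar)
  if (inherits(x, "energy_loss_web")) return(x$f)
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("expected a matrix, jacobian_matrix, normalized_matrix or energy_loss_web")
}

comp_species <- function(x) {
  if (is.list(x) && !is.null(x$species)) return(x$species)
  m <- comp_matrix(x)
  if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
}

# rebuild an object of the same flavour as `template` around a new matrix
comp_rewrap <- function(template, m) {
  if (inherits(template, "normalized_matrix")) {
    out <- template
    out$abar <- m
    return(out)
  }
  if (inherits(template, "jacobian_matrix")) {
    out <- template
    out$a <- m
    return(out)
  }
  m
}

stopifnot_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be square, got %s x %s", what,
                 NROW(m), NCOL(m)))
  }
  if (any(!is.finite(m))) stop(sprintf("%s contains non-finite entries", what))
  invisible(m)
}

# indices of all off-diagonal positions with non-zero value
offdiag_nonzero <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  idx[idx[, 1] != idx[, 2], , drop = FALSE]
}

# unordered reciprocal position pairs (i < j with both m[i,j], m[j,i] != 0);
# errors on one-sided links, which have no pair
reciprocal_pairs <- function(m, require_all_paired = FALSE) {
  S <- nrow(m)
  up <- which(upper.tri(m), arr.ind = TRUE)
  both <- m[up] != 0 & m[cbind(up[, 2], up[, 1])] != 0
  one_sided <- xor(m[up] != 0, m[cbind(up[, 2], up[, 1])] != 0)
  if (require_all_paired && any(one_sided)) {
    bad <- up[which(one_sided)[1], ]
    stop(sprintf(
      "one-sided non-zero link between species %d and %d: pairs are undefined",
      bad[1], bad[2]))
  }
  up[both, , drop = FALSE]
}

# all permutations of 1..n as an n!-row matrix (recursive, n <= 10 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- nrow(sub)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * r + 1L):(k * r)
    out[rows, 1L] <- k
    remaining <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(remaining[sub], nrow = r)
  }
  out
}

# deterministic per-replicate seed derivation, kept below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) %% 1000003) * 2048 + (index %% 2048) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
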