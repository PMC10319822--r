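---
title: "From overgrowth contests to network stability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From overgrowth contests to network stability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compstab)
```

## The model

`compstab` analyses the local stability of interference-competition
networks — communities of sessile organisms (the motivating system is
encrusting bryozoans) in which colonies compete for space by overgrowing
each other. Every pairwise contest ends in a win/loss or a draw, and every
outcome costs both parties energy. The analysis chain is:

1. **Species-contact matrices.** Field observations are summarised as a win
   matrix `W` (`W[i, j]` = contests in which a colony of species `i`
   overgrew one of `j`), a symmetric draw matrix `D`, and colony abundances
   `B`. `contact_data()` validates these; `read_contacts()` /
   `write_contacts()` handle a long TSV dialect and a wide matrix dialect.

2. **Energy-loss webs.** Each species' loss rate from each opponent is a
   cost-weighted outcome sum, `f[i, j] = p_win W[i, j] + p_loss W[j, i] +
   p_draw D[i, j]`, in biomass per time with colony biomass fixed at 1. On
   the diagonal, an intraspecific overgrowth event is simultaneously a win
   and a loss for the species, and a recorded intraspecific tie is doubled
   because it costs two colonies.

3. **Jacobian community matrix.** Under a Lotka-Volterra competition model
   with linear functional responses, assuming the observed system is at
   steady state with abundances `B`, the per-capita interaction strengths
   reduce to `a[i, j] = f[i, j] / B[j]` (units 1/time). The unobservable
   growth rates and competition coefficients cancel in this substitution
   and never appear in the code.

4. **Stability.** The system is locally stable iff the dominant eigenvalue
   of the Jacobian has negative real part. To compare systems on different
   time scales we use the dimensionless critical level of self-regulation
   `s*`: the factor by which the diagonal must be multiplied to sit exactly
   on the stability threshold. `s* > 1` flags an unstable system; `s* < 1`
   measures buffering capacity.

5. **Feedback structure.** The stability results are interpreted through
   feedback-loop weights `w^(k)`: the geometric mean magnitude of the links
   around a length-`k` simple directed cycle, scaled by the members'
   self-regulation terms. With all links negative, even-length loops are
   positive (self-reinforcing, destabilising) and odd-length loops negative
   (self-dampening). The heaviest 2-link loop, `w2max`, fully determines
   stability in the 2-species case and empirically governs relative
   instability in larger competition networks; hierarchy metrics (pairwise
   and community asymmetry, win index, triad intransitivity) quantify the
   organisation that keeps loops weak.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `p_win` | -0.1 | biomass/colony/time | cost of winning a contest |
| `p_loss` | -0.9 | biomass/colony/time | cost of being overgrown |
| `p_draw` | -0.2 | biomass/colony/time | cost of a tie, per colony |
| `diag_fill_factor` | 0.1 | — | unobserved self-regulation as a fraction of the mean Jacobian element |
| `fill_mean` | `"nonzero"` | — | whether the fill mean ignores structural zeros |
| `exact_limit` (loops) | 14 | species | largest S for the exact subset DP |
| `exact_limit` (ordering) | 9 | species | largest S for exhaustive order search |
| `sigma` | 0.8 | — | half-normal scale of random interaction strengths |

The cost values encode that losing (being overgrown) is far more expensive
than winning; the sensitivity sweep (`sensitivity_sweep()`,
`analysis/05_sensitivity.R`) re-runs the whole chain under alternative
splits — including a deliberately inverted one — and reports instability
counts and Spearman rank agreement of `s*` rather than assuming
insensitivity. One sign convention deserves note: all three costs are
losses and are required to be `<= 0`, so a draw's cost is `-0.2`; a loss
web is everywhere non-positive by construction.

Missing diagonal estimates are common because intraspecific contests are
rarely observed in low-abundance species. The fill mean is taken over the
non-zero pre-fill Jacobian entries by default; the alternative
(`fill_mean = "all"`) dilutes the mean by the zero fraction and is included
in the sensitivity sweep so the choice is checked, not assumed.

## Computing s*: bisection versus the normalised shortcut

`critical_self_regulation()` scales the diagonal by `s`, brackets the sign
change of `Re(lambda_d)` by geometric expansion from `s = 1`, and bisects
to a tolerance of 1e-8 on the eigenvalue's real part (up to 60 doublings;
failure to bracket is reported as such). Bisection assumes a single
crossing along the bracket, which no theorem guarantees here, so after
convergence the code verifies instability just below and stability just
above the root and falls back to a fine grid scan when the check fails.
Marginal systems (`|Re(lambda_d)| <` tolerance at `s = 1`) are reported as
`s* = 1` with a flag.

`critical_self_regulation_normalized()` uses the shortcut: for a
row-normalised matrix (uniform diagonal -1), `s*` is the maximum real part
of the eigenvalues of the matrix with zero diagonal. For a uniform
diagonal the identity is exact — scaling the diagonal shifts every
eigenvalue of the off-diagonal part rigidly — which is why the package's
cross-validation of the bisection machinery runs on normalised matrices.

For *heterogeneous* diagonals the two routes genuinely differ: the
stability transition can occur through a complex-conjugate pair, in which
case `det(sD + O) = 0` has no real root at the transition and the shortcut
(a real eigenvalue of the zero-diagonal normalised matrix) cannot coincide
with it. In our own synthetic ensembles the relative gap is usually below
1e-6 but reaches the percent-to-tens-of-percent range in a minority of
webs. `analyze()` therefore reports both values and their gap per
assemblage, and `critical_self_regulation_normalized(N, J = ...)` warns
when the relative gap exceeds 1e-3. The shortcut is used as the primary
route only where it is exact: ensembles of manipulated normalised
matrices.

## Loop-weight maxima: exact dynamic programme and its oracle

Loop weight is invariant under row normalisation, so
`max_loop_weight_per_length()` searches on the log-magnitudes of the
normalised matrix (log-domain arithmetic, `-Inf` for absent links, avoids
underflow in long loops). For each anchor vertex (the lowest-index member
of a cycle) a bitmask dynamic programme over vertex subsets propagates the
best path log-weight per (subset, endpoint); closing edges yield the
per-length maxima, and parent pointers recover the argmax cycle. The cost
grows as `2^S S^2`, which in pure R is practical to about `S = 14` —
comfortably above the 5-11 species of the study systems — so that is the
default `exact_limit`; beyond it a uniform random simple-cycle sampler
provides flagged lower bounds. A directed cycle and its reverse are
distinct traversals and both are searched; ties resolve to whichever is
found first.

The DP is verified against two independent routes: the package's own
depth-first exhaustive enumeration (`max_loop_weight_brute()`) and, in the
test suite, cycle enumeration built on igraph's simple-path search.

## Community asymmetry: a linear-ordering problem

Community asymmetry maximises, over species orderings, the ratio of mean
below-diagonal to mean above-diagonal non-zero magnitude. The exhaustive
search evaluates all `S!` orderings — vectorised across permutations per
matrix entry, practical to the default `exact_limit = 9` (9! ≈ 3.6e5
orderings in well under a second) — while larger systems use a
first-improvement hill-climb over pairwise transpositions from 50 starts
(the first at the dominance-rank order: species ordered by inflicted-minus-
suffered magnitude), flagged `heuristic` and interpretable as a lower
bound. Tests require the heuristic to recover the exact optimum on at
least 95% of small random instances. Inside ensemble randomisation
experiments the per-replicate index uses the heuristic with 5 restarts:
across thousands of replicates the exhaustive search would dominate
runtime while the replicate-to-replicate variation being measured is far
larger than the heuristic's rare shortfall.

## Null models and restorations

All five manipulations preserve the zero pattern, the diagonal, and the
multiset of non-zero off-diagonal values; each is checked on every output
in the tests. *Full* randomisation permutes all non-zero off-diagonal
values. *Weak* randomisation relocates reciprocal value pairs as units
with random orientation, preserving every 2-link loop; *minimal*
randomisation additionally keeps each pair's stronger member on its source
side of the diagonal, preserving the below/above value multisets and hence
community asymmetry at the source ordering. The two restorations re-pair
the value multiset strongest-with-weakest (which provably minimises the
heaviest 2-link loop for the given values; the suite confirms this against
brute-force enumeration of all pairings) and then, optionally, orient
every strong member below the diagonal. Weak randomisation randomises the
orientation within position pairs — orientation preservation is exactly
what distinguishes the minimal variant, so the two modes span both
readings of "reshuffling pairs".

Random competition matrices follow the May-style construction: fixed
diagonal (-1), independent pair activation at probability `C` (expected,
not exact, connectance), and link magnitudes `|Normal(0, sigma)|` negated;
`sigma` is a scale and is used as its magnitude 0.8. The `asymmetric` and
`symmetric` pairings sort the drawn magnitudes and couple
strongest-with-weakest or adjacent-in-order respectively.

## The synthetic generator

`generate_assemblage()` emulates the features of the field data that
matter to the pipeline: 5-11 species; connectance near 0.9; a dominance
hierarchy on distinct ranks whose decisiveness is a single logistic knob
`beta` (0 = coin-flip contests, large = strict transitive hierarchy,
default 1.5 which lands the win index in the observed 0.63-0.96 envelope
for most draws); draws at probability 0.2; contest counts scaling with the
geometric mean of the pair's abundances; log-normal abundances whose mean
declines with competitive ability (`abundance_gradient = -0.3`), making
weak competitors the abundant opportunists; and Poisson intraspecific
contests proportional to abundance, so rare species routinely lack
self-regulation estimates and exercise the diagonal-fill path. Rank-based
logistic dominance is the simplest mechanism producing the observed
continuum from noisy to near-perfect hierarchies with one knob.

What the generator does *not* emulate: spatial structure and colony
geometry, temporal dynamics, size-dependent contest outcomes, and
between-assemblage species overlap. Passing tests on synthetics therefore
validate the computational chain and the direction of structural effects,
not any quantitative claim about real assemblages.

Ensembles derive per-replicate seeds deterministically from
`(seed, index)`, so every experiment is reproducible from its parameters.

## Test and experiment design choices

The suite's ensemble-level claims are formulated at the population level:
for example, the ordering of median `s*` across manipulation intensities
(source <= minimal <= weak <= full) is evaluated over 500 draws each
generating a fresh steep-hierarchy assemblage, because for a single fixed
source the source-versus-minimal comparison can go either way (we measured
roughly a quarter of individual sources violating it) while the population
medians separate cleanly. Problem sizes in the default runs — 30
assemblages of 5-11 species, 500-1000 replicates per manipulation, 100
matrices per random-matrix cell — were chosen to keep every experiment
comfortably within an interactive desk session while leaving the
ensemble-level orderings far from their decision boundaries.

## Known limitations

- The analysis is local asymptotic stability only: no transients,
  reactivity, or permanence.
- `s*` by bisection inherits the single-crossing assumption; the grid-scan
  fallback reduces, but cannot eliminate, the risk of landing on a
  non-smallest root for pathological spectra.
- Total feedback at each level (the Levins-style alternating sums over
  disjunct loop sets) is not computed; the package works with per-length
  loop-weight *maxima*, plus sampled lower bounds above the exact limit.
- The heuristic community-asymmetry search is a lower bound for S > 9.
- The triad intransitivity index is an operational variant defined on
  Jacobian magnitudes; it is labelled as such in its output and is not a
  reproduction of any published competition-coefficient index.
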