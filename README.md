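# compstab

Stability and feedback structure of interference-competition networks.

Sessile encrusting animals such as bryozoans compete for space by
overgrowing each other's colonies. Every contest — win, loss or draw —
costs both parties energy, and in diverse assemblages these contests form
dense networks of purely competitive (−/−) interactions, typically
organised into near-perfect dominance hierarchies. A long-standing
question in community ecology is whether such hierarchies destabilise
multispecies coexistence, and what role "intransitive" (rock-paper-
scissors) competition plays. `compstab` implements the complete analysis
chain needed to address this with dynamic-systems tools, from raw contest
tallies to eigenvalue stability, feedback-loop spectra and null-model
experiments, for anyone analysing overgrowth-contest data or studying
stability in competition networks generally.

## The method

Observed contests are summarised per assemblage in species-contact
matrices: wins `W_ij`, symmetric draws `D_ij`, and colony abundances
`B_i`. The chain is

1. **Energy-loss web** (biomass/time):
   `f_ij = p_W W_ij + p_L L_ij + p_D D_ij`, with `L_ij = W_ji` and default
   costs `p_W = −0.1`, `p_L = −0.9`, `p_D = −0.2` per colony; intraspecific
   overgrowth counts as a win plus a loss, and intraspecific ties are
   doubled.
2. **Jacobian interaction strengths** (1/time), from a Lotka-Volterra
   model at steady state: `a_ij = f_ij / B_j`. Diagonals unobserved in the
   field (rare species) are filled as 0.1 × the mean Jacobian element, and
   flagged.
3. **Critical self-regulation** `s*`: the multiplier of the diagonal at
   which the dominant eigenvalue `Re(λ_d)` crosses zero, found by
   bracketed bisection, or — for row-normalised matrices with uniform
   diagonal −1 — as `max Re eig` of the matrix with zero diagonal.
   `s* > 1` means observed self-damping is insufficient: unstable.
4. **Feedback-loop weights**
   `w^(k) = |a_{i1 i2} ⋯ a_{ik i1} / (a_{i1 i1} ⋯ a_{ik ik})|^{1/k}`,
   maximised per loop length by an exact subset dynamic programme;
   `w²_max = max √(a_ij a_ji / |a_ii a_jj|)` is the heaviest pairwise
   positive feedback.
5. **Hierarchy metrics**: pairwise asymmetry (mean strong/weak ratio per
   reciprocal pair), community asymmetry (below/above-diagonal mean ratio,
   maximised over species orderings), the win index (polarisation of
   decisive contest outcomes, 0.5–1), and a triad intransitivity index.
6. **Null models**: full / weak / minimal randomisation of the normalised
   matrix, asymmetry restorations, and May-style random matrices with
   independent, asymmetric (strongest-with-weakest) or symmetric pairing.

## Worked example

```r
library(compstab)

cd <- generate_assemblage(synthetic_spec(S = 6, beta = 2, seed = 42))
cd
#> Species-contact data 'synthetic_S6_beta2': 6 species, 13 interacting pairs
#>   colonies: sp01=8, sp02=6, sp03=11, sp04=17, sp05=21, sp06=24

J <- jacobian(energy_loss_web(cd), cd$abundance)
J
#> Jacobian community matrix: 6 species, 3 filled diagonal(s) (factor 0.1)

critical_self_regulation(J)
#> s* = 9.26799 (unstable, bisection method)

max_loop_weight_per_length(J)
#>   k max_weight sign                         cycle method
#> 1 2   8.875302    1                     sp01;sp05  exact
#> 2 3   8.030231   -1                sp01;sp06;sp05  exact
#> 3 4   6.255382    1           sp01;sp06;sp05;sp04  exact
#> 4 5   6.695824   -1      sp01;sp03;sp02;sp06;sp05  exact
#> 5 6   6.200053    1 sp01;sp06;sp04;sp03;sp02;sp05  exact

ca <- community_asymmetry(J)
cat(round(ca$ratio, 2), "at", paste(ca$best_order, collapse = " > "))
#> 8.52 at sp01 > sp02 > sp03 > sp04 > sp05 > sp06

randomization_experiment(cd, kinds = c("full", "weak", "minimal"),
                         reps = 200, seed = 1)
#> Randomisation experiment
#>   source: s* = 9.091, w2max = 8.875
#>   full               median s* = 20.88
#>   minimal            median s* = 9.611
#>   weak               median s* = 12.08
```

Reading this: the six-species assemblage is far from stability — observed
intraspecific competition would need to be multiplied by about 9 to
stabilise it — and its instability is pinned to the heaviest 2-link loop
(`w²_max = 8.88`, attained by the sp01–sp05 pair; note `s*` tracks it
closely). Community asymmetry of 8.5 at the rank order sp01 > … > sp06
reflects the dominance hierarchy. Destroying that organisation makes
things worse: relocating intact interaction pairs (weak randomisation)
raises median `s*` to 12.1, and freely reshuffling all values (full
randomisation) to 20.9, because both manipulations let feedback loops grow
heavier. (The source `s*` differs slightly between the two displays: the
first is bisection on the raw Jacobian, the second the eigenvalue shortcut
on the normalised matrix; `analyze()` reports both and their gap.)

## The analysis workflow

The `analysis/` scripts run the full study pipeline on a simulated
30-assemblage ensemble and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # generate ensemble TSVs
Rscript analysis/02_stability.R      # per-assemblage records, s* ~ w2max
Rscript analysis/03_randomization.R  # null models + restorations, spectra
Rscript analysis/04_random_matrices.R # (S, C) stability-threshold curves
Rscript analysis/05_sensitivity.R    # cost-scenario and fill sensitivity
```

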