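# branchca

Branching morphogenesis of cultured embryonic kidney explants,
simulated and inferred. `branchca` provides three connected pieces for
people studying ureteric-bud branching (and lattice models of branching
epithelia generally):

1. **A cellular automaton coupled to a growth-factor field.**
   Epithelial cells on an `N x N` lattice move and divide; a
   quasi-steady dimensionless GDNF field `g` obeys
   `d_g lap(g) = g` on occupied sites (linear uptake), `lap(g) = 0` on
   matrix, with `g = 1` clamped at the domain edges. Division is gated
   by a probit switch `p_cd = Phi(c1 + c2 g)` — exactly 0.5 at the
   midpoint `g = -c1/c2` — and both chemotactic moves and anisotropic
   daughter placement choose among empty von Neumann neighbours with
   softmax probabilities `p_i = exp(beta g_i) / sum_j exp(beta g_j)`.
   Branches emerge when the rim of the mass straddles the switch
   midpoint: buds see more growth factor than necks and self-amplify.
2. **Matching morphometrics.** The two summary statistics of the
   imaging pipeline: explant area normalised by its initial value, and
   the number of branch points of the medial-axis skeleton
   (topology-preserving thinning, spur pruning, junction-cluster
   counting), applied identically to grayscale frames and simulation
   rasters.
3. **AABC parameter inference.** Approximate Approximate Bayesian
   Computation for `(c1, c2, p_move)`: a pilot library of true
   simulations, Epanechnikov-kernel weights over the `k` nearest pilot
   particles, Dirichlet-weighted resampling of pseudo-data, and
   rejection at the distance threshold that accepts exactly 5% of
   proposals.

## A worked example

Simulate the default reduced-scale explant (120×120 lattice, a
blob-with-buds initial mass of 636 cells) and summarise it:

```r
library(branchca)
p <- model_params()
p
#> Cellular-automaton model parameters
#>   grid 120 x 120, d_g = 0.0015 (lattice 21.2), 1 sweeps/h
#>   division switch: Phi(-25 + 120 g)  (midpoint g = 0.2083)
#>   p_move = 0.5, beta_move = 50, beta_div = 50, p_const = 0.5
#>   toggles: gdnf_division=TRUE chemotaxis=TRUE acd=TRUE attachment=FALSE

mask <- make_initial_mass(shape_spec("t_bud"), 120)
tr <- simulate_branching(mask, p, record_times_h = c(0, 10, 20, 30),
                         seed = 1)
tr
#> CA trajectory: 120 x 120 grid, 4 snapshots (t = 0, 10, 20, 30 h), seed 1
#>   cell counts: 636, 940, 1419, 2142

summarise_trajectory(tr)
#>   replicate_id time_h normalised_area branch_count
#> 1            1      0        1.000000            0
#> 2            1     10        1.477987            0
#> 3            1     20        2.231132            2
#> 4            1     30        3.367925            2
```

The mass triples its area over 30 simulated hours while the skeleton
acquires branch points — the explant-like regime. Toggling the
division gate off (`gdnf_division = FALSE`) grows a compact disc with
no branches; `run_ablation_experiment()` runs all 8 mechanism
combinations with replicate confidence bands, and `run_switch_sweep()`
shows that an intermediate switch sensitivity (`c2 = 120` at
`c1 = -25`) maximises branching against `c2 = 20` (growth never
starts) and `c2 = 400` (unbranched disc).

For inference, `build_pilot_library()` + `aabc_infer()` return a
classed fit with `coef()`, `summary()` and a corner-style `plot()`;
`run_inference_experiment()` wires the full synthetic-truth recovery
loop and reports the negative posterior correlation between `c1` and
`c2` induced by the switch midpoint.

A thin command-line front end with `simulate` / `summarize` / `infer` /
`fixtures` / `experiment` subcommands lives at `inst/cli/branchca`.

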