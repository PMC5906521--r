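---
title: "Methods: the branching automaton, its morphometrics, and AABC inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the branching automaton, its morphometrics, and AABC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`branchca` simulates the growth and branching of cultured embryonic
kidney explants: a mass of ureteric-bud epithelial cells on a square
lattice, coupled to a diffusible growth factor (called "GDNF"
throughout, as a stand-in for the mixture of mesenchyme- and
medium-derived factors that stimulate the epithelium). This vignette is
the package's account of the model, the measurement pipeline, the
inference scheme, and the numerical and design choices behind them.

## The coupled model

### Growth-factor field

Each lattice site holds either an epithelial cell or extracellular
matrix (ECM). GDNF diffuses from the domain edges, where the culture
medium holds it at a constant far-field concentration, and is consumed
by cells at a rate proportional to its local level. Because diffusion
equilibrates in minutes while divisions take hours, the field is
treated as quasi-steady: at every automaton sweep we solve, in
dimensionless form (`g` is concentration relative to the far field),

    d_g * lap(g) = g   on occupied sites
    lap(g)       = 0   on ECM sites
    g            = 1   on the boundary ring

with the 5-point finite-difference Laplacian. Linear uptake makes this
a sparse linear system with an M-matrix; `solve_gdnf()` relaxes it with
red–black Gauss–Seidel sweeps plus SOR over-relaxation (the classical
near-optimal factor `2/(1 + sin(pi/(N-1)))` by default), each update
projected onto `[0, 1]`. The projection is exact, not cosmetic: the
true solution satisfies the discrete maximum principle `0 <= g <= 1`,
projected SOR on an M-matrix converges to that same solution, and the
projection guarantees every *iterate* already respects the bounds. The
solver stops when the max-norm residual of the discrete equation falls
below `tolerance` (default `1e-6`) and fails loudly, carrying the
residual, if `max_iterations` is exhausted. Inside a simulation the
previous sweep's field warm-starts the next solve; occupancy changes
little per sweep, so warm solves converge in a handful of iterations.

The field length scale is the screening length `sqrt(d_g)` (in units of
the domain side): inside the mass, `g` decays over that distance from
its rim value. Cells on the clamped boundary ring would keep `g = 1`
(the boundary condition wins over uptake); in practice initial masses
are required to stay clear of the ring, and `simulate_branching()`
rejects masks that touch it.

### Cell rules

One sweep visits every cell present at sweep start exactly once, in a
fresh uniform random permutation; daughters and movers are not
revisited within the sweep. A cell with no empty von Neumann neighbour
does nothing. Otherwise one action is proposed: a **move** with
probability `p_move`, else a **division**. Moves are always carried
out. A division succeeds with the probit gate

    p_cd = Phi(c1 + c2 * g)

evaluated at the cell's own site. With `c1 < 0 < c2` this is a
sigmoidal switch with midpoint `g = -c1/c2` — where `p_cd` is exactly
0.5 — and steepness `c2`; at `g = 0` division is effectively off. The
destination site (for the mover or the daughter) is drawn from the
empty neighbours by a softmax over their field values,
`p_i = exp(beta * g_i) / sum_j exp(beta * g_j)`, with `beta_move`
("chemotaxis") or `beta_div` ("anisotropic cell division", ACD).
`beta = 0` is a uniform choice, which is exactly how the chemotaxis and
ACD mechanism toggles are implemented; the GDNF-division toggle swaps
the probit gate for a constant `p_const`. There is no cell death, and a
failed division gate is not retried as a move. An optional
`attachment_rule` vetoes any move whose destination would touch no cell
other than the mover's own origin, the cheapest local reading of
"cells remain attached to at least one neighbour"; it is off by
default.

The RNG contract: all randomness flows through R's stream in a fixed
order (sweep permutation, then per cell: action draw, gate draw, site
draw), so a seed makes whole trajectories bit-reproducible, and
`simulate_branching()` restores the caller's RNG state on exit.

### Why this generates branches

Division is confined to the rim (interior cells have no space) and
gated by `g`. When the rim sits *near the switch midpoint*, convex
protrusions — closer to the far-field supply — see higher `g` than
concave necks, so buds divide and necks stall: small protrusions
self-amplify into branches, sharpened further by ACD placing daughters
up-gradient. When the rim sits well above the midpoint every rim cell
divides and the mass grows as a compact disc; well below, growth
stalls. This is why both the switch shape (`c1`, `c2`) and the field
depletion (`d_g`, mass size) matter, and why intermediate `c2` at fixed
`c1 = -25` maximises branching in `run_switch_sweep()`: `c2 = 20` puts
the midpoint at `g = 1.25`, unreachable, and growth never starts;
`c2 = 400` puts it at `0.06`, below any rim value, and the mass grows
as an unbranched disc.

## Parameters, defaults, and the reduced-scale calibration

| parameter | default | meaning |
|---|---|---|
| `grid_size` | 120 | lattice side `N`; the domain is the unit square |
| `d_g` | 0.0015 | continuum dimensionless diffusion coefficient; lattice working value `d_g (N-1)^2 ≈ 21` |
| `c1`, `c2` | −25, 120 | probit switch location and sensitivity (midpoint `g ≈ 0.208`) |
| `p_move` | 0.5 | probability a proposed action is a move |
| `beta_move`, `beta_div` | 50 | softmax sensitivities for chemotaxis / ACD |
| `p_const` | 0.5 | division probability when the GDNF gate is toggled off |
| `steps_per_hour` | 1 | sweep-to-hours mapping |
| `tolerance` | 1e-6 | field-solver residual (max-norm) |
| `spur_min_length` | 5 px | skeleton spurs shorter than this are pruned |
| `presmooth_radius` | 2 px | disc radius of the morphological smoothing |

The package's defaults describe a *reduced-scale* configuration — a
120×120 domain with a ~640-cell initial mass, against the full-scale
400×400 domains of the original explant study — chosen so the whole
replicate experiments run in minutes. Three defaults are calibrations
the reduced scale forces, fixed once from a parameter sweep of the
generator and not revisited:

* **`d_g = 0.0015`.** The branching instability needs the rim value of
  `g` to straddle the switch midpoint. At the reduced geometry the
  full-scale value `d_g = 0.006` floods the mass (rim `g ≈ 0.26–0.49`,
  all above the 0.208 midpoint) and produces compact unbranched
  growth; `0.0015` (screening length ≈ 4.6 px against a mass radius
  ≈ 14 px) puts the rim at the midpoint. The full-scale value remains
  one argument away.
* **`steps_per_hour = 1`.** The sweep↔time mapping is not fixed by the
  model; one sweep per hour makes a default run roughly triple its
  area by 30 h with branch counts climbing over 10–30 h, in line with
  explant trajectories.
* **`beta = 50`.** Neighbour `g`-differences at the rim are of order
  0.02–0.1, so `beta = 50` gives a strong but not deterministic
  up-gradient bias (odds ratios of ~3–150 across that range).

## Morphometrics

`summarise_trajectory()` reproduces the imaging pipeline applied to
explant movie frames, applied identically to automaton rasters:

1. **Bulk mass.** For grayscale frames, `extract_bulk_mass()`
   thresholds (Otsu by default), fills interior holes and keeps the
   largest 8-connected component. Automaton snapshots get the same
   hole-fill and largest-component cleanup, so detached random-walking
   cells never contaminate the skeleton. The *area* statistic is the
   raw occupied-pixel count normalised by its `t = 0` value — the cell
   number proxy.
2. **Smoothing.** Lattice rasters are jagged at the single-cell scale.
   `skeletonize()` smooths with a morphological *closing followed by
   opening* (disc radius `presmooth_radius`). Closing alone fills
   single-cell indentations but cannot remove single-cell protrusions,
   and either kind of roughness spawns spurious skeleton branches;
   with closing+opening, provably non-branching masses (static or
   compact discs) score ~0 branch points while true lobes, an order of
   magnitude wider than the disc, are untouched. Structures thinner
   than the disc do not survive an opening, so use
   `presmooth_radius = 0` for already-smooth thin shapes.
3. **Skeleton.** Topology-preserving Guo–Hall two-subiteration
   thinning (implemented in C++; skeleton analysis is 8-connected even
   though the automaton's neighbourhood is 4-connected). Terminal
   spurs shorter than `spur_min_length` are pruned by walking inward
   from each endpoint; pruning passes repeat until stable.
4. **Branch points.** Skeleton pixels with ≥ 3 skeleton neighbours,
   merged over 8-connected runs so that the 2–3 adjacent junction
   pixels thinning emits for one biological branch point count once.
   One known artefact: a symmetric diagonal X-crossing can thin into
   two 3-junctions a few pixels apart and then counts twice — a
   property of all thinning-based junction counts, not of this
   implementation.

Because the pruning threshold and smoothing radius are method choices
with no counterpart recorded for the original pipeline, absolute branch
counts carry a method-dependent offset; the package's replicate
experiments are therefore read as *orderings* across conditions, not as
absolute curves.

## AABC inference

True simulations are too slow to place inside a rejection-ABC loop at
scale, so `aabc_infer()` implements Approximate Approximate Bayesian
Computation: a pilot library of `m` true simulations at prior-drawn
parameters is built once (`build_pilot_library()`, default 2 replicates
per particle, summaries = normalised area and branch count at
t = 10, 20, 30 h), and each of the `n_proposals` prior draws θ* is then
scored against *resampled* pseudo-data instead of fresh simulations:

1. Epanechnikov weights over the pilot particles,
   `w_i = (3/4)(1/d_(k+1))(1 − (d_i/d_(k+1))²)` for the `k` nearest
   particles in parameter space and 0 beyond, with Euclidean distances
   after rescaling each parameter to unit prior range (raw scales
   differ by a factor ~200). Distance ties at the bandwidth are broken
   by particle index; if the kernel vanishes on every selected
   neighbour (an exact tie) the selected set gets equal weight.
2. Resampling probabilities `phi ~ Dirichlet(w)` over the
   positive-weight particles (normalised gammas).
3. A pseudo-dataset: each pseudo replicate is a whole stored replicate
   summary vector — drawn by particle from `phi`, then replicate
   uniformly — preserving the within-replicate correlation of area and
   branch count.
4. The distance between the replicate-mean observed and pseudo summary
   vectors, each dimension standardised by the pooled pilot-library
   standard deviation (raw branch counts would otherwise dominate; a
   raw-distance mode is available via `standardise = FALSE`).
   The recorded distance is averaged over `n_pseudo` (default 10)
   pseudo-datasets: resampling is essentially free next to a true
   simulation, and a single 2-replicate pseudo-mean is noisy enough to
   blur the implied likelihood, so the averaging is pure variance
   reduction; `n_pseudo = 1` gives the single-draw scheme.
5. The threshold ε admits exactly the `accept_quantile` (default 5%)
   fraction of proposals: the smallest distances by rank, ties broken
   by proposal index, with ε reported as the smallest rejected
   distance. A rank rule rather than a quantile cut because distances
   inherit ties from the finite resampling pool; `accept_quantile = 1`
   sets ε = ∞ and returns the prior.

The result is a classed fit: `coef()` gives posterior means,
`summary()` quantiles, `plot()` a corner-style panel of marginals and
pairwise scatters. Convergence in the sense of a sampling budget is
operationalised as the fixed `n_proposals`; comparing posterior
summaries across the two half-budgets of `$distances` is the cheap
stability check.

Two structural facts about this posterior are worth knowing before
reading one. The switch midpoint `-c1/c2` ties `c1` and `c2` together:
parameter pairs along `c1 ≈ -k c2` produce near-identical gates, so
accepted `(c1, c2)` pairs correlate negatively and the identifiable
quantity is closer to the ridge than to either coordinate. And `p_move`
is weakly identified except at high values where growth stalls. The
parameter-recovery experiment (`run_inference_experiment()`, synthetic
observed data at a known truth) scores accordingly: the posterior mean
of `c2` — the best-identified coordinate — against the prior mean.

## What the synthetic generator does and does not emulate

The original explant movies are not deposited, so the fixtures module
stands in for them. `make_initial_mass()` rasterises deterministic
starting shapes (an ellipse; the default `t_bud` blob-with-terminal-
buds that resembles an explant after its first buds; a cross for
exercising the morphometrics), scaled as fractions of the grid.
`make_reference_observed()` runs the *real* simulator at a known
parameter triple and returns its summaries plus the truth, which is
what the inference tests recover. What this emulates: the summary
trajectories (areas, branch counts) of explant-like growth at matched
time points. What it does not: fluorescence noise, segmentation error,
3-D projection effects, mesenchyme, and between-explant biological
variability beyond the automaton's own stochasticity. Tests passing on
these fixtures show the pipeline and inference machinery are correct
and self-consistent at reduced scale; they do not validate the model
against real kidneys.

## Problem sizes and numerical choices

The replicate experiments default to 120×120 domains, 50 replicates
per condition and a 30 h horizon (~0.7 s per trajectory); the
inference experiment uses an 80×80 pilot library of m = 500 particles
× 2 replicates and 2000 proposals. Full-scale settings (400×400,
n = 200, tens of thousands of proposals) are one configuration change
away. Degenerate inputs are handled explicitly: empty masks, masks
touching the clamped ring, all-background thresholds, non-convergent
solves (error carrying the residual), duplicated θ* in the weight
kernel (degenerate-kernel error), and all-zero weight vectors are all
rejected with typed errors rather than propagated as NaNs.

## Known limitations

Single cell type (no mesenchyme, no GDNF–Wnt11–RET feedback), 2-D
lattice with volume-exclusion only (no adhesion or mechanics), one
generic growth factor, quasi-steady field (no transient diffusion),
and branch *counts* only — no branch angles, no primary/secondary
classification, no tip/stalk statistics. Absolute branch counts are
pipeline-dependent (see above); cross-condition orderings are the
robust output.
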