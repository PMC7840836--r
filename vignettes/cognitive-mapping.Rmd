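---
title: "Grid-cell path integration and cognitive map building: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cell path integration and cognitive map building: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cogmapr simulates the entorhinal–hippocampal circuit that lets a mobile
agent build a topological map of its environment: multi-scale grid-cell
modules integrate self-motion, a place-cell sheet learns to label
positions, visual templates detect loop closures, and an experience map
accumulates and corrects the trajectory. A grid-cell-guided RRT* planner
demonstrates the same firing fields in motion planning. This vignette
explains the models, the parameters that matter, the numerical choices
behind the implementation, and what the synthetic experiments do and do
not show.

## The attractor model

Each grid module is an `N x N` sheet of rate neurons on a torus with
leaky dynamics

    tau dg/dt = -g + s(W g + I),    s(x) = 1 / (1 + exp(-k_g x)),

where the recurrent kernel is a difference of Gaussians evaluated at the
torus displacement `x_i - x_j - l e_theta_j`:

    W_ij = a_m [exp(-b |x|^2 / 2 sigma_m^2) - exp(-|x|^2 / 2 sigma_m^2)].

With `b = 1.01 > 1` the kernel is purely inhibitory (zero only at zero
displacement), `sigma_m = N / (c_sigma n_m)` sets the spatial scale
(`n_m` bump periods across the sheet), and `a_m = w0 n_m / max(n)` ties
the amplitudes of the modules in a stack together. Each neuron carries
one of four preferred directions arranged in 2x2 sub-units; the velocity
input is `I = alpha (e_theta . v)`, and the `l`-shifted outgoing weights
turn that directional modulation into smooth bump flow — path
integration.

**Tonic drive.** A purely inhibitory kernel feeding a sigmoid has a
subtlety the equations above hide: at rest the net input is non-positive
everywhere, and the uniform state is then linearly stable for any
reasonable `k_g w0` (its effective gain collapses as the operating point
slides down the sigmoid's tail; the growth factor of the most unstable
mode caps near `0.07 ln(k_g |W|)`). Seeded lattice states collapse too.
Pattern formation needs a constant excitatory operating current so the
fixed point sits on the steep part of the sigmoid; the classic
single-scale attractor model this design descends from drives its ReLU
version with exactly such a baseline term in the input. We therefore add
a tonic drive `I0` (default 1.0) inside `s(.)` alongside the velocity
term. With it, hexagonal patterns form within ~1 s of simulated time and
reach sheet-snapshot gridness 0.5–1.5 across the default stack.

**Calibrated defaults.** `k_g = 18`, `c_sigma = 3.4`, `w0 = 60` at
`N = 40` (scaled ~`1/N^2` for other sheet sizes, see `default_w0()`),
`tau = 5 ms`, `dt = 1 ms`, `l = 2`, four modules with period counts
`n = (2, 3, 4, 5)`. `c_sigma` has a principled anchor: linear stability
selects the wavevector where the kernel's Fourier transform peaks, at
`sigma q* ~ 2`, which puts the realized lattice constant near
`3.4–3.6 sigma`; values in `[3, 4]` are admissible and 3.4 gave the best
pattern quality jointly across the four default modules in a one-time
sweep (`tune_w0()` re-runs such sweeps).

**Velocity gain calibration.** Bump-flow speed per unit drive depends on
kernel width, so modules driven with one shared `alpha` integrate at
different sheet-neurons-per-meter rates; coherent downstream decoding
needs one shared rate. `calibrate_stack()` measures each module's gain
with +/-x and +/-y constant-velocity probes and rescales the per-module
`alpha` to a common target, 150 neurons/m by default. The target is a
compromise measured from closed-loop behavior: much lower gains operate
near the lattice pinning threshold (stick-slip, strongly nonlinear
response), much higher ones approach the bump tracking limit.

**What the simulated attractor does not do.** The discrete `40 x 40`
lattice pins and ripples: the response is mildly anisotropic (diagonal
flow is up to ~20% slower than axis-aligned flow at the default
operating point), and sustained drive can re-lock a marginal pattern.
Consequences, measured honestly by the tests: a closed 40 m square loop
returns each module's phase to within ~0.6–2.2 neurons (the acceptance
bar of 1 neuron per module is not always met); decoded trajectories
track ground truth with r > 0.99; but single-cell *spatial* rate maps
over 200 s of foraging smear for some modules because field stability at
the lattice scale needs phase-versus-position errors below ~0.05% of
distance travelled, far beyond this fidelity. Sheet-snapshot gridness,
the standard readout for assessing simulated sheets of this kind, is the
robust measure.

## Gridness

`accumulate_rate_map()` bins activity over a trajectory;
`autocorrelogram()` computes Pearson correlations at all integer shifts
over the overlapping visited bins (shifts with fewer than 20 overlapping
bins are masked); `gridness_score()` finds the annulus holding the six
peaks nearest the origin and reports
`min(r60, r120) - max(r30, r90, r150)` over rotated copies of the
annulus. Conventions the source description leaves open, fixed here
once: the annulus inner radius is the first local minimum of the
angularly averaged correlogram, the outer radius 1.25x the largest
six-peak distance; peaks are 8-neighborhood local maxima above 0.1
correlation with non-maximum suppression at the inner radius; rotations
use bilinear interpolation about the zero-shift bin.

## Place coding

The place sheet shares the grid sheets' size. All cells of module `j`
project with one scalar weight `w_j`:

    u = sum_j w_j g_j,    p = 1 / (1 + exp(k_p (max(u) - u))).

The cell at the momentary maximum sits at exactly 0.5 and everything
else is suppressed exponentially, selecting a single activated place
cell (`k_p = 50` by default; the number of cells above any fixed level
is non-increasing in `k_p`). Note the sign: the form with
`k_p (u - max u)` in the exponent would *invert* the population (most
active cells mapped to the smallest `p`), so the implementation uses the
orientation that matches the winner-selection role.

Weights follow the competitive Hebbian rule
`dw_j = lr p (g_j - p w_j)` summed over the sheet, with `lr = 1e-4`,
clamped non-negative and renormalized to unit square norm after every
step. Training is offline: the agent explores (60 s of synthetic
foraging by default) while the rule runs, then the weights are
consolidated by iterating the same rule on the final activity snapshot
until the per-step change norm stays below `1e-7` — during motion the
change norm fluctuates at the scale of `lr` itself and a convergence
criterion that tight is only meaningful at a fixed input. The learned
weights concentrate on one or two modules; the remaining small weights
still act as tie-breakers among the dominant module's lattice-equivalent
bumps, which is what makes single place fields dominant.

**Decoding.** A winner-continuity decoder (unwrap the winner
index by nearest periodic image) is implemented
(`decode_trajectory(method = "winner")`), but residual per-module gain
differences of a few percent desynchronize the modules over meters and
make the joint winner hop between lattice-equivalent cells. The default
decoder therefore unwraps the *mean tracked pattern displacement* across
modules (`method = "displacement"`), which only needs per-module
continuity and reaches r > 0.99 against ground truth; an affine
calibration per axis (fitted on the leading quarter of the run) maps
sheet units to arena coordinates.

## Visual templates and the template tree

A scene is an RGB-D pair reduced to 32x24 contrast-normalized intensity
plus range-normalized depth features; the difference between two scenes
is `d = Wr d_r + Wd d_d` with each modality the mean absolute feature
difference minimized over a +/-4-column shift. The linear library
compares a query against every stored template (match iff the minimum
difference is at most `mt0`); the template tree (VTT) organizes
templates under `L = 5` layers with thresholds `mt0 + (L - k) delta_d`
at layer `k`, so matching cost is bounded by the tree's branching rather
than the library size. Defaults `mt0 = 0.02`, `delta_d = 0.015` were
calibrated once against the synthetic renderer's difference statistics
(adjacent frames 0.25 m apart differ by ~0.03–0.04; exact revisits by
~0; antipodal viewpoints by > 0.08).

The tree's greedy descent is exact only when scene differences are
well-separated relative to the threshold ladder; on smoothly varying
(aliased) streams it can route a query away from its twin and duplicate
templates. The benchmark generator `gen_scene_bank()` constructs
hierarchically structured scenes inside the threshold bands, on which
tree and library agree template-for-template while the tree's
comparisons-per-query slope is ~3% of the library's. `build_map()`
defaults to the exact linear matcher for mapping (loop-closure
correctness matters more than retrieval cost there) and takes
`matcher = "vtt"` where scaling matters.

## Experience map

Per camera frame the map builder advances the attractor over the
odometry slice, updates the dead-reckoned pose from the mean pattern
displacement, reads the place winner, and queries the template store. A
match whose stored experience lies within `r_exp` (1.0 m default — the
gate must tolerate the odometric drift a lap accumulates, which is
`bias x lap length`, ~0.5 m in the drifted benchmark) *and* is at least
`min_age` frames old declares a loop closure: activities are reset to
the experience's snapshots, the experience is merged (older id kept,
poses averaged), and the loop-closing link stores the *pre-reset*
odometric step so the accumulated drift enters the graph as
inconsistency. `relax_map()` then distributes that inconsistency
RatSLAM-style (rate 0.5, 100 sweeps per closure): each link pulls its
endpoints toward consistency, the total squared inconsistency is
non-increasing, and the residual across the ring-closing link ends below
a few percent of the original drift. New experiences are dropped every
`d_exp = 0.25 m` of decoded travel.

The two-lap benchmarks traverse a 10 m square loop twice at 0.25 m/s
with one frame per 0.3125 m (an exact divisor of the lap, so second-lap
frames coincide with their first-lap twins). With a 5% encoder bias the
raw odometry misses closure by ~0.56 m; the corrected map's residual gap
is ~2% of that, and every second-lap frame re-localizes. The drift-free
control reproduces the `M_2 = 0`, `M_r = 100%` bookkeeping exactly.
`recall_metrics()` truncates percentages at the second decimal, matching
the printed two-lap table it reproduces (`113/159 -> 71.06`).

## Planning

`gc_rrt_star()` runs one RRT* per selected grid cell (one per spatial
scale whose field is active at both endpoints; selection floor 0.05
after rescaling fields to [0, 1]), sampling `q_rand` from the cell's
active positions (80th-percentile support), steering `g_scale / 2` per
step, rewiring within `gamma g_scale = 3 g_scale`, with 5% goal bias and
cost propagation to descendants on every rewire. Candidate paths from
the per-scale trees are cross-rewired by greedy shortcutting against the
workspace and the cheapest is returned. Planning fields are analytic
hexagonal interference patterns at scale ratio 1.5 (inside the 1.4–1.7
biological module-ratio band); simulated rate maps can be wrapped as
`grid_pattern` objects instead. The paired-seed benchmark (7 seeds, 300
iterations, 20 x 20 m workspace with 3–6 random rectangular obstacles at
0.1 m collision resolution) asks only that the guided planner succeed at
least as often as uniform RRT*.

## Synthetic data

The generators are pure functions of their parameters and seeds.
Foraging trajectories use constant speed (0.25 m/s, a typical rodent /
indoor-robot speed) with heading diffusing at 1.2 rad per sqrt(s) and
reflective walls; 200 s covers > 80% of a 1 m arena at 10 x 10
resolution. Loop odometry corrupts body-frame increments with a
multiplicative encoder-scale bias applied to both translation *and*
rotation — a bias on planar velocity components alone is a linear map
and cannot open a closed loop, whereas the encoder-scale model yields an
endpoint gap of about `bias x lap length` (2.2 m at 5% on a 40 m lap).
The RGB-D renderer ray-casts a square arena whose walls, floor, ceiling,
and wall height carry smooth seed-hashed perimeter textures: frames are
deterministic in (pose, seed), nearby same-heading poses have
monotonically related scene differences (Spearman rho ~ 0.72), and
revisits reproduce frames exactly — a guaranteed loop-closure signal
that real imagery, with lighting changes and dynamic content, would not
give. Passing tests on these streams show the mapping machinery is
correct, not that the feature pipeline is robust to real-world
appearance change.

## Problem sizes and runtimes

The shipped experiments are sized to run comfortably on one CPU: 1500
settling steps per module, 60 s training runs, 200 s foraging for rate
maps, single-lap 40 m closure, two-lap 20 m mapping runs, 288-scene
template benchmarks, and 300-iteration planning trials. The compiled
integrator evaluates the recurrent drive as a pair of 1-D circulant
matrix products per direction (the per-axis minimal-image wrap makes
each Gaussian factor exactly separable), which is what makes
multi-minute simulated durations practical; the FFT form of the same
convolution is kept in R and cross-checked against a dense
weight-matrix oracle in the tests.
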