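---
title: "The fairy-ring model: equations, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fairy-ring model: equations, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairyringr)
```

## The phenomenon and the model

Fairy rings are circular colonies of soil fungi, common in grasslands, whose
underground mycelial front expands radially by a few centimetres per year for
decades. Above ground they are visible as concentric belts of killed and/or
unusually lush vegetation. Field observations distinguish six configurations:
a dead belt followed on the inside by a flourishing one (type 1); the same
with a second flourishing belt ahead of the dead one (type 1.1), or with the
leading belt stronger than the trailing one (type 1.3); a dead belt alone
(type 1.2); a flourishing belt alone (type 2); and no visible effect at all
(type 3).

`fairyringr` simulates this system with six coupled reaction--diffusion
equations on a 1D transect or 2D lattice, for the state fields (all densities
in g dm^-2^):

* `F` — fungal mycelium,
* `I` — a fungus-produced self-inhibitor (the hypothesised agent is
  extracellular self-DNA accumulating in previously occupied soil),
* `T` — phytotoxins, `S` — phytostimulants ("fairy chemicals"),
* `P` — plant biomass, `N` — soil nutrients.

The local dynamics are:

$$
\begin{aligned}
\partial_t F &= g_F F\,(1 - s_I I)\,\frac{W}{W+k_W} - d_F F^2 - s_F F I + D_F \nabla^2 F\\
\partial_t I &= c_I\,(d_F F^2 + s_F F I) - k_I I - l_I I \bar W\\
\partial_t T &= c_T F - k_T T - l_T T \bar W\\
\partial_t S &= c_S F - k_S S\\
\partial_t P &= g_P P\,[\bar W (q_P + S + N) - P] - s_T T P + D_P \nabla^2 P\\
\partial_t N &= g_N (g_P P^2 + s_T P T)\,\bar W - u_N\, g_P \bar W P N - l_N N \bar W
\end{aligned}
$$

with the available-water function

$$
\bar W = \begin{cases} 1 - b^{\,aF - W} & aF < W\\ 0 & aF \ge W,\end{cases}
$$

which requires $b > 1$ so that $\bar W \in [0, 1)$. The fungus draws on the
total soil-water input $W$ (its mycelium reaches beyond the hydrophobic
patch), while plants and all leaching terms see only the fraction $\bar W$
that infiltrates past the hydrophobic mat. Only `F` and `P` diffuse; the four
chemicals are treated as laterally immobile in soil.

Two mechanisms of vegetation damage are encoded and can be toggled
(`fr_hypothesis()`): *hydrophobicity* (`a = 2`; `a = 0` disables it) and
*phytotoxicity* (`s_T > 0`; `s_T = 0` disables it). The combined
configuration uses `a = 2` with `s_T` in [0.1, 0.5]; the phytotoxicity-only
configuration uses `s_T` in [0.9, 1.3]. Ring (rather than disk) growth needs
neither: it is produced by the self-inhibition loop `F -> I -| F`, and
disappears when `s_I = s_F = 0`.

## Parameters and defaults

`fr_params()` carries the published reference values. Three parameters are
published as ranges rather than points; their defaults here are:

* `g_F = 0.03` d^-1^, the midpoint of [0.01, 0.05];
* `W = 1` (dimensionless water input, range [0.1, 2]) — the value used in the
  reference demonstration run of the model and the natural mid-range sward;
* `s_T = 0.3`, the midpoint of the combined-hypothesis range [0.1, 0.5]
  (with `a = 2`), i.e. the default parameter set is the combined model.

All parameters are non-negative; `b = 9` (and any `b > 1`) keeps
$\bar W$ in $[0,1)$. `k_W` is published as dimensionless and is added
directly to `W` in the Michaelis--Menten factor; the model is implemented
literally as printed.

## Numerics

The integrator is explicit forward Euler at `dt = 1` d on a grid with
`dx = 1` dm (the published 0.1 m resolution), zero-flux (mirrored ghost cell)
boundaries, for 2000 days. The diffusion number
$\max(D_F, D_P)\,dt/dx^2 = 0.01$ is far below the stability bound 0.25, which
`fr_config()` enforces. The update order within a step is: $\bar W$ from the
fungal field at the start of the step; all six reactions from that same
snapshot (a frozen-coefficient scheme, so the result does not depend on the
order in which fields are updated); diffusion for `F` and `P`; and a final
clip at zero, since an explicit step can overshoot a mortality term in cells
that are already nearly empty.

The reference spatial setup is a 400 x 400 lattice with the inoculum
(`F = 0.01`) in the central cell and `P = 1` everywhere. The workhorse for
sweeps is the 1D transect: 400 cells with the inoculum in cell 1, whose
mirror boundary makes it equivalent to the centre of a symmetric 799-cell
domain. The 1D Laplacian is Cartesian, not polar-radial: far from the centre
the curvature term $\frac{1}{r}\partial_r$ is negligible against the reaction
rates, so a planar front is a good approximation of the annulus — but
establishment from the inoculum is *easier* in 1D than from a point in 2D,
where diffusion dilutes the inoculum over an area before growth takes over.
This matters for the weakest-fungus corner of parameter sweeps (see
"Limitations").

Two numerical properties of the solution are worth knowing:

* **The front is a travelling pulse about 4 cells wide.** Pointwise
  comparisons between discretizations (halving `dt` or `dx`) are dominated by
  the slow drift of the front position — a 1--5% speed difference accumulates
  over 2000 d into order-one local differences at the front, even though the
  shape and speed themselves are stable (speed changes by ~1% under
  dt-halving and ~5% under dx-halving). The test suite therefore checks
  refinement agreement on the smooth (fungus-free) dynamics, where it is
  exact to round-off, and speed stability for the front. For the same reason,
  co-moving shape constancy (`front_profile_drift()`) is assessed at
  near-commensurate integer displacements: a fractional-cell shift of a
  4-cell pulse cannot be represented on the grid and aliases into an apparent
  ~40% change.
* **Band widths and peak positions are quantized to the grid.** `BZ` counts
  whole cells below threshold and `RW` is a difference of argmax positions,
  so both move in 1-dm steps; parameters whose true effect on them is
  sub-cell appear exactly constant across a +/-50% sweep.

## Biometrics and classification

`fr_biometrics()` reduces a final `(x, F, P)` transect to the five
field-measurable indicators: the fungal peak `FB`; plant stimulation `PS` and
inhibition `PI` as the maximum deviation of `P` above/below the baseline
`P_inf`; the bare-zone width `BZ` (total width where
`P < P_inf (1 - eps)`); and the ring width `RW` (distance between the fungal
and plant peaks, reported as `NA` when no stimulated band exists, since there
is then no plant peak to measure to).

The baseline is the mean of `P` over the fungus-free far field, beyond the
front plus a 10-cell buffer. Its closed form (`plant_baseline()`) is the
coupled plant--nutrient fixed point
$P^* = \bar W (q_P + N^*)$, $N^* = g_N g_P P^{*2} / (u_N g_P P^* + l_N)$:
note that logistic plant turnover releases nutrients even without fungus, so
the baseline sits *above* the water-limited capacity $\bar W q_P$ whenever
`g_N > 0` (1.0794 vs 0.8889 at the defaults) and equals it when `g_N = 0`.

Significance of a band is relative: deviations smaller than `eps = 0.02`
(2% of the baseline) are ignored. The published typology gives no threshold;
2% is small enough to keep genuine belts and large enough to mute numerical
ripple, and it is reported with every classification and configurable
everywhere. "Dead vegetation" is likewise operationalized as
`P < P_inf (1 - eps)` rather than `P = 0`, because the model rarely reaches
exact zero.

`fr_classify()` is a total decision tree over the significant bands, tagged
ahead/behind relative to the fungal peak: no bands → 3; stimulation only → 2;
inhibition only → 1.2; inhibition with stimulation behind only → 1; both
sides with the leading belt at most as strong as the trailing one → 1.1;
leading belt strictly stronger (including a leading belt with no trailing
one) → 1.3. Ties among identical global maxima are broken toward the front.

## Sensitivity analysis

`fr_sensitivity()` performs the one-at-a-time sweep: each parameter in turn
at 0.5, 0.75, 1, 1.25, 1.5 x its default (five levels across the published
+/-50% range — enough points for a meaningful Pearson correlation while
keeping the full 24-parameter sweep to ~120 runs), one full 1D simulation and
biometric read-out per level. Per (parameter, metric) pair it reports the
Pearson correlation sign — with a dead zone: `|r| < 0.1` is reported as 0
rather than asserting a sign from noise — and the fold change
`(max - min)/min`, which is undefined (flagged `NA`, not infinite) when the
minimum is 0 or when a level is undefined. The heatmap matrix divides each
metric column by its maximum, so intensities are comparable within a column
only. Sweeps run in 1D by default; 2D is available but changes no sign calls
that the grid does not already quantize away.

Two caveats found while validating against the published sign table, both
documented rather than patched: `PS` falls monotonically with `k_S` in this
implementation (faster stimulant degradation means less stimulation), and
`PI` is non-monotone in `W` at the default base because the plant trough is
pinned at zero only while `W < a F_{peak}` — with the stronger-fungus base
`g_F = 0.05` the published positive sign is recovered. Both behaviours are
properties of the equations as printed, not of the numerics.

## Worked example

```{r, eval = FALSE}
library(fairyringr)

cfg <- fr_config(fr_params(), geometry = 400L, n_steps = 2000L)
sim <- fr_run(cfg)
summary(sim)

tr <- final_transect(sim)
b <- fr_biometrics(tr)
b
fr_classify(b)

plot(sim)           # plant and fungal transects
plot(sim, "front")  # front position vs time
```

The default run produces a type 1 ring: a bare zone of 5 dm riding the
fungal front (peak 0.448 g dm^-2^ at 56 dm after 2000 d, travelling at
0.0314 dm d^-1^), with a stimulated belt just inside it. Setting
`s_I = 0, s_F = 0` turns the annulus into a disk; `fr_preset("type13_demo")`
(strong, fast-cycling stimulants: `c_S = 0.8`, `k_S = 1`, `g_N = 0.2`,
`W = 2`, `g_F = 0.05`) produces the rare type 1.3, with the leading
stimulated belt stronger than the trailing one.

## What the simulations do and do not show

The simulator reproduces the published qualitative claims at desk scale (1D,
400 cells, 2000 d): all five types from the combined model across its
parameter ranges; the exclusion of the doubly-stimulated types 1.1/1.3 under
phytotoxicity alone; ring emergence strictly through self-inhibition; and
travelling-wave front propagation. It is still an idealized model: space is
homogeneous and flat (no slopes, so no arcs), the water input is constant (no
seasonality, so no type switching within a year), plant and fungal
communities are single aggregated densities, and the chemistry is four
first-order pools. Classification of simulated transects at a 2% relative
threshold also differs in one visible way from typing colour panels by eye:
a weak fungus in a near-bare, water-starved sward (low `W`) always registers
as inhibition here, because $\bar W$ is extremely sensitive to `F` at low
`W`, whereas such a ring would plausibly be called "no evident effect" in
the field. The hydrophobicity-only sweep therefore yields four types on the
default grid, with type 3 appearing once phytotoxicity is available to
offset stimulation (combined sweep) or at parameter combinations off that
grid.
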