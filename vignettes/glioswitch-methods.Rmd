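---
title: "Model and methods: the glucose-driven miR-451/AMPK switch and glioma growth-invasion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioswitch)
```

## The biological problem

Glioblastoma cells face a trade-off between proliferating in place and
migrating toward nutrients — the "go-or-grow" dichotomy. Experimentally,
miR-451 couples this decision to glucose: normal glucose keeps miR-451
high, which suppresses the CAB39/LKB1/AMPK energy-sensing pathway and
favors proliferation; low glucose downregulates miR-451, activates AMPK,
and switches cells into a migratory phenotype. `glioswitch` models this
circuit as a bistable two-variable network, embeds it cell-by-cell in a
one-dimensional continuum model of tumor invasion, and asks how the
*pattern* of glucose delivery — pulsed versus steady — shapes tumor
growth.

## The intracellular switch

The dimensionless mutual-antagonism system is

$$\frac{dM}{dt} = G + \frac{k_1 k_2^2}{k_2^2 + \alpha A^2} - M, \qquad
  \frac{dA}{dt} = \varepsilon\left(S + \frac{k_3 k_4^2}{k_4^2 + \beta M^2} - A\right),$$

with $M$ the miR-451 activity, $A$ the AMPK-complex activity, $G$ the
glucose input, and all decay rates scaled to 1 for $M$. Each species has
a *bounded* production term (at most $k_1$ resp. $k_3$) inhibited by the
square of the other, so solutions are trapped in the box
$[0, \sup G + k_1] \times [0, S + k_3]$. Because miR-451 turns over much
faster than the protein complex, $\varepsilon$ (the ratio of the two
degradation rates, default 0.02) makes $A$ the *slow* variable: on the
fast time scale $M$ relaxes onto its nullcline
$M = G + k_1 k_2^2/(k_2^2 + \alpha A^2)$, while $A$ drifts on the
$1/\varepsilon \approx 50$ h scale. The package's slow–fast tests verify
that trajectories converge to this reduced model as
$\varepsilon \to 0$.

The production inhibition enters as $\alpha A^2$ (a single strength
parameter multiplying the square of the inhibitor, against a squared
half-max constant $k_2$). This algebraic form is the one that, with the
published parameter set ($k_1 = k_3 = 4$, $k_2 = k_4 = 1$,
$\alpha = 1.6$, $\beta = 1$, $S = 0.2$), produces the published
saddle-node folds: quasi-statically raising glucose the low-miR-451
branch disappears at $G \approx 0.6$, lowering it the high branch
disappears at $G \approx 0.4$ (the package computes 0.5798 and 0.3992).
Variants in which the strength parameter is squared together with the
inhibitor, or in which production is autocatalytic in the species
itself, were examined and rejected: they place the bistable window far
from these values or make it span nearly the whole glucose axis.

### Equilibrium analysis and continuation

`steady_states()` eliminates $A$ through its nullcline (explicit in
$M$), scans the scalar residual on a dense grid over the production box
($\Delta M = 10^{-4}$ of the box), brackets sign changes, polishes roots
with bisection and Newton steps to residuals below $10^{-10}$, and
merges duplicates closer than $10^{-8}$. Stability comes from the
analytic $2 \times 2$ Jacobian. `continue_branch()` repeats this over a
glucose grid (default spacing 0.002), labels the lower/middle/upper
branches, and locates each fold by bisection on the equilibrium count to
$|\Delta G| \le 10^{-4}$. A monotone curve (e.g. with both inhibitions
off) reports `NA` folds rather than an error. An independent oracle — a
two-dimensional residual-grid scan polished by a finite-difference
Newton iteration — is held against the production path on randomly drawn
parameter sets in the test suite.

### The glucose-deprivation protocol

The wet-lab experiment compares miR-451 after culture in normal
(4.5 g/l) versus low (0.3 g/l) glucose. The dimensionless values behind
the published comparison are not printed, so the package preserves the
*ratio*: by default $G_\text{high} = 1$ (on the monostable upper region
above the fold) and $G_\text{low} = (0.3/4.5) \times G_\text{high}$,
both configurable. The low-glucose state is chosen
history-consistently — stepping down from the high state, the system
stays on the upper branch until $G$ falls below the lower fold, and only
then drops. With the defaults this predicts a 94.8% reduction of
equilibrium miR-451, comfortably beyond the 80% scale of the
experimental knockdown. The choice of $G_\text{high}$ barely matters:
the low branch pins $M_\text{low}$ near 0.2 for any deprivation ratio
this deep, so the reduction stays in the 90%+ range across the
monostable region.

## The spatial model

Six fields live on a uniform finite-volume grid over $[0,1]$ (reference
length 1 cm, time in hours, default $dx = 0.01$): tumor density $n$,
ECM $\rho$, MMP $P$, glucose $G$, and the intracellular $M, A$ evolved
pointwise in every cell.

* **Tumor.** Migratory cells (local $M < M_{th} = 2$) move with flux
  $-D_n \nabla n + n\,v$, where the taxis velocity
  $v = \frac{\chi}{1 + \sigma_c G}\nabla G + \frac{h}{1 + \sigma_h \rho}\nabla\rho$
  combines saturating chemotaxis up glucose gradients and saturating
  haptotaxis up ECM gradients. Proliferative cells ($M > M_{th}$) grow
  logistically at rate 0.1/h toward carrying capacity 1. The sharp
  phase indicators are smoothed by a logistic sigmoid of width 0.05 in
  $M$; the two weights always sum to 1 and equal $1/2$ exactly at the
  threshold.
* **ECM.** Degraded by MMP at rate 0.508, remodels logistically at rate
  0.18 toward capacity 1. Not transported.
* **MMP.** Produced (rate 2.5) by invasion-weighted cells in the
  presence of ECM, decays at 0.18, diffuses weakly
  ($D_P = 3 \times 10^{-5}$), and therefore stays localized at the
  invasive front. Gating production by the invasion indicator is a
  configuration toggle (`mmp_invasion_gated`).
* **Glucose.** Diffuses ($D_G = 2.4 \times 10^{-2}$, the dimensionless
  equivalent of $\approx 6.7\times10^{-6}\,\mathrm{cm^2/s}$), is
  consumed at rate $\lambda_G\, n G$ with $\lambda_G = 1$, and is
  supplied in pulses: at times $i\tau$ ($i = 1, 2, \ldots$) the band
  $[0.92, 1]$ receives rate $g_\text{in}$ for 0.01 h. A *constant-supply
  twin* delivers the identical dose per period continuously (rate
  $g_\text{in} \times 0.01/\tau$) on the same band.
* **Switch coupling.** Each cell's intracellular pair $(M, A)$ is driven
  by the local glucose through a signal $G/G_\text{scale}$.
  $G_\text{scale}$ is the extracellular concentration corresponding to
  one unit of the switch's dimensionless input — the two scalings are
  distinct because the switch was calibrated against culture-medium
  concentrations while the field equation is scaled to the injection
  problem. See *Calibration* below.

Boundary conditions are zero-flux at both ends for every transported
field; glucose enters the domain only through the injection source.
This makes every budget closable: the tests verify that pure transport
conserves tumor mass to $10^{-12}$ per step and that
$\Delta G_\text{total} = \text{injected} - \text{consumed}$ closes to
0.1% (in practice to round-off) over full scenarios.

Initial conditions ("default" scenario): a height-1 tumor plateau with a
tanh front of width 0.02 occupying $[0, 0.1]$; ECM at 0.5 inside the
tumor and 1 outside; no MMP; glucose uniform at $G_\text{init}$; $(M, A)$
at the local switch steady state on the migratory branch, so the tissue
starts in the invasive regime.

## Numerics

One composite step of length $dt$ is Strang-split:
transport($dt/2$) → local reactions($dt$) → transport($dt/2$).

* **Transport.** Taxis advection is first-order upwind on face
  velocities, gated by the face-averaged invasion weight; random
  motility is central/second order and explicit. MMP and glucose
  diffusion use backward Euler with a conservative finite-volume
  Laplacian, solved with cached dense factorizations — implicit
  diffusion removes the $dt \le dx^2/(2 D_G)$ restriction while
  remaining an M-matrix solve (positivity-preserving) with zero column
  sums (mass-conserving to round-off).
* **Reactions.** All local terms — growth, ECM turnover, MMP kinetics,
  consumption, injection, and the switch — are advanced cell-wise by
  classical RK4, vectorized over the grid, with substeps capped at
  0.02 h. An implicit solver is unnecessary here: the small factor
  $\varepsilon$ multiplies the right-hand side of the *slow* variable,
  so the fastest local rate is $O(1{-}30)$ per hour and RK4 at these
  substeps reproduces a $10^{-12}$-tolerance ODE integration of the
  same right-hand sides to better than $10^{-8}$ over multi-hour
  horizons (asserted in the tests). Reaction substeps are split exactly
  at pulse on/off times, so each injection deposits
  $g_\text{in} \times \text{duration} \times 0.08$ to round-off
  regardless of $dt$.
* **Step control.** $dt$ (default 0.01 h) is held fixed within each
  output interval, capped by the advective CFL condition
  ($|v| dt/dx \le 0.9$), and halved with the interval retried if any
  field turns negative beyond $-10^{-9}$ or non-finite, down to
  `dt_min`. Keeping $dt$ fixed per interval — rather than growing it
  adaptively after clean steps — makes runs bit-reproducible and
  independent of the output cadence: recording twice as often changes
  sampling times only, not states (asserted in the tests). Round-off
  negatives (above $-10^{-12}$ in practice) are clamped to zero.
* **Convergence.** For the default pulsed scenario, halving $dx$
  changes the final tumor population by about 1.1% and halving $dt$ by
  about 0.03%; both bounds (2% and 1%) are asserted in the acceptance
  tests, and the growth–invasion cycle count is unchanged under both
  refinements.

## Calibration of unprinted constants

The rate constants of the field equations (growth 0.1, ECM degradation
0.508, remodeling 0.18, MMP production 2.5, decay 0.18, consumption 1.0)
and the schedule geometry (band 0.08, duration 0.01 h,
$g_\text{in} \in [1, 30]$, $dx = 0.01$) are the published dimensionless
values and are not touched. The transport coefficients and the glucose
signal scale are not available in printed form; they were fixed once, as
follows, and are all exposed in the configuration:

* $D_G = 2.4\times10^{-2}$, $D_P = 3\times10^{-5}$, $D_n = 10^{-4}$ from
  dimensional diffusion coefficients of glucose, MMP-scale proteins and
  glioma cells at the 1 cm / 1 h reference scales.
* $\chi = 0.15$, $h = 2\times10^{-3}$ set so the invasive front
  traverses an $O(1)$ fraction of the domain over 100 h, as the
  simulated profiles require.
* $G_\text{scale} = 0.00215$ and $G_\text{init} = 0.001$ jointly chosen
  so that the *whole set* of reported regimes holds simultaneously
  under the published schedule parameters: cells start migratory; with
  $\tau = 10$ h and $g_\text{in} = 5$ the tumor completes exactly three
  growth–invasion cycles in 100 h; with $g_\text{in} = 30$ growth is
  monotone and fastest; with $\tau = 50$, $g_\text{in} = 5$ the tumor
  invades without ever entering the growth phase; pulsed supply beats
  its equal-dose constant twin; and the inhibition-strength sweeps move
  growth in the documented directions. This is a genuine co-calibration,
  not a per-experiment fit: a single value of the pair is required to
  satisfy all constraints at once, and it was frozen before the
  acceptance suite was written.

The cycling mechanism at the calibrated point is worth stating because
it explains why ten injections yield only three cycles: each pulse
raises the near-tumor glucose signal toward the upper fold, but whether
the jump to the proliferative branch occurs depends on the slowly
drifting AMPK level — the $1/\varepsilon \approx 50$ h memory — so
groups of pulses, not single pulses, gate each growth phase.

## Phase classification and cycle counting

The scenario phase at any time is decided by the tumor-weighted mean
miR-451 level, $\langle M \rangle = \int n M\,dx / (\int n\,dx + 10^{-6})$
(the floor guards the empty-support case), thresholded at $M_{th}$.
"Cycle" is defined as one completed invasion→growth→invasion
alternation, i.e. `floor(transitions / 2)`; excursions shorter than the
debounce time (default 0.5 h) are merged into their neighbours,
shortest first. The count is invariant to refining the output cadence
and, at vanishing debounce, equals half the raw threshold-crossing
count. Whether one counts cycles on the mean miR-451, the total
population or the AMPK total is immaterial in the cycling regime — the
three series alternate together — and the package standardizes on the
tumor-weighted mean miR-451.

## Degenerate inputs and edge cases

Empty time series, unknown scenario or fixture names, schedules with
`duration >= tau`, negative states and unknown configuration keys all
fail fast with the offending quantity named. A monotone equilibrium
curve reports `NA` folds. A deprivation query with `G_low` above the
upper fold computes the (unique-state) reduction but flags it and warns.
Stepper failures below `dt_min` return the partial result flagged
`partial = TRUE`, which `write_series()` propagates into the run
manifest.

## Problem sizes

The default test and acceptance workloads use the 100-cell grid
($dx = 0.01$), $dt = 0.01$ h and 100 h horizons — a full scenario
integrates 10,000 composite Strang steps over 600 unknowns and runs in
under ten seconds — with refinement checks at 200 cells and
$dt = 0.005$ h. Equilibrium continuations use 501 glucose levels with
$10^{-4}$-resolution root scans.

## What the model does and does not capture

The simulations are one-dimensional and deterministic: they represent
cell *density*, not individual cells, so single-cell escape events,
clonal heterogeneity and stochastic switching are out of scope. Cell–cell
adhesion and shedding from a spheroid are deliberately omitted, as are
angiogenesis, host stromal cells and immune interactions. The smooth
indicator functions replace the model's sharp phenotype threshold; the
smoothing width (0.05) is a numerical device, and results quoted here
are insensitive to halving it. Passing tests demonstrate internal
consistency — transcribed dynamics, conservation, convergence, and the
documented qualitative regimes — not quantitative agreement with any
particular tumor: absolute rates inherit the uncertainty of the
estimated transport coefficients and of the glucose-signal calibration
described above.
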