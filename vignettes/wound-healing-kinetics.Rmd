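---
title: "Separating migration from proliferation in scratch-assay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating migration from proliferation in scratch-assay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundkinetics)
```

## The model and its assumptions

A scratch wound in a confluent monolayer closes by two mechanisms:
cells at the edge migrate into the gap, and cells everywhere divide
until density saturates. `woundkinetics` models the density profile
u(x, t) along the closure direction with the Fisher–Kolmogoroff
(Fisher–KPP) equation,

$$\frac{\partial u}{\partial t}
  = D\,\frac{\partial^2 u}{\partial x^2}
  + k\,u\left(1 - \frac{u}{\hat u}\right),$$

which assumes (i) cell migration is a persistent random walk, so at
the population scale it is Fickian diffusion with a random motility
coefficient $D$; (ii) proliferation is logistic with rate
$k = \ln 2/\tau$ ($\tau$ the doubling time) saturating at the
confluent density $\hat u$; (iii) the wound is straight, so the
problem is one-dimensional in $x$. The equation admits traveling-wave
fronts whose asymptotic speed is the classical minimum
$v = 2\sqrt{Dk}$.

The measurement chain inverts this relation algebraically rather than
fitting the PDE to data: the normalized wound area $A/A_0$ declines —
after a lag $t_L$ — at a constant rate $\alpha$; a straight wound of
initial width $b$ closing from both edges gives the edge speed
$v = \alpha b/2$; with $\tau$ measured independently from growth
curves, $D = \tau v^2/(4\ln 2)$. The Thiele modulus compares
proliferation to motility over the wound width and diagnoses the
closure regime (small: migration-dominated; large:
proliferation-dominated). Its printed form in the wound-healing
literature is dimensionally ambiguous; this package uses the standard
first-order convention $\phi = b\sqrt{k/D}$, which is dimensionless,
and exposes the literal ratio $b^2 k/D$ behind
`thiele_modulus(..., literal = TRUE)` for comparison. Whether the
length scale should be $b$ or $b/2$ is equally unrecoverable from the
literature's notation; $b$ was chosen and is stated here so the
convention is explicit.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `D` (control) | µm²/h | 600 | keratinocyte-sheet scale motility; closes a visible fraction of the default wound in 18 h |
| `tau` | h | 20 | typical immortalized-keratinocyte doubling time |
| `u_hat` | — | 1 | densities are kept normalized; only ratios to confluence matter downstream |
| `b` | µm | 1000 | wide enough that neither condition exhausts the wound within the 18 h record (a validity requirement of the linear-range fit) |
| frame interval / span | h | 0.25 / 18 | the standard time-lapse protocol this package targets (73 frames) |
| `pixel_size` | µm/px | 4 | 5×-objective scale |
| `occupancy_threshold` | fraction of û | 0.2 | density at which cells visibly cover the substrate in the renderer; also defines the ground-truth mask |
| `cell_texture_amplitude` / `noise_sd` | intensity | 0.25 / 0.02 | texture contrast ≈ 12× the noise floor, comparable to well-exposed phase contrast |
| segmentation `window` | px | 15 | local-sd window ≈ one cell diameter at 4 µm/px |
| `morph_radius` | px | 7 | removes speckle holes smaller than a cell |
| `min_texture` | intensity | 0.05 | absolute fallback separating "no cells anywhere" from "confluent everywhere" when Otsu's split is uninformative |

## What the synthetic generator emulates — and what it does not

The generator exists so every downstream stage has ground truth. It
emulates: FK density dynamics with a rectangular scratch initial
condition; extrusion of the 1D profile into 2D frames of a vertical
wound stripe; texture contrast between cell-covered and cell-free
regions (zero-mean speckle where the local density exceeds the
occupancy threshold); per-pixel Gaussian read noise; and
growth-curve counts with mean-one multiplicative lognormal noise.

It does **not** emulate curved or ragged wound edges (2D dynamics),
cell-scale granularity (occupancy is a deterministic threshold on the
coarse density, not sampled cells), phase-contrast optics (halo and
shade-off artifacts), illumination gradients, focus drift, or stage
jitter. Passing tests therefore demonstrate that the measurement chain
is correct *given the model's own assumptions* — an internal
consistency proof, not evidence that the segmentation defaults are
optimal for any particular microscope.

## Numerical choices

**Integrator.** Explicit forward-time central-space (FTCS)
differencing — the simplest auditable scheme; the grids involved are
desk-scale. The solver refuses any step above the stability limit
$\Delta t \le \Delta x^2/(2D)$ with a typed error
(`wk_stability_error`) rather than returning garbage; with `dt = NA`
it picks 80% of the limit and subdivides so snapshots land exactly on
the requested times. Boundary nodes use the cell-centered
finite-volume (single-sided) stencil, so zero-flux boundaries conserve
$\sum u\,\Delta x$ to machine precision when $k = 0$ — a test anchors
this, along with a <1% $L_2$ match to the Gaussian heat kernel in the
pure-diffusion limit.

**Front-speed measurement.** Fronts started from compact data approach
$2\sqrt{Dk}$ slowly, with a transient that decays like $\ln t/t$.
`estimate_front_speed()` therefore fits the half-maximum level-set
trajectory with $x(t) = v\,t - c\ln t + x_0$ over the late half of the
record, which recovers the asymptotic speed to within a few percent at
horizons of roughly $8/k$; a plain linear fit at the same horizon is
~15% low.

**Linear-range detection.** The lag and slope of $A/A_0$ are fitted by
a continuous two-segment model (flat, then a declining line), scanning
every admissible breakpoint and keeping the least-squares optimum; the
breakpoint is $t_L$. This is deterministic and reproduces a planted
piecewise-linear series exactly. A slope from fewer than five points
is refused; a best slope ≥ 0 (up to round-off, $10^{-10}$/h) is
reported as "no closure" with $\alpha = 0$; a lag exceeding half the
record warns.

**Growth fit.** $n_0$ is pinned to the first count and $\tau$ is the
only adjustable parameter, fitted in $\log_2$ space by least squares
through the origin — closed-form, and exact on noiseless data.

**Degenerate segmentation inputs.** Otsu's threshold always splits a
texture map, even when there is only one class. When the two classes'
mean texture differs by less than a factor of two the split is deemed
uninformative and the absolute `min_texture` rule decides, which sends
a fully confluent frame to an empty mask and an empty dish to a
full-frame mask. A perfectly constant frame returns a flagged
full-frame mask with a warning.

**Seeds.** Every stochastic function takes an explicit seed and
restores the global RNG state. The pipeline derives one seed per
replicate from the root seed; the derived seeds are *shared* across
conditions, so replicate *i* of each condition sees the same noise
realization — this pairs replicates for the paired t-test and makes
two identically parameterized conditions give a ratio of exactly 1.

## Validation design and problem sizes

Two regimes matter, and they are validated separately.

*Relative comparisons at assay scale (18 h).* At realistic doubling
times the front is still pre-asymptotic after 18 h ($k t \approx
0.6$), so the absolute $D$ inferred from $\alpha$ is biased low.
However, the leading transient correction scales as $\sqrt{D}$ just as
the asymptotic speed does, so between two conditions sharing $\tau$
the α *ratio* already equals $\sqrt{D_{\mathrm{ratio}}}$ at 18 h. The
default experiment plants a 3.24-fold motility contrast and the full
pipeline recovers the predicted ratio $\sqrt{3.24} = 1.80$ within a
few percent (the acceptance script recomputes this end to end; three
replicates per condition, 73 frames of 800×120 px each).

*Absolute recovery in the wave regime.* Recovering planted $(D^*,
\tau^*)$ absolutely requires $k t \gg 1$. The validation run uses
$\tau^* = 6$ h, $D^* = 200$ µm²/h, an 8.6 mm wound on a 19 mm domain,
400 h of acquisition at 2.5 h intervals ($k t_{\mathrm{end}} \approx
46$) — sizes chosen so the transient bias falls well inside the 15%
target while the run stays desk-scale (a 3801-node grid, 161 rendered
frames of 1900×96 px). Within it, $\hat\tau$ lands within 5% and
$\hat D$ within 15% of the planted values.

A useful cancellation makes the inversion robust to segmentation bias:
the texture window erodes the wound by a constant margin, deflating
both the measured $b$ and $A_0$ by the same factor; since
$v = \alpha\,\hat b/2 = |dA/dt|\,\hat b/(2A_0)$, the margin cancels
exactly as long as the *measured* initial width is used — which the
pipeline does.

## Known limitations

- The algebraic inversion reports biased absolute $D$ whenever the
  record ends before the traveling-wave regime; at assay-scale
  horizons treat $D$ as a relative index between conditions, or extend
  the record. (Fitting $D$ and $k$ jointly against full density
  profiles would remove the bias but is deliberately out of scope —
  the point of the method is the simple algebraic route.)
- Rendering is 1D-extruded: segmentation performance on curved or
  ragged wounds is untested by construction.
- The renderer's binary occupancy hides partial-density texture
  gradients; real edges are softer, so real-data Jaccard overlap will
  be below the synthetic figure.
- The paired t-test pairs replicates by index; with real biological
  replicates, pair by experiment day before calling it.
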