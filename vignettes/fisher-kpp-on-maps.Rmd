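---
title: "Fisher–KPP growth and diffusion on raster maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher–KPP growth and diffusion on raster maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kppmap)
```

## The model

`kppmap` solves the Fisher–KPP growth–diffusion equation on gridded
geographical domains:

$$\frac{\partial p}{\partial t} = c\,\nabla^2 p
  + \lambda\Bigl(1 - \frac{p}{K(\mathbf{x},t)}\Bigr)p,$$

where $p$ is a population density, $c$ the diffusivity (the physical
diffusion coefficient is $D = 2c$, in km²/yr), $\lambda = r$ the logistic
growth rate (1/yr), and $K(\mathbf{x},t)$ a space- and time-dependent
carrying capacity raster with $K = 0$ on water. In scaled units
($\lambda = 1$, $c = 1/2$, $u = p/K$) the equation admits traveling waves
with asymptotic speed $v = 2\sqrt{\lambda c} = \sqrt{2}$; in physical units
$v = 2\sqrt{rD}$. The intended application regime is continental-scale
dispersal on paleoclimate capacity maps, where coastlines move, land bridges
open and close, and the habitable domain is highly irregular.

## The numerical scheme

Space is discretized with the standard second-difference operator $A$
(rows $1, -2, 1$) in each direction; time stepping is controlled by the CFL
parameter $k = c\,h/\Delta x^2$. An explicit 2-D Euler update is stable only
for $k < 1/4$ (verified by brute-force von Neumann scan in
`explicit_stability_threshold()`), which would force impractically small
steps. Instead, each step of length $h$ is Godunov-split into

1. an $x$ trapezoidal pure-diffusion half-step
   $(1 - \tfrac{k}{4}A_x)u^\star = (1 + \tfrac{k}{4}A_x)u$,
2. an explicit $y$ Euler predictor (full $k$, as the scheme prescribes)
   $u_E = u^\star + kA_y u^\star + \lambda h(1 - u^\star/K(t))u^\star$,
3. a semi-implicit trapezoidal $y$ step whose logistic term is linearized
   with $u_E$:
   $(1 - \tfrac{k}{2}A_y - \tfrac{\lambda h}{2}(1 - u_E/K(t+h)))u^{\star\star}
   = (1 + \tfrac{k}{2}A_y + \tfrac{\lambda h}{2}(1 - u^\star/K(t)))u^\star$,
4. a second $x$ diffusion half-step.

Every linear solve is tridiagonal (Thomas elimination; the diagonal is
$O(1)$-strong, with a dense fallback should a pivot ever degenerate), and
every named stage is clamped to $[0, K]$ of its target time — the scheme's
regularization, applied unconditionally. The trailing half-step of one step
may be fused with the leading half-step of the next
(`combine_half_steps = TRUE`); the two variants agree to $O(h^2)$ and the
transparent unfused form is the default.

The split semi-implicit step has Fourier gain $\le 1$ for *all* $k$
(`split_step_gain()`), and the package's oracle comparisons run it at
$k \approx 1$. Formal linear stability is not the whole story, though: the
predictor and the explicit right-hand sides still use forward differences,
and for $k \gtrsim 1.3$ they can turn negative on peaked data, after which
the stage clamps produce *pinned fronts* (a wave that freezes mid-domain with
exactly constant mass — we observed this on a land-bridge test at $k = 2$).
`run_simulation()` therefore warns above $k = 1.25$, and the recommended
defaults are $\lambda h \le 0.05$ and $k \le 1$.

### Boundary conditions

Two coastline treatments are provided:

* **Dirichlet** (`bc = "dirichlet"`): segments are conceptually padded with a
  zero pixel at each end. This systematically starves coastal cells (the
  smoothing reaches the zero pad), which is visible in the tests as coastal
  densities well below $K$ — the main reason Neumann is the default.
* **Neumann** (`bc = "neumann"`): zero net flux into the sea, imposed through
  the second-order one-sided derivative rows $(1, -4/3, 1/3)$ at segment
  ends. The $1/3$ corner entries would make the system bandwidth-5, so they
  are decoupled by an explicit Heun (predictor–corrector trapezoid) estimate
  of the third and third-from-last cells, moved to the right-hand side; the
  remaining system is strictly tridiagonal. Refreshing the end cells from
  the boundary rows after the solve is implemented (`refresh_ends`) but off
  by default — it changes results below $10^{-3}$.

A Neumann heat half-step alone is only determined up to an additive
constant; uniqueness over a full step comes from the logistic term, so
half-steps are never taken in isolation.

Habitable runs of one, two or three cells carry no usable derivative
information and get special cases: $n=1$ reduces to the semi-implicit
logistic update; $n=3$ collapses to a single value
$u_2 = \mathrm{RHS}_2/(2S_1 + S_2)$ shared by all three cells; $n=2$ applies
the raw $2\times2$ operator to the old data and then forces the two entries
equal. Two design points deserve flagging:

* The common value chosen for the equalized pair is the **mean** of the two
  solved entries (mass-preserving for the pure-diffusion $2\times2$
  operator); the scheme's description requires equality but does not name
  the common value.
* The raw $2\times2$ operator does **not** annihilate constants (its row
  sums are $-1$), so a two-cell islet at $u = K$ decays slightly instead of
  sitting exactly still. We keep the operator as specified; the exact
  $u = K$ fixed-point property holds for segment lengths 1, 3 and $> 3$, and
  the fixed-point acceptance test uses a rectangular island accordingly.

Whether the Heun-corrected boundary rows also apply to the pure-diffusion
$x$ half-steps is not pinned down by the scheme's description (the bordered
system is only written out with growth terms); we apply the same boundary
rows uniformly, with a diffusion-only Heun estimate, so both sub-steps see
the same coastline physics.

### Map segmentation

The habitable set is decomposed once per capacity-frame interval into
maximal row and column runs (`segment_mask()`), and all 1-D solves act on
these segments independently — on a world map roughly 71% of pixels are
water, so this also bounds scratch storage by one row or column. When the
interval changes, a new mask is computed from the two bracketing frames,
population on flooded cells is discarded, and newly emerged land starts
empty (`apply_mask_transition()`); this is the simplest mass-safe policy for
moving coastlines, isolated behind one operation.

## Time interpolation of capacity frames

Between consecutive frames $K_L$ (at $t_L$) and $K_H$ (at $t_H$) the
capacity is the homotopy $K = K_L(1-S) + K_H S$ with
$S(z) = (1 + e^{-z})^{-1}$ and the warped time

$$z(t) = \frac{2\Delta T(t - t_L) - \Delta T^2}
  {\bigl((t - t_L)(\Delta T - (t - t_L))\bigr)^\nu},
  \qquad \Delta T = t_H - t_L.$$

The endpoints are $0/0$ forms; we return the analytic limits
($S = 0$ at $t_L$, $S = 1$ at $t_H$) exactly. The default $\nu = 1$ makes
$z$ invariant under rescaling all times, flattens every time-derivative of
$S(z(t))$ at both endpoints, and keeps the interpolant forward/backward
symmetric, $S(z(t_H - t)) = 1 - S(z(t))$; $\nu = 1/2$ is close to linear
away from the ends but turns sharply near them, and $\nu < 1/2$ (extra
inflection points) is rejected. A cell is habitable for a whole interval iff
$\max(K_L, K_H)$ exceeds the water threshold, so a bridge whose capacity
rises from zero is segmented from the interval start while $S \approx 0$
still keeps it impassable; resegmentation happens only at interval changes.
Because the kernels divide by $K$, habitable-cell capacity is floored at
$10^{-6}\max K$; the clamp then uses the floored value, which can let $u$
exceed the raw interpolated $K$ by at most that floor — negligible at the
scales involved.

The frame schedule may be nonuniform (the motivating application uses 61
frames from 120 kya to 1 kya in 4-, 2- and 1-ky steps). Manifests are
CSV tables of (`time_kya`, `path`) pairs; times are converted once to a
forward simulation clock, $t_{\mathrm{sim}} =
(\mathrm{anchor}_{\mathrm{kya}} - \mathrm{kya}) \times 1000$ years, so the
stepper never does backwards-time arithmetic.

## The dispersal pipeline

A run (`run_simulation()`) seeds a Gaussian population (default width
$\sigma = 3$ pixels, peak at a fraction of the local capacity), advances the
split step over the frame stack, and records per-pixel *arrival*: the first
discrete step at which $u \ge \mathrm{ccFRAC}\cdot K(\mathbf{x},t)$ against
the *current interpolated local* capacity. The default
$\mathrm{ccFRAC} = 0.1$ probes the steep front rather than the diffusion
tail; arrivals are insensitive between 0.1 and 0.2 but move substantially at
0.5, which the acceptance suite reproduces on a corridor. No sub-step
interpolation is applied to arrival times ($h$ is small against the
kilo-year reporting scale).

Parameter fitting (`grid_search()`) minimizes
$\mathrm{RMS} = \sqrt{\mathrm{mean}\bigl((t^{\mathrm{sim}} -
t^{\mathrm{arch}})^2\bigr)}$ over site pairs — the two-site form
$\sqrt{\tfrac12\sum(\cdot)^2}$ used to fit the American-site arrival data is
the special case — with non-arrival penalized as $+\infty$ and ties broken
by smaller RMS, then smaller $D$, then smaller $r$. On synthetic corridor
arrivals generated at known $(r^*, D^*)$ the search returns the exact
generating cell with RMS 0, and the recovered surface is shallow in $D$ but
sensitive to $r$, matching the published optimization geometry
($r = 2.04\times10^{-3}\,\mathrm{yr}^{-1}$, $D = 190\,\mathrm{km^2/yr}$ on
the real NPP stack, which this package does not ship).

## Synthetic worlds and what green tests establish

`synthetic_world()` builds corridors (1-D physics), rectangular islands,
two-island worlds with a 1-pixel bridge opening at a scheduled frame
(emulating a land-bridge narrative), and an archipelago guaranteed to
contain segments of lengths 1, 2, 3 and $>3$. These exercise every code
path — segmentation, short segments, resegmentation, interpolation,
arrivals — but they are *not* real geography: capacity levels are piecewise
constant, coasts are axis-aligned, and pixel metric is uniform (no latitude
correction, matching the uniform-pixel treatment of the source maps). A
green suite therefore establishes correctness of the numerics and pipeline
mechanics, not fidelity of any particular paleo-dispersal reconstruction;
reproducing published world-map arrival tables requires the original NPP
frame stack and site coordinates, which are inputs, not package contents.

## Numerical choices worth knowing

* **Oracles**: the independent references are method-of-lines
  discretizations (central differences at $\ge 4\times$ resolution, mirror
  or zero ghosts) integrated with a self-contained adaptive Dormand–Prince
  RK45 — a deliberately different code path from the production kernels.
  The radial reference uses the cylindrical Laplacian with the
  $\nabla^2 u(0) = 2u_{rr}(0)$ symmetry limit.
* **Discontinuous initial data** are sampled as cell averages (a cell
  centered on the jump takes $1/2$): coarse and fine grids then represent
  the same initial mass, and solver-vs-oracle comparisons measure scheme
  error rather than a spurious front phase offset.
* **Front speed** is measured from the level-$\tfrac12$ crossing (linear
  interpolation between grid points) fitted over the last half of the
  trace; KPP fronts converge to the asymptotic speed like $v - O(1/t)$, so
  early windows bias the estimate low.
* **Order**: halving $h$ and $\Delta x$ together cuts the oracle-measured
  error by $\approx 4\times$ ($O(h^2) + O(\Delta x^2)$); higher-order
  schemes are out of scope by design — on ragged coastlines stability is
  worth more than order.
* **Determinism**: identical configurations produce bit-identical
  trajectories; the only randomness anywhere is the archipelago's scattered
  cells, which take an explicit seed (default 0) and restore the caller's
  RNG state.

## Known limitations

Two-cell Neumann segments are slightly dissipative (see above). The
uniform-pixel metric ignores projection distortion. Population on flooded
cells is discarded rather than displaced. The $y$ predictor uses the full
CFL weight even though it feeds a half-weighted trapezoid — kept as
specified, with both choices agreeing at $O(h^2)$. Heuristic
travel-distance scalings of the form $a\sqrt{rD}\,t_A + b\sqrt{D t_A}$ are
discussed in the source material but never estimated; they are not
implemented.
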