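---
title: "Methods: landmark-based cell-wall growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based cell-wall growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(wallmark)
```

# The model

`wallmark` studies how a rod-shaped bacterial cell wall grows, using
wall-anchored protein complexes (flagellar motors) as fixed material
landmarks. The cell is a spherocylinder: a cylindrical **active zone** of
length $L$ and diameter $D$, closed by two hemispherical **polar caps**. The
caps, plus an adjacent collar of wall material, are **inert**: no new
peptidoglycan is inserted there. The inert zone has axial size $P_{yc}$
measured from the pole tip.

Within the active zone, wall material is inserted homogeneously, so a
landmark at axial position $y$ (measured from mid-cell) moves with the local
dilation velocity

$$ V(y, t) = H(t)\, y, \qquad H(t) = H_0 (1 + \beta t), $$

the axial analogue of a Hubble flow. Integrating $dL/dt = H(t)\,L$ gives the
exact growth factor $G(t) = \exp\!\big(H_0 (t + \beta t^2/2)\big)$ used by
the simulator; there is no time-discretization error anywhere in the
generator.

Two exact invariants follow and anchor most of the test suite:

1. **Normalized coordinate constancy.** With $N_y = y / L$, an active-zone
   landmark keeps $N_y$ constant during elongation. The simulator stores
   $N_y$ as the state variable and derives lab positions per frame, so this
   invariant holds to machine precision, not approximately.
2. **The hinge law.** A landmark's distance to its nearer pole tip,
   $P_y$, satisfies $P_y(t) - P_{yc} = (P_y(0) - P_{yc})\,G(t)$ in the
   active zone and $P_y(t) = P_y(0)$ in the inert zone. The per-landmark
   average velocity $V_{P_y}$ (OLS slope of $P_y$ against $t$) is therefore
   *exactly* piecewise linear in the initial $P_y$:
   $$ V_{P_y} = \begin{cases} 0 & P_y < P_{yc} \\
      k\,(P_y - P_{yc}) & P_y \ge P_{yc} \end{cases} $$
   with $k$ equal to the OLS slope of $G(t)$ against $t$ over the observation
   window. This holds even with time-varying $H$, which is why the
   changepoint fit recovers the ground truth to grid resolution on
   noise-free data.

## Division and the Bernoulli shift map

Division is modelled as local insertion at mid-cell: over
`division_duration` minutes a septal offset $s(t)$ grows linearly from 0 to
the cap size $P_{yc}$, displacing every landmark outward (on its side) by
$s(t)$, while the two half-rods keep elongating (by default; see *Open
choices*). At completion the cell splits; each daughter inherits half the
active zone plus a newly built polar cap of size $P_{yc}$.

In the normalized coordinate this implements, exactly,

$$ N' = \begin{cases} 2N - \tfrac12 & 0 < N \le \tfrac12 \\
        2N + \tfrac12 & -\tfrac12 \le N < 0, \end{cases} $$

the **Bernoulli shift map**. A landmark exactly at $N = 0$ is assigned a side
by a seeded fair coin. The simulator computes daughter coordinates with the
same floating-point expression as `bernoulli_step()`, so simulated lineages
satisfy the map with *zero* residual — a consistency check between the
mechanistic simulator and the symbolic map, not a numerical tolerance.

The uniform law on $[-1/2, 1/2]$ is invariant under the map, and any
absolutely continuous initial law converges to it; `evolve_distribution()`
demonstrates this for the centre-biased truncated-Gaussian law
($\sigma = 0.4$) that describes newly produced motors, and the test suite
checks the per-generation Kolmogorov–Smirnov distances against an
analytically computed pushforward oracle. `bernoulli_iterate_exact()`
iterates rational starting points in exact integer arithmetic
($p/q \mapsto (4p \mp q)/(2q)$, reduced), where floating point would
eventually drift off the periodic orbit.

# Generator parameters

| Parameter | Default | Rationale |
|---|---|---|
| `cap_size_c` | 0.27 µm (LB), 0.22 (TB), 0.37 (SOC) | measured inert-zone sizes per growth medium |
| `diameter_D` | 1.06 µm (LB), 1.02 (TB), 1.11 (SOC) | TB/SOC measured; **LB is not a measured value** — 1.06 interpolates between TB and SOC, consistent with LB's intermediate nutrient quality |
| `initial_active_length_L0` | 2.0 µm | typical newborn rod |
| `growth_rate_H0` | 0.01 /min | doubling-scale elongation over ~1 h |
| `growth_acceleration_beta` | 0.005 /min² | mild super-exponential growth; set 0 for pure exponential |
| `frame_interval_dt` | 10 min | imaging cadence |
| `n_frames` | 7 | a 60-minute observation window |
| `n_motors` | 9 | ~8.5 spots per cell, matching observed spot density |
| `localization_sigma` | 0.03 µm | typical single-particle localization error |
| `render$pixel_size` | 0.052 µm | camera scale (52 nm/px) |
| `render$psf_sigma` | 0.10 µm | diffraction-limited PSF width |

The defaults are study conditions, not tuning knobs: they were fixed before
the acceptance tests were frozen.

## What the generator does and does not emulate

Emulated: homogeneous axial dilation with inert poles; time-varying growth
rate; septal growth and the cross-generation map; landmark placement uniform
over the wall (founding cells) or centre-biased (new motors); isotropic
Gaussian localization noise; missed detections; diffraction-limited
rendering (Gaussian PSF, constant background, Poisson shot noise) with a
matched phase-contrast-like body channel.

Not emulated: wall twist (landmarks do not rotate around the axis), membrane
fluorescence background structure, focal drift, cell tilting out of the
focal plane, motor assembly/disassembly dynamics, and crowding between
neighbouring cells (each cell is rendered alone).

# Imaging pipeline choices

* **Spot localization** fits a symmetric 2D Gaussian with constant offset
  (`minpack.lm::nlsLM`) in a 12 × 12 px window around smoothed local maxima.
  On isolated-spot fixtures the noise-free bias is at machine precision and
  the RMSE at peak SNR ≈ 10 is ~0.08 px. Errors on dense frames are
  PSF-overlap physics, not localizer error: two motors closer than ~0.25 µm
  are a single diffraction blob.
* **Merged detections** carry inflated fitted widths. The end-to-end
  analysis excludes detections with `sigma_px` above 1.2 × the PSF width —
  standard single-particle quality control; without it, velocity traces built
  from unresolved pairs drag the changepoint fit low.
* **Segmentation** thresholds (Otsu) a smoothed, 4×-bicubic-upsampled body
  frame and extracts the subpixel iso-contour at the threshold level
  (`grDevices::contourLines`). The bicubic upsampling is an in-package
  separable Catmull–Rom interpolant implemented as two matrix products
  (`EBImage::resize` offers no bicubic filter); the working contour is
  capped at 600 resampled points before the $O(n^2)$ pole search.
* **Midline** extraction pairs the two contour poles (maximal separation,
  arc-balanced), resamples both halves, and takes midpoints. Midline length
  recovers the true cell length to ~0.1% and the diameter to ~1%.
* **Division detection** measures contour convexity defects (depth below the
  convex hull) in the central fifth of the midline, requiring the defect to
  persist for two frames.
* **Trace linking** minimizes total frame-to-frame displacement under a gate
  of 0.3 µm per 10 min, solved exactly (Hungarian algorithm) rather than
  greedily: greedy nearest-neighbour matching produces cascade cross-links on
  dense frames. On fixtures whose motors are mutually resolvable
  (pairwise separation ≥ 0.25 µm) linking accuracy is 100% over seeds 1–10;
  with unconstrained placement residual errors are confined to
  sub-diffraction pairs (true separations 0.08–0.14 µm).

## Problem sizes

Recovery analyses pool motors across cells with `simulate_cohort()` — the
observed spot density is ~8.5 per cell, so e.g. 195 motors span ~22 cells.
Packing all motors onto one cell is unphysical and breaks both linking and
the changepoint fit. The end-to-end imaging fixture uses 50 cells × 4 motors
(≈1.6 spots/µm, matching the observed density) rather than 6+ motors per
2.5 µm newborn cell (double the observed density), a choice fixed before the
tests were frozen.

# Changepoint fit

`fit_inert_zone()` profiles the hinge model
$V_{P_y} = k \max(0, P_y - P_{yc})$ (plateau pinned at exactly zero) over a
1 nm changepoint grid, with $k$ in closed form at each candidate
($k = \sum w V / \sum w^2$, $w = \max(0, P - c)$), and a case-resampling
bootstrap (1000 replicates, percentile interval) for the confidence
interval. The bootstrap is vectorized through multinomial count matrices, so
1000 replicates at $n \approx 200$ take about a second.

# Open modelling choices (and what was chosen)

* **Does elongation pause during septal growth?** Default: no
  (`elongation_during_division = TRUE`); the two processes are treated as
  independent. The flag exposes the alternative.
* **Lateral positions.** Motors sit on the cylindrical envelope at uniform
  azimuth; the projected lateral coordinate is $\tfrac{D}{2}\sin\theta$
  (arcsine law across the cell width), the physically correct projection.
* **Pole distance is axial.** $P_y$ is measured along the midline axis
  (image analysis) or as half-length minus $|y|$ (simulator); geodesic
  distance over the hemispherical cap is not modelled.
* **Mid-cell ties.** A landmark exactly at the division site goes to either
  daughter with probability 1/2 via a named, seeded substream, keeping runs
  reproducible.

# Reproducibility

Every stochastic element draws from a named substream
(`placement:<cell>`, `noise`, `miss`, `coin:<cell>`, `shot:<cell>:<frame>`,
`bootstrap`, `bernoulli-init`) derived from one root seed, so toggling one
stage never shifts another stage's draws. `run_pipeline()` writes a
`manifest.json` with the resolved configuration, substream seeds, and md5
checksums of every output; identical manifests certify byte-identical
outputs.

```{r example, eval = FALSE}
cfg <- sim_preset("LB", n_motors = 9, rng_seed = 1)
res <- run_pipeline(cfg, "out", generations = 1)
res$inert_fit
```
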