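---
title: "Methods: from UAV point clouds to dynamic plot phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from UAV point clouds to dynamic plot phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerialpheno)
```

aerialpheno turns the standard products of a UAV survey over a gridded
field trial — a per-date 3D point cloud and RGB orthomosaic — into
plot-level static traits and, across dates, dynamic growth phenotypes.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not establish.

## 1. Canopy height model

**Denoising.** Photogrammetric clouds carry reconstruction outliers. We
use the classical statistical outlier removal rule: for each point,
compute the mean Euclidean distance $d_i$ to its $k$ nearest neighbours
(default $k = 8$); flag points with $d_i > \bar d + \alpha\,\mathrm{sd}(d)$
(default $\alpha = 1$). Both parameters are exposed; the literature
gives no universal setting and the defaults suit clouds with hundreds of
points per plot. Note the rule's geometry: on any *bounded* regular
grid the corner points have the largest $d_i$ and are flagged at
$\alpha = 1$ — this is a property of the rule, not a defect.

**Ground classification.** A simplified cloth-simulation filter: the
cloud is inverted and a particle grid (spacing `cloth_resolution`,
default 0.2 m — deliberately finer than landscape-survey settings, since
a trial field is tens of metres across) falls onto it. Each iteration a
particle drops by a fixed step, sticks to the highest inverted point in
its cell, and is smoothed toward its 4-neighbour mean `rigidness` times
(default 2). After settling, unpinned particles (cells with no
collision, e.g. sparse field edges) are relaxed to the harmonic
interpolation of their pinned neighbours — without this step the cloth
sags by up to one gravity step over empty cells and mislabels edge
points. A point is ground iff its vertical distance to the bilinearly
interpolated cloth is below `class_threshold` (default 0.05 m; raise it
for noisy clouds).

**Rasterization and differencing.** Each class is Delaunay-triangulated
in (x, y) and plane-interpolated onto a regular grid (default cell 0.05
m); this is exact for points sampled from a plane. Because the
aboveground triangulation spans its convex hull, it would "bridge" bare
inter-plot gaps with phantom canopy; the surface model therefore keeps
the canopy TIN only in cells actually containing aboveground points
(occupancy dilated by one cell) and uses the ground elevation elsewhere.
The CHM is $\max(0, \text{surface} - \text{ground}) \times 100$ in cm —
clipped so vertical noise never produces negative heights — and any
remaining field-level slope plane $z = \alpha x + \beta y + \gamma$
fitted to ground references is removed (idempotently). No-data
propagates through all raster arithmetic.

## 2. Alignment and plot segmentation

The four surveyed ROI corners define an exact four-point projective
transform (direct linear transform, 8 unknowns) onto the ROI rectangle
of the orthomosaic pixel frame; a corner-mapping residual above 0.5 px
aborts the run as an alignment failure. Continuous rasters warp with
bilinear inverse mapping, masks with nearest-neighbour (so labels are
never invented). PNG images carry no georeference, so the season config
anchors the world frame at the orthomosaic's bottom-left corner and
states `px_per_m`.

Plot masks come from the CHM of one user-chosen reference date and
benchmark every other date of the season:

1. **ISODATA threshold** — iterate $t \leftarrow$ midpoint of the two
   class means until the move is below 0.5; vegetation is above $t$.
2. **Restricted Hough transform** on the *complement* (the bare gaps
   are the line evidence), $\theta$ within ±5° of each axis, 1° steps,
   1-px $\rho$ bins. A bin becomes a candidate when its votes reach
   `vote_frac` of the relevant image dimension. The default is 0.8: a
   true boundary runs essentially the whole image, while an oblique
   chord can stay inside a gap band for only $\approx$ 0.7 of it, and at
   the conventional 0.5 the accumulator floods with such chords whenever
   gap evidence is abundant.
3. **Merging** — single-linkage clustering of candidate positions at
   half the expected plot pitch, clusters replaced by rounded means;
   manually supplied lines are unioned in and re-merged. Candidates
   within the merge distance of the image border are the border.
4. **Assembly** — image borders are implicit outer boundaries; the
   boundary count must match the trial layout exactly (anything else is
   a hard, named error), and cells are labelled row-major from the
   layout. Uneven pitches are used as found, never idealized.

Every mask is then shrunk about its centroid per trait: scale 0.3 for
heights (avoids inter-plot leaf overlap), 0.7 for coverage, colour and
texture, 0.9 for seedling counting. The whole chain is deterministic.

## 3. Static traits

* **Percentile heights** — H90th/H95th/H50th are the means of the top
  10 % / 5 % / 50 % of CHM cells in the (scaled) plot box, i.e. the mean
  of the top fraction rather than a single quantile. Quantile cuts carry
  a $10^{-7}$ relative tolerance so exact plateau ties survive TIN
  floating-point jitter.
* **Seedling counts** — CHM cells at or above the in-plot 95th
  percentile, gated by normalized excess green $\ge$ 0.40 (removes soil
  clods and water of any height), one 3×3 binary erosion to split
  touching plants, then 8-connected components of at least 4 px. One
  erosion pass is the default because disks with $\ge$ 3 px separation
  are already distinct; more passes only shrink genuine seedlings.
* **Canopy coverage (CCI)** — CHM cells at or above the in-plot median,
  refined by a 51-px mean-filter adaptive threshold (offset 0), overlaid
  on the RGB; pixels count as green when CIELAB $a^* < -5$ (the
  blue-grey of paddy water sits above that gate, chlorophyll well
  below). CCI is green pixels over all pixels of the scale-0.7 box.
* **Vegetative indices** — chromatic coordinates $r, g, b$ give
  ExG $= 2g - r - b$, its affine normalization $(ExG+1)/3 \in [0,1]$
  (exact, since chromatic ExG ranges over $[-1, 2]$), ExR $= 1.4r - g$,
  and NVI $= (g-r)/(g+r)$; GLI, VARI and NDYI are the standard raw-ratio
  forms. All are invariant to image-wide intensity scaling; black and
  zero-denominator pixels are skipped. The normalized green–red
  difference is used for NVI — the upstream source defers its exact
  formula to supplementary material, so the standard literature
  definition is adopted and documented here.
* **GLCM texture** — the region is quantized to 32 equal-width levels; a
  symmetric normalized co-occurrence matrix at distance 1 is averaged
  over 0°/45°/90°/135°; ASM $= \sum P^2$, dissimilarity
  $= \sum P|i-j|$.

## 4. Dynamic traits

Per plot and trait, the multi-date series is fitted with an offset
Gaussian $f(t) = d + a e^{-(t-b)^2/2c^2}$ by bounded nonlinear least
squares (`nls` port algorithm polished by L-BFGS-B; initialization
$a_0 = \max - \min$, $b_0$ = day of max, $c_0$ = span/4, $d_0 = \min$;
bounds $a > 0$, $c \in [1, 200]$, $b \in$ domain ± 30 d). The offset $d$
is our addition to the plain Gaussian: trait floors (bare-soil ExG, the
pre-emergence CHM) are not zero, and the noiseless recovery tests keep
the extra parameter honest. A width at its bound or unclean convergence
attaches a warning to the curve rather than failing.

From the fitted curve, everything is closed-form and cross-checked
against 0.1-day grid sampling:

* growth-difference curve $f'(t)$ (analytic derivative);
* knee points = stationary days of $f'$ = inflection days $b \pm c$,
  reported as the sorted interval; the **rapid growth phase** is
  $[b-c,\, b+c]$, clipped to the observed domain with a flag. We derive
  the knees from derivative roots rather than a knee-locator heuristic —
  the stated detection conditions ($f'_{\text{diff}} = 0$ with a sign on
  $f''_{\text{diff}}$) *are* the derivative roots, so the utility cited
  upstream is treated as an implementation detail. The upstream KP1/KP2
  labels applied to a bell curve are ambiguous; the sorted interval is
  not.
* **fastest growth rate** at the rising inflection: day $b - c$, value
  $(a/c)e^{-1/2}$;
* **average growth rate** over $[t_0, t_1]$:
  $100\,(f(t_1)-f(t_0)) / ((t_1-t_0)(d+a))$ — percent of the seasonal
  maximum per day. The upstream source says only "%"; this definition is
  recorded in the output metadata, and an absolute units/day variant is
  available via `normalize = FALSE`. Reported over $[0, \text{FGR day}]$,
  $[0, \text{max day}]$ and the RGP;
* **normalized curvature** $\kappa = |f''|/(1+f'^2)^{3/2}$, divided by
  its maximum (skipped and flagged for a flat curve). Its argmax marks
  the **max-trait day** (equal to $b$ within one grid step; checked),
  and its first local minimum strictly after the maximum marks the
  **beginning of ripening** ($\approx b + c$, where $f'' = 0$) —
  undefined when the curve is still rising at the last flight. The
  search is restricted to after the curvature maximum because before it
  the same minima mark establishment, not ripening.

Days are reported to 0.1 d. Range-bounded traits (CCI) clamp the
reported maximum to their range.

## 5. The synthetic world

The generators state one fixed world and the tests never tune it:

* a sloped plane $z = 0.02x + 0.01y + 3$ carrying `n_rows × n_cols`
  plots of 2.0 × 1.2 m with 0.4 m water-filled gaps and a 0.8 m margin;
* per-plot canopies of 60–130 cm (the span of paddy-rice canopies),
  shaped as a plateau over the central 75 % of the plot falling to zero
  along a Beta(4, 2) profile — any profile with a known top decile
  works, and the plateau makes the height truth inside centrally scaled
  boxes exactly the nominal height;
* ground points at 50 m⁻², 500 canopy-surface points per plot, optional
  Gaussian z-noise and 5–100 m vertical outliers at a stated fraction;
* orthomosaics at 40 px/m where plot pixels are green with probability
  equal to the plot's coverage fraction; the seedling scene paints 18
  disks (radius 3 px, a typical transplanting design) plus optional
  brown clods of identical size and height — distractors that only the
  colour gate can reject, mimicking paddy soil clods and water-level
  artefacts;
* trait series $d + a e^{-(t-b)^2/2c^2} + N(0,\sigma)$ sampled at eight
  flights on days 10–115 after sowing.

Everything is a pure function of (truth, seed); identical seeds give
byte-identical outputs.

What a green suite establishes: the geometry, labelling, trait
arithmetic and curve analysis are correct on fields that satisfy the
platform's own stated assumptions (regular gridded layout, visible
gaps, green-dominant canopies). What it does not establish: robustness
to SfM doming and ghosting, radiometric drift between flights, lodging,
weeds inside plots, or irregular/zigzag layouts — the last is explicitly
out of scope for the segmentation model.

## 6. Numerical choices and degenerate inputs

* Raster convention: top-left origin, 0-based half-open boxes
  $[r_0,r_1)\times[c_0,c_1)$, stated once and asserted everywhere.
* PNG is the raster store (lossless; 16-bit greyscale written by a
  built-in encoder since the `png` package writes only 8-bit); LAS is
  read natively (1.0–1.4, point formats 0–5), whitespace `x y z [r g b]`
  text is the cloud dialect of record.
* Hough $\rho$ binning uses half-up rounding — R's banker's rounding
  merges adjacent integer-offset pixel columns into shared bins and
  fabricates peaks.
* Duplicate (x, y) locations are averaged before triangulation;
  collinear point sets are hard errors for TIN, plane fits and
  homographies.
* Constant images are an error for ISODATA; constant series are an
  error for curve fitting; empty plot boxes yield missing values, not
  exceptions.
* The cloth settles when the largest particle move is under $10^{-4}$ m
  or after 500 iterations.

## 7. Known limitations

Segmentation assumes one dominant grid orientation aligned with the
ROI; rotated or zigzag trials need upstream rotation or manual lines.
The Gaussian family cannot represent late-season plateaus
(grain-filling); curves with the peak outside the flight window return
clipped or undefined phase days by design. CCI's median-based canopy
mask assumes the plot is not fully closed *and* not fully bare in the
CHM — after canopy closure, coverage saturates and the trait loses
meaning, which is why it is defined for pre-closure dates. The
performance-matrix montage renders plot crops and labels only; it adds
no summary statistics.
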