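---
title: "Planning uniform dose painting with a focused heavy-ion microbeam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning uniform dose painting with a focused heavy-ion microbeam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpaint)
library(dplyr)
```

## The problem

A focused heavy-ion microbeam steers a micrometre-scale beam spot with a
scanner and can, in principle, "paint" any shape observed under the targeting
microscope: an organ of an immobilized *C. elegans*, a group of cells, a test
pattern on a track-detector film. Radiobiology, however, prescribes exposure
as absorbed dose (Gy), while the machine delivers individual ions — and for
high-LET ions each traversal deposits so much energy that the dose in any
small area can only take a few discrete values. Planning a "uniform 100 Gy to
the gonad" therefore means answering three questions:

1. **Which pixels?** Turn a drawn shape or a thresholded fluorescence image
   into a pixel mask on the calibrated camera grid.
2. **How many ions?** Convert the prescribed dose into a natural number of
   traversals for the mask's physical area.
3. **Where exactly?** Place those ions so the deposition is as spatially
   uniform as a finite point pattern can be, and emit the coordinates as a
   scan list the beam scanner consumes.

ionpaint implements this pipeline, plus a virtual CR-39 track detector that
renders the planned hits as etch pits and quantifies the uniformity and the
geometric fidelity of the result.

## Dosimetry of discrete ion hits

For ions of LET $L$ (keV/μm) crossing a unit-density, water-equivalent target
of area $S$ (μm²), consider a slab of thickness $t$: one traversal deposits
$L\,t$ keV into a mass $\rho S t$. The thickness cancels, and with
$1\,\mathrm{keV} = 1.602\times10^{-16}\,\mathrm{J}$ and
$1\,\mathrm{μm^3}$ of unit-density material $= 10^{-15}\,\mathrm{kg}$, each
ion contributes a dose

$$ d_1 = \frac{L \cdot k}{S}, \qquad k = 0.1602\ \mathrm{Gy\,μm^3/keV}. $$

The ion count for a prescription $D$ is the nearest natural number to the
exact expectation,

$$ P = \mathrm{round}\!\left(\frac{D \cdot S}{L \cdot k}\right), $$

and the fluence (ions per μm²) is $F = D/(L k)$. With carbon ions at
$L = 80$ keV/μm this gives the package's anchor values: one ion in a
2 × 2 μm block deposits `r block_dose(1, 80, 4)` Gy, two ions
`r block_dose(2, 80, 4)` Gy, and 100 Gy corresponds to
`r round(fluence(100, 80), 2)` ions/μm². Nothing in between is physically
realizable — this is the dose quantization that makes high-LET planning hard
(for protons, with LET two orders of magnitude lower, the same rounding is
negligible).

`quantization_report()` makes the consequence explicit per region: the
realized dose `block_dose(P, L, S)` differs from the prescription by at most
half a quantum $L k / S$, and regions whose relative error exceeds 5% are
flagged — typically tiny regions whose prescription is below half a quantum,
where the nearest realizable dose is zero.

Rounding is half-away-from-zero; among natural numbers it minimizes the
realized-dose error, and the tie at exactly half a quantum is resolved
upward so a positive prescription on a region large enough to matter is never
silently dropped.

## Region geometry

Masks live on a `calibrated_grid()`: pixel $(i, j)$ spans
$[i, i+1)\times[j, j+1)$ in pixel units and physical coordinates are pixel
coordinates times the scalar μm/px calibration (default 228.9 μm per
180 px, the targeting-camera factor; the default 480 × 640 px screen is
configurable and nothing depends on it). Rasterization uses the
**pixel-centre rule**: a pixel belongs to a shape iff its centre lies inside
the closed contour. The rule is the standard unambiguous scan-conversion
choice; area errors are $O(\text{perimeter})$ pixels and irrelevant next to
the dose quantization. Cardinal splines are sampled at 16 points per control
interval into a polygon before scan conversion; at tension 1 they reduce
exactly to the control polygon.

Brightness partitions use half-open bins (lowest bin open below, top bin
closed above), so every pixel belongs to exactly one band and the union of
bands is the full image — no pixel is double-dosed and none is lost. Bands
may legitimately be empty (a constant image occupies one band); empty bands
are retained with their dose and simply receive no ions.

## Placing the ions

`plan_hits()` first gives every mask pixel the same whole number of "base"
ions (`decompose_per_pixel()`), then spreads the remainder $R < |mask|$ with
one of three methods:

* **random coordinate** — $R$ independent uniform positions in the mask.
  Complete spatial randomness: quadrat counts are Poisson, the
  variance-to-mean (dispersion) index is ≈ 1, and the pattern shows the
  clumps and voids characteristic of pseudorandom points.
* **pixel hit probability** — each pixel is hit independently with
  probability $R/|mask|$. The expected count is $R$ but the total is
  Binomial, so the delivered dose itself becomes stochastic; the total is
  deliberately not renormalized.
* **even random** (production method) — stratified sampling: the mask is
  partitioned into $R$ equal-count cells and one hit is placed uniformly
  inside each. Exactly $R$ hits, zero count variance at the stratification
  scale, yet random within cells — uniform *and* random.

The stratification generalizes a rectangular grid to arbitrary organ-shaped
masks by ordering the pixels along a row-major serpentine (boustrophedon)
traversal and cutting the sequence into $R$ contiguous chunks whose sizes
differ by at most one pixel, larger chunks first (a deterministic,
testable tie-break). Serpentine chunks are contiguous and compact on convex
masks and remain usable on concave, multi-component ones; a Hilbert-curve
ordering would give more isotropic cells and is a possible refinement, but
the dispersion-index comparisons below do not depend on it.

Base ions are placed at a uniform sub-pixel offset rather than at pixel
centres: the 5 μm beam spot dwarfs the ~1.3 μm pixel, so sub-pixel
position carries no physical information, and random offsets avoid lattice
artifacts in the simulated detector read-out.

Every region draws from its own RNG substream seeded by a hash of
`(master seed, region label)`, so a plan is reproducible bit-exactly and
adding, removing or reordering regions never perturbs another region's
coordinates.

```{r methods, fig.width = 6, fig.height = 3}
g <- calibrated_grid(100, 100, 1)
m <- rasterize_shape(shape_rectangle(0, 0, 100, 100), g)
parts <- equal_count_partition(m, 500)
for (f in c(sample_even_random, sample_random_coordinate)) {
  print(glance(quadrat_dispersion(f(m, 500, g, seed = 1), m, g, cells = parts)))
}
```

## The virtual CR-39 detector

Etched CR-39 film is the ground truth for where ions actually landed. The
simulator models the two blurring terms the film reveals:

* **beam-pointing spread**: each hit is displaced by a vector uniform on the
  disk of the spot diameter. A hard-edged disk (not a Gaussian) is
  deliberate: it makes the maximum possible contour expansion an exact
  geometric bound, $(\text{spot} + \text{pit})/2 = 3.5$ μm for a 5 μm
  spot and 2 μm pits, which a Gaussian tail would never attain or respect.
* **etch-pit size**: each (displaced) hit is rendered as a disk of the
  minimum optically visible pit diameter, 2 μm by default. Pit growth
  kinetics during etching are not modelled — one visible diameter
  parameterizes the rendering.

`contour_expansion()` measures how far the rendered pit region protrudes
beyond the target mask: the maximum Euclidean distance from the mask to any
outside foreground pixel, computed from a distance transform of the mask
(`EBImage::distmap`) minus half a pixel to refer distances to the mask edge
rather than to pixel centres. The measurement therefore carries a
discretization uncertainty of about one pixel — at the 0.1 μm/px
resolution used in the package's simulations, ~0.1 μm, well inside the
0.2 μm tolerance with which a dense boundary irradiation (≥ 10⁴ hits in
the outer 0.2 μm of the target) approaches the 3.5 μm bound. That frame —
an 80 × 60 μm field at 0.1 μm/px with 12 000 boundary-band hits — keeps
the computation to a couple of seconds while making the probability that no
hit comes within 0.2 μm of the bound vanishingly small.

Ion scattering in air and tissue is **not** modelled: the sub-0.1% stray
hits seen on real film have no published model to emulate. The
`outside_fraction` statistic exists so measured patterns can be audited the
same way, but simulated patterns without jitter always have outside fraction
exactly 0.

`realized_dose_map()` bins hits into 2 × 2 μm blocks (configurable) and
converts counts to dose; values are exact multiples of the per-block quantum
and total energy is conserved identically, including hits jittered off the
field of view.

## Uniformity statistics

`quadrat_dispersion()` reports quadrat counts, the dispersion index
$I = s^2/\bar n$ (sample variance over mean: 0 for perfectly even placement,
≈ 1 under complete spatial randomness, > 1 for clumping), the chi-square
statistic $\sum_i (n_i - \bar n)^2/\bar n$ with $m - 1$ degrees of freedom,
and the fraction of hits outside the reference mask. Quadrats default to the
stratification cells when comparing placement methods (where even random has
$I = 0$ by construction) and to a regular $q \times q$ grid over the mask
bounding box for generic reports; with zero hits the index is undefined and
reported as `NA`.

## Synthetic fixtures

The fixtures module generates the demonstration targets deterministically
from a seed, so every experiment in the tests and scripts runs without any
external data:

* a centred **circle** (180 px diameter on the default screen) — the convex
  test field for uniform filling;
* **linear and radial gradients** for five-band multi-dose painting
  (0.5–2.5 Gy), exercising batch irradiation of regions at different doses;
* stylized **organ masks**: a pharynx (two elliptical bulbs joined by a
  narrow isthmus band), the same with the isthmus removed (exactly two
  connected components — the geometry used to spare the nerve ring), single
  bulbs, and a U-shaped gonad band whose bounding box spans more than one
  480 px field of view.

These are geometric proxies, not anatomy: the planner is shape-agnostic, so
what matters is covering the shape classes (convex, concave/elongated,
multi-component, graded-dose), not fluorescence realism. Consequently,
passing tests demonstrate the planner's geometric and statistical behaviour
on such shapes; they say nothing about segmentation quality on real
micrographs, about scattering, or about biological response — those remain
properties of the instrument and the organism.

## Degenerate inputs and numerical choices

* Shapes that enclose no pixel centre (zero-area contours) raise an
  empty-mask error rather than planning zero ions silently.
* `ion_count()` requires positive area and LET; dose 0 plans zero hits.
* Stratification requires $1 \le R \le |mask|$; `plan_hits()` never violates
  it because the remainder of integer division is below the pixel count by
  construction.
* Scan lists print coordinates at fixed 4-decimal precision (0.1 nm at
  1 μm/px — far below any physical meaning) so files are byte-reproducible
  across runs and platforms.
* Coordinates are exported in pixel and μm frames, with optional per-axis
  affine voltage columns; the voltage contract (gain, offset, limits) is an
  abstraction of a scanner interface, not a specific device driver.

## Limitations

* LET is a user input, assumed constant over the (thin) target; no
  stopping-power computation, depth dependence, or track-structure model.
* No biological-effect modelling (RBE), no etching chemistry, no optical
  point-spread simulation, and no beam-halo reproduction for collimated
  systems.
* Hardware control (accelerator, scanner, stage) is out of scope; the
  package ends at the scan-list file and starts again at measured hit
  coordinates.
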