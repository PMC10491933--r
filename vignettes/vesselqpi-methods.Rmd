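---
title: "Methods: simulated quantitative phase imaging of cerebral vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated quantitative phase imaging of cerebral vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselqpi)
```

## The problem

Label-free quantitative phase imaging of thick tissue can map the absolute
refractive index (RI) of blood-vessel walls, the cells retained in their
lumens, and the surrounding medium. From such maps one can quantify vessel
wall thickness, lumen diameter, the fraction of a lumen occupied by blood
cells (%Fill), the RI statistics of the wall, and — where a vessel wall is
ruptured — how the wall RI behaves as a function of the distance from the
break. `vesselqpi` implements that entire measurement chain together with a
synthetic phantom generator, so every stage is testable end to end without
access to animal imaging data.

## The imaging model

### Forward model

The simulated instrument is an epi-illumination differential phase contrast
(DPC) system: four sources at azimuths 0/90/180/270 degrees illuminate the
sample obliquely, and each opposing pair produces one DPC image. In the weak
phase regime the normalized intensity modulation is linear in the sample
phase $\phi$:

$$ I_{a,b} = I_0 \left( 1 \pm \mathcal{F}^{-1}[H \cdot \mathcal{F}[\phi]] \right), \qquad
   d = \frac{I_a - I_b}{I_a + I_b} = \mathcal{F}^{-1}[H \, \mathcal{F}[\phi]] . $$

$H$ is the weak-object phase transfer function for partially coherent oblique
illumination. The literature the instrument descends from does not restate
the functional form, so the package computes $H$ from first principles with a
**half-pupil source model**: the pupil is a disc of radius
$\mathrm{NA}/\lambda$ in frequency space, the effective source for the x-shear
axis is the pupil restricted to $u_x > 0$, and

$$ H(\mathbf u) \propto i\,[C(\mathbf u) - C(-\mathbf u)], \qquad
   C(\mathbf u) = \textstyle\sum_{\mathbf v} S(\mathbf v) P(\mathbf v) P(\mathbf v + \mathbf u), $$

normalized by the background intensity $\sum S |P|^2$. The correlation is
evaluated on a two-fold zero-padded frequency lattice (so no circular
wrap-around), and the result is antisymmetrized exactly on the image grid.
Two properties follow by construction and are asserted in tests to machine
precision: $H(0,0) = 0$ (no DC phase response — absolute phase offsets are
invisible) and $H(-u_x, u_y) = -H(u_x, u_y)$ (odd shear symmetry). Support is
clipped at the partially coherent cutoff $2\,\mathrm{NA}/\lambda$. The source
model is one plain function, so an alternative effective-source distribution
can be substituted without touching the inversion.

The normalized-difference DPC convention (rather than a bare subtraction) is
a package convention: it makes DPC values dimensionless and bounded in
$[-1, 1]$, and it is what makes the forward and inverse operators an exact
pair.

### Inversion and the phase-to-RI relation

Phase is recovered by Tikhonov-regularized deconvolution over both shear
axes:

$$ \hat\phi = \mathcal{F}^{-1}\!\left[
   \frac{\sum_k H_k^* \mathcal{F}[d_k]}{\sum_k |H_k|^2 + \alpha} \right]. $$

Because $H(0) = 0$, the mean of $\hat\phi$ is unrecoverable; the package
reports recovered phase **mean-zero** and, after conversion to RI, maps are
therefore *relative to the field mean plus the medium RI*. This matters for
absolute wall-RI readings: wall RI excess is attenuated by the band-pass
nature of $\sum_k|H_k|^2$ (about 35% for a 4 um wall at the default optics),
so recovered wall RI is biased toward the medium while *ordering between
groups is preserved*. Group comparisons of wall RI are consequently valid in
sign and significance, but recovered magnitudes understate generated
differences; the tests assert magnitude recovery only on the
identity-acquisition path (ground-truth stacks analysed directly).

RI and phase convert through the linear relation

$$ \Delta n = \frac{\lambda \, \Delta\phi}{2\pi\,\Delta z}, $$

with $\lambda = 0.72$ um, the effective slice thickness $\Delta z = 3.2$ um
(the axial resolution of the simulated system), and the medium RI
$n_m = 1.3440$ (brain tissue). These three values, the 0.6 NA, the 1 um
z-step, the >20 um diameter filter, the 20 um moving window, and the
50/350 um region bounds are protocol constants; everything else below is a
package convention and is listed with its rationale.

### Key tunable parameters

| parameter | default | unit | status |
|---|---|---|---|
| `wavelength` | 0.72 | um | protocol |
| `slice_thickness_dz` | 3.2 | um | protocol |
| `medium_ri_nm` | 1.3440 | — | protocol |
| `numerical_aperture` | 0.6 | — | protocol |
| `z_step` | 1.0 | um | protocol |
| `pixel_size` | 0.5 | um/px | convention (0.75 um lateral resolution sampled near Nyquist) |
| `tikhonov_alpha` | 1e-3 | — | convention, L-curve on the synthetic bench |
| diameter threshold | 20 (strict >) | um | protocol |
| moving window | 20, centered | um | protocol (centered vs trailing not stated; centered chosen) |
| region bounds | 50, 350 (boundaries to mid) | um | protocol / boundary convention |
| `cell_contrast` | 0.01 | RI units | convention, see segmentation |

## The synthetic phantom

`build_ri_volume()` renders a cylindrical vessel: a lumen of radius $R$ at
the medium RI, a wall of thickness $t$ at $n_m + \Delta n_\mathrm{wall}$,
embedded in a uniform medium. By default the axis lies **along the lateral x
grid axis**, so axial slices are longitudinal sections and the slice through
the axis shows the widest lumen band — this is what gives widest-slice
selection and long (>350 um) along-wall break profiles physical meaning. An
`axis = "z"` mode renders the classic cross-sectional annulus used by several
geometric tests. An optional tilt moves the widest slice off the stack
center to exercise slice selection.

Blood cells are spheres of uniform RI excess (the simplest shape that
supports an area-fraction statistic), centered on the plane that
`select_widest_slice()` will pick, and placed by random sequential insertion
of whole discs inside the lumen until the covered fraction reaches the
target; overlap between cells is allowed, so the achievable range extends to
near 100% with an overshoot of at most one cell's area. Wall "fibers" are
thin elevated-RI runs inside the wall whose segment length parameter spans
continuous (long) versus fragmented (short) fiber textures. Photon noise is
applied **at acquisition** (Poisson, per pixel, per source), never to the
ground-truth RI volume.

Defaults the source protocol does not specify, chosen once as
physiologically plausible and then frozen: wall RI excess 0.020, cell RI
excess 0.040 (red-blood-cell-like against saline), fiber excess 0.020,
lumen radius 15 um, wall 4 um, cell radius 3 um. They are assumptions, not
literature values.

What the generator deliberately does *not* emulate: parenchyma texture,
myelinated structure, multiple scattering (the forward model starts from the
effective oblique source), vessel curvature, and anisotropic cell shapes. A
green end-to-end test therefore establishes that the *measurement chain* is
correct on geometry it fully controls — not that the chain is robust to real
tissue clutter.

## Segmentation choices

Interior and wall masks are first-class *inputs* (8-bit label TIFF,
0/1/2/3 = background/interior/wall/cell), mirroring a manual-segmentation
workflow; the phantom supplies ground-truth masks. No automatic vessel
segmentation is claimed.

Cell detection inside the lumen is Canny edge detection plus a separation
step. Canny thresholds default to Otsu of the in-lumen gradient magnitude
(high) and half of it (low). Edge contours are closed (radius 1; larger radii
bridge neighbouring cells) and filled; pixels brighter than the out-of-lumen
background median by `cell_contrast` are added (recovering packed cell
masses with no interior edges); the union is opened by one pixel; and each
component is kept only if its peak contrast (90th percentile) reaches
`cell_contrast`, cut at **half its peak height** — the half-height contour of
a blurred object passes through the true boundary, which removes the
~half-pixel halo bias a raw edge-fill carries. Finally holes are filled,
because the band-pass transfer function makes the interior of large cell
masses sag toward background. On the synthetic bench this recovers target
fills of 0–80% within ±5 percentage points through the full noisy
acquisition path; near-jammed lumens (>90%) remain biased low and are
flagged as a limitation.

%Fill uses the interior-only denominator (the wall is excluded). The source
formula's "area of the entire blood vessel" is ambiguous on this point; the
interior-only reading is recorded here as the package's interpretation.

## Morphometry conventions

* **Wall thickness**: one sample per medial-axis pixel, `2*EDT - 1` pixels
  (EDT = exact Euclidean distance transform). The `-1` makes a one-pixel band
  read exactly one pixel; even-width bands read one pixel thin — within the
  stated ±1 px tolerance. Samples within one typical wall-thickness of a
  skeleton endpoint are excluded (break tips and field-of-view truncations
  produce artificially shrinking distances there). A ray-casting estimator
  along the local normal is available as a cross-check and warns at >15%
  median disagreement.
* **Lumen diameter**: the maximal inscribed circle, `2 * max(EDT)`, honoring
  a center-to-boundary reading for non-circular lumens; the center is the
  EDT argmax.
* **Diameter filter**: strict `> 20` um; a vessel at exactly 20 um is
  excluded. Idempotent.

## Break profiles

Break endpoints are degree-1 nodes of the wall skeleton. Thinning retracts
free ends of a thick band inward by about half the band width, so each
endpoint is extended along the outward skeleton direction to the last wall
pixel, recovering the break face to within ~2 px on bench geometries.
Endpoints within 2 px of the image border are treated as field-of-view
truncations and dropped. Manual break annotations override detection.

Distances are **geodesic within the wall mask** (8-connected, 1/√2 step
weights — Dijkstra, asserted exactly equal to a brute-force oracle), not
straight-line: a distance "along the blood vessel wall". With two break tips,
every wall pixel takes the minimum distance over the tips of its own
connected component (the conservative reading). The moving mean/SD uses a
centered 20 um window sampled at the pixel pitch; windows with fewer than 3
samples yield `NA`. Region labels: near < 50 um, mid [50, 350] um (boundary
values to mid), far > 350 um. Profiles may be pooled across vessels before
windowing or windowed per vessel; the pipeline records per-vessel profiles
and leaves pooling to the caller.

## Statistics

Group comparison defaults to the **per-animal** unit of analysis: each
animal contributes the unweighted mean over its included vessels, and the
two groups are compared with a two-sided pooled-variance t-test (Welch by
flag) and a two-sided F-test on variances. Identical constant groups return
the convention `t = 0, p = 1`; zero variance in an F-test is a typed error
(`vesselqpi_zero_variance`). A per-vessel unit switch treats each included
vessel as independent. No multiple-testing correction is applied, matching
the source protocol; callers comparing many metrics should apply
`p.adjust(..., "BH")` downstream.

Calibration is tested end to end: on 50 synthetic null cohorts
(identical group parameters, 3 animals per group, full
simulate→reconstruct→segment→quantify→stats chain at 128×128) the t-test
rejects at close to the nominal 5%, and a generated wall-RI difference of
0.01 is recovered with the correct sign in ≥90% of seeds.

## Numerical and reproducibility choices

* Frequency grids are in cycles/um derived from `pixel_size`, FFT wrap
  order; transforms are unnormalized forward / `1/N` inverse.
* All randomness flows through seed streams derived from one master seed
  (kept below $2^{31}$); every generator restores the caller's RNG state.
  Two runs of the pipeline with the same config and seed produce
  byte-identical output tables, including noisy stages.
* Stacks are float32 multi-page TIFF with one page per z-slice; masks are
  8-bit label TIFF. The package carries its own minimal baseline TIFF codec
  (uncompressed, little-endian, single-strip pages) because the target
  environment provides no TIFF library; it was cross-validated against an
  independent Python reader/writer.
* Degenerate inputs are contracts, not crashes: empty masks are named
  errors, sub-3-sample windows are `NA` estimates, a 100% fill target is
  best-effort, slices tied on diameter resolve to the smallest index.

## Known limitations

* Absolute recovered RI carries the mean-zero / band-pass bias described
  above; only the identity-acquisition path yields unbiased magnitudes.
* Cell segmentation degrades above ~90% fill (packing limit, no interior
  edges, band-pass sag).
* The thickness estimator reads even-width bands one pixel thin and is
  validated for bands at least ~3 px wide at the analysis scale.
* The forward model is single-scatter weak-phase; it does not simulate how
  oblique back-illumination arises in tissue, only its effective result.
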