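---
title: "Quantifying tumor-induced collagen orientation: models and methods"
author: "ecmorient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-induced collagen orientation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmorient)
```

## The measurement problem

Tumor spheroids growing in 3D collagen I gels pull on the surrounding
fibrous matrix and re-orient collagen fibers radially, far beyond the
spheroid's own footprint. Endothelial cell spheroids injected into such a
gel sense this remote anisotropy and sprout preferentially toward the
tumor. `ecmorient` quantifies both sides of that interaction from standard
microscopy channels:

* **reflection microscopy** of the unlabeled collagen network, from which
  fibrillar segments are detected;
* **DIC (transmitted-light) images** of the tumor spheroid, from which the
  spheroid mask and radius are segmented;
* **Hoechst z-stacks**, from which nuclei are counted;
* **binary injection masks** of endothelial spheroids, from which
  direction, elongation and their product are scored.

Because no public microscopy data accompany this problem, the package
ships a ground-truthed synthetic-scene generator; every stage of the
analysis is validated against scenes whose statistical structure is known
exactly.

## The orientation statistic and its distance profile

For a detected fiber with centroid $c$ and axis orientation $\phi$
(degrees in $[0,180)$, headless), and a tumor spheroid centered at $T$,
the **orientation parameter** is

$$ s \;=\; \cos^2\!\big(\angle(\,c - T,\; \phi\,)\big) \in [0, 1], $$

the squared cosine of the acute angle between the radial vector and the
fiber axis. Radially pointing fibers score 1, tangential fibers 0, and a
uniformly random fiber population averages exactly 0.5 — the statistic's
key calibration property, which `fiber_orientation_parameter()` reproduces
to 0.005 at $n = 10^5$ in the test suite.

Each fiber is assigned a distance to the spheroid *edge*: centroid
distance to $T$ in micrometres minus the spheroid radius (fibers with
negative distance sit inside the mask and are excluded). Orientation
parameters are averaged in half-open distance bins of 67 µm (100 px at
0.67 µm/px, both configurable), giving an `orientation_profile`.

To the binned means at distances beyond 100 µm a two-parameter single
exponential plateauing at the random baseline is fitted:

$$ y(x) \;=\; 0.5 + (Y_0 - 0.5)\,e^{-x/L_0}, $$

where $Y_0$ is the extrapolated orientation at the spheroid edge and $L_0$
the decay length in µm. Two derived quantities summarize a well:

* **integrated orientation** $\int_0^\infty (y(x) - 0.5)\,dx = (Y_0 -
  0.5)\,L_0$ (µm) — tested against numerical quadrature at $10^{-6}$
  relative tolerance;
* **orientation extent** — the largest distance at which the lower 95%
  confidence bound of the fitted curve still exceeds 0.5, i.e. the range
  over which orientation is statistically distinguishable from random.

A well's collagen value is classified **oriented** when it exceeds the
mean of a reference (control) set by more than one standard deviation
(`classify_oriented()`). Group comparisons use the Mann–Whitney U test for
distribution-level data and the unpaired two-sided Student's t-test for
integrated orientation (`compare_groups()`).

### Numerical choices in the fit

* The model is linear in the amplitude $A = Y_0 - 0.5$ once $L_0$ is
  fixed, so the optimizer is initialized by profiling $L_0$ on a 60-point
  log grid with the closed-form weighted least-squares amplitude, then
  polished with Levenberg–Marquardt (`minpack.lm::nlsLM`) under the bounds
  $Y_0 \in [0,1]$, $L_0 \in (0, 10\,x_{max}]$. If the polish step fails —
  notably on perfectly flat profiles, whose gradient is singular — the
  profiled-grid solution is reported with a Gauss–Newton covariance from
  the analytic Jacobian, so a plateau-only profile cleanly yields
  $Y_0 = 0.5$ and integrated orientation 0 instead of an error.
* Confidence bands use the delta method on the fit covariance with a
  $t$ quantile at (bins − 2) degrees of freedom. The extent is read off a
  1 µm grid up to the last populated bin edge and is 0 when the band never
  clears 0.5.
* Bin means are unweighted by default, matching the convention of fitting
  the displayed profile. For simulation work the package uses the
  config-exposed inverse-SE weighting (`weights = "inverse_se"`,
  $w \propto n/\mathrm{sd}^2$): distance bins at several decay lengths
  from the spheroid contain few fibers and carry almost no signal, and
  giving them full weight makes the unweighted estimator unstable
  precisely on weak-signal fields (amplitude 0.1, short decay), where it
  can collapse onto a parameter bound. Inverse-variance weighting is the
  statistically efficient choice and is what the recovery benchmarks
  report.

## Fiber extraction

The reflection-channel chain follows a classical sequence, each step
exposed as its own function:

1. `subtract_background()` — subtract a circular-averaging-filter
   background (radius 10 px), computed with reflective padding.
2. `rollingball_mask()` — square the signal and flag pixels whose squared
   intensity strictly exceeds the local mean plus 0.5 local standard
   deviations of squared intensity, computed over a circular
   neighbourhood of radius 5 px ("within 5 px distance" is read as a
   disc, matching the circular averaging idiom; a square window is
   available). The local standard deviation uses population ($n$)
   normalization; this too is configurable.
3. `clean_binary()` — remove pixels with zero 8-connected neighbours,
   then close with a 3×3 square structuring element.
4. `label_fibers()` — 8-connected components with strictly more than 20
   pixels and equivalent-ellipse eccentricity ≥ 0.9 become fibers, with
   centroid, principal-axis angle and eccentricity from central second
   moments (regionprops semantics).

The disc-window local statistics and component labeling are implemented in
C++ (a sliding-window cumulative-sum filter and union-find labeling),
because a 20-megapixel scene needs them in well under a second; the test
suite proves them *exactly* equal to brute-force double-loop references on
random images. Angle conventions: image x rightwards, y downwards,
axial angles in $[0,180)$ from +x; all coordinates are 0-based pixel
centres.

## Spheroid morphometry and nuclei counting

DIC images are normalized to a background illumination estimated by a
large median filter. The median window must exceed the spheroid diameter,
otherwise the spheroid itself is absorbed into the "background" and
divides itself out; the default radius is 200 px, computed on a
downsampled copy (the background is smooth by construction, so this loses
nothing and keeps the kernel cheap). The dark core is the below-(mean −
2 SD) component nearest the image centre after Gaussian blur (σ = 4 px).
The full spheroid adds the migration rim: Canny edges of the normalized
image (σ = 2 px; hysteresis thresholds from an Otsu split of the
gradient-magnitude histogram, which separates the noise floor from true
edges even when edges are sparse), dilated by 15 px, united with the core,
hole-filled, then eroded back by the same 15 px. The erode-back step makes
the operation a closing of the rim rather than an expansion, so the
recovered radius does not inherit the dilation radius; phantom spheroids
with cores of 50–150 px and rims of 0–60 px are recovered within 10% (in
practice within ~3%). The reported radius is the equivalent-circle radius
$\sqrt{A/\pi}$ of the combined mask; `expansion_ratio()` divides the
radii of two time points.

Nuclei are counted on the z-summed, Gaussian-blurred stack: threshold at
mean + 2 SD, watershed on the distance transform (tolerance 0.3, which
splits blobs whose centres are ≥ 4σ apart), and two guards against
degenerate inputs — a 20 px minimum object area and a peak-prominence
floor of median + 8 MAD, which no extremum of pure noise reaches (the
maximum of a blank noise image stays below ~5 robust SDs) while genuine
nuclei tower above it.

## Endothelial scoring

From an injection mask's central second moments: the **elongation** is the
equivalent-ellipse major/minor axis ratio; the **direction** maps the
acute angle between the mask's long axis and the vector to the tumor
centre linearly onto $[0,1]$ ($1$ = pointing at the tumor, $0$ =
perpendicular); the **orientation score** is their product, so a round
spheroid scores low no matter where it points. The mask centroid stands
in for the spheroid centre. Near-circular masks (elongation < 1.05) get a
`low_confidence` flag — they are scored, not filtered — and a perfectly
isotropic mask is reported indeterminate since its long axis is
undefined. Pearson correlation plus a linear fit against local collagen
orientation is available via `score_correlation()`.

## The synthetic-scene generator

`generate_fiber_field()` draws fiber centroids uniformly over the image
outside the tumor disk and orients each fiber by a two-component mixture:
with probability $w_0\,e^{-d/\lambda}$ ($d$ = distance to the spheroid
edge) the fiber is exactly radial plus optional Gaussian wobble, otherwise
uniform on $[0,180)$. The mixture is chosen because its expectation is
exactly the analysis model,

$$ E[\cos^2](d) = 0.5 + 0.5\,w_0\,e^{-d/\lambda}, $$

so ground truth for the fit is $Y_0 = 0.5 + 0.5 w_0$ and $L_0 = \lambda$.
`render_reflection_image()` draws anti-aliased segments (~25 px long, 1 px
thick by default) with per-fiber brightness jitter, optional blur, and
additive Gaussian noise, rescaled to $[0,1]$. One seeded pseudo-random
stream per scene makes fields and renderings bit-reproducible; the
caller's RNG state is left untouched.

The DIC phantom is a dark disk plus a granular annulus on a smooth uneven
illumination field. The rim texture is blob-scale (~5 px patches, as
migrating cells appear in DIC), not per-pixel white noise — white noise
would be erased by the Canny pre-blur and is not what cells look like.
Nuclei stacks place Gaussian blobs (σ = 2.5 px) with a minimum centre
separation, spread over neighbouring z-planes; endothelial fixtures are
filled ellipses at controlled angle and axis ratio.

What the generator does **not** emulate: fiber curvature (the detector's
eccentricity gate assumes near-linear structures), 3D fiber networks and
z-resolved anisotropy, gel mechanics, fluorescence spectral realism, and
the true density/length distributions of 1 mg/mL rat-tail collagen, which
are not reported anywhere we could calibrate against. Passing the
recovery benchmarks therefore demonstrates that the *algorithm chain* is
correct and unbiased under the stated generative model, not that the
defaults are tuned to any particular gel chemistry.

## Recovery benchmarks and problem sizes

The package validates the whole chain — render, extract, bin, fit — by
parameter recovery on a $(w_0, \lambda)$ grid $\{0.2, 0.5, 0.8\} \times
\{200, 500, 1000\}$ µm with 20 000 fibers per scene
(`recovery_grid()`). Twenty seeded scenes are assigned round-robin over
the nine cells and the pooled median relative errors of $Y_0$ and $L_0$
must stay below 10%.

Two scene-design points matter here:

* **Field of view scales with $\lambda$.** $L_0$ is identified by how the
  profile bends over a few decay lengths, so each scene's pixel size is
  $\lambda/500$ µm/px (clamped to $[0.45, 1.4]$) over a fixed 4500² px
  canvas, spanning 3–5 decay lengths in every cell. A fixed physical
  field either truncates the decay ($\lambda = 1000$) or starves the
  near-edge bins ($\lambda = 200$).
* **Fiber coverage stays near 6%.** Crossing fibers merge into components
  that fail the eccentricity gate, and in oriented regions tangential
  fibers cross more often than radial ones, so high densities bias the
  recovered amplitude upwards (about +0.1 on $Y_0$ at ~13% coverage in
  our experiments). 20 000 fibers of ~25 px on a 4500² px canvas keep the
  bias well inside the error budget. Extraction typically reports
  slightly *more* fibers than were generated (~26k from 20k) because
  thresholding occasionally splits a rendered fiber; the binned means are
  insensitive to this.

A full-chain scene takes roughly 10 s on one core; the 20-scene benchmark
runs in a few minutes. Unit tests use much smaller scenes (hundreds of
fibers, 256–1024 px images, 512 px phantoms) chosen so each property is
tested at the smallest size where its statistics are decisive.

## Pipeline and outputs

`run_well()` orchestrates everything a well config provides: t0/t48
morphometry and expansion ratio, nuclei counts, fiber extraction, the
profile/fit/extent, and per-injection endothelial scores with the local
collagen orientation (the profile bin containing the injection's
distance) and optional oriented/random classification against reference
values. Stages fail independently; a partial report lists its errors by
stage. Outputs are plain CSV tables (fibers, bins, injections) plus one
JSON summary echoing every parameter actually used, and reruns are
byte-identical. `compare_regions()` reproduces the severed-vs-control
comparison as pure data analysis on rectangular or annular-sector
regions. Thin command-line wrappers (`inst/cli/analyze_well.R`,
`inst/cli/make_fixtures.R`) expose the same functions to shell users.

## Known limitations

* The exact functional form fitted and the confidence procedure for the
  extent criterion are our documented choices (delta-method bands;
  bootstrap over fibers would be a drop-in alternative).
* Orientation is measured per fiber *segment*; long curved fibers are
  fragmented by design and contribute several local orientations.
* The spheroid "radius" of an irregular mask is an equivalent-circle
  summary; strongly anisotropic invasion fronts deserve the principal
  axes also reported in `spheroid_mask` objects.
* Sub-resolution fibers and anisotropic PSFs are outside the rendering
  model; at real microscope resolution the eccentricity gate's behaviour
  should be re-checked against manual annotation.
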