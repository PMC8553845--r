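---
title: "Mapping compound-eye sampling resolution from pseudopupil scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping compound-eye sampling resolution from pseudopupil scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facetmap)
```

## The measurement

An apposition compound eye samples the visual world with one optical unit
(ommatidium) per facet.  The angular divergence between the optical axes
of neighbouring ommatidia — the interommatidial angle, $\Delta\varphi$ —
sets the local sampling resolution, and eye regions of minimal
$\Delta\varphi$ are *acute zones*.  The pseudopupil makes this quantity
measurable in a living animal: the dark (or, with fluorophore-stained
photoreceptors, bright) spot on the eye surface marks the ommatidia whose
axes point at the observer, and when the head is rotated by a known angle
on a two-axis goniometer the spot travels across the facet mosaic.  The
number of facets it crosses per degree of rotation is the reciprocal of
the local interommatidial angle.

`facetmap` implements that pipeline end to end, together with a synthetic
eye generator that provides ground truth for validating every stage:

1. **hex lattice** — facet-row coordinates $(u, v)$ on the hexagonal
   mosaic, with the planar working basis $x = u + v/2$,
   $y = v\sqrt{3}/2$;
2. **synthetic eye** — a parametric acuity field integrated into a
   per-facet gaze field, observed over a goniometer grid and optionally
   rendered into fluorescent/dark image frames;
3. **pupil detection** — sub-pixel centre localisation, intensity
   profiles, landmark registration, facet-diameter measurement;
4. **acuity map** — finite-difference recovery of the local angular
   magnification and assembly of the $\Delta\varphi(azimuth, elevation)$
   map with its acute-zone summary.

## Lattice conventions

Facet-row coordinates follow the two hexagonal row axes at 60°; integer
$(u,v)$ are facet centres and fractional values sub-facet positions (a
pseudopupil centre is typically fractional).  The package fixes the
$u$-axis horizontal and the $v$-axis at $+60°$, so that $x$ aligns with
azimuth and $y$ with elevation in the visual field.  This is a working
convention, not a claim about any species' anatomy: the orientation of
the real facet rows in an image is a free parameter of the registration
(`lattice_frame$orientation_deg`), solved from landmark correspondences
by `solve_lattice_frame()`.  All internal distances are in facet units
(pitch = 1); micrometres enter only through the pixel scale and the facet
pitch of a frame.

## The synthetic eye

### Acuity field

`acuity_field()` is piecewise linear: a flat plateau of half-width $w$
around the frontal axis at the minimum $\Delta\varphi_{\min}$, with
independent linear rises in $|azimuth|$, dorsal and ventral elevation.
The honeybee-forager preset is

| parameter | value | role |
|---|---|---|
| `dphi_min_deg` | 1.30° | frontal acute-zone minimum |
| `plateau_halfwidth_deg` | 10° | flat acute-zone core |
| `slope_az` | 0.00875 °/° | shallow equatorial rise |
| `slope_dorsal` | 0.10 °/° | steep dorsal fall-off |
| `slope_ventral` | 0.015 °/° | gentle ventral fall-off |

These are *derived constants*, constructed — not measured — so that the
full pipeline at the standard 10° goniometer step recovers a frontal
minimum of 1.30°, equatorial values at or below 1.7° out to 40° azimuth,
ventral values at or below 1.9° down to −30°, and dorsal values at or
above 2° by +20° elevation.  A 10° finite difference recovers the
*harmonic mean* of the field over the step, which is why the flat plateau
is needed for the recovered minimum to equal the field minimum exactly,
and why the preset slopes are gentler than the recovered gradients
suggest.

### Gaze field construction

`build_eye()` assigns elevation along the central column by integrating
$d\eta/dy = \Delta\varphi(0, \eta)$ and azimuth along each row by
integrating the field at the row's elevation per unit planar $x$.
Because the field is piecewise linear, both cumulative integrals have
closed forms (linear inside the plateau, logarithmic outside) and are
exactly invertible — `observe()` solves the inverse analytically rather
than numerically, so noiseless observation and gaze evaluation round-trip
to machine precision.  A consequence of integrating a *continuous* field
is that the angular step between adjacent facets equals the harmonic mean
of the field over the unit step; wherever the field is locally constant
(uniform fields, the preset plateau) this is the field value itself.

Goniometer geometry: longitude is a rotation about the vertical head
axis, so at latitude $\ell$ one degree of longitude sweeps the gaze by
$\cos\ell$ degrees of arc along the parallel.  The generator therefore
maps a pose $(\ell, \lambda)$ to the facet at arc coordinate
$\xi = \lambda\cos\ell$ along its row.  Two geometric consequences
matter downstream: the pupil's response to longitude is foreshortened by
$\cos\ell$, and a latitude step at non-zero longitude drags the gaze
sideways along the parallel (meridian convergence,
$\partial\xi/\partial\ell = \lambda\, d\cos\ell/d\ell$).  Both vanish on
the equator and on the frontal meridian — which is where all the
acute-zone claims live.

### Noise model and randomness

Centre-localisation error is applied as independent Gaussian noise in
planar *facet* coordinates (that is where a human or a centroid estimator
errs), not in angles.  Every stochastic element — scan noise, landmark
placement, pixel noise — derives from a single integer seed per
model/scan/render, and noiseless runs are bit-deterministic.

### Rendered frames

`render_frame()` draws the facet mosaic as tangent discs (radius 0.52
pitch) and shades each pixel by the pupil envelope at the pixel's own
gaze direction: Gaussian
$\exp(-\theta^2/2\sigma^2)$ with $\sigma = 20° \times \mathrm{NA}$ for
the fluorescent mode, and an inverted envelope broader by the factor 1.8
for the dark mode — capturing the observed behaviour that the
double-pass fluorescent pupil is sharper than the dark principal pupil
while sharing its centre, and that the apparent pupil width scales with
the numerical aperture of the objective.  Brightness varies continuously
across the pupil rather than per-facet: a strictly facet-uniform
rendering would quantise intensity profiles to facet-sized steps and make
sub-facet width measurements meaningless; the smooth envelope is the
package's phenomenological model of the deep-pupil image seen through the
mosaic.  This is deliberately not physical optics: no diffraction, no
corneal ray tracing, no screening-pigment spectra.  Landmark facets
(fluorescent crystals sprinkled on the cornea) are rendered saturated;
because they outshine the pupil peak, the frame-based recovery path
detects on a landmark-free render and registers on the landmark render of
the same pose.

## The estimator

At each grid node the 2×2 displacement matrix $M$ holds the finite
difference of the centre's planar position per degree of *gaze arc*:
the raw pose differences (central at interior nodes, one-sided at edges)
are normalised by the pose→arc Jacobian
$P = \begin{pmatrix}\cos\ell & \lambda\,\Delta\cos\ell/\Delta\ell\\ 0 & 1\end{pmatrix}$
computed with the same differencing scheme.  The first factor is the
standard cos-latitude correction (without it, off-equator horizontal
components are biased by $1/\cos\ell$); the off-diagonal term removes the
meridian-convergence shear from the vertical component (without it,
$\Delta\varphi_v$ is biased off the frontal meridian).  Using the same
scheme for data and normalisation makes the recovery *exact* for a
uniform field at every node, edges included — the package's analytic
validation limit.

The local Jacobian $J = M^{-1}$ (degrees of gaze per facet) yields

* $\Delta\varphi_h = \lVert J e_x \rVert$,
  $\Delta\varphi_v = \lVert J e_y \rVert$, and their arithmetic mean
  `dphi_mean` — the primary map value;
* `dphi_3axis` — the mean of $\lVert J p_k \rVert$ over the three
  hexagonal row directions, the convention used by the classical
  pseudopupil literature.

Both are always computed and exported; for isotropic $J$ they coincide.
The classical quadrature combination
$\Delta\varphi = \sqrt{\Delta\varphi_h^2 + \Delta\varphi_v^2}$ is
provided as `hex_combine()`; note that in the classical worked example
$\Delta\varphi_h$ means *half* the horizontal row separation (rows are
vertically offset by half a facet, so each row's horizontal neighbour
spacing is twice the column spacing) — the halving is left to the
caller.

No spatial smoothing is applied by default: a 10° step already traverses
about five facets, so the finite difference inherently averages over
roughly the 5 × 5-facet rhomboid used by the manual procedure.  An
optional 3×3 node median filter (`map_median_filter()`) exists but is off
everywhere in this package's analyses.  Nodes with a missing neighbour or
a near-singular $M$ (|det| ≤ 1e−9) are flagged invalid, never
interpolated; edge nodes carry a lower-confidence flag.

`summarize_map()` reports the minimum `dphi_mean` with its grid-node
location (ties broken by smallest elevation, then smallest azimuth — on
the preset plateau the one-sided edge node at azimuth −10° ties the
frontal-axis node exactly, so the reported argmin is the edge node while
the frontal axis attains the same minimum), the azimuth span of
equatorial nodes at or below the threshold (+0.05° tolerance), the
matching frontal-meridian elevation span, and the qualifying node count.

## Validation and its limits

The test suite validates each stage against independent oracles: brute
force for lattice rounding, analytic values for profiles and FWHM
(triangle geometry, $2\sqrt{2\ln 2}\,\sigma$), the generator's own
closed-form gaze field for detection and registration, explicit
three-term averages for the hex-axis statistic, and the uniform-field
exactness limit for the whole pipeline.  End-to-end, the noiseless
honeybee-preset scan (72 observations, < 10 s) must reproduce the
acute-zone claims listed above.

What passing these tests does *not* show: the generator emulates an
idealised eye — separable acuity field, exact hexagonal lattice, isotropic
local steps, Gaussian localisation error, phenomenological optics.  Real
eyes have lattice defects, anisotropy, curvature-dependent facet
diameters, and detection artefacts that the synthetic study cannot
probe.  Claims about real animals require real image data through the
same interfaces (TSV observation tables; TIFF/PNG frames).

Noise robustness deserves a specific caveat.  Because the estimator
inverts $M$, centre noise is amplified roughly by $\Delta\varphi^2$: with
0.2-facet noise the frontal plateau reconstructs to ~0.01–0.05° RMS, but
the steep dorsal rows ($\Delta\varphi$ ≈ 3–3.6°) contribute several times
that, and the interior-node map RMSE fluctuates around 0.15° (roughly
0.09–0.26° across seeds).  A fixed-seed check against a hard 0.15°
bound is therefore marginal by construction; the package reports the
honest figure rather than smoothing it away (the median filter would
roughly halve it, but stays off by default as a documented design
choice).  When mapping steep gradients with noisy centres, prefer finer
goniometer steps or replicate scans over post-hoc smoothing.

## Numerical choices

* Closed-form gaze integrals and inverses; no quadrature, tolerance-free.
* Registration is a complex-regression similarity fit (rotation + uniform
  scale + translation), requiring ≥ 2 distinct landmarks; residual RMS is
  attached to the solved frame.
* Centre detection: threshold at `min + 0.5 (max − min)`, 4-connected
  component containing the global maximum, background-subtracted
  intensity centroid — invariant to affine intensity rescaling; the dark
  mode runs the identical estimator on the inverted frame.  The original
  procedure locates centres by eye; the centroid is a fixed, reproducible
  convention, not the original authors'.
* Profiles: bilinear sampling, min–max normalised ("relative pixel
  values"); FWHM by linear interpolation of the half-maximum crossings
  nearest the peak; plateau ties resolve to the smallest position.
* Singularity guard $|\det M| > 10^{-9}$; Jacobian identity verified to
  $10^{-9}$ in tests.
* Problem sizes: the standard 9 × 8 pose grid (72 observations) for all
  map-level analyses; 256 × 256 px frames at 2.5 µm/px (8 px per 20 µm
  facet) for image-stage analyses.

## Worked example

```{r}
model <- build_eye(honeybee_field(), seed = 1)
obs <- scan_eye(model)
map <- build_map(obs)
summarize_map(map)
```

The `analysis/` directory runs the full study as numbered stages
(simulate, detect, map, recover) writing tables under `results/`, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.
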