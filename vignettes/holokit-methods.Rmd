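---
title: "Models and methods behind holokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holokit)
```

## The imaging problem

A lens-less digital inline holographic microscope (DIHM) is three parts: a
point-like light source (a laser diode coupled into a single-mode fibre, or
an LED behind a pinhole), a bare CMOS sensor at distance $f$ from the
source, and, between the two at distance $s$ from the sensor, a glass slide
carrying semi-transparent micro-objects — beads, red blood cells, plant
cells. Light scattered by an object interferes on the sensor with the
unscattered part of the same wave; the recorded intensity pattern (the
hologram) encodes both amplitude and phase of the object field, and a
numerical back-propagation refocuses any plane of the sample volume from a
single exposure.

holokit implements this computational chain end to end: closed-form design
calculators, a scalar-diffraction simulator with a brute-force reference
integrator, angular-spectrum reconstruction with autofocus, and
quantitative bar-target contrast analysis.

## Design formulas

For illumination wavelength $\lambda$, an $N \times N$ pixel sensor of
pitch $p$ and object distance $s$, the module implements

* lateral resolution, NA form: $\delta_{\mathrm{lat}} = \lambda / (2\,\mathrm{NA})$,
  where the effective aperture of the recording is the half detector side
  seen from the object, $\mathrm{NA} = (N p / 2)/s$ — in that reading the
  pixel form $\delta_{\mathrm{lat}} = s\lambda/(Np)$ is the same bound, and
  the two functions agree to machine precision for every valid geometry;
* optimal object distance $s_{\mathrm{opt}} = f / (1 + f\lambda/(Np^2))$ —
  closer to the sensor the geometry resolves better, but the fringes pack
  below the pixel pitch; the optimum balances the two;
* axial resolution $\delta_{\mathrm{ax}} = \lambda/(2\,\mathrm{NA}^2) = 2 s^2 \lambda / (Np)^2$;
* temporal coherence length of a Gaussian spectral line,
  $L_c = \lambda^2 / (\pi\,\Delta\lambda)$, with `Inf` as the documented
  value for a strictly monochromatic source ($\Delta\lambda = 0$ is a
  legitimate laser-like configuration, not an error);
* Gaussian beam geometry: Rayleigh length $z_r = \pi w_0^2/\lambda$ and
  $1/e^2$ diameter $d(z) = 2 w_0 \sqrt{1 + (z/z_r)^2}$, with $w_0$ the
  mode-field *radius* (half the usually quoted mode-field diameter);
* USAF-1951 chart arithmetic: element frequency
  $2^{\,g + (e-1)/6}$ line pairs per millimetre, line width half a period.

For the reference geometry used throughout the package — $f$ = 30 mm,
$s$ = 5.91 mm, $N$ = 2464, $p$ = 1.12 µm — these give 0.87 µm (405 nm
laser arm) and 0.92 µm (430 nm LED arm) lateral resolution, and the design
report also derives the fringe magnification $M = f/(f-s) \approx 1.245$
and the object-side field of view $N p / M$ (the detector side demagnified
back to the object plane; a common alternative convention scales by $s/f$
instead, which we do not use because it is not the geometric projection).

## Forward model

The simulator builds a complex transmission map per occupied depth plane:
an opaque disk transmits `amplitude_transmittance` inside its radius; a
phase sphere adds the projected-chord phase
$\exp(i k\, \Delta n \cdot 2\sqrt{r^2-\rho^2})$ of a uniform sphere (the
simplest model that produces realistic cell-like fringe systems; the
defaults $\Delta n = 0.06$ for red-blood-cell-like objects are synthetic
fixture values, not measured constants); a bar target is five dark bars of
one line width at a period of two widths, bar length five widths, matching
the contrast-analysis convention of four contrast values per element.

Illumination is the paraxial spherical wave of the point source,
$\frac{f}{d}\exp\!\left[i k\left(d + \rho^2/2d\right)\right]$ with
$d = f - z$; multi-plane scenes are imaged by a thin-object cascade
(multiply by the plane's transmission, propagate to the next plane). Free
space propagation uses the angular-spectrum transfer function
$H(f_x,f_y) = \exp\!\left(i z \sqrt{k^2 - 4\pi^2(f_x^2+f_y^2)}\right)$,
with evanescent components set to exactly zero (at millimetre distances
they are attenuated by hundreds of orders of magnitude; zeroing is the
numerically safe choice). On propagating components $|H|=1$, so
propagation conserves energy to rounding error and is exactly invertible.

Two properties of the discrete model deserve attention:

* **Periodic wrap-around.** An FFT model is periodic: light diffracted
  past the sensor edge re-enters from the other side. For studies where
  the finite camera aperture *is* the resolution mechanism,
  `simulate_hologram(pad_factor = ...)` simulates on an enlarged grid and
  crops the central camera region, so that high-angle diffraction orders
  are genuinely lost.
* **Reference truncation.** The companion brute-force integrator
  (`direct_integral_oracle`) evaluates the Fresnel–Kirchhoff double sum
  with exact point-to-point distances; it necessarily truncates the
  reference wave at the grid aperture, so its background carries edge
  diffraction that the periodic FFT background does not. The two models
  are therefore compared on the *object-scattered* field (object run minus
  reference run, exact by linearity in both), where they agree to a few
  tenths of a percent RMS; the raw backgrounds describe two different
  physical apertures and are not comparable at that level. Likewise, a
  hard-truncated unit aperture never propagates to a flat field on a 64²
  grid — its edge wave keeps several percent of central ripple at any
  distance — so the oracle's free-propagation sanity check asserts
  bounded ripple rather than near-perfect uniformity.

Partial coherence is modelled by incoherent averaging: Gauss–Hermite nodes
(default 7) across the Gaussian spectral line, and a deterministic
sunflower sampling (default 13 points) of the source disk. For
single-depth scenes the source average exploits an exact paraxial
identity — displacing the source by $\xi$ rigidly shifts the detector
intensity by $-\xi z/(f-z)$ — so one simulation per wavelength plus
Fourier subpixel shifts reproduces the per-source-point average at a
thirteenth of the cost; multi-depth scenes fall back to the full loop.
Detector noise is Poisson sampling at a stated photons-per-pixel scale
followed by uniform quantisation, always seeded.

## Reconstruction

Reconstruction operates on the background-subtracted contrast hologram
$I - B$ (zero-mean, unit-max), not on $\sqrt{I}$: this matches the linear
in-line approximation in which the contrast is the interference term
between reference and object wave. Back-propagating the contrast by $z$
returns amplitude, phase and intensity images; the twin image — the
defocused conjugate inherent to in-line holography — is left in place, as
usual when the recording distance is large against the object size. With
`use_effective_geometry = TRUE` the point-source recording is first mapped
to its plane-wave equivalent (magnification $M = f/(f-z)$, effective
distance $z_{\mathrm{eff}} = z (f-z)/f$, image pitch $p/M$), so that the
returned images are in object-plane coordinates; with the flag off the
plain two-FFT plane-wave reconstruction is performed, as in the common
desktop reconstruction tools that take acquisition distance, wavelength
and image size as their only inputs.

`autofocus()` is a coarse grid search over the normalised intensity
variance (`focus_metric()`, scale-invariant, documented as replaceable)
refined by golden-section search. For *single-particle* work the package
adds `locate_particle()`, which is more careful, because two artifacts
systematically mislead whole-image metrics:

* the defocused twin image and the quadratic $|S|^2$ term fill the field
  with structured haze that swamps a whole-image metric for a compact
  object — hence the focus curve is evaluated in a small crop around the
  object, on the variance of the real part referenced to the crop's mean
  phase (invariant to the overall piston $e^{-ikz}$);
* a strong phase sphere is a converging microlens (focal length roughly
  $r/2\Delta n$, tens of micrometres for cell-like parameters): caustic
  planes below the object plane out-shine the object's own image. Above
  the plane there is no structure at all, so the object plane is the
  upper *edge* of the focus-curve plateau; for `object_class = "phase"`
  the estimator takes the steepest-descent edge of the fine curve and
  then refines within ±1.5 axial resolutions to the plane where the
  rim of the object's radial support is sharpest.

Centre and radius then come from the ring-averaged amplitude-deviation
profile around the object: the support edge is the outermost descent below
the haze floor plus 35 % of the peak-to-haze span (strong phase objects
show a central spike, interior nulls and a rim hump, so the *last*
crossing is the rim), minus a quarter pixel for rim diffraction. On the
package's ten-scene fixture suite (beads of 3.25 µm radius, cell-like
spheres of 4 µm, depths 1.2–2 mm, half the scenes with Poisson noise at
10⁴ photons/pixel and 8-bit quantisation) this recovers lateral position
and radius within one pixel and depth within twice the axial resolution.
The estimator is not unconditionally robust: in a wider seed sweep roughly
one deep, noisy phase sphere in ten still misses the depth tolerance, a
limitation inherited from the microlens ambiguity.

## Bar-target contrast analysis

Following the standard procedure, each element's region of interest is
averaged along the bar direction; the Michelson contrast
$K = (I_{\max}-I_{\min})/(I_{\max}+I_{\min})$ of consecutive extrema is
computed, giving four values for a five-bar element; an element counts as
resolved when both orientations yield exactly four contrasts with mean
$K$ at or above a configurable threshold (default 0.05 — the visual
criterion used with physical charts is not numerically specified anywhere,
so the package makes it explicit and tunable), and the last resolvable
element is the finest one before the first failure.

Three implementation details matter on simulated coherent data:

* extremum detection smooths over about *half a bar width* (a fixed
  3-sample window under-smooths coarse bars, whose coherent Gibbs ringing
  sits at the diffraction scale) and prunes oscillations below 15 % of
  the profile range;
* background-subtracted amplitude reconstructions render opaque bars
  *bright* on a dark field — the dual of the chart photograph — so the
  gap/bar polarity is decided from the profile margins, and one contrast
  is computed per interior gap either way;
* `normalize_enhance()` (linear rescale after clipping 0.2 % of each
  intensity tail, the usual display normalisation) is part of the
  processing chain, but note that for a single small element the bright
  bars can occupy less than the clipped tail fraction of the image, which
  distorts per-element percentiles in a way a whole-slide photograph never
  sees.

## The desk-scale resolution study

`usaf_resolution_study()` reproduces, at desk scale, the instrument
comparison between a coherent 405 nm laser arm and a partially coherent
430 nm LED arm (15 nm FWHM, 15 µm pinhole). The absolute experimental
contrast values of a physical chart are not reproducible in a small
simulation; the study instead establishes the *relative* statements: the
laser arm resolves strictly finer elements than the LED arm on identical
scenes, mean contrast does not increase with spatial frequency, and the
laser arm's cutoff matches the pixel-limited prediction within one chart
step.

Problem sizes were fixed as the package's own choice before any
measurements were frozen: a 512² camera at the real 1.12 µm pitch, object
at $s$ = 4.25 mm with the bench ratio $s/f \approx 0.197$
($\delta_{\mathrm{LD}} \approx 3.0$ µm, comfortably above the 2-pixel
printability floor), groups 6–7, forward padding 1.5×. Four deliberate
protocol choices, each with a measured rationale:

* **per-element exposures**: on a 512² grid a full multi-element panel
  occupies some 20 % of the field and inter-element coherent crosstalk,
  twin haze and wrap-around dominate the profiles, which a physical
  slide on a 2464² camera never experiences (there the panel covers a few
  percent); each element is therefore imaged alone at the field centre;
* **finite aperture**: without pad-and-crop, the periodic forward model
  returns diffraction orders that the real camera loses, and the
  resolution cutoff never appears;
* **sub-pixel averaging**: bars a few pixels wide rasterised at a single
  alignment bias individual element contrasts by up to ±0.08; averaging
  the element over placements 0, 1/3 and 2/3 px removes this
  discretisation artifact, exactly as a physical slide sits at an
  arbitrary alignment;
* **scan order**: elements are measured from coarse to fine and the scan
  stops at the first unresolved element, which is also the
  last-resolvable rule's own stopping point.

With these conditions the laser arm resolves to group 7 element 3 (3.10
µm line width, against a 3.00 µm prediction) and the LED arm to group 7
element 1 (3.91 µm) — the same element the physical LED instrument
reaches — and both contrast series are non-increasing within a 0.02
single-step tolerance. Contrast is throughout taken on the normalised
amplitude image at the known target depth in effective geometry.

## What the synthetic data do and do not show

The generator emulates: point-source spherical illumination and fringe
magnification, thin absorbing and refracting objects, finite spectral and
spatial coherence, photon shot noise and quantisation, and the finite
camera aperture. It does not emulate: rigorous Mie scattering (projected
phase only), volumetric multiple scattering, sensor fixed-pattern noise or
Bayer demosaicing, mechanical drift, or the twin-image suppression /
pixel super-resolution techniques of more elaborate pipelines. Passing
tests therefore validate the computational chain under the model's
physics; they do not certify performance on real recordings, where
alignment, background drift and sensor artifacts add error sources the
fixtures deliberately exclude.

## Numerical conventions

All lengths are metres internally; configuration files must carry unit
suffixes. Grids are row-major with row = y, origin at the image centre
(pixel `n %/% 2 + 1`), frequencies in cycles per metre, z positive from
detector towards source, back-propagation by negative distances.
Non-square or awkward grid sizes are zero-padded to the next 5-smooth
square for the FFT and cropped back. Reconstruction distances must be
strictly positive; `z >= f` is rejected in effective geometry. Stochastic
stages (noise) demand an explicit seed and restore the caller's RNG
state; everything else is deterministic, and identical inputs give
bit-identical outputs.
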