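---
title: "Methods: electromagnetic modeling of organism radar cross sections"
author: "aeroscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electromagnetic modeling of organism radar cross sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Weather and research radars routinely detect flying animals, but turning
echoes into biology needs the radar cross section (RCS) of the animal —
how much power it scatters back, as a function of look angle, polarization
and wavelength. Measuring RCS on specimens is slow and delicate;
`aeroscatter` instead computes it from a 3-D body model with a homogenized
("body-averaged") complex permittivity, and supplies everything needed to
check such a computation the way a microwave laboratory would: Mie
reference spheres, an emulated network-analyzer measurement with
substitution calibration, and the polarimetric analytics used on weather
radars (differential RCS, simultaneous-transmit emulation, sector
statistics).

## The scattering model

The solver is a method-of-moments discretization of the volume
electric-field integral equation, better known as the coupled-dipole or
discrete-dipole method. The body is voxelized onto a cubic lattice of
pitch $d$; cell $i$ carries a scalar polarizability $\alpha_i$ and a
moment $\mathbf p_i$ satisfying

$$\alpha_i^{-1}\mathbf p_i \;-\; \sum_{j\ne i} \mathbf G(\mathbf r_i-\mathbf r_j)\,\mathbf p_j \;=\; \mathbf E_{\rm inc}(\mathbf r_i),$$

with $\mathbf G$ the free-space dyadic Green function. Far-field
backscatter amplitudes are coherent phase-weighted sums of the moments,
normalized so that $\sigma_{pq} = 4\pi\,|S_{pq}|^2$. This volume
formulation was chosen over a surface-integral one because it is exactly
verifiable against the Mie series for dielectric spheres, handles
arbitrary inhomogeneous bodies (including partially filled boundary
cells), and reduces to closed forms for one and two dipoles — each of
which is an oracle in the test suite.

Conventions that matter:

* **Time factor** $e^{+j\omega t}$, so lossy media have
  $\varepsilon = \varepsilon' - j\varepsilon''$ and the shipped
  body-average tissue value is $29.29 - j12.89$ (X band). Internally the
  solver uses the opposite (physics) convention and conjugates at its
  boundary; all cross sections are convention-free.
* **Axes**: $x$ anteroposterior (nose $\to +x$), $y$ lateral, $z$
  dorsoventral. Azimuth $0^\circ$ is head-on, increasing clockwise seen
  from above.
* **Polarization basis** (backscatter alignment): for look direction
  $\hat k$, $\hat h = \widehat{\hat k \times \hat z}$ is horizontal at
  zero scan-plane tilt and $\hat v = \hat k\times\hat h$. The same basis
  is used for transmit and receive, which makes reciprocity appear as
  $S_{HV} = S_{VH}$ — asserted on every solve in the tests.
* **Scan-plane tilt** is a rotation of the horizontal scan plane about
  the anteroposterior axis. A tilt of $35^\circ$ reproduces a
  measurement plane tilted relative to the polarization plane; the
  geometric meaning of such a tilt is genuinely underdetermined in
  laboratory descriptions, and this is the one consistent reading the
  package commits to.

### Polarizability

Per-cell polarizability starts from Clausius–Mossotti,
$\alpha_{CM} = \tfrac{3d^3}{4\pi}\,\tfrac{\varepsilon-1}{\varepsilon+2}$,
with the lattice-dispersion-relation (LDR) correction and the
radiative-reaction term as the default (`model = "ldr"`); `cm_rr` and
bare `cm` are available for testing limits. The LDR orientation factor is
fixed at its orientation average $S = 0.2$ rather than recomputed per
incidence: an azimuth sweep can then reuse one matrix factorization for
every look angle and both polarizations. The residual effect on cross
sections is far below the discretization error at the spacings used here.

### Discretization

The default spacing rule is $d = \lambda/(10|m|)$ ($|m| \approx 5.66$ for
the tissue value at X band), capped at any thin-feature thickness. The
solver warns at $|m|kd > 0.5$ and refuses $|m|kd > 1$. Voxelization
includes a cell iff its **center** is inside the watertight surface
(generalized winding number); with `partial = TRUE`, cells cut by the
surface instead receive a volume-fraction-diluted permittivity
(arithmetic mixing with vacuum, fraction from a sub-grid, quantized to
1/32 so that mirror symmetry survives floating-point jitter). Partial
filling is what lets 1-mm wing membranes survive on lattices coarser than
the membrane; arithmetic mixing is exact in the quasistatic limit for
fields parallel to a lamina, which is the horizontal-polarization case
the long-wavelength analyses use.

The cell-center grid is centered on the body's bounding box with an even
cell count per axis, which coincides with "bounding-box minimum $+d/2$"
whenever the span is an integer multiple of $d$. The even count is
deliberate: body mid-planes then always fall *between* lattice sites, so
the mirror symmetries of symmetric bodies survive discretization exactly.

### Solution paths

* **Dense direct** (LAPACK `zgesv`): used when the (possibly reduced)
  system is at most ~12 000 unknowns. Bitwise reproducible.
* **Mirror-parity reduction**: a lattice symmetric across $m$ grid
  mid-planes block-diagonalizes into $2^m$ parity sectors on a $1/2^m$
  fundamental domain (method of images). An azimuth sweep factors each
  sector once and back-substitutes all azimuths and polarizations; parity
  sectors that a given excitation does not excite are skipped. The
  half-body `symmetric_solve()` operation is the $m=1$ case; tests check
  both against brute-force full-lattice solves.
* **FFT-accelerated BiCGSTAB**: above the dense limit, the Green
  convolution is applied on the padded bounding grid by 3-D FFTs,
  matrix-free, to a relative residual of $10^{-5}$ by default.

## Reference solutions and calibration

The Mie module implements the partial-wave series for homogeneous
dielectric spheres (logarithmic derivative by downward recurrence) and
perfectly conducting spheres (PEC limit of the coefficients, not a
large-permittivity dielectric), truncated at $N = \lceil x + 4x^{1/3} +
2\rceil$. Backscatter uses the alternating series at $180^\circ$ with the
same $\sigma = 4\pi|S|^2/k^2$ normalization as the solver, so the two are
directly comparable — that comparison, over size parameters up to 2 at
the tissue permittivity, is the package's primary accuracy gate (10%
relative at $|m|kd \le 0.5$, and empirically much better at moderate
sizes).

The measurement-emulation module synthesizes stepped-frequency records
(amplitude $\propto\sqrt\sigma$, two-way phase $e^{-j2kR}$, complex
Gaussian noise at a settable floor in dBm), averages repeats coherently,
converts to range profiles by inverse DFT (rectangular window by default,
Hann optional), gates 15 cm around the target, and calibrates by
substitution against the 15.82-mm conducting sphere whose true RCS comes
from the Mie module. The alias-free range is $c/2\Delta f$ (267 m for a
0.5614-MHz step). Cross-polar isolation is computed on the gated sphere
record, exploiting the sphere's lack of cross-polar scattering.

## What the synthetic data emulate — and what they do not

The toy organism (ellipsoidal head+torso, full axes
$50\times23.12\times15.8$ mm, plus two 1-mm prismatic wing plates,
default span 0.24 m and chord 0.06 m) is a parametric stand-in for an
anatomical small-bat mesh, which is not publicly available. Its defaults
were chosen once as plausible flight-posture dimensions for a small
free-tailed bat; they are *not* measured anatomy, so tests that pass on
the toy demonstrate solver and pipeline correctness plus qualitative
wavelength trends, not agreement with any particular specimen.

A finding worth stating explicitly: extended wings are **not**
"anatomical detail" in the size-ratio sense. A 1-mm membrane at the
tissue permittivity carries an in-plane polarizability of roughly
$V(\varepsilon-1)/4\pi$ per unit volume against
$3V(\varepsilon-1)/(\varepsilon+2)/4\pi$ for a compact body — about an
order of magnitude more per unit volume — so a winged body is
wing-dominated at every long wavelength and its pattern is
*anti-correlated* with that of a torso-only ellipsoid (the two peak at
orthogonal azimuths). The package therefore defines
`equivalent_ellipsoid()` from the body's approximate overall dimensions
along all three anatomical axes, wing span included; against that
ellipsoid the toy's horizontal-polarization pattern correlation rises
toward 1 once $\lambda/L$ exceeds about 4, which is the behavior the
size-ratio rule describes.
Likewise the VNA scenes contain idealized point scatterers and white
noise — no antenna patterns, drift, or correlated clutter — so
calibration tests demonstrate the processing chain, not instrument
behavior.

## Numerical choices and degenerate inputs

* Dense solves are exact to machine precision; iterative tolerance
  $10^{-5}$ relative residual, BiCGSTAB capped at 2000 iterations with a
  convergence error reporting the residual on failure.
* $\sigma = 0$ (deep nulls) is clamped by a configurable floor
  ($10^{-10}\,$m$^2$) before dB conversion.
* Sector windows are half-open $[\mathrm{lo}, \mathrm{hi})$; the median
  filter window includes both endpoints and uses the midpoint convention
  for even counts.
* The equivalence threshold on a size-ratio curve is operationalized as
  the smallest ratio with $r \ge 0.9$ sustained at all larger ratios.
* Meshes must be watertight (directed-edge pairing); per-region
  components must be individually closed. Degenerate faces are rejected.
* Vertical look directions fall back to $\hat h = \hat y$.

## Problem sizes used by the tests and the acceptance script

Full-fidelity runs of the flagship comparison (the equivalent ellipsoid
at 10 GHz, $d \approx 0.4$ mm, 1–2$^\circ$ azimuths) are multi-hour
computations; the shipped checks use the coarse-grid pilot the package
documents as its standard desk-scale configuration: $d = 0.8$ mm
($|m|kd \approx 0.95$), $10^\circ$ azimuths, mirror-parity dense path
(~19 000 sites, fundamental domain ~2 300). At this resolution the
full-circle and side-on sector means sit within a fraction of a dB of
their converged values; the head-on sector — the deep-null aspect, an
order of magnitude weaker than broadside — converges to a value a
couple of dB below faceted-surface reference models (facet glints fill
a smooth body's null), a model-class difference the tests record
rather than hide. Sphere gates run at $|m|kd \le 0.5$ for size parameters
0.5–1.66 on the dense path and 2.0 on the FFT path; at this material's
very high index the spheres whose size parameters fall on internal
resonance flanks (x near 0.5 and 1.66) converge markedly more slowly
than the off-resonance ones, which the tests document rather than mask.
The size-ratio scenario uses the toy organism with partial-volume voxels
at up to 2.1 mm pitch and $30^\circ$ azimuths: coarse, but the compared
quantity is a pattern correlation, which is insensitive to that
coarseness.

## Known limitations

* Homogeneous (or per-region homogeneous) permittivity only; no
  frequency-dispersive material models within a single run.
* Monostatic far fields only (arbitrary incidence, backscatter
  reception).
* The coupled-dipole method degrades for $|m|kd \to 1$; at the tissue
  permittivity that bound is reached quickly, so high-accuracy X-band
  work on full-size bodies needs the FFT path and patience.
* The scan-plane-tilt reading and the LDR orientation-average choice are
  documented commitments, not the only defensible ones.
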