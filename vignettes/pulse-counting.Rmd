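---
title: "Electron pulse counting for STEM detectors: models, discriminator and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron pulse counting for STEM detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecount)
```

## The problem

Conventional scanning transmission electron microscopy (STEM) detectors
integrate an analog signal: a scintillator converts each scattered
electron into a light pulse that a photomultiplier turns into a
voltage transient of roughly a microsecond. The recorded image
intensity therefore depends on scintillation strength, light-guide
geometry and amplifier settings, carries Gaussian read noise on top of
the unavoidable Poisson electron statistics, and smears along the fast
scan direction whenever the pixel dwell time approaches the detector
decay time. Counting the individual electron pulses instead yields an
image in units of electrons: zero in vacuum, uniform response across
the detector, pure Poisson statistics, and no temporal streaking,
because each electron is recorded as a delta function at its arrival.

`pulsecount` is a software model of a real-time hardware pulse counter
operating on a digitized detector signal (a 14-bit ADC clocked at
125 MHz, i.e. one sample per 8 ns). Every stage of that system —
detector impulse response, electron arrival statistics, trace
digitization, pulse discrimination, image formation, and detector
quality metrics — is implemented as testable R functions, so the
behavioural claims about counting (efficiency under pile-up, streak
removal, uniformity) can be exercised quantitatively on synthetic
signals with known ground truth.

## Detector response model

The single-electron response is modelled as a double exponential

$$ s(t) \propto \left(1 - e^{-t/\tau_r}\right) e^{-t/\tau_f}, $$

sampled on the ADC clock grid and normalised to unit peak
(`make_kernel()`). Measured responses give the defaults: a
scintillator rises in about 100 ns and falls with
$\tau_f = 0.413\,\mu s$; a solid-state (direct-electron) detector is
much faster, modelled with a 20 ns rise and 50 ns fall. The closed
form is a modelling choice — measured pulse shapes can be loaded from
CSV (`read_kernel_csv()`) and used everywhere a parametric kernel can.

Scintillators can additionally show *afterglow*: a second, much slower
decay (here defaulting to $4.5\,\mu s$), attributed to slow release of
charge trapped at defects. `make_afterglow_kernel()` mixes a slow
exponential tail into the fast kernel with a configurable peak
fraction. The default fraction of 0.05 encodes that the afterglow is
far weaker than the primary pulse; no measured amplitude ratio is
available, so the value is a declared, configurable convention.

Kernels are truncated once the tail falls below $10^{-3}$ of the peak.
This bounds the cost of trace synthesis; the discarded tail carries
less than 0.1% of the pulse height and is invisible at any realistic
noise level. Both constants are arguments, not magic numbers.

Decay constants are estimated with `fit_decay()`, a damped
least-squares fit of $A e^{-t/b} + c$ with starting values from a
log-linear regression on the baseline-subtracted tail. Fits are
unweighted; the time window is exposed as a parameter because a window
that starts too early biases $b$: the rising-edge factor only reaches
99.96% of unity eight rise constants past the onset, and when a slow
afterglow component is present the fast component must decay below
about 1% of it before a single-exponential model applies (about
$4\,\mu s$ for the default mixture). The package's own acceptance
checks use exactly these analytically derived windows.

## Event and trace simulation

Electron arrivals are a homogeneous Poisson process
(`sample_poisson_events()`): the expected electrons per microsecond is
the proxy for beam current. Pulse heights are truncated-Gaussian with
coefficient of variation 0.15 by default — detectors show pulse-height
spread, but no specific distribution is implied by the hardware, so
the choice is declared and configurable. Segmented detectors are
described by annular-sector geometries (`detector_geometry()`); the
reference layout (`geometry_quadrants_rings()`) splits the innermost
annulus into four quadrants and surrounds it with two complete rings,
because Rutherford-like scattering concentrates dose at low angles
where subdividing helps most. Events land with uniform azimuth and a
radius drawn from a radial intensity profile; the default is a
power law $w(r) \propto r^{-3}$ emulating high-angle scattering, and
measured profiles can be supplied as knot/weight tables.

Traces are exact linear superpositions of kernel copies plus white
Gaussian noise (`synthesize_trace()`). Event times are continuous, but
each pulse starts at the first sample instant at or after its arrival:
a clocked ADC sees no sub-sample phase, and at 8 ns resolution
sub-sample interpolation would model precision the hardware does not
have. Quantization (`quantize_adc()`) clips to the ADC input range,
scales to the code range and rounds half-to-even.

What the generator deliberately does *not* model: electron-optical
scattering itself (the radial profile is an input, not a multislice
calculation), detector backscattering (near unity transmission
assumed), and coloured noise (white Gaussian by default, with a hook
for measured noise traces). Passing tests therefore demonstrate the
signal-processing claims, not detector physics beyond the
phenomenological pulse model.

## The discriminator

`discriminate()` replicates the hardware counting logic as a
deterministic two-state machine over a working signal — the raw trace
in amplitude mode, or the finite-lag difference
$g[i] = s[i] - s[i-\ell]$ in gradient mode:

* **armed**: when `min_consecutive_above` consecutive working samples
  exceed the threshold, an event is recorded and the machine holds.
* **hold**: the machine re-arms once `min_consecutive_below`
  consecutive samples are at or below the threshold (minus an optional
  hysteresis) *and* the dead time has elapsed.

The consecutive-sample requirements suppress isolated noise
excursions; the dead time enforces the minimum spacing of output
pulses. Defaults (lag 4 samples = 32 ns, two samples above/below, dead
time 2) span the ~100 ns rising edge at 8 ns sampling. Gradient mode
is the interesting one: because only the rising edge produces a large
positive gradient, detection becomes immune to baseline drift from
accumulated afterglow and to amplitude variations across the detector,
and the discriminator re-arms as soon as the edge has passed rather
than waiting a full pulse decay — the mechanism behind its higher
efficiency under pile-up.

Two details are not fixed by the hardware description and are exposed
as options: the event timestamp is the *first* sample of the
qualifying run by default (`record_at = "run_start"`, the
hardware-plausible choice; `"run_end"` is available), and in gradient
mode the re-arm condition watches the gradient, keeping the two modes
symmetric. Hysteresis defaults to zero but exists because real
discriminators often need it: near threshold, noise comparable to the
local slope can re-trigger on a single decaying pulse, which is why
low-rate efficiencies can slightly exceed one.

Efficiency is the plain count ratio detected/true, which can exceed 1
when noise triggers; a time-matched scorer would hide that failure
mode, so the count ratio is the reported definition and values are
never clipped.

## Scan imaging and streak diagnostics

`simulate_scan()` rasters a specimen map (a grid of rate multipliers)
row by row, synthesising *one continuous trace per row* so that pulses
straddle pixel boundaries exactly as in hardware, then forms three
images from identical data: analog (mean of trace samples in each
dwell window, an integrating ADC), counted (discriminated events
binned into half-open dwell windows), and ground truth. Rows reset the
detector by default; an optional flyback-carryover flag lets afterglow
persist across row changes. Frames are independent and averaged.

Streaking is quantified two ways. `edge_tail_length()` measures how
many pixels past a bright/dark edge the row-averaged profile stays
above 10% of the step. `directional_spectrum_ratio()` compares mean
periodogram power in the top-quartile frequency band along the fast
axis against the same band along the slow axis; the zero-frequency
lines are excluded because any pattern constant along one axis — the
specimen itself in a step-edge scan — lives there and would
contaminate the anisotropy measurement, and the corner where both
axes are high is shared and dropped. An isotropic image scores ~1; an
analog image at 50 ns dwell with a scintillator kernel scores orders
of magnitude below 1.

The step-edge demonstration uses 128x128 pixels, 50 ns dwell, 50
frames and 0.25 electrons per microsecond. The rate is chosen to be a
genuinely sparse counting dose: at higher rates pile-up losses
anticorrelate neighbouring pixels along the fast axis and push the
counted-image spectrum ratio visibly above 1 — a real effect of the
method, not an artifact, but a different regime from the streak
comparison. The spectrum ratio of a counted image is stochastic with a
spread of a few percent at this size, so the reported value averages
two independent replicates.

## Detector-map quality metrics

Detector maps (images of the detector's own sensitivity) are analysed
by `detector_qc()`:

* **Active region**: pixels above the midpoint of the map intensities,
  `(min + max)/2`. The region may be discontinuous; a robust variant
  uses the 1%/99% quantiles so a hot pixel cannot empty the mask.
* **Normalization**: background maps to 0, the active-region mean to 1.
* **Ellipticity**: major/minor diameter ratio of the enclosed inner
  opening, from second-moment ellipse analysis (exact for a filled
  ellipse, rotation invariant). Non-annular masks have no opening and
  report `NA`.
* **Flatness**: azimuthal mean of the normalized map (active pixels)
  in 1-pixel radial bins, restricted to bins where the active mask's
  azimuthal average is at least 0.9 — so segment gaps and edges do not
  contaminate the radial profile. Score: RMS deviation from 1.
* **Roundness**: radial mean in 360 azimuthal bins over the valid
  radial annulus, including *all* pixels there — dead wedges and
  segment gaps contribute their low signal, which is exactly the
  azimuthal non-uniformity the metric measures. Score: RMS deviation
  from 1.
* **Smoothness**: RMS deviation of individual active pixels from 1,
  optionally after 3x3 median detrending.

The scalar scores are RMS fractional deviations (lower is better).
The literature defines the four properties but not a unique scalar
formula, so RMS is this package's declared convention, used
consistently; comparability of absolute values with other
implementations is not claimed. The profile center is the inner
opening's centroid when one exists; otherwise the bounding-box center
of the active region is used, which stays unbiased when a dead wedge
bridges the opening to the outside (a mask centroid would shift away
from the wedge).

`synth_detector_map()` renders geometries with known injected
imperfections — per-segment sensitivities, inter-segment gaps, inner
opening ellipticity (area-preserving anisotropic stretch), radial
ramps, azimuthal sinusoids, pixel noise — so every metric can be
validated as a round trip against its injected value, including the
null calibration (ellipticity 1, scores 0) on an ideal annulus.

## The efficiency study

`run_efficiency_curve()` evaluates detection efficiency over a grid of
electron rates and conditions (amplitude vs gradient mode, monolithic
vs segmented, scintillator vs solid-state), with 100 repetitions of
1000 microsecond streams per point. The design is paired: every
condition is measured on identical electron events (common seed
stream), so condition orderings are deterministic given the seed and a
paired bootstrap gives their confidence. Electrons missing every
segment — inside the inner hole, beyond the outer ring, or in a gap —
are excluded from truth and traces alike, so monolithic and segmented
detectors are compared on the same detectable electrons.

Thresholds are tuned per condition by grid search on a held-out
calibration stream at the study rate (fractions 0.15-0.85 of the
working-signal peak of a unit pulse), selecting the threshold whose
detected count is closest to truth; this mirrors the practice of
optimising threshold levels for a specific data stream. Trace noise
defaults to 0.02 of the unit pulse height (a clean photomultiplier
signal); the pulse-height spread and noise spectrum of any particular
instrument are not reproduced, so only orderings and limits — not
absolute curve values — are asserted anywhere.

At 10 electrons per microsecond on a scintillator the study reproduces
the expected hierarchy: amplitude thresholding on a monolithic
detector collapses (the summed signal rarely falls below threshold),
gradient thresholding recovers roughly half the electrons, segmentation
improves both, the combination of segmentation and gradient
thresholding is best, and the faster solid-state kernel beats the
scintillator under matched conditions. At 0.01 electrons per
microsecond every condition is essentially lossless. The absolute
ceiling of the method is one event per two ADC samples — 62.5 MHz at
the 125 MHz clock — reached only by a synthetic alternating signal;
pile-up limits real signals far below that.

## Problem sizes and reproducibility

The bundled tests validate each operation on small grids (traces of
$10^2$-$10^5$ samples, maps of 128-256 pixels, 5-20 repetitions) and
run the full study conditions — 100 repetitions, 1000 microsecond
streams, 128x128 scans at 50 frames, 256-pixel maps — in the
acceptance suite; these sizes are the package's reference study
conditions. All randomness flows from explicit integer seeds; the
command-line interface derives per-stage seeds from one global seed by
a fixed hash (`derive_seed()`), so adding a stage never perturbs
another stage's draws, and writes the resolved configuration next to
every output so any run can be reproduced bit-identically.

## Known limitations

* The pulse model is phenomenological; scintillator photophysics
  (trap states, emission spectra) and detector backscattering are out
  of scope.
* The radial scattering profile is an input; no electron-optical
  simulation is performed.
* Efficiency values depend on the declared pulse-height and noise
  defaults; only orderings and limits are asserted.
* Montage stitching, scan distortion, drift and multi-frame
  registration are not modelled.
* Ellipticity requires an enclosed inner opening; circular (non-
  annular) detectors report `NA` by design.
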