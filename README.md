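# pulsecount

Software model of real-time electron pulse counting for scanning
transmission electron microscopy (STEM) detectors.

Conventional STEM detectors integrate an analog voltage: each scattered
electron excites a scintillator/photomultiplier chain into a ~1 µs
transient, so recorded intensities are arbitrary units contaminated by
Gaussian noise, detector non-uniformity, and temporal streaking at fast
scan rates. Counting the individual electron pulses instead yields
images in units of electrons — zero vacuum level, Poisson-only noise,
uniform response, no streaks. `pulsecount` implements, as plain R
functions, every stage of a hardware pulse counter built on a 125 MHz
14-bit digitizer (8 ns samples), so its behavioural claims can be
tested end to end on synthetic signals with known ground truth:

* **Detector response** — unit-peak double-exponential pulse kernels
  (scintillator: 100 ns rise, 0.413 µs fall; solid-state: 20 ns/50 ns),
  optional slow afterglow admixture (4.5 µs), and exponential-decay
  fitting of the model *A e^(−t/b) + c* (`make_kernel`, `fit_decay`).
* **Event/trace simulation** — Poisson arrivals, truncated-Gaussian
  pulse heights, segmented detector geometries with a weighted radial
  landing distribution, exact superposition trace synthesis, ADC
  quantization (`simulate_events`, `synthesize_trace`, `quantize_adc`).
* **Counting engine** — a deterministic discriminator state machine in
  amplitude or gradient (finite-difference) domain with
  consecutive-sample noise suppression, dead time and hysteresis
  (`discriminate`), event binning and count-ratio detection efficiency.
* **Scan imaging** — simultaneous analog/counted/truth images from the
  identical per-row trace, with streak diagnostics: edge tail length
  and the fast-vs-slow-axis high-frequency power ratio
  (`simulate_scan`, `directional_spectrum_ratio`).
* **Detector-map QC** — ellipticity of the inner opening, flatness,
  roundness and smoothness of sensitivity maps, plus a synthetic map
  generator with injectable defects (`detector_qc`,
  `synth_detector_map`).
* **Efficiency study** — detection efficiency vs electron rate for
  amplitude/gradient × monolithic/segmented × scintillator/solid-state,
  paired on identical events, with per-stream threshold optimisation
  and bootstrap ordering confidence (`run_efficiency_curve`).

## Worked example

Simulate a detector seeing 3.75 electrons/µs for 200 µs and count them
by gradient thresholding:

```r
library(pulsecount)

kernel <- make_kernel("scintillator")
kernel
#> pulse_kernel (scintillator): 390 samples at 8 ns (3.12 us long)

events <- simulate_events(rate = 3.75, duration = 200, seed = 42)
events
#> event_stream: 787 events over 200 us (0 segments hit)

trace <- synthesize_trace(events, kernel, noise_sigma = 0.02, seed = 42)
cfg <- discriminator_config("gradient",
                            threshold = 0.5 * working_peak(kernel, "gradient"))
det <- discriminate(trace, cfg)
det
#> detection_result: 505 events (gradient mode, threshold 0.233897)

detection_efficiency(det, events)
#> [1] 0.642
```

At this rate pile-up already costs ~36% of the electrons — the
motivation for segmented detectors and gradient thresholding (see
`run_efficiency_curve()` and the vignette). Fitting the decay of a
single synthesized pulse recovers the kernel's time constant:

```r
pulse <- synthesize_trace(event_stream(0.05, duration = 5), kernel,
                          duration = 5)
fit_decay(trace_times(pulse), pulse$samples, window = c(0.9, 5))
#> Exponential decay fit: A * exp(-t/b) + c
#>   A = 2.10329 +/- 0.0019
#>   b = 0.413963 +/- 0.00014 us
#>   c = -0.000155647 +/- 1.1e-05
```

Detector-map QC on a synthetic six-segment detector (four quadrants,
two rings, 3° gaps):

```r
detector_qc(synth_detector_map(geometry_quadrants_rings(gap = 3),
                               n = 256, scale = 0.9))
#> Detector map QC
#>   ellipticity : 1.0000
#>   flatness    : 0 (RMS, radial)
#>   roundness   : 0.03705 (RMS, azimuthal)
#>   smoothness  : 0 (RMS, pixel)
#>   active radii: 27 - 108 px
```

The segment gaps show up in roundness (azimuthal uniformity) while the
radial profile stays flat — the metrics separate geometry from
sensitivity defects.

A thin command-line wrapper is installed at `inst/cli/pulsecount` with
subcommands `simulate`, `count`, `scan`, `qc`, `efficiency` and
`fit-decay`; every run writes its resolved configuration and seed next
to its outputs, making results reproducible bit for bit.

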