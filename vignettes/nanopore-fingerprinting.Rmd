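---
title: "Nanopore peptide fingerprinting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanopore peptide fingerprinting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`porefp` turns raw ionic-current recordings of protease-digested proteins
into excluded-current spectra and identifies proteins by spectral matching.
This vignette documents the underlying models, every tunable parameter that
matters, the numerical choices made where the method leaves them open, and
what the synthetic-data generator does and does not emulate.

## The signal model

A peptide entering the nanopore reduces the open-pore current `I_O` (pA) to
a blocked level `I_B`. We work throughout in the positive-baseline
convention: recordings made under a negative applied potential are negated
at ingestion (`normalize_polarity()`), so blockades are always downward
deflections and the excluded current

$$I_{ex}\% = \frac{|I_O - I_B|}{I_O} \times 100$$

lives on [0, 100] regardless of polarity. The magnitude convention is
deliberate: written with a signed difference the quantity would change sign
with recording polarity, while its physical meaning — the fraction of the
ionic current excluded by the analyte's volume — is sign-free.

Each blockade is modelled as a *generalized flat-top normal* (gNDF) shape,

$$f(t) = I_O - \Delta I_B \exp\!\left(-\left(\frac{(t-\mu)^2}{2\sigma^2}\right)^{\beta}\right),
\qquad \beta > 0,$$

which interpolates between a spike (β < 1), a Gaussian (β = 1), and a
flat-topped pulse (β > 1). A single closed form thus captures both the
low-pass filter response (short events never reach a flat top) and the
resident-peptide plateau of long events. Dwell time is the fitted shape's
full width at half maximum,

$$\mathrm{FWHM} = 2\sigma\sqrt{2(\ln 2)^{1/\beta}},$$

which, unlike a threshold-crossing duration, is not skewed for events
comparable in length to the filter response.

Spike-like events with β < 1 are rejected: their amplitude is dominated by
the filter, so `ΔI_B` (and hence `I_ex%`) cannot be estimated reliably.
Only Gaussian and flat-top events enter spectra, which markedly reduces
replicate-to-replicate variance.

## Event extraction: parameters and numerics

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k` | 3 | — | detection threshold in units of local noise spread |
| `window_length` | 50 ms of samples | samples | rolling baseline window |
| `min_length` | 5 | samples | minimum above-threshold run |
| `beta_min` | 1 | — | shape-filter acceptance bound |
| `beta_max` | 10 | — | upper fit bound on β |
| `rss_gate` | 10 | — | reject fits with per-sample RSS > gate × spread² |
| `cutoff` | none (5 kHz typical) | Hz | optional Gaussian low-pass before detection |

Design choices the method itself leaves open, and how they were resolved:

- **Baseline.** The open-pore level and noise scale are estimated per
  non-overlapping window as median and 1.4826 × MAD, linearly interpolated
  between window centers. Robust statistics make the estimate insensitive
  to the events themselves up to at least 10% event duty cycle (tested).
  50 ms windows track slow drift while averaging over many events' worth
  of baseline.
- **Candidate segments.** Maximal runs deviating from the baseline by more
  than `k`× spread toward blockade are extended outward to the baseline
  re-crossing and padded by one core width (minimum 50 samples) on each
  side, then overlapping segments are merged. The pad gives every fit a
  stretch of genuine baseline to anchor `I_O` without bridging
  well-separated neighbouring events into one segment. At a 3σ threshold
  isolated noise samples cross constantly (≈ 0.13% of samples one-sided),
  so a candidate must hold the threshold for `min_length` consecutive
  samples; five samples suppress the false-positive rate below one per
  10⁶ samples while keeping every event long enough to be height-estimated.
- **Fitting.** Bounded Levenberg–Marquardt least squares (`minpack.lm`)
  over all five parameters, initialized at μ = time of the current minimum,
  ΔI_B = baseline − extremum, σ from the half-depth width, β = 1.
  Convergence tolerance 1e−10, 200 iterations. A fit converging onto the
  β = 1 bound from below (within 1e−6) is treated as Gaussian, not
  spike-like. A quality gate on the residual sum of squares (off-switchable
  via `rss_gate = Inf`) additionally rejects segments a single gNDF cannot
  describe, e.g. two overlapping events merged into one segment.
- **Filtering.** The digital Gaussian low-pass is parameterized by its
  −3 dB frequency: a sinusoid at the cutoff leaves with 1/√2 of its input
  amplitude. Because the kernel here is only a few samples wide, the
  discrete kernel's response deviates from the continuous-Gaussian formula,
  so the kernel standard deviation is refined numerically until the sampled
  response at the cutoff is exactly −3 dB. Edges are handled by reflection.
  Whether to filter before or after detection is not dictated by the
  method; `detect_events()` filters before detection when a cutoff is
  given, since the fit assumes the filtered shape.

## Spectra, re-alignment, and baseline correction

Spectra are histograms of accepted events' `I_ex%` on 100 unit bins,
half-open `[a, a+1)` with the last bin closed so a full blockade (100%)
is kept. Normalization divides by the event count.

Replicates drift along the `I_ex%` axis with salt concentration,
temperature, and amplifier offset. Re-alignment shifts the sample spectrum
over a ±5 I_ex% grid in 0.05 steps and keeps the shift minimizing the
residual sum of squares against a reference. Two choices are open here:

- **Interpolation.** Shifting a 1%-binned spectrum by 0.05% requires
  sub-bin interpolation; bin values are treated as samples at bin centers
  and interpolated linearly, with mass shifted outside [0, 100] dropped.
- **Reference and order.** The reference is the first replicate per
  protein by input order (overridable), and spectra are normalized first,
  aligned second — alignment of count-normalized spectra makes the error
  metric independent of replicate event counts.

Baseline correction (rolling minimum over 8 bins, smoothed by a moving
average of the same window, subtracted and clamped at zero) is provided
for display, but is **off** in the matching path: the derivative in the
matching score already cancels baseline sloping, and the correction is an
extra nonlinearity with a free parameter.

## Mass calibration and MS projection

Mean `I_ex%` versus peptide mass is described by a second-order polynomial
$I_{ex}(m) = b_0 + b_1 m + b_2 m^2$, fitted by unweighted ordinary least
squares (no variance weights: replicate scatter of the calibrant means is
roughly homogeneous across the mass window). "Including the origin" is
implemented by appending (0, 0) as one ordinary data point rather than
constraining $b_0 = 0$ — a massless analyte excludes no current, but the
constraint form would contradict the nonzero fitted intercept. The shipped
default model (`b0 = 3.28`, `b1 = 7.23e−2`, `b2 = −1.33e−5`, domain
0–1700 Da) is monotone increasing over its whole domain; inversion solves
the quadratic and keeps the in-domain root.

An ESI-MS peak table is projected into a predicted spectrum by placing a
Gaussian of σ = 0.5 I_ex% (an arbitrary display width, matching the
resolution of measured spectra) at each peptide's calibrated position.
Orbitrap detectors report intensity as the squared ion count, so peak
areas enter under a square root. Two readings of that correction are
defensible — the root of the summed mixture, or per-peak roots summed —
and both are implemented (`mode = "sum_then_sqrt"` is the default;
peak *positions* are identical under both, only relative heights differ).
The density is evaluated on a 0.05% grid and averaged into the standard
1% bins so projected and measured spectra share a grid.

## Spectral matching

The similarity score is the squared first-derivative Euclidean cosine

$$DEuc = \frac{(\sum_i \Delta a_i \Delta b_i)^2}{\sum_i \Delta a_i^2 \sum_i \Delta b_i^2} \in [0, 1],$$

computed on forward first differences of the normalized spectra restricted
to the 50–98 I_ex% window (below ≈50% small-peptide signal mixes with
sub-detection-limit noise; above 98% sit full blockades). Differentiation
makes the score exactly invariant to per-bin constant offsets, and the
ratio to positive rescaling of either spectrum. The window is half-open
[50, 98) at the bin level; "numerical differentiation" is taken as the
forward difference.

Identification is leave-one-out: each replicate (sample) is scored against
every protein's mean spectrum computed from all *other* measurements, and
assigned to the argmax. Exact score ties are reported as ties (predicted
label `NA`), never silently broken by input order. For display the
protein × protein matrix of sample-averaged scores is normalized per row
(row maximum to 100 by default; row-sum normalization is offered — the
argmax assignment is identical under both).

## The synthetic-data generator

`simulate_trace()` emulates the recording conditions the analysis targets:
a 100 pA positive open-pore current with 2 pA additive white Gaussian
noise sampled at 50 kHz, blockades rendered exactly as gNDF shapes whose
depths derive from peptide masses through the calibration model plus 1%
Gaussian jitter, log-normal dwell times (median 2 ms, shape 0.3), shapes
uniform on [0.7, 3.0] so that the spike filter sees genuine β < 1 events,
Poisson event times, and a per-replicate global `I_ex%` offset
(σ = 1%) emulating run-to-run drift — the feature the re-alignment stage
exists to remove. An optional capture-bias weight per peptide stands in
for the charge/hydrophobicity capture effects of real pores without
modelling their physics. All randomness flows from one seed; derived
per-replicate seeds are recorded in the output.

What it does **not** emulate — and hence what passing tests do not show
about real recordings: the analog Bessel filter of the acquisition
hardware (events are ideal gNDF shapes, so the fitter is tested against
its own model family); 1/f and interference noise; baseline drift within
a trace; multi-level sub-states; capture-rate physics; and the
volume-versus-mass discrepancies that make real calibrations only
approximately quadratic. The simulator validates the pipeline's
statistical machinery, not the pore physics.

Degenerate inputs are refused rather than guessed at: flat traces cannot
be thresholded, empty event tables cannot make spectra, configurations
with event_rate × median dwell > 0.1 would violate the sparse-event
assumption and raise an error advising a lower rate.

## Problem sizes and verification

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to give stable statistics while remaining quick on one CPU:
200 isolated events for gNDF parameter recovery (depth mean absolute
relative error < 2%, β < 10%, ≥ 95% detection and acceptance); 100 spikes
and 100 flat-tops for the shape filter; 100 Monte-Carlo repeats of a
7-point calibration at 0.5% noise; six imposed spectral offsets spanning
±4.8%; 1000 random sequences against an independent regex cleavage
oracle; and an end-to-end benchmark of 4 synthetic proteins × 3
replicates (30 s traces at 20 events/s, ≈ 600 injected events each) that
must be identified 12/12 by leave-one-out matching with every on-diagonal
mean score exceeding its row's off-diagonal scores. No empirical claim is
made here that those runs do not themselves compute.

## Known limitations

- The gNDF fitter assumes one event per segment; overlapping events are
  merged by the threshold search and then rejected by the fit-quality
  gate rather than deconvolved.
- Dwell times shorter than ~5 samples are dropped at detection; at 50 kHz
  and 5 kHz filtering this is the sensible floor, but it biases dwell-time
  distributions at the short end.
- The mass→I_ex% calibration is a pore- and buffer-specific empirical
  curve; the shipped default applies to the FraC G13F T1 pore in 1 M KCl
  at pH 3.8 and should be refitted for any other system.
- Identification is closed-set: a spectrum is always assigned to the best
  database protein; there is no open-set rejection of proteins absent
  from the database.
- Axon Binary Format traces are not read; convert to two-column text
  first.
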