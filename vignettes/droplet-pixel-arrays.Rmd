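---
title: "Methods: simulating and compiling droplet pixel arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and compiling droplet pixel arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletpix)
```

# The system being modeled

A desk-scale droplet-microfluidics platform generates monodisperse aqueous
droplets in oil, loads them with combinations of three fluorophores
(excited at 405, 488 and 561 nm), senses each droplet as it transits three
laser excitation points in front of a single photomultiplier tube (PMT),
sorts selected droplets dielectrophoretically, and immobilizes them in a
serpentine chain of anchors. Because each newly sorted droplet enters the
chain and knocks every occupant one anchor further along, the array is a
first-in/first-out displacement register; sorting droplets in the right
color order therefore *paints* an image, 25 droplets per 5×5 tile, and
a correctly rendered image is a visual certificate that every sensing and
sorting step upstream was correct.

`dropletpix` implements this computational layer — signal synthesis, peak
detection, classification, component surrogates, the image compiler, and
an end-to-end workflow simulator — so the whole chain can be exercised and
falsified on a desk, with ground truth, and without hardware.

# Synthetic PMT traces

A trace is `baseline + drift·t + ε + Σ pulses` on a uniform grid, with
`ε ~ N(0, noise_sd²)` and Gaussian pulses. Design choices:

* **Gaussian pulses.** The true transit pulse shape is set by flow profile
  and beam geometry and is not characterized; a Gaussian is smooth,
  symmetric, and gives one interpretable width parameter.
* **Linear drift.** Only the *existence* of baseline drift is
  characterized (it is the stated reason peak samples are excluded from
  the baseline average). A linear ramp is the simplest adversarial case
  for a moving-average tracker: any unmodeled curvature is locally linear
  at the window scale anyway.
* **Single multiplexed stream.** The three lasers share one PMT, so one
  droplet yields three time-separated pulses in a single stream rather
  than three parallel channels.

## The stated world (defaults)

The sampling rate and transit timing of the instrument are not
characterized, so the package fixes one realistic operating point and
keeps it everywhere:

| parameter | default | why |
|---|---|---|
| sample rate | 10 kHz | comfortably resolves ms-scale transits on a microcontroller-class ADC |
| baseline | 0.5 V, noise SD 0.02 V | mid-range PMT offset; noise sets the SNR scale |
| channel levels | low 0.2 V, high 2.0 V | low level = 10× noise SD, i.e. SNR 10, the regime the detector must handle; high level well separated |
| transit spacing | 3 ms | three pulses per droplet, each pair separated by ≥10 pulse widths |
| pulse width (σ) | 0.3 ms | ≈3 samples per σ: narrow but detectable (≥3-sample peaks) |
| inter-droplet gap | 20 ms | 50 droplets/s, below the 80 /s sorting cap |
| group CV | 5% | tight, monodisperse populations; between-group separation ≈ 18 within-group SDs |

An earlier bring-up configuration (2 ms spacing, 0.4 ms σ) violated the
generator's own contract: the Gaussian tails between consecutive pulses
stayed above the detection threshold and the three per-droplet peaks
merged into one. The defaults above restore the defining property that
each droplet produces three separable peaks; they were fixed before the
acceptance suite was written and have not been revisited.

# Streaming peak detection

The detector mirrors the real-time microcontroller algorithm. It keeps a
moving average over the most recent `baseline_window` (default 200)
samples that were classified as baseline. A peak opens when the signal
exceeds

`threshold = mean(window) + k · SD(window)`, default `k = 5`,

and closes when the signal returns to or below the threshold *frozen at
entry*; its magnitude is the in-peak maximum minus the baseline at entry
(a maximum, not an area — magnitude is the quantity the hardware
thresholds against). Samples inside a peak are never added to the window,
which is what keeps the baseline from drifting upward through a burst of
transits. Peaks shorter than `min_peak_samples` (3) are discarded; a peak
still open at end-of-stream is closed at the last sample. The first
`baseline_window` samples are always baseline (warm-up).

Numerical and algorithmic choices:

* **"SD of the moving average"** is read as the SD of the *samples in the
  window*. The alternative reading — the standard error of the mean,
  smaller by √n — shrinks with window length, is numerically fragile, and
  at `k = 5` would put the threshold inside the noise band. Both are
  available (`sd_mode = "window"` / `"mean"`).
* **Flank guard band.** Excluding only *above-threshold* samples is not
  enough: the sub-threshold rising and falling flanks of every pulse
  would enter the window, inflate its SD, raise the threshold, which
  admits even more flank into the window — a positive feedback that was
  measured (in this package's stated world) to triple the effective
  threshold and swallow the 0.2 V low-level peaks. The detector therefore
  delays baseline commits through a `baseline_guard_samples` lag FIFO
  (default 10 samples = 1 ms): the pending samples are discarded when a
  peak opens (rising flank) and the same number of samples is skipped
  after a peak closes (falling flank). Setting the guard to 0 reproduces
  the naive reading. This is the package's own engineering addition to
  the published algorithm description and is flagged as such.
* **Streaming state.** All detector state (ring buffer, pending FIFO,
  running sums, open-peak registers) round-trips through the chunked API,
  so feeding a trace in arbitrary chunks is bit-identical to one pass —
  the property a firmware port needs.
* **Running sums.** Mean and SD come from running `Σx, Σx²` over the ring
  buffer; at trace magnitudes (~1 V) and window lengths (~10³) the
  cancellation error is ~10⁻¹³ of the variance, far below any decision
  boundary, and a negative-variance guard handles constant input.
* **Ablation.** `include_peaks_in_baseline = TRUE` feeds every sample to
  the baseline, reproducing the failure the exclusion rule prevents; the
  test suite uses it as the contrast arm for drift immunity.

Peaks whose start times fall within `group_time` (8 ms: the 6 ms transit
span plus flank slack, well under the 20 ms droplet gap) of the group's
first peak form one droplet signature; groups with a peak count different
from the expected 3 are flagged incomplete, padded with zeros, and must
never be sorted.

# Classification onto the palette

Palette index is the binary encoding `4·blue + 2·green + red` of the
per-channel high/low levels. Two classifiers are provided because it is
not characterized which one drove live sorting decisions:

* `fit_kmeans()` — unsupervised recovery of the populations:
  `stats::kmeans` on the raw 3-channel magnitudes, Euclidean distance, 10
  seeded restarts. Centroids get palette labels by thresholding each
  channel at the midpoint of that channel's centroid range. No log
  transform: magnitudes are already background-subtracted and the
  palette corners make the metric choice immaterial except for ties.
* `calibrate_thresholds()` — supervised per-channel tests with thresholds
  at the midpoint of the low and high calibration means (1.1 V by
  default), the natural choice for a microcontroller comparing against
  target values.

Ties (equidistant centroids, values exactly at threshold) resolve to the
lowest palette index, for determinism. Incomplete signatures classify to
`NA` — a droplet the sorter must not deflect.

# Component surrogates

Only operating-envelope endpoints are characterized for the hardware
components, so the surrogates are calibrated to reproduce exactly those
endpoints and the standard monotonicities, and refuse extrapolation:

* **Generation.** On log-normalized flows `x` (oil), `y` (water) in
  [0, 1], diameter maps `(1−x)^a·y^b` and rate `x^c·y^d` onto 95–176 µm
  and 4–368 Hz (exponents default 1, configurable). Droplets shrink with
  more oil and grow with more water; rate rises with both. Out-of-range
  flows raise errors naming the violated bound, mirroring the physical
  failure modes (unstable generation below, broken bonding/doublets
  above).
* **Poisson loading.** Exact pmf via `stats::dpois`;
  `encapsulation_stats()` returns P(0), P(1) and P(1)/(1−P(0)). At λ = 0
  the occupied fraction is 0/0; the analytic limit 1 is returned.
  OD→cells uses 2.88×10⁸ (*E. coli*) and 1×10⁷ (*S. cerevisiae*)
  cells/(mL·OD).
* **Picoinjection.** Absolute pressures are not characterized, so
  pressure is normalized to [−1, 1] about equilibrium and mapped
  piecewise-linearly with f(−1) = −3%, f(0) = 0, f(+1) = +50%; strictly
  monotone, and `picoinject()` conserves volume exactly.
* **Sorting regimes.** At 1 mL/hr the characterized brackets are
  no-deflection below 100 V and failure above 400 V; `sorted` fills the
  closed interval between. Boundaries scale linearly with flow by default
  (drag force ~ velocity; only the 1 mL/hr bracket is printed, so the
  scaling is configurable).
* **Anchors.** The trap-and-knock band on a normalized flow axis defaults
  to [0.5, 1.5], with `stuck` below and `pass` above — the three ordered
  outcomes partition the axis.
* Throughput caps (80 droplets/s sorting; ~100 Hz picoinjection) are
  stored as metadata and enforced by the simulator as rate limits, not
  re-derived.

# The pixel compiler

`quantize_image()` block-averages an RGB raster to the target grid and
assigns each cell the nearest palette color (palette at the corners of
the RGB cube, so nearest-color equals per-channel midpoint thresholding);
exact ties go to the lowest index, making a mid-gray image quantize to
black deterministically. Quantization is idempotent through rendering.

The serpentine map is the boustrophedon traversal from the entrance at
the top-left (row 1 left→right, row 2 right→left, …). The physical
traversal direction is not printed; any bijection consistent with the
FIFO law works, and the map lives in one place (`anchor_array()`).
Because `n` pushes leave the `(n+1−i)`-th pushed droplet at position `i`,
`compile_instructions()` simply reads the target colors along the
serpentine from the farthest anchor back to the entrance;
`replay_instructions()` is the independent oracle that pushes them
through the FIFO and must reproduce the tile exactly.

`decompose_grid()` tiles a mosaic row-major into 5×5 tiles and
deduplicates patterns by exact equality (so each unique pattern is
generated once and reused); `stitch_tiles()` is its validated inverse.
The "editable interface" of the original tool is deliberately out of
scope; edits are pixel overrides applied to the grid before compilation.

# The workflow simulator

`run_workflow()` draws droplet groups i.i.d. uniformly (the physical
reinjection order is unknowable), synthesizes the full PMT trace for the
stream, and runs the *actual* detector and classifier on it — the
simulator consumes no ground truth for its decisions (truth is only used
to align logs for reporting). The sorter follows a wait-for-color policy:
a droplet is deflected iff its classified color matches the next
unfulfilled instruction; everything else passes to waste. Sort timestamps
respect the 80 droplets/s cap. Sorted droplets are pushed through the
anchor FIFO and the final grid is verified pixel-by-pixel against the
target.

Fault injection models the three named failure modes: *nonspecific
sorting* (a non-matching droplet is deflected and consumes the
instruction), *anchor skip* (a sorted droplet is lost before the array —
the instruction is consumed but nothing is pushed, so everything sorted
earlier shifts one anchor toward the far end and unoccupied far anchors
render dark), and *double occupancy* (an extra push whose excess knocks
the earliest droplet off the far end). The mechanics of these faults are
not characterized; these choices make each fault leave a distinct,
localizable fingerprint in the verification report, which is the point of
the diagnostic use case.

A stream of `stream_factor × 8 × n_instructions` droplets (default factor
4, i.e. ~800 for a tile) makes exhaustion a >15σ event for a uniform
8-color stream; exhaustion raises a typed incomplete-run condition with
the fulfillment count.

# What a green test establishes — and what it does not

The generator emulates pulse trains over drifting noisy baselines with
realistic timing, but **not**: photon shot noise or PMT gain statistics,
pulse-shape asymmetry, droplet-size-coupled transit variation, optical
crosstalk between fluorophores, coincident droplets, or pressure
fluctuations coupling the components. Detector recall of 1.0 at SNR 10,
perfect k-means recovery, and pixel-exact workflow fidelity are therefore
statements about the algorithmic chain (no logic, bookkeeping or
inversion errors; correct behavior under the modeled noise), not about
instrument-level limits of detection. The wet-lab quantities (fluorophore
LODs, biological fluorescence distributions) are deliberately not
reproduced.

Other known limitations: anchor-array hydrodynamic resistance is not
modeled (the source material itself states opposite polarities for its
effect on trapping in two places, which is recorded, not resolved);
regime-boundary scaling away from 1 mL/hr and the generation response
surface interior are uncharacterized interpolations; the 35-glyph
alphanumeric library uses a package-designed font (the original glyph set
is not enumerated); droplet arrival is strictly periodic rather than a
point process.
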