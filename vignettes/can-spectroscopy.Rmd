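---
title: "Cell adhesion noise spectroscopy: model, pipeline and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell adhesion noise spectroscopy: model, pipeline and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canspec)
```

## The physical model

A non-electrogenic cell adhering to the oxide surface of a capacitive
CMOS sensor leaves an electrolyte-filled cleft, tens of nanometres thick,
between its membrane and the chip. That cleft behaves as an ohmic
resistance $R_\mathrm{cleft}$, and like any resistor it generates
Johnson–Nyquist thermal voltage noise with a one-sided spectral power
density

$$S_V = 4\,k_B\,T\,R_\mathrm{cleft},$$

with $k_B$ the Boltzmann constant (exact SI value,
$1.380649\times 10^{-23}$ J/K) and $T$ the absolute temperature. A sensor
under a cell therefore records *more* voltage noise than a bare sensor,
and the excess — the **cell adhesion noise**
$\Delta S_V = S_V^\mathrm{culture} - S_V^\mathrm{bare}$ — is a label-free,
non-invasive detection signal. Inverting the relation gives the cleft
resistance from a measured plateau:

$$R_\mathrm{cleft} = \frac{\Delta S_V}{4 k_B T}.$$

```{r eq1}
cleft_resistance(V2_per_Hz(0.027), temperature = 310.15) / 1e6  # MOhm
```

A plateau of $0.027\ \mu V^2/\mathrm{Hz}$ at incubation temperature
(310.15 K) corresponds to a 1.58 MΩ cleft. The temperature matters: the
same plateau at room temperature would imply 1.64 MΩ, which is why the
package defaults every temperature to 37 °C unless the recording metadata
says otherwise.

Two spectral regions bracket the usable signal. Below ~10 kHz the
recordings are dominated by $1/f$ setup noise and are excluded from
analysis. Between 100 and 450 kHz the adhesion noise is flat — a
frequency-independent, purely resistive cleft — and this *plateau band*
carries the biology. A single analysis frequency in the middle of the
band, 300 kHz, summarises each sensor into one scalar, giving the
*electrical image* of the chip.

## The analysis pipeline

Starting from per-sensor voltage time series (or precomputed PSDs) of a
culture recording and a bare-sensor calibration of the same chip:

1. **Welch PSD estimation** (`welch_psd()`): Hann window, 50% overlap,
   4096-sample segments at 1 MHz sampling. These defaults give a 244 Hz
   bin width — fine enough for the 1–450 kHz acquisition band — and
   several hundred averaged segments per second of data. The estimator
   satisfies Parseval's contract (PSD integral ≈ series variance, tested
   at < 2%). The acquisition software that motivated this package computes
   $S_V$ internally without documenting its estimator; Welch with stated
   parameters is this package's documented, reproducible substitute.
2. **Background subtraction** (`subtract_background()`): bin-wise
   culture − bare, valid because the cleft noise and the sensor's own
   background are independent sources whose powers add. The raw
   difference keeps negative bins: they are genuine estimation noise, and
   clamping them before averaging would bias plateau means upward.
   Negative values are clamped to zero only in the imaging map
   (`extract_map()`), where Otsu thresholding benefits from a stable
   background class.
3. **Map extraction** (`extract_map()`): value at the frequency bin
   nearest 300 kHz; exact ties resolve to the lower bin. Nearest-bin
   lookup (not interpolation) matches a discrete acquisition grid and is
   exactly reproducible.
4. **Segmentation** (`segment_cells()`): percentile grayscale mapping
   (1st–99th percentile window onto 0–255, scale-invariant), 5×5 Gaussian
   blur with σ = 1 px to suppress single-sensor errors, Otsu thresholding,
   morphological opening then closing with 3×3 box elements, and removal
   of components under 4 sensors (roughly one 15 µm cell at ~6 µm pitch).
   The source pipeline names these operations without parameters; all
   values here are package defaults, exposed as arguments.
5. **Quantification**: covered area is the exact count ratio
   `100 · cell-covered sensors / all sensors`; the mean $\Delta S_V$ over
   cell-detecting sensors uses raw (unclamped) values; time-course tables
   feed unpaired t-tests and one-/two-way ANOVA with the four-level star
   annotation (`group_compare()`), deliberately without multiple-testing
   correction to match common reporting practice in this assay class.

An independent per-sensor rule, `detect_cells_threshold()` (culture PSD
above the sensor's calibrated background mean plus $k\sigma$), is provided
alongside the image pipeline; on well-resolved layouts both exceed 0.95
balanced accuracy against simulator ground truth.

## The simulator

Because no public recordings exist for this assay, the package ships a
physics-grounded generator whose ground truth drives every downstream
test.

**Layouts** (`build_layout()`): elliptical cell footprints with axes drawn
from a diameter distribution, placed uniformly without overlap (bounding
circles) and rasterized onto the grid through the physical pitch: a sensor
is cell-covered when its centre falls inside the ellipse, and a 3×3
subsample of its footprint provides a fractional coverage weight at the
boundary. Single HT-29-like cells are ~15 µm and dermal fibroblasts
~40 µm; because adherent epithelial cultures grow as multi-cell clusters,
the experiment-level defaults use cluster-scale footprints (35 ± 8 µm).
Random sequential placement of disjoint disks jams near 55% coverage, so
denser layouts admit a bounded overlap (`max_overlap`), with the first
cell keeping any contested sensor.

**Spectra** (`synth_psd()`): each sensor's one-sided PSD is
$$S_V(f) = \frac{A_\mathrm{pink}}{f^\alpha} + S_\mathrm{white}
  + \mathbb{1}_\mathrm{cell}\, w\, \phi\, 4 k_B T R_J\, B(f),$$
where $w$ is the coverage weight, $\phi$ the cell's adhesion-area
fraction, and $B(f)$ the plateau band response: 1 on 100–450 kHz with a
raised-cosine roll-off in $\log_2 f$ reaching zero one octave outside
either edge. Only in-band flatness is physically constrained; the roll-off
shape is a modelling choice kept continuous so spectral estimates near the
band edges are undistorted. Additive composition encodes the
uncorrelated-sources assumption, and in the noiseless limit the
culture-minus-bare difference equals $w \phi\, 4k_B T R_J$ exactly (a
tested invariant).

Three noise layers make the synthetic data realistic:

* *device mismatch* — per-sensor background offsets (relative SD 0.5),
  fixed per chip and **shared** between the culture recording and its bare
  calibration, since real mismatch is a device property; this is precisely
  what background subtraction cancels;
* *session drift* — a smaller per-sensor change between recording sessions
  (relative SD 0.03) that subtraction does not cancel;
* *estimation noise* — each bin scaled by $\chi^2_{2K}/2K$, the sampling
  distribution of a Welch estimate over $K$ averages (default
  $K = 487$, i.e. 1 s of data at the default Welch settings).

No background amplitudes are published for this hardware. The defaults
($S_\mathrm{white} = 5\times10^{-15}\ V^2/\mathrm{Hz}$, $A_\mathrm{pink}$
set so the $1/f$ term crosses the white floor at 10 kHz) were chosen once
so that a typical plateau of 0.01–0.03 µV²/Hz stands 5–10 background
standard deviations above the subtracted background — detectable, but not
trivially so — and are recorded in every fixture manifest rather than
asserted as measured values.

**Dynamics** (`evolve_layout()`): proliferation adds daughter footprints
adjacent to random parents until the covered area tracks
$\exp(\mathrm{rate}\cdot t)$; detachment removes each cell with per-hour
hazard; both are label-conserving, so true area trajectories are monotone
by construction. The presets are calibrated analytically to the observed
drug-response magnitudes: doubling of covered area over 72 h untreated
($\mathrm{rate} = \ln 2 / 72\ \mathrm{h}^{-1}$) and a 1.8-fold decline
under cytotoxic treatment ($\ln 1.8 / 72$). With ~100 cells the Bernoulli
detachment realisation scatters a few percent around the calibrated fold.

**Time series** (`synth_timeseries()`): white complex-Gaussian spectra
shaped by $\sqrt{S_V(f)}$ and inverse-transformed, so Welch estimates
converge to the target and Parseval holds.

## What the simulator does and does not emulate

It reproduces the features the pipeline actually exploits: grid geometry
and pitch, the $1/f$-plus-white background, flat in-band adhesion
plateaus scaling as $4k_BT R_J$, partial sensor coverage at cell borders,
chip-to-chip and session-to-session variability, estimation noise, and
growth/detachment kinetics. It does **not** model amplifier transfer
functions or ADC quantisation, spatial noise correlation between
neighbouring sensors, cell migration or shape change, membrane-process
noise beyond the ohmic cleft, or optical micrographs (overlays consume a
user-supplied image and affine transform — registration is explicitly the
user's input, not an algorithm here). Passing tests therefore demonstrate
correctness of the *analysis* under the stated noise model, not
performance on any particular laboratory's recordings.

## Numerical choices and degenerate cases

* Internal units are strictly SI (V²/Hz, Hz, K, Ω); µV²/Hz and MΩ appear
  only at presentation boundaries (`uV2_per_Hz()`), eliminating the
  $10^{-12}$ scaling bug class.
* Sensors are addressed 0-based, row-major, row = slow axis; the
  grid↔linear mapping is a tested bijection.
* Otsu ties: every threshold inside an empty histogram gap induces the
  same partition; the plateau of maximisers resolves to its midpoint
  (the common library convention). A constant image yields an empty mask
  and threshold 255 by convention.
* A constant adhesion map grayscales to an all-zero image (no dynamic
  range); grayscale mapping is invariant to positive rescaling.
* Gaussian blur uses a reflective border; kernel 1 is the identity.
* Morphology order is opening → closing. Hand-working small cases shows a
  single-pixel hole in a block is only recovered when the object is
  comfortably larger than the 3×3 element (an 8×8 block works; a 6×6
  block loses its interior to the opening) — one reason the cleanup
  parameters are exposed.
* Plateau flatness is max $|\log_{10}(S/\bar S)|$ over in-band bins with
  a 0.15 default threshold for the "resistive" flag; no published
  criterion exists, so the value is configurable and documented.
* Fold changes always report magnitude ≥ 1 plus an explicit direction
  label, since "x-fold" phrasing is ambiguous between senses.
* The exact physical extent `n · pitch` of the default 256 × 384 array is
  1.664 mm × 2.1504 mm; data sheets round it. The package stores the exact
  value and never reconciles the rounded one.

## Problem sizes in the test suite

The shipped tests exercise the full pipeline at desk scale: 64 × 96
sensor grids (6,144 sensors) for segmentation and dynamics studies, 1 s of
1 MHz single-sensor data for spectral round trips, 20-layout sweeps of
10–60% true coverage for area-recovery benchmarking, and exhaustive
oracles (flood fill, brute-force Otsu scans) on 32 × 32 masks and random
histograms. The full 256 × 384 geometry is validated for bookkeeping and
is directly usable in `simulate_experiment()` at proportionally larger
run times.

## Known limitations

Segmentation accuracy degrades for objects near the morphological
resolution limit (~2–3 sensors across, i.e. isolated 15 µm cells at 6 µm
pitch): opening shaves thin boundary rings, so per-sensor balanced
accuracy is quoted for cluster-scale objects. The mean $\Delta S_V$ over
all mask sensors sits systematically below the single-cleft plateau
because boundary sensors are only partially covered — the package exposes
coverage weights so users can restrict to interior sensors when estimating
$R_\mathrm{cleft}$. The cytoplasmic-resistivity analysis of the core-coat
conductor model is out of scope: its governing equations live in prior
work and are not reimplemented here.
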