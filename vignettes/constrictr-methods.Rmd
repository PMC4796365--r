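---
title: "Quantifying cell migration through microchannel constrictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell migration through microchannel constrictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constrictr)
```

## The assay and its measurements

Fast amoeboid cells such as dendritic cells (DCs) migrate spontaneously
through microfabricated channels (width *d* ≈ 7 µm) containing
constrictions of width *W* (1–3.5 µm) and length *L* (5–20 µm). Two
fluorescence channels are recorded every 2 min: an F-actin reporter
(LifeAct) delineating the cell, and a DNA stain (Hoechst) delineating the
nucleus. The cell body passes narrow gaps easily; the nucleus, stiffened
by its lamin A/C shell, is the limiting cargo. The phenomenon of interest
is a transient, Arp2/3-nucleated actin shell that assembles around the
nucleus inside small constrictions ("confinement-induced actin network"),
correlates with successful nuclear passage, and coincides with local
rupture of the nuclear lamina at the leading nuclear pole.

`constrictr` implements the full measurement chain for this assay:

* **microdevice frame** — axial positions in µm; the constriction is the
  half-open interval `[center − L/2, center + L/2)`. A front exactly at
  the entry plane counts as *entered* (ties break toward "entered", the
  generous convention for scoring nuclear entry). Pixel `i` has its
  centre at `(i − 0.5) · pixel_size`.
* **segmentation** — per frame, per channel: Gaussian smoothing (σ = 1 px),
  automatic thresholding, hole filling, largest connected component.
* **tracking** — per-frame centres of mass and front/back axial edges of
  cell and nucleus; instantaneous velocities by backward difference.
* **events** — the four-phase passage structure (cell entry, nuclear
  entry, nuclear exit, cell exit), the outcome label, passage and
  non-passage times.
* **actin metrics** — normalized mean actin inside the constriction and
  in the perinuclear cortex; a per-cell binary enrichment call; nuclear
  circularity; the DNA-thickness/actin relation; peribead actin.
* **lamina metrics** — angular intensity profile of the lamina ring on
  fixed-cell stills, gap detection, rupture perimeter, tip localization.
* **statistics** — Fisher's exact test and the Mann–Whitney test,
  implemented from first principles with pinned-down two-sided
  conventions, plus mean/s.d./s.e.m. summaries.

No public raw data accompany the quantified cohorts this package
emulates, so validation is by **calibration recovery**: a synthetic
movie generator encodes each cohort statistic as ground truth, and the
measurement chain — run blind to that truth — must recover it within
sampling error. The generator is therefore first-class, tested code.

## The synthetic-movie generator

One cell per movie travels toward +x through a single constriction.
Defaults are the conditions of the emulated assay:

* **Geometry**: 7 × 5 µm channel, one 15-µm constriction centred at
  50 µm, imaged at 0.325 µm/px (20× scale) on 256 × 64 px frames, one
  frame every 2 min, at most 60 frames per movie (we record 80 for the
  large recovery cohorts so that slow cells resolve their outcome).
* **Speed law**: free speeds are drawn from a normal distribution
  truncated below at 0.5 µm/min. The printed cohort statistics
  (4.48 ± 3.93 µm/min) are sample moments of *observed*, necessarily
  positive speeds, so the generator solves for the underlying normal
  parameters whose *truncated* law realizes exactly those moments
  (µ₀ ≈ −291, σ₀ ≈ 34.5 — an almost-exponential speed distribution with
  floor 0.5). Truncating `N(4.48, 3.93)` naively would realize a mean of
  5.59 µm/min and mis-encode the calibration target.
* **Outcome law**: passage is Bernoulli with width-calibrated
  probability: 4% at 1 µm, 40% at 1.5 µm, 78% at ≥ 3 µm. The 2-µm value
  (60%) is linearly interpolated and not a printed number. Non-passers
  split into those that initiate nuclear entry before reversing
  (probability 0.6 — the underlying fraction is shown only graphically
  in the emulated study, so this is a fixed, plausible choice) and those
  that stop short of the entry plane.
* **Slowdown**: during nuclear transit (nuclear front at the entrance
  until nuclear back past the exit) the speed is multiplied by
  `1 − s`, with `s` drawn per cell around the width-calibrated mean
  (0.41 at 1.5 µm; 0.27 at 2 µm and 0.50 at 1 µm are interpolated /
  extrapolated, not printed) with s.d. 0.08. The per-cell spread models
  biological variability and gives the cohort mean an honest standard
  error.
* **Reversal dynamics**: a non-passer advances to a sampled penetration
  depth, dwells for `U(1.0, 1.5)` times the passage duration of a
  matched passing cell — so non-passers spend at least as much time
  engaged as passers — and then reverses at free speed.
* **Rendering**: the cell is a wall-clipped capsule (half-length 10 µm —
  longer than the constriction, as in the assay imagery, so whole-cell
  normalization retains body outside the gap during transit) with a
  cortical rim and a rear-pole enrichment; the wall profile tapers over
  1.5 µm at the constriction mouth so outlines narrow smoothly. The
  nucleus is an ellipse (3.5 × 2.6 µm semi-axes) whose transverse extent
  is clamped by the walls; its per-column integrated DNA intensity is
  conserved, so squeezing raises local density exactly as chromatin
  compaction appears in projection. If a cell's enrichment flag is set
  and the nucleus overlaps a constriction narrower than 3 µm (the
  enrichment is specific to small constrictions), a perinuclear shell is
  painted as a band straddling the nuclear outline at
  `enrichment_amplitude` (default 5) times the cortical-rim intensity
  scale — calibrated so the *measured* normalized perinuclear actin of
  enriched transits peaks near 1.6–1.7, comfortably above the detector
  floor, in line with the 1.5–3× enrichment the assay reports.
  Frames are blurred by a Gaussian PSF (σ = 0.3 µm) and carry Poisson
  photon noise plus Gaussian read noise (σ = 2 counts), clamped at zero.
* **Lamina panels** are fixed-cell stills: the lamina stain is a band of
  constant physical thickness (0.9 µm) along an elliptical nuclear
  outline, with condition-dependent elongation. With the calibrated
  probability (87% / 43% / 7% for long-constriction, short-constriction
  and straight-channel conditions) one angular sector of span
  `U(30°, 120°)` is erased; with probability 0.97 the gap centre sits at
  the leading pole, otherwise uniformly in [60°, 300°].
* **Beads**: a rigid bead (3 µm) rides 6 µm ahead of the cell centre in
  a third channel. A peribead actin ring is painted (probability 0.88, chosen
  strictly inside the printed "more than 80%" bound with the same
  clear-the-bound-with-margin logic as the enrichment probabilities)
  only when the bead diameter matches the constriction width within
  0.25 µm and the bead is inside; oversized beads stall at the entrance
  and stall the cell.

Determinism: one master seed fixes the latent cohort; every cell carries
a derived noise seed, so re-rendering any cell is bitwise reproducible
regardless of execution order.

### What the generator does *not* emulate

Real movies contain multiple cells per channel, uneven illumination,
photobleaching, focus drift, membrane ruffling, and cells whose area and
length fluctuate. Passing the recovery suite shows that the measurement
chain is *correct* (it recovers known truth through rendering, noise and
blind re-measurement); it does not show robustness to every real-data
artefact. The passage probabilities are also keyed on constriction
*width* alone, whereas the physical determinant is the cross-sectional
area — acceptable for pipeline-recovery testing, not a physical model.

## Measurement choices that required judgement

**Thresholding.** The assay's own analysis names no threshold operator;
we use Otsu's criterion on the smoothed frame, with two safeguards. A
robust contrast gate (`max − median ≤ 10 × MAD` ⇒ "no object") prevents
pure camera noise from segmenting into a percolated foreground after a
cell leaves the field. And because a small, very bright structure (the
perinuclear shell, a bead, condensed chromatin) can capture the
two-class threshold and collapse the mask onto itself, we also compute
the lowest threshold of the three-class Otsu criterion and use it when
most foreground mass falls between the two thresholds — i.e. when the
two-class split evidently cut through the cell.

**Mask accuracy.** On noiseless renders, masks are sub-pixel accurate
while the cell is in the wide channel (IoU ≈ 0.9 against truth). While
the cell is fully squeezed its outline is only ~6 px thick, and the
~1 px outward bias of a global threshold at a locally bright (cortical)
edge costs 25–30% of overlap; per-frame IoU there is ~0.65–0.8. Edge
positions (front/back), which drive event classification, shift by ≤ 1
px and event times by less than one frame. We state this limitation
rather than tuning the renderer's optics to hide it.

**Velocities.** Instantaneous velocity is the backward difference of
position, assigned to the later frame, unsmoothed (2-min sampling).
The cohort free-speed statistic uses the cell-mask centroid, which is
unbiased in straight channels. For the *normalized velocity variation*
(the slowdown metric), the position proxy is the DNA-intensity-weighted
nuclear centre of mass: per-column intensity conservation makes it exact
under squeezing, whereas the binary cell-mask centroid acquires a
shape-change bias of up to ~30% in entry/exit transition frames. The
baseline is the mean velocity over frames strictly before the nuclear
front first reaches the entry plane; in-constriction samples are
counted only when the whole inter-frame interval has the nucleus
engaged, so entry/exit straddling samples never dilute the estimate.
The mask-centroid variants remain available via the `source` argument.

**Event rules.** Entry/exit events are first crossings of the entry/exit
planes by the relevant edge. A reversal is scored when, after entry, the
cell front retreats ≥ 2 µm behind the entrance (ε, above pixel/jitter
scale); nuclear entry requires the nuclear front to exceed the entrance
by ≥ 0.5 µm (δ). The reversal *moment* — needed for the non-passage
time — is the last frame at which the front still sits at its running
maximum. Censored cells (movie ends while engaged) are excluded from
passage percentages in both numerator and denominator. Only the first
engagement per movie is scored; a cell that reversed and later returned
would be scored by its first resolved outcome.

**Enrichment call.** The assay reports "actin accumulation" as a binary
score without a stated criterion. We flag a cell when the peak
normalized perinuclear actin during nuclear engagement (entry to exit or
reversal) reaches its own pre-entry baseline mean + 2 s.d. *and* an
absolute floor of 1.2. The floor makes the call robust to the purely
geometric rise of the cortex signal when the cell narrows; the adaptive
part makes it robust to per-cell intensity scale. At least three
pre-entry frames are required, so cells faster than ~11 µm/min in the
default geometry are not evaluable (≈ 4% of cells; reported fractions
are over evaluable cells). The window opening "before nuclear entry"
(for the accumulation-ahead-of-the-nucleus pattern of some non-passers)
is `[cell entry, nuclear entry)`.

**Peribead annulus.** The bead annulus (bead dilated 3× minus bead) is
restricted to the *interior* of the cell (cell mask eroded 4×): inside a
narrow constriction the raw annulus runs straight through the cell's
constitutive cortical rim, and every unmatched-width transit would be
falsely flagged by cortex signal that has nothing to do with the bead.

**Nuclear circularity.** `4πA/P²` is computed from a sub-pixel boundary
polygon: the pixel-edge outline simplified by Ramer–Douglas–Peucker
(tolerance 1 px), an approximation to the minimum-perimeter polygon
through the digitization band. Raw pixel-edge outlines overestimate a
disk's perimeter by ~27% and marching squares by ~7% (digitized disk
"circularity" 0.87); the simplified polygon gives 0.98 for a radius-20
disk, exactly π/4 for an axis-aligned square, and respects the
isoperimetric bound up to discretization (≤ 1.02). Area comes from the
same polygon so the two identities are mutually consistent.

**Lamina gaps.** The angular profile averages the lamina intensity in a
one-pixel boundary band of the nucleus mask over 360 1° bins (empty bins
interpolated circularly). A gap is a maximal circular run of bins below
α = 0.5 times the profile median; a ring is ruptured when the longest
gap spans ≥ 15°. Both constants are config-exposed; on the default
synthetic panel they make zero classification errors in 120 rings
(`test-laminaquant.R`). Tip localization uses a ±45° cone about the
boundary point furthest along the migration axis. Rupture perimeter
converts angular span to arc length on the nucleus boundary polygon's
perimeter.

## Problem sizes and tolerances

The recovery cohorts follow the emulated study's printed cohort sizes
where they exist and otherwise use sizes at which binomial/normal 3-s.e.
bands are decisive: 300 straight-channel tracks for the speed law, 400
transits per width for the passage curve, 200 conditioned transits for
the slowdown and for each arm of the enrichment dichotomy, 400 stills
per lamina condition, and 200 bead transits. All stochastic acceptance
checks use three standard errors of the measured statistic. Exact
checks (morphology counts, normalization identities, test p-values
against enumeration) use tolerances at machine-precision scale, except
where an approximation is itself under test (normal-vs-exact
Mann–Whitney: absolute error < 0.015 at n = 8 + 8).

## Degenerate inputs and numerical conventions

Classified error conditions (`NoCellDetected`, `NoNucleusDetected`,
`EmptyPerinuclearRegion`, `UndefinedBaseline`, `NotEncountered`,
`TrackTooShort`, `CellNotInConstriction`, `NaNIntensity`,
`NoRingSignal`, `BeadOutsideCell`, `InsufficientColumns`, ...) separate
expected analysis failures from programming errors; per-cell failures
never abort a cohort. A constriction narrower than one pixel still
yields a one-column mask. Frames in which an object touches an axial
image border have the clipped edge and the centroid invalidated but
keep the trustworthy opposite edge, so exits at the field boundary are
still scored. Division-free conventions: a zero-margin 2×2 table gives
Fisher p = 1; identical pooled samples give Mann–Whitney p = 1; a
single value has an undefined s.e.m. (reported missing).

## Known limitations

* One cell per movie; multi-cell linking is out of scope.
* The squeeze-frame IoU limitation described above.
* The cell-mask centroid is not a reliable velocity proxy during strong
  shape change; use the nuclear intensity centroid (the default for the
  slowdown metric).
* Lamina analysis operates on fixed-cell stills, matching the
  immunofluorescence design of the emulated experiments, not on
  time-lapse.
* The generator's speed law has a heavy upper tail (its printed mean and
  s.d. force a near-exponential shape above the floor); speeds above
  ~20 µm/min are rare but possible, and such cells may yield too few
  frames to be evaluable for baseline-dependent metrics.
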