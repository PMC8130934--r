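---
title: "Methods: in vivo oscillatory phenotyping with hippophen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in vivo oscillatory phenotyping with hippophen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippophen)
```

## The problem

Hippocampal and entorhinal neuron types differ sharply in when they fire
relative to network events: the phase of the 4–12 Hz theta oscillation,
sharp-wave ripples (SWR) in CA1, and dentate spikes (DS) in the dentate
gyrus. Published measurements of these phenotypes are scattered across
laboratories that record in different layers, under different behavioral
states and recording methods, and with different phase conventions (some
call the local theta peak 0°, others the trough). `hippophen` implements
the full chain needed to consolidate such data into a per-type knowledge
base and to use it: event detection from layer-labeled LFP, per-cell
phenotype metrics, phase normalization to a common reference,
metadata-aware aggregation, knowledge-base–anchored classification of
extracellular units, and a categorical pairwise association screen.

Every stage is exercised against a synthetic-data generator that produces
LFP, spike trains, membrane-potential traces and literature-style
evidence tables with known ground truth.

## Event detection

**Filtering.** All band filters are windowed-sinc FIR kernels (Hamming
window) applied forward and backward, so the net phase shift is zero and
band peaks stay where they are. Kernel length is three periods of the low
cutoff. The test suite checks passband gain (within 1% for an 8 Hz tone
through the 4–12 Hz filter), stopband rejection (50 Hz residual below
1%), and the symmetry of the impulse response.

**Theta epochs.** The criterion for "continuous theta" is operational:
the ratio of 4–12 Hz power to broadband (1–50 Hz) power, both smoothed
over a 1 s sliding window, must exceed 0.4; gaps shorter than 0.5 s are
merged and epochs shorter than 1 s dropped. All four numbers are
arguments of `detect_theta_epochs()`. With these defaults a pure theta
segment is covered almost entirely, white noise yields no epochs, and a
theta/noise boundary is located to within a fraction of the smoothing
window.

**Theta cycles and phase.** Cycles are segmented peak-to-peak on the
filtered trace and the instantaneous phase is anchored to the waveform:
0° at each detected CA1 stratum-pyramidale (SP) peak, 180° at the
intervening trough, 360° at the next peak, with piecewise-linear
interpolation between anchors. We anchor to waveform extrema rather than
taking the analytic-signal angle because the downstream convention —
CA1-SP theta peak at exactly 0° — is then honored by construction, not
just on average for symmetric waveforms.

**SWR.** Candidate ripples are intervals where the smoothed (10 ms)
magnitude of the analytic signal of the 100–600 Hz band on the SP channel
exceeds a threshold of 3 SD above its mean (configurable within 2–5 SD;
the literature uses 2–3); event boundaries extend to the 1 SD crossings,
candidates closer than 30 ms are merged and those shorter than 20 ms
dropped. Candidate sharp waves are detected the same way on the absolute
deviation of the <100 Hz low-passed stratum-radiatum (SR) channel. An SWR
is reported only when a ripple peak and a sharp-wave peak coincide within
±50 ms. The pairing window replaces the manual visual confirmation used
with real recordings by an explicit, testable coincidence rule; minimum
duration and merge gap are configuration entries, not claims about any
published procedure.

**DS.** Dentate spikes use the sharp-wave branch verbatim on the hilar
channel, without pairing.

## Per-cell phenotypes

* **Phase locking.** Each spike inside a theta epoch gets an
  interpolated phase; the preferred phase is the circular mean and the
  mean vector length (MVL) is the resultant length of the unit vectors,
  0 for no locking and 1 for perfect locking. Firing histograms use 18
  bins per cycle. Results with fewer than 20 spikes are flagged
  undefined (with the reason attached) rather than dropped, as are
  perfectly uniform distributions where the mean direction is
  meaningless.
* **SWR/DS ratio.** Firing rate inside ±25 ms of each event peak divided
  by the basal rate. The basal rate is computed on all time outside any
  event padded by 100 ms; both windows are configurable. Ten events are
  required before a ratio is reported.
* **Bursting index.** The fraction of theta-epoch spikes that belong to
  complex-spike bursts: maximal runs of at least 3 spikes with all
  consecutive inter-spike intervals under 8 ms. A "complex spike count"
  could also be read as the number of burst events; we count spikes
  within bursts, which keeps the index in [0, 1], and expose the ISI and
  run-length criteria as arguments.
* **Autocorrelogram.** Spike-pair lags in 2.5 ms bins over ±500 ms,
  zero-lag self-pairs excluded. Positive lags are binned and mirrored, so
  the histogram is symmetric by construction even when lags fall exactly
  on bin edges.
* **Membrane biophysics.** From 500 ms current steps: resting potential
  and input resistance come from the linear regression of steady-state
  baseline potential on holding current (intercept and slope); the
  membrane time constant from a single-exponential fit to a subthreshold
  step onset; action-potential threshold as the voltage, relative to the
  pre-step baseline, at which dV/dt first exceeds 10 V/s (the
  baseline-relative reading matches the few-millivolt magnitudes
  reported for such thresholds in vivo); fast afterhyperpolarization as
  the threshold-to-trough depth after the first spike; and spike width as
  the peak-to-trough delay.

## Phase normalization

Phases reported at any layer are referred to the CA1-SP theta peak by
adding a per-layer offset and, for trough-at-0 conventions, 180°:

`normalized = wrap360(reported + offset(site) + 180·[trough0])`

The offsets ship as a versioned CSV (`inst/extdata/layer_offsets.csv`)
rather than constants in code, because they are estimated mean phase
shifts that a user may legitimately replace: DG cell layer −160°, hilus
−170°, CA3a −30°, CA3b −80°, CA3c −180°, CA2 −10°, CA1 SLM −180°, CA1 SR
−60°, CA1 SP 0°, entorhinal layer I −180° and layers II–VI 0°. Layers
with no established offset (DG molecular layer, CA1 stratum oriens) are
deliberately absent from the table; records citing them are rejected with
a reason, never guessed. Only theta phases are offset-corrected — ripple-
and gamma-band phases have no established layer-to-layer equivalence and
pass through untouched. Degrees are used everywhere and outputs wrap to
[0, 360).

Digitized points from published polar plots or phase histograms are
aggregated with weighted circular means (`aggregate_digitized()`), with
histogram counts as weights.

## Knowledge base

`aggregate_evidence()` produces one summary per (type, variable,
metadata stratum): circular mean ± circular SD for phases, arithmetic
mean ± SD otherwise. The circular SD convention is `sqrt(-2 ln r)` in
degrees, which matches the dispersion of a wrapped normal at moderate
concentrations (tested against direct simulation). Missing metadata
values form their own `"unknown"` stratum rather than silently vanishing.

`select_preferred()` reduces strata to one summary per (type, variable)
using an ordered preference: drug-free states before anesthesia, and
morphologically validated single-cell methods before extracellular ones;
ties break by larger n, then citation-key order, so the choice is
deterministic. The ordering is a package default (`metadata_priority()`),
configurable because no universal rule exists; pooling is within
(state, method) by default, with sex and age carried but not stratified.

## Unit classification

Units are placed in the (preferred theta phase, SWR ratio) plane. No
canonical metric exists for that space, so the package defines one: phase
on the unit circle (cos μ, sin μ) and the ratio log1p-transformed and
z-scored against the reference cells, with equal weight to both blocks
(configurable). Reference centroids are initialized at label means and
refined by k-means; assignment is nearest refined centroid with
deterministic tie-breaking by label order.

Significance uses a label-permutation test: the fraction of label
shufflings in which the unit lies at least as close to its nearest
recomputed label-mean centroid as observed, with the add-one correction.
Both the observed and the permuted statistic use label-mean centroids,
which makes the p-value exchangeable — and therefore uniform — under the
null; the test suite verifies this calibration (200 replicates, 999
permutations, Kolmogorov–Smirnov test). Published analyses of this kind
report p-values without describing the procedure; ours is seeded and
documented, and we make no claim of reproducing any specific published
p-value.

## Property correlation screen

Continuous in vivo variables are categorized before contingency analysis:
theta phases within ±90° of the CA1-SP peak are "peak-aligned" and the
rest "trough-aligned" (the dichotomy's boundary is not standardized; ±90°
is the package default and an argument), SWR ratios split at 1
(boundary in the ≥1 class), and rates/biophysics take the top versus
bottom tercile with the middle third treated as missing.

Barnard's exact unconditional test treats the 2×2 table as two
independent binomials; the two-sided p-value is the supremum over the
nuisance success probability of the probability of outcomes at least as
extreme in absolute pooled Wald score. The supremum is evaluated on
1001 equally spaced nuisance values with local refinement around the grid
maximizer, which reproduces a direct enumeration oracle to better than
1e-6 for every table with total count up to 20 (and matches
`scipy.stats.barnard_exact` where we compared during development).
Spearman correlations use average ranks; p-values come from exhaustive
permutation up to n = 7 (beyond that the factorial enumeration cost is
not worth it at desk scale and the t approximation on n − 2 degrees of
freedom takes over). Mann–Whitney U is reported in the smaller-U
convention with ties counted half; Student t uses pooled variance. The
default pairwise scan reports raw p-values — mirroring how such screens
are usually reported — with an optional `p_adjust` argument.

## The synthetic-data generator

The generator's defaults are the study conditions used throughout the
tests and the acceptance script:

* LFP at 1250 samples/s (real recordings are often acquired at 20 kHz;
  1250 Hz retains the 100–600 Hz ripple band above the Nyquist margin at
  desk-scale cost), 8 Hz theta, with per-layer amplitudes and phase
  shifts (CA1-SP 0°, CA1-SR −60°, hilus −170°) and white noise of 20 µV
  SD per channel.
* SWR at 0.2 events/s: a Gaussian-windowed (SD 10 ms) ripple burst on
  CA1-SP plus a coincident negative sharp wave (SD 20 ms) on CA1-SR; DS
  at 0.2 events/s as brief (SD 5 ms) positive hilar deflections. Event
  amplitudes default to roughly five times the standard deviation of the
  event-free detection trace, the regime in which the detection
  benchmark (10 seeds × 10 min) holds recall and precision at or above
  0.95. No published quantitative SWR waveform template exists; the
  Gaussian envelope is a free, documented choice. Event peaks are placed
  at least 200 ms apart so detection tests remain unambiguous.
* Spike trains by thinning of an inhomogeneous Poisson process whose
  rate is baseline × von Mises kernel exp(κ cos(θ−μ))/I₀(κ) × event
  gain. The gain applies within ±25 ms of event peaks — the same window
  the ratio estimator uses by default, so generator and estimator agree
  by construction. Bursts are inserted post hoc as 3-spike groups and
  the train re-sorted; thinning plus post-hoc bursts is simple and
  auditable. Because theta phase sweeps uniformly in time, the phase
  marginal of a thinned train is exactly von Mises, which is what makes
  the closed-form MVL check (I₁(κ)/I₀(κ)) valid.
* Membrane traces integrate the exact exponential update of an RC
  membrane with a stereotyped spike template above threshold.
* Evidence tables draw per-cell values from a 35-type truth table whose
  summary structure mirrors a curated literature compilation (including
  a 19-cell urethane CA1 pyramidal stratum at 206° ± 30° and three
  CA1 PV-marked interneuron types totalling 28 cells); reported phases
  are re-expressed in each stratum's site and convention so that
  normalization must invert the map exactly. This table is a synthetic
  stand-in: its per-cell values are simulated, not mined.

What the generator does **not** emulate: 1/f background spectra,
gamma/epsilon bands, theta harmonics and waveform asymmetry, movement and
electrode artifacts, non-stationary state changes, and spike-sorting
errors. Green tests therefore demonstrate the correctness of the
algorithms under their stated assumptions, not detector performance on
real recordings — thresholds will need re-tuning against labeled real
data.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use: 10 min × 10 seeds for the
detection benchmark; ~10,000 spikes per κ for phase-locking recovery; a
fast-spiking unit over ~360 events for gain recovery (keeping the
Monte Carlo error of the ratio estimate a few percent, well inside the
±15% band); all 5335 canonical 2×2 tables (total ≤ 20)
for the Barnard oracle sweep; 60 random cases at group sizes ≤ 12 for
Mann–Whitney; 50 seeds × 2 units for classification; and 200 replicates
× 999 permutations for p-value calibration. These sizes keep a full run
in the minutes range on one CPU while leaving Monte Carlo error well
inside each stated tolerance.

Degenerate inputs are errors, not NaNs: zero-SD detection traces,
all-zero contingency tables, singular biophysics regressions, unknown
layer labels. Statistical results that exist but are unreliable (too few
spikes or events, uniform phases, zero-variance ranks) carry an explicit
`undefined` flag with a reason string.

## Known limitations

* The theta-epoch criterion is power-ratio based and will accept any
  narrowband 4–12 Hz signal, rhythmic artifacts included.
* The sharp-wave detector uses absolute deviation, so polarity reversals
  across the recording are tolerated but polarity itself is not checked.
* `fit_reference()` assumes the labeled feature vectors are trustworthy;
  there is no outlier handling.
* Barnard's test enumerates (n₁+1)(n₂+1) outcomes per table and is meant
  for knowledge-base-sized tables (tens of types), not large samples.
* The evidence generator draws independent per-cell values; it does not
  model between-study heterogeneity or citation overlap.
* For strongly phase-locked units, event ratios estimated from few
  events are confounded with phase preference: each ±25 ms window
  samples a narrow theta-phase slice, so with tens of events the
  in-window rate depends on where the events happened to fall on the
  theta cycle. The 10-event minimum flags, but does not remove, this
  small-sample interaction; it averages out over ~100 events.
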