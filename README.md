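# hippophen

In vivo oscillatory phenotyping of hippocampal and entorhinal neuron
types: event detection in layer-labeled LFP, per-cell phase-locking and
event-modulation metrics, cross-laboratory phase normalization, a
neuron-type knowledge base, knowledge-base–anchored classification of
extracellular units, and a pairwise property-association screen.

## The problem

Single-cell recordings report *when* a neuron fires relative to network
events — the 4–12 Hz theta rhythm, sharp-wave ripples (SWR) in CA1, and
dentate spikes (DS) in the dentate gyrus — but different laboratories
reference phase to different layers and conventions, record under
different states and methods, and summarize differently. `hippophen`
makes these measurements commensurable and turns them into a per-type
knowledge base.

The quantitative core:

* **Phase locking.** Spike phases θᵢ relative to the CA1 stratum
  pyramidale (SP) theta peak (0°); preferred phase μ = arg Σ exp(iθᵢ)
  and mean vector length MVL = |Σ exp(iθᵢ)| / n ∈ [0, 1].
* **Event modulation.** SWR (or DS) ratio = firing rate within ±25 ms of
  the event peak ÷ basal rate; >1 activation, <1 suppression.
* **Phase normalization.** `wrap360(reported + Δφ(layer) + 180·[trough
  convention])`, with shipped layer offsets (e.g. CA1 SR −60°, hilus
  −170°, DG cell layer −160°).
* **Detection.** Zero-phase FIR filtering; theta epochs by band-power
  dominance; SWR as a 100–600 Hz SP-envelope threshold crossing paired
  with a <100 Hz stratum-radiatum sharp wave; DS as hilar deflections
  (default threshold 3 SD).
* **Statistics.** Barnard's exact unconditional 2×2 test (Wald score,
  nuisance supremum on a refined 1001-point grid), Spearman rank
  correlation (exact permutation null at small n), Mann–Whitney U and
  pooled-variance Student t.
* **Classification.** Units embedded as (cos μ, sin μ, z-scored
  log1p ratio), assigned to the nearest k-means-refined knowledge-base
  centroid, with a seeded label-permutation p-value.

A synthetic-data module generates layered theta LFP with SWR/DS events,
von Mises phase-locked spike trains, current-step membrane traces and
literature-style evidence tables — all with ground truth — so every
stage is testable end to end.

## Worked example

```r
library(hippophen)

# simulate 10 minutes of layered LFP with SWR and DS events
sim <- generate_lfp(sim_config(seed = 1))
spk <- generate_spikes(list(pyr = unit_spec(baseline_rate = 6,
                                            pref_phase_deg = 206,
                                            kappa = 1.2, swr_gain = 3)),
                       sim$truth, seed = 2)

# detect events and build the phase series
epochs <- detect_theta_epochs(sim$lfp)
cycles <- segment_theta_cycles(sim$lfp, epochs)
swr <- detect_swr(sim$lfp)

# per-cell phenotype
ph <- spike_phases(spk$spikes$time_s, cycles$phases)
circular_mean_mvl(ph)[c("mu_deg", "r", "n")]
#> $mu_deg
#> [1] 205.372
#> $r
#> [1] 0.5152312
#> $n
#> [1] 3648
event_ratio(spk$spikes$time_s, swr, span = c(0, 600))$ratio
#> [1] 3.055361
```

The unit was simulated with a preferred phase of 206°, a von Mises
concentration whose closed-form MVL is I₁(1.2)/I₀(1.2) ≈ 0.513, and a
3-fold rate gain inside SWR windows; the pipeline recovers all three
from the raw traces. Normalizing a literature value works the same way:

```r
normalize_phase(90, "CA1-SR", "peak0")   # reported 90 deg at CA1 SR
#> [1] 30
```

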