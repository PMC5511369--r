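---
title: "Methods: simulating and detecting synapses between clonally related interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting synapses between clonally related interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecircuit)
```

## The scientific problem

Neocortical GABAergic interneurons derived from the same dividing progenitor
(a clone) tend to settle near one another and, according to paired-recording
studies, preferentially form gap-junction (electrical) synapses with their
siblings while forming GABAergic chemical synapses indiscriminately. Testing
that claim requires a chain of analyses: classifying each recorded cell as
fast-spiking (FS) or non-fast-spiking (non-FS), calling electrical and
chemical connections from multi-cell patch-clamp recordings, quantifying
spike synchrony, quantifying spatial clustering of labelled cells, and
comparing connection rates across lineage categories with contingency
statistics. `clonecircuit` implements that chain end-to-end, together with a
ground-truth simulator so every stage can be validated against circuits whose
connectivity is known exactly.

## The forward model

Each cell is a leaky single compartment,
\(C\,dV/dt = -g_L (V - E_\mathrm{rest}) + I_\mathrm{inj} + I_\mathrm{gap} +
I_\mathrm{syn}\),
integrated by forward Euler at a 0.05 ms step (two substeps per sample at
the 10 kHz recording rate). This resolves the 5 ms pulses of the stimulation
protocol and the 1 ms cross-correlogram bins while staying far below the
shortest membrane time constant in use (~15 ms).

Action potentials are not integrated. When the membrane crosses an
(adapting) threshold, the voltage follows a parametric template — a
quarter-sine upstroke to the peak over the rise time, a quarter-cosine
downstroke whose duration is set so that the width at half peak-to-threshold
amplitude equals the requested half-width, and a half-cosine dip reaching
the afterhyperpolarization (AHP) minimum exactly `ahp_time_ms` after the
peak. The point of a stamped waveform is controllability: the features the
FS/non-FS classifier measures (half-width, AHP amplitude, AHP time from
peak) are parameters of the template, so round-trip tests can assert exact
recovery. Spike-frequency adaptation is a per-spike increment to a threshold
offset that decays with a 200 ms time constant; FS presets use increment 0
(adaptation ratio ~1), non-FS and pyramidal presets use 4–5 mV.

Gap junctions pass ohmic current \(g\,(V_j - V_i)\). For a passive pair this
gives the closed-form steady-state coupling coefficient
\(cc = g / (g + G_2)\) with \(G_2\) the receiver's leak conductance — the
analytic oracle used throughout the tests. Chemical synapses launch a
difference-of-exponentials conductance transient (default rise 0.5 ms,
decay 8 ms) at a fixed latency (0.8–5 ms) after the presynaptic AP peak.
The synaptic reversal defaults to −40 mV: a high-chloride pipette solution
makes GABAergic currents depolarized-reversing, and −40 mV lies between the
two voltage-clamp holding potentials used for chemical probing (−70 and
−20 mV), so PSCs are measurable, with opposite signs, at both.

Recording noise is white Gaussian observation noise added to the stored
traces, defaults 0.05 mV (current clamp) and 0.5 pA (voltage clamp); no
slice noise floor is published for these recordings, so the defaults were
chosen once as a plausible modern-rig level that genuinely exercises the
0.1 mV / 0.5 pA detection criteria (the averaged-trace noise sits roughly an
order of magnitude below each criterion at 10-trial averaging). An optional
slow sinusoidal drift and, inside the integrator, white or shared
Ornstein–Uhlenbeck current noise are available for experiments that need
baseline wander or spike-time jitter.

## The stimulation protocol and session layout

One trial of the probing protocol injects, into a single driver cell: two
5 ms suprathreshold pulses 50 ms apart (20 Hz), a third 5 ms pulse at
500 ms, a 200 ms low suprathreshold step, and — 300 ms after that step ends
— a 200 ms, −200 pA hyperpolarizing step. Per probed driver a session holds
10 trials with every cell in current clamp (electrical probing) and 10
trials with all non-driver cells voltage clamped (chemical probing),
alternating −70/−20 mV holdings — at least 20 trials per pair and direction.

## Connection detection

**Electrical.** The receiver's current-clamp traces are averaged across
trials; the deflection is the mean over the last 100 ms of the
hyperpolarizing step minus a 50 ms pre-pulse baseline. The window maximizes
signal-to-noise for a step response; the published criterion states only the
0.1 mV threshold, not the averaging window. A pair is coupled when the
deflection exceeds 0.1 mV with the driver's (hyperpolarizing) sign, probed
from either side — gap junctions are bidirectional, so the pair-level call
is the OR of the two directions. The coupling coefficient is the ratio of
receiver to driver deflection from the same epochs.

**Chemical.** Presynaptic AP peaks are located as the voltage maximum within
each brief-pulse epoch of the driver's own trace. The AP-peak-triggered
average of the postsynaptic clamp current is baseline-subtracted
((−5, 0] ms pre-peak) and the extremum within (1, 5] ms is the PSC
amplitude; the connection is called when it exceeds 0.5 pA. The extremum
(rather than the window mean) is robust to latency jitter; the window-mean
variant is available via `detection_criteria(psc_measure = "mean")`.
Reported latency is the PSC onset (10% crossing before the extremum), which
recovers the synaptic delay; the extremum lag is also returned.

**Disambiguation.** In a gap-coupled pair the driver's AP leaks a spikelet
current transient into the voltage-clamped receiver that can exceed 0.5 pA
and masquerade as a PSC. Because the receiver is clamped, however, the
hyperpolarizing epoch of the very same trials measures the gap conductance
directly — the receiver's current deflection equals −g times the driver's
voltage deflection, with no network confounds — so `detect_chemical()`
estimates ĝ from that epoch and subtracts the predicted spikelet current
−ĝ·ΔV_pre(t) from the triggered average before applying the criterion.
The subtraction is only engaged when the hyper-epoch deflection is clearly
resolved (>0.3 pA), so uncoupled pairs are not burdened with the estimation
noise. An earlier design compared PSC signs across the −70/−20 mV holdings
(a GABAergic PSC with ~−40 mV reversal flips, a spikelet largely does not);
that check fails for strongly coupled pairs, whose operating point — and
hence artifact shape — itself shifts with the neighbour's holding, which is
why the conductance-subtraction route was adopted. Sub-criterion chemical
synapses (PSC near 0.5 pA) coexisting with strong gap junctions remain hard
to call; the simulated fidelity experiments use ~9–15 pA PSCs, far above
that regime.

## Spike synchrony

Cross-correlograms count ordered spike-time differences in 1 ms bins over a
±window (≥200 ms per side), with bin index `round(lag)` so that exchanging
the trains exactly mirrors the counts. Each bin is normalized to a standard
score against the independence expectation \(E = \lambda_1 \lambda_2
\Delta t\, T\) with Poisson s.d. \(\sigma = \sqrt{E}\); λ are the average
rates over the recording time T. A bin is a significant peak when its Z
exceeds that of *every* other bin within ±200 ms by more than 3; this is the
strict reading of the published rule, and the permissive
single-neighbour variant is available (`rule = "any"`). Edge bins compare
against their truncated neighbourhood. A consequence of the strict rule is
that only sub-millisecond-sharp synchrony can ever be significant — a peak
spread evenly over two adjacent bins defeats it — which matches its intended
use as a gap-junction signature.

The packaged synchrony experiment (`simulate_paired_drive`) drives a
gap-coupled FS pair (coupling coefficient 0.2) with near-threshold DC plus
two noise sources: independent white current noise (120 pA·√ms) that makes
firing irregular, and a shared Ornstein–Uhlenbeck current (70 pA, τ = 50 ms)
standing in for slow common network drive. The shared component co-modulates
excitability on tens of milliseconds — producing only a broad correlogram
hump on its own — while spikelet transmission through the gap junction adds
the sharp near-zero-lag component; zeroing the gap conductance (the
pharmacological-blockade analogue) removes exactly that sharp component.
A 240 s recording gives the test enough counts for the 3-SD rule at these
rates (~30 Hz).

## FS / non-FS classification

The nine features are extracted from a characterization family of one
subthreshold 500 ms step and 1 s depolarizing steps: resting potential
(pre-stimulus mean), input resistance (steady-state deflection over
current), AP threshold (voltage where dV/dt first reaches 20 mV/ms — a
standard operational criterion), half-width at half peak-to-threshold
amplitude, 10–90% rise time, peak-to-threshold e-fold decay time, maximal
firing frequency (largest spike count within the 1 s steps), AHP amplitude
(threshold minus post-spike minimum), AHP time from peak, and the
adaptation ratio (last/first interspike interval within the 1 s step).
Level crossings are linearly interpolated for sub-sample precision.

A cell is FS iff it satisfies **all nine** published bounds (≥80 Hz, AHP
≥8 mV, threshold ≥−35 mV, R_in ≤300 MΩ, adaptation ≤2.5, half-width
≤1.7 ms, rise ≤1.9 ms, decay ≤7.5 ms, AHP time ≤6.5 ms), boundaries
inclusive; everything else is non-FS. The published description ("a
combination of features, including …") does not state the combination rule;
the strict conjunction is the only parameter-free reading of the listed
bounds, and it is monotone (moving any feature toward its FS side can never
un-classify an FS cell), which the property tests assert.

## Spatial and clonal statistics

All distances are 3-D Euclidean in micrometres; 2-D inputs are accepted
with z = 0. Nearest-neighbour distances (NND) support three class rules:
pooled, within-label (nearest same-fluorophore neighbour), and cross-label
(each cell of either label against the other label, both directions pooled
into one sample — the published figure shows a single cross-colour curve,
and pooling is the symmetric choice). An optional guard-region
(minus-sampling) edge correction restricts focal points to those at least a
guard distance from the bounding-box faces; without it the empirical CDF of
a bounded uniform pattern deviates from the unbounded Poisson law
\(F(d) = 1 - \exp(-\tfrac{4}{3}\pi\lambda d^3)\) near the boundary, which
is exactly how the analytic oracle test uses it.

Intra- versus interclonal analysis enumerates every pair of clone-assigned
cells; single-cell clones contribute only interclonal pairs. Dendrograms
use agglomerative single linkage (the conventional default of the linkage
function in the cited analysis environments; average linkage is available),
with Newick export via `ape`. The same-barcode fraction at a distance
cut-off (e.g. 450 μm) is a plain pair enumeration and is checked against a
brute-force oracle in the tests. The original barcoded reconstructions are
not redistributable, so the ingestion path (`read_barcoded_csv`) is
exercised on synthetic clone sets written in the external column layout;
files and fixtures built this way are named `synthetic_*`.

The clonal pattern generator places clone centres uniformly in a cubic
volume, members as isotropic Gaussian offsets (default s.d. 50 μm, the
scale of reported intra-cluster dispersion), sizes 1 + Poisson, and keeps
each clone with probability `labelling_density`; low density yields the
sparse, spatially isolated clusters characteristic of low-titre labelling.
What it does not emulate: laminar anisotropy, barrel/column structure,
migration-path elongation, or density gradients across areas — so spatial
tests passing here show correctness of the statistics, not realism of
cortical geometry.

## Cohort statistics

Connection rates are printed as 100·k/n rounded half-up to one decimal,
matching the published convention. Group contrasts use Pearson's χ² without
continuity correction — the choice that reproduces the published
significance calls on the published 2×2 tables — with Fisher's exact test
available for sparse tables and Yates correction behind a flag. Distance
strata default to [0,20), [20,50), [50,100), [100,150), [150,200),
[200,∞) μm and age strata to ≤P6, P7–P10, P11–P13, P14–P21, ≥P22; the outer
edges are stated in the source text, the intermediate edges are
configurable choices. No multiple-testing correction is applied, mirroring
the original analysis; this is a faithful-reproduction choice, not a
statistical recommendation. The bundled `paper_counts.csv` transcribes every
(k, n) pair-outcome count printed in the source Results, and
`reproduce_paper()` recomputes each percentage and significance label from
those counts alone.

## Numerical and design notes

* Determinism: every stochastic entry point takes a seed and restores the
  caller's RNG state; identical seeds give bit-identical sessions, and the
  on-disk session container (JSON attributes + full-precision CSV traces)
  round-trips losslessly.
* The detection-fidelity generator draws gap conductances giving direct
  coupling coefficients in 0.012–0.025. Electrotonic coupling is
  transitive: in a multi-cell net, two-hop deflections are physically
  detectable by an amplitude criterion, so "detected graph = generating
  graph" is only well-posed in the regime where direct deflections exceed
  0.1 mV and all indirect paths stay below it. The chosen range leaves
  roughly 4× margin on the direct side and 10% on the worst-case indirect
  side for quadruple recordings.
* Distance ties in linkage and nearest-neighbour searches are broken by
  lower cell index, for determinism.
* Degenerate inputs: empty clone sets are legal outputs of the generator
  (all clones unsampled) but not legal inputs to the spatial statistics;
  pairs with fewer than the minimum trials raise insufficient-data errors
  rather than returning weak calls; rates with n = 0 are errors, and empty
  strata are reported with n = 0 and excluded from testing.
* Problem sizes in the packaged checks (100 random circuits, 1000 null
  pairs, 300 Poisson null correlograms, 5000-point NND patterns, 100
  cohort replicates) were chosen so the full validation completes in a few
  minutes on one core while keeping Monte-Carlo error well inside the
  asserted tolerances.

## Known limitations

Single-compartment cells cannot express dendritic gap-junction filtering or
electrotonically remote synapses; stamped APs make spike shape independent
of drive; the chemical synapse model is deterministic (no release failures
or depression, so high-frequency paradigms will overestimate non-FS synapse
detectability); the disambiguation rule assumes PSC reversal strictly
between the two holdings; and the cohort generator treats pairs as
independent, ignoring the within-quadruple correlation of real recordings.
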