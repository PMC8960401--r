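---
title: "Analysing E/I network activity on multi-well MEAs with meanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing E/I network activity on multi-well MEAs with meanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(meanet)
```

## The problem

Co-cultures of human iPSC-derived glutamatergic and GABAergic neurons grown
on multi-well micro-electrode arrays (MEAs) develop spontaneous activity
that evolves from random spiking through local bursting to synchronised
network-wide bursts. Once GABAergic signalling has matured into a
hyperpolarising (inhibitory) influence, the amount of inhibition in the
network is visible in a small set of well-level parameters: inhibition
shortens network bursts, lowers the firing and network-burst rates, and
raises the fraction of spikes that belong to no burst at all. `meanet`
implements the full analysis chain needed to quantify these effects —
spike detection from raw traces, single-channel and network burst
detection, nine well-level parameters, well quality control, burst-shape
comparison and canonical discriminant analysis — together with a synthetic
generator that plants known structure so every stage can be validated end
to end.

## The detection model

**Spike detection.** Raw extracellular signals are sampled at 10 kHz,
band-limited with a 2nd-order Butterworth high-pass at 100 Hz and a
4th-order Butterworth low-pass at 3500 Hz, and thresholded at ±4.5 noise
standard deviations. Three numerical choices are ours where the processing
convention is not dictated by the recording system:

* the noise SD is the robust estimate $\hat\sigma = \mathrm{median}(|x|)/0.6745$,
  which is essentially immune to the spikes themselves;
* both filters are applied forward–backward (zero phase), so filtering
  never shifts spike timestamps; the price is that the effective magnitude
  response is the squared Butterworth response, which the tests account
  for;
* a spike is timestamped at the extremum sample of its suprathreshold
  excursion (extremum timing is more jitter-stable than
  threshold-crossing timing), and events closer than a 1 ms dead time are
  collapsed to the larger extremum. The threshold is applied to the whole
  recording, not per sliding window.

**Burst detection** is a three-stage rule applied per electrode, in a fixed
order. (1) *Detect*: maximal runs of spikes whose every inter-spike
interval (ISI) is at most 30 ms become candidates spanning first to last
spike; we read the 30 ms boundary inclusively (an ISI of exactly 30 ms
continues the burst), since the verbal rule leaves the boundary case open.
(2) *Merge*: candidates separated by less than 65 ms (end to next start)
are merged transitively. (3) *Filter*: anything shorter than 50 ms or with
fewer than 4 spikes is discarded. Merging precedes filtering so that merged
bursts can survive the filter.

**Network bursts.** A channel counts as *active* when its mean firing rate
exceeds 0.1 Hz — the same threshold the exclusion criteria use. A network
burst occurs when bursts run simultaneously on *more than* 80% of the
active channels (strictly: with 10 active channels, 9 coincident bursting
channels qualify and 8 do not). "Simultaneously" is evaluated by a
sweep-line over the burst intervals, which avoids introducing a bin-width
parameter. The rule leaves the *extent* of a network burst undefined; we
take the union of all single-channel bursts intersecting the
above-threshold seed interval, because network-burst duration is a
headline metric and the union is the most inclusive defensible reading.
Overlapping windows are merged.

## The nine parameters

`compute_features()` returns, per well: mean firing rate (MFR, averaged
over all electrodes including silent ones), percentage of random spikes
(PRS: spikes in neither a burst on their own channel nor any network-burst
window — the inclusive reading of the definition; by construction PRS plus
the non-random percentage is exactly 100), single-channel burst rate,
duration, firing rate in burst and inter-burst interval (averaged over
channels with at least one burst), and network-burst rate (NBR), duration
(NBD, the window duration) and inter-burst interval. All inter-burst
intervals are end-to-next-start. A well without network bursts reports
NBR = 0 but *missing* NBD/NIBI rather than zero, so group averages are not
dragged toward zero by inactive wells.

## Burst shapes and their comparison

`burst_shape()` aligns every network burst at its window start and bins
the spikes of all channels (default 10 ms bins, configurable — no standard
value exists) out to the longest window. Group comparisons run a two-sample
t-test per bin across wells and control the family-wise error with the
Holm–Šidák step-down procedure: with $m$ bins and ordered p-values
$p_{(1)} \le \dots \le p_{(m)}$, step $i$ is significant iff
$p_{(i)} \le 1 - (1-\alpha)^{1/(m-i+1)}$ and all earlier steps were. With
$m = 1$ the threshold reduces to $\alpha$ exactly.

## Quality control

`qc_well()` applies six independent exclusion rules before any group
analysis: inactivity (< 3 channels above 0.1 Hz), a 1 Hz MFR floor for
control wells only, spikes on < 80% of channels, no network bursts at
DIV 28, network bursts confined to < 80% of channels, and a firing rate
that decreases over development. Two operationalisations were open: the
development trend is read as last-versus-first recorded DIV (a slope test
would need a model the rule does not state), and the channel-coverage rules
are evaluated per DIV with a violation at any DIV excluding the well. A
well never recorded at DIV 28 cannot be assessed for the DIV-28 rule; that
is reported as a note, not a violation.

## Canonical discriminant analysis

`canonical_discriminant()` solves $B a = \lambda W a$ (between- versus
pooled within-group scatter) through a Cholesky-symmetrised dense
eigendecomposition; canonical correlations are
$\sqrt{\lambda/(1+\lambda)}$. Coefficients are scaled to unit pooled
within-group score variance and scores are centred on the grand centroid —
the conventions of the major commercial statistics packages, so results are
directly comparable. The structure matrix contains pooled within-group
correlations between each input variable and each canonical score; it is
how we rank which of the nine parameters carries a group difference. Signs
are fixed by making the largest-magnitude loading of each function
positive. Rows with missing values (typically wells without network bursts,
which lack NBD/NIBI) are dropped with a message rather than imputed. The
analysis is used descriptively — score plots with 95% concentration
ellipses centred on group centroids, via `plot()` — and no classification
step is provided. The ellipses are per-group covariance concentration
ellipses; a centroid-confidence alternative would shrink with $n$ and is
not what score plots conventionally show.

## The synthetic generator

`simulate_well()` plants ground truth a detector can be held to: network
burst windows from a renewal process (exponential end-to-onset gaps at the
configured rate, gamma durations with configurable CV), inside which every
recruited channel fires as a homogeneous Poisson process at the in-burst
rate, its onset jittered by a Gaussian (SD 5 ms by default); tonic
background spiking is Poisson throughout. The generative model is a
deliberate simplification chosen for recoverability, not biophysics.
Defaults mirror the recording conditions: 12 electrodes, 600 s, and an
inhibition knob spanning the 0–0.35 range of inhibitory fractions used in
E/I titrations. The knob maps linearly onto planted NBD (1200 → 300 ms),
in-burst rate (150 → 60 Hz) and tonic rate (0.3 → 0.8 Hz); endpoints were
chosen once to reproduce the direction and rough magnitude of the
experimentally observed titration trends and are configurable.
`simulate_ei_series()` copies every other field — including the seed — so a
titration series is a paired design, and returning the knob to 0
regenerates exactly the uninhibited member of the pair: the in-silico twin
of acute pharmacological disinhibition, under which a network that never
had inhibition is unchanged by construction.

Specs whose mean inter-burst gap falls below 200 ms are rejected outright:
closer planted bursts would be merged by the 65 ms rule and the ground
truth would stop being identifiable. Each channel draws from its own
derived RNG sub-stream, so enlarging a well leaves existing channels'
trains byte-identical. Two features of real recordings are deliberately
absent: within-burst rate profiles are flat (real network bursts typically
decay, and no quantitative profile was available to emulate; the rate is a
single configurable number), and there is no electrode cross-talk,
drifting excitability, or non-Poisson ISI structure. Tests passing on this
generator therefore validate the *rules* of the pipeline, not its
behaviour on every pathology of real data. Because onsets are jittered,
planted in-burst spikes can fall slightly outside their nominal window;
ground-truth consumers should allow a few jitter SDs of slack.

Raw-trace synthesis superimposes a biphasic ~1.5 ms template, peak-aligned,
on Gaussian noise; PSC streams draw decay times from two zero-truncated
normal distributions (defaults 2.0 ± 0.5 ms glutamatergic, 7.0 ± 1.5 ms
GABAergic), which makes the misclassification rate of the 3.8 ms decay
cutoff available in closed form for validation.

## Worked example

```{r example}
series <- simulate_ei_series(network_spec(duration_s = 300, seed = 2),
                             c(0, 0.35))
wells <- lapply(series, `[[`, "well")
feats <- feature_table(wells)
feats[, c("well_id", "inhibitory_fraction", "mfr_hz", "prs_pct",
          "nbr_per_min", "nbd_ms")]
```

The inhibited well shows the expected signature: shorter network bursts,
lower MFR, higher PRS.

```{r shapes}
nb <- detect_network_bursts(wells[[1]])
shp <- burst_shape(wells[[1]], nb, bin_width_ms = 50)
plot(seq_along(shp$mean_profile) * 50, shp$mean_profile, type = "h",
     xlab = "time from burst onset (ms)", ylab = "spikes per 50 ms bin")
```

## Problem sizes and numerical choices

The validation suite runs the pipeline at the native recording scale
(12 channels, 600 s) for the recovery and titration checks, averaging over
10 generator seeds; oracle-equivalence checks use 1000 random small trains
and dense 60 × 9 feature tables. Boundary comparisons in the burst rules
use a 10^-9 ms guard so that hand-constructed fixtures on an exact
millisecond grid behave per the stated inclusive/strict rules despite
binary floating point. Ties at the decay-time cutoff are assigned to the
fast (glutamatergic) class; ties where one burst ends exactly as another
starts count as instantaneous overlap.

## Known limitations

* Burst-rule conventions not fixed by the verbal definitions (inclusive
  30 ms ISI, end-to-start 65 ms gap, union windows) are our documented
  readings; alternatives would shift NBD by up to the ISI scale.
* The generator's flat in-burst rate means burst-shape statistics on
  synthetic data are uninformative about real decaying profiles.
* The whole-recording noise estimate assumes stationary noise; recordings
  with strong drift should be segmented upstream.
* No spike sorting: a channel is treated as one multi-unit source, as in
  the multiwell analysis convention this package follows.
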