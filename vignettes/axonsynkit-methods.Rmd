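---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

axonsynkit quantifies five phenotyping read-outs used to characterize
pathogenic KIF1A variants (KAND) in human iPSC-derived NGN2 neurons:
axonal transport of synaptic vesicle precursors (SVPs) from kymographs,
stable SVP+ site density and its spatial relation to microtubule
plus-end comets, multi-electrode-array (MEA) activity, synapse
apposition counts, and relative mRNA expression by ΔΔCt.  Each analysis
is paired with a synthetic-data generator whose ground truth makes the
detectors scoreable.  This vignette documents the models, the tunable
parameters and the choices made where the design was genuinely open.

## Genotype presets

`kand_presets()` holds one parameter row per genotype (WT, C92X —
a KIF1A-null nonsense variant, P305L — hypoactive, R350G — hyperactive).
Entries with a published anchor are fixed: wild-type anterograde flux of
5 vesicles/min at a top speed near 4 µm/s; retrograde maximum velocity
2.8 µm/s (WT) vs 3.5 µm/s (R350G); stable SVP+ site densities of 0.6
(WT and C92X), 0.31 (R350G) and 0.72 (P305L) sites per 10 µm; relative
KIF1A mRNA of 100/15/48/36% of wild-type; a 100-fold firing-rate
increase under astrocyte co-culture.  The remaining entries
(`comet_rate` = 0.05 comets/µm/min, `assoc_prob`, monoculture
`mfr_base` of 0.2–0.4 Hz, burst rates of 0.15–0.3 bursts/min,
flux-ratio 0.6, `intensity_scale` 0.7 for C92X/P305L) are calibration
choices: values a practitioner would call typical for DIV21 iNeurons,
fixed once and overridable via `genotype_params(g, ...)`.  The motile
intensity reduction of C92X/P305L cargo is only reported graphically in
the source work, so `intensity_scale = 0.7` is an explicit placeholder.

## SVP track generation and the "fast run" model

`gen_svp_tracks()` draws per-axon anterograde and retrograde track
counts as Poisson with mean `flux * duration / 60`, and builds each
track as a piecewise-constant-velocity polyline of 3–5 segments
(pauses, speed < 0.1 µm/s, occur with probability 0.3 per segment).
The headline velocity statistic — the mean of the five fastest segment
speeds per axon — is made identifiable by construction: in each axon
and direction, five designated *fast-run* segments get speeds from
Normal(`vmax_mean`, 0.03 · `vmax_mean`) while all other moving segments
cruise at `vmax_mean` · Uniform(0.4, 0.85).  The top-5 statistic is
therefore unbiased for `vmax_mean` regardless of how many tracks a
Poisson draw produced, which a tail-of-a-common-distribution design
would not give.  Tracks are guaranteed a net displacement of at least
15 µm so that generated "motile" cargo sits safely above the 10 µm
classification bound.

Rendering (`render_kymograph()`) paints tracks as 3-pixel-wide
anti-aliased streaks (Gaussian cross-section, unit peak) on a constant
background of 100 AU with Gaussian read noise (SD 10 AU), emulating a
photobleached-background acquisition; no bleach-recovery gradient is
modelled because imaging starts after photobleaching.  Calibration
defaults are 0.16 µm/px (typical 100×/sCMOS; not stated in the source
work) and 0.2 s/row (5 frames/s SVP mode) or 1 s/row (comet mode).

## Automated tracing

`trace_tracks()` replaces manual kymograph tracing: per-row local
maxima above a robust background (global median + 3 MAD) are linked
row-to-row against a constant-velocity prediction and simplified to
inflection points (Douglas–Peucker, 1 px tolerance) — the same
representation a human tracer records.  Three guards keep automated
linking honest on crowded kymographs, and their parameters are exposed:

* a two-regime matching gate — young tracks (fewer than 3 detections)
  may move up to `max_speed_um_s` (6.5 µm/s) per elapsed second, while
  established tracks must stay within 0.8 µm + 1 µm/s of their
  prediction even across a detection gap, so a dead track cannot "hop"
  onto a neighbour at an implied 10 µm/s;
* a direction-consistency veto — a track with more than 3 µm of net
  displacement never links to a detection implying fast (> 0.8 µm/s)
  movement the other way, which prevents identity swaps where
  anterograde and retrograde tracks cross (resuming after a pause keeps
  the net direction and is unaffected);
* a 5-detection minimum and a 3-point median filter before
  simplification, which remove noise chains and single-row flickers.

Because residual sub-second kinks are linking artifacts rather than
movement, `max_velocity()` pools only segments sustained for at least
1 s (configurable) and at least 0.1 µm/s (pauses are not "fastest
velocities").  Direction classification uses strict inequalities: net
displacement of exactly 10 µm is non-motile.  Flux counts classified
tracks once each, matching how cargos entering a 100 µm window are
tallied; anterograde is the direction of increasing coordinate, and
readers of external data must state orientation.

With these defaults the full generate → render → trace → summarize
pipeline recovers preset flux and both directional velocity statistics
within 10% at 50 axons (the scale used by `scripts/acceptance.R` and
the acceptance tests; a 300 s movie over a 100 µm axon segment per
axon).

## SVP+ sites and microtubule comets

`gen_comet_site_axon()` draws site counts as Poisson
(`site_density · length / 10`) and places centroids with a 3 µm
hard-core repulsion — stable presynaptic accumulations are spatially
discrete, and the repulsion keeps the detector's 1 µm merge rule from
conflating ground-truth sites.  Comet counts are Poisson
(`comet_rate · length · duration / 60`); a fraction `assoc_prob`
initiates within 10 µm of a site centroid (uniform placement when an
axon happens to have no sites); growth speeds are Normal(0.1, 0.02)
µm/s truncated positive, lifetimes 10–60 s, 90% anterograde.

`detect_svp_sites()` operationalizes "stationary signal consistently
above background for the entire recording" as: columns above the
global median + 3 MAD threshold in at least 95% of rows, adjacent
bright runs closer than 1 µm merged (the 3 px line width blurs band
edges), centroids intensity-weighted.  The 95% persistence tolerates
isolated noise dropouts while still rejecting a band present for half
the movie.  Comet–site association is scored on *any point of the
comet's span* falling within 10 µm of a site centroid; a start-point
only mode is available (`mode = "start"`).  The site-density regression
(`density_regression()`) is ordinary least squares of site density on
comet density via `lm`, with `tidy()`/`glance()` accessors.

## MEA generation and analysis

`gen_mea_recording()` builds 12-electrode wells: background Poisson
spikes at `mfr_base`, burst epochs (onsets Poisson at `burst_rate`/min,
size 3 + Geometric with mean ≈ 4.9 spikes, within-burst ISIs
Exponential with 20 ms mean), and network events that trigger bursts on
a random ≥ 4-electrode subset with ≤ 20 ms onset jitter.  Spikes closer
than 1.5 ms are thinned so every ground-truth spike is resolvable by a
detector with a 1 ms dead time; at co-culture rates (~30 Hz) this thins
trains by roughly 4%, which the stochastic tolerances absorb.  With
`with_traces = TRUE` spikes become biphasic 1 ms waveforms (peak 10×
the noise SD) on Gaussian noise at 20 kHz.  Astrocyte co-culture
(`coculture_params()`) scales baseline *and* burst rates 100-fold and
enables network bursting — a uniform activity scaling, not astrocyte
biophysics.

The analysis chain follows the recording platform's stated processing:
zero-phase cascade of a 2nd-order 100 Hz high-pass, 4th-order 3500 Hz
low-pass and 50 Hz notch (biquad; quality factor 30, unstated in the
source and chosen as a conventional narrow notch); spike detection at
±5 baseline SDs with the SD estimated as median(|x|)/0.6745 so the
spikes themselves do not inflate the threshold; active electrodes
strictly above 10 spikes/min; well mean firing rate averaged over
active electrodes only.

The two stated burst constants conflict for gaps in (50, 100] ms: an
ISI join of 50 ms versus termination after 100 ms of silence.  The
resolution implemented: a burst is *seeded* by a spike pair with ISI
≤ 50 ms, *continues* through gaps up to 100 ms, and *terminates* at the
first gap above 100 ms; a leading 50–100 ms gap does not extend a burst
backwards; bursts need ≥ 3 spikes (unstated; configurable).  Network
bursts are maximal spans with ≥ 4 electrodes simultaneously in a burst.
Burst frequency is reported per well as the total across active
electrodes per minute (whether the platform normalizes per electrode is
unstated; this choice is configurable downstream since per-electrode
burst tables are returned).

## Synapse quantification

`gen_synapse_field()` lays out presynaptic puncta with pairwise spacing
above 3× the apposition gap, gives exactly `floor(apposed_frac ·
n_pre)` of them a partner within the gap, and scatters lone
postsynaptic puncta far (> 3× gap) from every presynaptic punctum —
a regime in which greedy matching is provably optimal, so the matcher
can be scored exactly.  `detect_puncta()` follows the described
synapse-counting settings: Otsu-seeded provisional components, final
threshold at two-thirds of the mean provisional puncta intensity, 3-D
connected components (2-D labelling per slice, merged across slices),
equivalent-diameter windows 0.2–2.5 µm (pre) and 0.06–2 µm (post).  It
is a simplified reimplementation of those settings, not a port of the
plugin internals.  Apposition matching uses a centroid gap of ≤ 0.5 µm
(the plugin's dilation/overlap distance is unstated; 0.5 µm is
comparable to one dilation step at the stated pixel scales), greedy
nearest-neighbour, one-to-one.  Apposed fractions, density per MAP2
area, the 2×k chi-square of apposed vs lone puncta
(`chisq.test`, no continuity correction), top-percent intensity masks
(3% synaptophysin, 2% synaptobrevin-2) and polygonal ROI means complete
the module.

## ΔΔCt and SuperPlot aggregation

`delta_delta_ct()` implements the Livak form: per-sample ΔCt against
the housekeeping gene, genotype means, ΔΔCt against the reference
genotype, expression = 2^−ΔΔCt (reference exactly 1; invariant to
global and housekeeping-wide Ct shifts).  Averaging per-sample fold
changes instead is available via `per_sample = TRUE`.  Note on noise
propagation: with 0.2-cycle noise and 3 replicates a single run carries
about 0.23 cycles of ΔΔCt noise (≈ 17% in expression), so recovery
tests at that noise level average over runs.

`superplot_summarize()` guards against pseudoreplication: units are
averaged within biological replicates, the genotype mean is the
unweighted mean of replicate means, and dispersion is the SD of
replicate means (n − 1), never of pooled units; single-replicate
genotypes are flagged with undefined SD.  Statistical genotype
comparisons beyond the chi-square (mixed models, Kruskal–Wallis/Dunn,
ANOVA) are deliberately out of scope — the pipeline emits tidy
replicate-level tables ready for those tools.

## Problem sizes and determinism

Every generator is a pure function of its parameters and an integer
seed (`withr::local_seed`; RNG state restored).  The acceptance script
and tests use 50 axons per genotype for transport and site recovery,
5 + 5 wells for the mono/co-culture comparison, and 60 s voltage wells
at 20 kHz — sizes chosen so a desk-scale run finishes in minutes while
keeping sampling error well inside the stated tolerances (e.g. site
density SE ≈ 0.035 at 50 axons against a 15% band).  `run_pipeline()`
writes a JSON manifest (seed, parameters, package version) so every
output table is traceable.

## What passing tests do and do not show

The generators reproduce summary statistics — Poisson event counts,
velocity distributions with designated fast runs, burst/network
structure, apposition geometry — not biophysics: no motor mechanics,
microtubule lattice chemistry, vesicle loading, astrocyte signalling or
electrode drift.  Recovery of a preset therefore validates the
*quantification procedures* (tracing, detection rules, normalizations)
under the statistical structure the analyses assume; it does not
validate those assumptions on real microscopes or MEA rigs.  Known
limitations: the tracer resolves crossing particles imperfectly on very
dense kymographs (mitigated by the gates above and quantified by the
recovery tests); site detection merges ground-truth sites closer than
about 1 µm; sub-voxel puncta are detected but their equivalent
diameters quantize to the voxel size.
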