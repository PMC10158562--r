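---
title: "Topographic and microstate analysis of picture-naming ERPs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic and microstate analysis of picture-naming ERPs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`erpmicro` implements the analysis chain used in developmental picture-naming
electrophysiology: multi-group, multi-condition epoched EEG is carried from
raw trial tensors to single-subject averages, reference-free topographic
statistics, microstate segmentation of grand averages, and back-fitting of
the resulting template maps to individual ERPs. The central scientific idea
is that the scalp electric field moves through a sequence of quasi-stable
topographies ("microstates"); differences between groups can then be either
*quantitative* (the same maps, shifted or stretched in time) or
*qualitative* (different maps altogether), and the pipeline is designed to
separate the two.

Throughout, a "map" is the vector of average-referenced potentials across
electrodes at one time-frame (TF; one sample, ~1.95 ms at 512 Hz). All
global measures derive from two primitives:

* **Global field power**, `GFP(t) = sqrt(mean(u(t)^2))`, the spatial
  standard deviation of the average-referenced map with the 1/N
  (population) convention. The N vs N-1 choice changes every downstream
  number, so it is fixed and documented here: 1/N is used everywhere.
* **Global map dissimilarity**, the RMS difference of two GFP-normalized
  maps, with the identity `DISS^2 = 2(1 - r)` linking it to the spatial
  Pearson correlation `r`.

Maps whose GFP falls below `1e-9` microvolts have no defined topography;
such TFs are excluded from dissimilarity-based statistics and labeled
"unassigned" rather than imputed.

# Preprocessing

The canonical stage order is fixed and logged: band-pass filter, average
reference, baseline correction (stimulus-locked epochs only), artifact and
error rejection, bad-electrode interpolation, averaging.

* **Filtering.** Second-order Butterworth high- and low-pass filters
  (defaults 0.2 and 30 Hz, 12 dB/octave) applied forward-backward
  (zero-phase, acausal) per trial and electrode, with odd-reflection
  padding at both epoch edges. Reflection padding is our choice of edge
  treatment; it avoids committing to any particular toolbox's default and
  keeps the transient inside the first and last few dozen TFs.
* **Artifact rejection.** Visual artifact screening is not reproducible, so
  the deterministic stand-in is an amplitude criterion: any trial
  containing a sample beyond ±100 microvolts (configurable) is rejected,
  together with trials answered incorrectly. Only trials surviving in both
  the stimulus-locked and response-locked alignment enter the averages.
* **Interpolation.** Bad channels are rebuilt by order-4 spherical splines
  (regularization 1e-5, 50 Legendre terms) from the good channels, with a
  hard limit of 20% of the montage. The implementation was verified to
  agree with an independent reference implementation to seven digits.
  Because replacing channels perturbs the zero-mean property, the average
  reference is re-applied after interpolation so the invariant holds after
  every post-reference stage.
* **Averaging.** A subject average requires at least 55 surviving trials by
  default; scaled-down synthetic runs lower this limit explicitly in their
  configuration. Subjects below the limit are excluded with a logged
  reason, never silently.

The montage is a set of unit-sphere electrode positions with a neighbor
graph. The graph is built by connecting electrodes closer than a distance
threshold grown until the graph is connected. A triangulation would serve
equally well; the threshold graph was chosen because it is simple, explicit
and easy to test, and the spatial-extent criterion below only needs *some*
well-defined, connected notion of adjacency.

# Point-wise waveform statistics

At every electrode and TF a split-plot ANOVA is computed with group as a
between-subject factor and condition (age-of-acquisition class) as a
within-subject factor, using closed-form sums of squares vectorized over
all points; the engine is validated in the tests against `stats::aov` with
an `Error(subject/condition)` stratum, and against the `F = t^2` identity
in the two-group one-condition case. Significance uses alpha 0.01 plus the
joint extent criterion: an effect must last at least 10 consecutive TFs
and, at each TF of the run, cover a connected set of at least 5
supra-threshold electrodes in the montage graph. No further
multiple-testing correction is applied; the extent criterion is the
correction, and the null simulations in the acceptance tests verify the
familywise error it yields.

# Topographic tests

**Topographic consistency (TCT).** Per TF, the statistic is the GFP of the
across-subject mean map; the null is built by shuffling the electrode
assignment independently within each subject and re-averaging. One shuffle
per subject and permutation is applied across all TFs of a series — each
TF's test is exact, and the scheme keeps the permutation count independent
of epoch length.

**Topographic ANOVA (tANOVA).** Subject maps are GFP-normalized; the effect
size at each TF is the *generalized dissimilarity*: the mean over factor
levels of the DISS between the level-mean map and the grand-mean map (the
natural multi-level generalization of pairwise DISS for a 4 x 2 design).
Randomization schemes: subject-to-group reshuffling for the group effect;
within-subject condition swaps for the condition effect; for the
interaction, cell means are double-centered (both main effects removed)
before the dissimilarity is evaluated, under within-subject condition
swaps. The observed statistic counts as one permutation, so p is never
exactly zero and equals `(1 + #{perm >= obs}) / (n_perm + 1)`. Permuted
statistics are compared to the observed value with a `1e-12` slack so that
exact ties (degenerate designs, rescaled inputs) count as ties regardless
of floating-point noise. Significance requires 12 consecutive TFs at
alpha 0.01.

# Alignment and overlap removal

Response-locked epochs are 250 TFs ending 50 TFs before the vocal onset of
each trial; this convention (rather than centering near the -50 TF point)
is the one under which the combined ERP covers exactly picture onset to 50
TFs before articulation, and it remains configurable. RT outliers
(< 500 ms or > 2000 ms, inclusive bounds retained) and errors are removed
before epoching. All ms-to-frame conversions round half away from zero and
are applied once per quantity, never cumulatively.

The overlap between the stimulus- and response-locked ERP is removed by
keeping the first `round(RT*fs/1000) - 300` post-onset frames of the
stimulus-locked ERP and appending all 250 response-locked frames; the
combined length is therefore `round(RT*fs/1000) - 50` frames. Group-mean
RTs place the cut for grand averages; each subject's own mean RT places it
for the individual ERPs used in fitting (the group-mean variant is also
supported). Group combined ERPs legitimately differ in length when group
RTs differ, and segmentation and fitting handle unequal lengths.

# Microstate segmentation (TAAHC)

Segmentation runs jointly on all group x condition grand-average combined
ERPs, so the template set is shared across datasets. The algorithm:

1. *Atomization*: every TF (with defined topography) starts as its own
   cluster; label runs never cross dataset boundaries.
2. *Agglomeration*: repeatedly, the cluster contributing least to the
   global explained variance (GEV) is dissolved and each of its members is
   reassigned to the cluster whose centroid correlates best with it.
   Centroids are GFP-weighted means of member maps, polarity-aligned to the
   member with the largest GFP, and renormalized to unit GFP.
3. *Convergence polish*: at each requested k, reassignment and centroid
   recomputation alternate until the labeling is stable. This standard
   refinement removes the path dependence of the greedy agglomeration; on
   tiny instances the tests verify that the polished solution matches or
   exceeds the exhaustively enumerated optimum over contiguous
   two-cluster segmentations.
4. *Post-processing*: centroids correlating at least 0.95 are merged;
   labeled segments shorter than 12 TFs (~24 ms) are absorbed by the
   neighboring label with the higher mean correlation over the segment.

Correlation is *signed* and no polarity inversion is applied when labeling:
ERP component maps (e.g. a P1 versus an N1 topography) differ by more than
polarity, unlike spontaneous-EEG microstates where inversion is
conventional. Model selection returns the smallest k whose total GEV
reaches 0.95, reporting the full GEV-vs-k curve; if no k reaches the
threshold the largest model is returned with a warning rather than a
silent choice.

Tie-breaking in labeling is deterministic: equal correlations resolve to
the previous TF's label (temporal continuity), else to the lowest template
index.

# Back-fitting and fitting statistics

Within each fitting window, every TF of an individual ERP is labeled with
the candidate template of highest signed correlation, **provided the
correlation reaches a floor of 0.5**; TFs below the floor stay unassigned.
The floor is a deliberate design choice: without it every TF would be
assigned to *some* candidate, and an individual whose window contains no
reliable topography would still accumulate map durations — presence would
then be unfalsifiable. With the floor, pure-noise individuals produce no
presence for any map (verified in the tests), while at 10 dB SNR real
state TFs correlate ~0.95 and are essentially never lost. Short runs are
smoothed exactly as in segmentation; short unassigned gaps between two
assigned runs are filled by the better-correlating neighbor, which keeps
state durations unbiased at state edges.

A map is *present* when its total assigned duration reaches 12 TFs (the
paper-style presence notion is reported without a definition anywhere we
could adopt it from, so the threshold is a package decision, matching the
segmentation's minimum duration). Duration is the assigned TF count times
1000/fs; per-map GEV is computed within the window. Group/condition
statistics on GEV and duration reuse the split-plot engine; presence is
tabulated per group and condition, and per-subject mean GEV can be
correlated with a covariate such as age.

The three default fitting windows are derived from the selected
segmentation: an early window at 68-202 ms (the first visual component),
the remaining stimulus-locked portion from ~200 ms to the overlap cut, and
the response-locked portion; candidates in each window are the maps the
grand-average labeling uses there.

# The synthetic generator

The generator defines the study conditions: 4 groups x 20 subjects x 2
conditions, 60 trials per condition, a 128-electrode montage (32 for
scaled-down runs) at 512 Hz; stimulus-locked epochs of 300 TFs including
50 pre-stimulus TFs; response-locked epochs of 250 TFs ending 50 TFs
before vocal onset. Each trial is simulated as one continuous segment long
enough for both alignments and then windowed, which guarantees the two
alignments are mutually consistent re-windowings of the same data.

* **Signal.** A sequence of planted states (template map x raised-cosine
  amplitude envelope, default 10-40 ms ramps to avoid filter ringing):
  four stimulus-locked states spanning roughly the P1 / N1 / P2 / late
  windows at 2.5-4 microvolts, and two response-locked states in the last
  ~420-100 ms before vocal onset. Template maps are dipolar-source fields,
  average-referenced, unit-GFP, with pairwise |r| at most 0.6.
* **Group structure.** Younger groups get delayed stimulus-locked
  components (+30, +10, 0, 0 ms) and larger amplitudes (x1.4, x1.2, x1,
  x1), the canonical developmental pattern for visual ERP components.
* **Condition effect.** An age-of-acquisition-like additive amplitude
  difference (0.8 microvolts) on stimulus-locked states overlapping a late
  window (350-450 ms); a template substitution variant is also supported.
* **Noise.** White electrode noise smoothed with a Gaussian kernel over the
  montage (correlation length 0.5 chord units) and re-centered to the
  average reference. Volume conduction makes real EEG noise spatially
  smooth; unsmoothed noise would make every topographic test unrealistically
  easy.
* **Behavior.** RTs are truncated-normal (bounds 500-2000 ms) with group
  locations 980/950/925/900 ms and scale 110 ms; accuracy is logistic with
  group offsets giving ~93% (children) to ~96% (adults) correct. Error
  trials are marked and excluded downstream. The child-adult RT gap is
  deliberately smaller than real developmental gaps: the 300-TF
  stimulus-locked epoch supports the overlap-removal coverage contract
  only up to ~1074 ms mean RT, and the generator's defaults keep every
  simulated subject inside that contract. In the pipeline, a subject or
  group mean RT beyond that limit is clipped to it with a log entry rather
  than crashing the run.

What the generator does *not* emulate: real artifact morphology (blinks,
muscle; rejection is exercised with planted amplitude spikes), trial-level
latency jitter of components, inter-subject topographic variability of the
underlying sources, electrode impedance drift, and non-stationary noise.
Passing tests therefore demonstrate the correctness and calibration of the
statistics under the planted model, not robustness to every property of
real recordings.

# Numerical choices

* ms -> TF conversions round half away from zero, once per quantity.
* Permutation p-values include the observed data as one permutation;
  permutation comparisons use a `1e-12` tie slack.
* GFP <= 1e-9 defines an undefined field (unassigned / untestable).
* Degenerate ANOVA cells follow the convention F = 0, p = 1 when both the
  effect and error sums of squares vanish.
* All randomness flows through explicit integer seeds; equal seeds
  reproduce every artifact of a pipeline run bit-exactly (hashes are
  recorded in the run manifest), and sub-seeds for the individual stages
  are derived from the run seed by fixed offsets.

# Problem sizes

The shipped demonstration profile uses 4 groups x 5 subjects x 2
conditions, 32 electrodes, 30 trials per condition, 1000 tANOVA
permutations and 500 consistency-test permutations; it exercises every
stage in about three minutes on one CPU. The test suite's null-calibration
study uses 200 replicates of 2 groups x 10 subjects at 32 electrodes and
100 TFs with 1000 permutations; template-recovery studies use 20 seeded
runs of 20 subjects at 10 dB SNR. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in
minutes.

# Known limitations

* Reading vendor raw formats (BDF/EDF+) is out of scope; epoched tensors
  enter through `epoch_set()` (any reader can adapt into it), and montages
  through the plain-text position format.
* The split-plot ANOVA assumes balanced conditions within subject (each
  subject contributes every condition); unbalanced group sizes are
  supported, missing cells are an error.
* With two conditions the within-subject permutation space is `2^S`;
  p-values at very small S are correspondingly coarse.
* The back-fitting correlation floor (0.5) is a scale-free but arbitrary
  point; it is configurable, and analyses that need the classical
  assign-everything behavior can set it to -1.
* Source localization is not performed anywhere in the pipeline.
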