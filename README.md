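# erpmicro

Topographic and microstate analysis of picture-naming ERPs in R.

`erpmicro` implements, as a tested and reusable pipeline, the ERP analysis
chain of a developmental picture-naming study design: preprocessing of
stimulus- and response-locked epochs, reference-free topographic statistics,
microstate segmentation with individual back-fitting, and the removal of
the stimulus/response overlap that lets both alignments be analyzed as one
combined signal. A synthetic-data generator plants known microstate
structure, latency shifts, amplitude scaling and reaction-time behavior, so
every stage can be verified against ground truth.

## Who it is for

Researchers analyzing multi-group, multi-condition event-related potentials
(e.g. developmental or clinical group comparisons in language production)
who need the *global* (reference-free) analysis toolbox: global field
power, topographic dissimilarity, randomization tests of topography, and
microstate decomposition — rather than channel-by-channel waveform tests
alone.

## The statistics at the core

With `u(t)` the average-referenced scalp map at time-frame `t` across `N`
electrodes:

- **GFP** (global field power): `GFP(t) = sqrt( (1/N) Σᵢ uᵢ(t)² )` — the
  reference-free field strength.
- **DISS** (global map dissimilarity) between maps `u`, `v`:
  `DISS = sqrt( (1/N) Σᵢ (uᵢ/GFP_u − vᵢ/GFP_v)² )`, with
  `DISS² = 2(1 − r)` for spatial correlation `r`; 0 = identical topography,
  2 = polarity inversion.
- **tANOVA**: per-TF randomization test of topographic differences. Effect
  size = mean over factor levels of the DISS between level-mean and
  grand-mean maps; null built by reshuffling group membership (between) or
  swapping condition labels within subjects (within); significance requires
  12 consecutive TFs at p < 0.01.
- **TCT** (topographic consistency test): GFP of the across-subject mean
  map against an electrode-shuffled null — are topographies consistent
  across subjects at all?
- **Point-wise ANOVA**: split-plot F at every electrode × TF (group
  between, condition within), kept only when lasting ≥ 10 consecutive TFs
  on ≥ 5 adjacent electrodes at α = 0.01.
- **TAAHC** microstate segmentation: temporal atomize & agglomerate
  hierarchical clustering of the grand-average combined ERPs into unit-GFP
  template maps (minimum duration 12 TFs, 95% merge correlation), model
  selected as the smallest k explaining 95% of the variance (GEV).
- **Back-fitting**: each template's presence, global explained variance and
  duration in every individual ERP, compared across groups/conditions.

## Worked example

The demonstration profile (4 groups × 5 subjects × 2 conditions, 32
electrodes, 512 Hz) runs the full pipeline in about three minutes:

```r
library(erpmicro)
res <- run_pipeline(demo_config(seed = 1), "demo-run")
str(res$summary)
```

Output (abridged):

```
List of 9
 $ seed                              : int 1
 $ n_subjects_analyzed               : int 20
 $ excluded_subjects                 : chr(0)
 $ selected_k                        : int 6
 $ total_gev                         : num 0.992
 $ tanova_group_sig_fraction_stimulus: num 0.54
 $ anova_group_sig_fraction_stimulus : num 0.636
 $ p1_latency_ms                     : G1 139, G2 119, G3 109, G4 109
 $ group_mean_rt_ms                  : G1 993, G2 967, G3 941, G4 912
```

Reading it: the segmentation selected `k = 6` template maps — exactly the
six planted by the generator — explaining 99.2% of the grand-average
variance. The tANOVA finds topographic group differences over 54% of the
stimulus-locked epoch (the generator plants group latency shifts and
amplitude scaling there), the waveform ANOVA flags 64% of it, and the P1
peak latencies recover the planted 30/10/0/0 ms group delays on top of the
~109 ms base latency. Group mean RTs reproduce the planted ~80 ms
child–adult gap. `report("demo-run")` renders GFP curves, significance
rasters, template topographies and segmentation timelines from the run
directory.

A thin command-line wrapper is installed at
`inst/scripts/erp-pipeline.R` (`run-all`, `simulate`, `report`
subcommands).

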