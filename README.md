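# rinoise

Psychophysics and EEG analysis for the **race-in-noise** paradigm: observers
categorize the race of face images (East Asian, EA, vs West European, WE)
whose *phase coherence* — the fraction of original Fourier phase structure
retained — is degraded parametrically while the amplitude spectrum is held
fixed. The package is for researchers studying the Other-Race Categorization
Advantage (ORCA): the finding that other-race faces are categorized faster,
and at low image coherence *more accurately*, than own-race faces, with a
behavioral threshold near 20% coherence and accompanying occipito-temporal
ERP effects in the P1/N170/N250 range.

It provides, end to end:

* **Stimulus generation** — luminance/contrast/amplitude-spectrum
  equalization of an image set and phase scrambling at arbitrary coherence,
  with exact amplitude-spectrum preservation
  (`match_set_statistics()`, `phase_scramble()`, `render_stimulus_set()`);
* **Default Bayesian paired test** — the JZS Bayes factor with a Cauchy
  prior (scale r) on standardized effect size,

  BF₁₀ = ∫₀^∞ (1+Ng)^(−1/2) [1 + t²/((1+Ng)ν)]^(−(ν+1)/2) π(g) dg
         ÷ [1 + t²/ν]^(−(ν+1)/2),   g ~ InvGamma(1/2, r²/2), ν = n − 1,

  evaluated in log space so BF values past 10⁶ don't overflow
  (`jzs_paired_bf()`, `classify_evidence()`);
* **Behavioral pipeline** — RT trial filtering (100–2000 ms), the 75%
  full-structure accuracy screen, per-coherence EA-vs-WE Bayes factor
  contrasts on RT and accuracy, signal detection analysis (d′, criterion)
  and participant-level bootstrap intervals
  (`filter_trials()`, `screen_participants()`, `orca_contrasts()`,
  `sdt_analysis()`, `bootstrap_ci()`);
* **ERP pipeline** — zero-phase 0.1–30 Hz band-pass, baseline correction,
  common-average reference, ±100 µV trial rejection, spherical-spline
  channel interpolation, sample-wise cluster Bayes factor scans over
  0–420 ms with evidence-window extraction (BF₁₀ > 10) and per-electrode BF
  topographies (`preprocess_cohort()`, `cluster_bf_scan()`,
  `extract_windows()`, `bf_topomap()`);
* **Synthetic-data generator** — behavioral sessions (840 trials, 60 per
  race × coherence cell) and multi-channel ERP cohorts with P1/N170/N250
  components, 1/f noise and injectable race effects, with machine-readable
  ground truth for parameter-recovery testing (`generate_session()`,
  `generate_erp_cohort()`, `ground_truth_report()`).

## Worked example

A paired Bayes factor on 16 participants' condition-mean RTs (EA vs WE):

```r
library(rinoise)
jzs_paired_bf(rt_ea, rt_we)
#> JZS paired/one-sample Bayes factor
#>   BF10 = 7.98943e+06 (log BF10 = 15.8936)
#>   t = -13.1259, n = 16, rscale = 0.7071
#>   relative integration error <= 2.44e-14
```

BF₁₀ ≈ 8 × 10⁶ is extreme evidence that the EA and WE means differ; the
negative t says EA responses were faster.

The full behavioral pipeline on a synthetic 12-participant cohort:

```r
trials <- generate_behavior_cohort(12, seed = 42)
summ   <- condition_summaries(filter_trials(trials))
summ   <- summ[summ$participant %in% screen_participants(summ), ]
orca_contrasts(summ)
#>   coherence mean_rt_ea mean_rt_we rt_bf10  rt_evidence acc_bf10 acc_evidence
#> 1        10        846        836   0.444 inconclusive 5.24e+02  alternative
#> 2        20        774        823   3.415  alternative 1.08e+00 inconclusive
#> 3        30        722        815 573.772  alternative 7.26e+04  alternative
#> 4        40        729        781  11.234  alternative 2.67e+01  alternative
#> 5        50        692        765 406.959  alternative 2.91e+00 inconclusive
#> 6        60        707        748   7.563  alternative 7.79e-01 inconclusive
#> 7       100        678        676   0.295         null 3.36e-01 inconclusive
```

Read this as the ORCA signature the generator plants: no RT difference at
10% coherence (but an *accuracy* asymmetry from a WE guessing bias — see
below), an EA speed advantage appearing at 20% (rt_bf10 > 3), peaking at
30%, and vanishing at full coherence, where there is moderate evidence the
two races are categorized equally fast (BF₁₀ = 0.295 ≤ 0.33).

The guessing bias at the lowest coherence shows up in signal detection
terms — discriminability near zero with a criterion shifted toward WE
responses:

```r
sdt <- sdt_analysis(filter_trials(trials), coherence = 10)
attr(sdt, "group_means")
#>    dprime criterion
#> 0.1865192 0.2234502
```

(Here C > 0 means a bias toward responding "WE"; d′ near 0 says the faces
were barely discriminable at 10% coherence.)

`run_pipeline()` chains simulation, behavior, ERP scans and figures into a
report bundle with CSVs and a JSON provenance block.

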