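---
title: "Race-in-noise methods: phase scrambling, Bayesian thresholds, and sample-wise ERP evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Race-in-noise methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinoise)
```

## The paradigm

In a race-in-noise experiment, observers categorize the race of face images
(East Asian, EA, vs West European, WE) whose *phase coherence* — the fraction
of the original Fourier phase structure retained — is varied parametrically
while the amplitude spectrum is held fixed. Behaviorally, other-race faces
are categorized faster and, at low coherence, more accurately than own-race
faces (the Other-Race Categorization Advantage, ORCA), with a threshold
around 20% coherence below which own-race faces fall to chance. Neurally,
the same contrast is probed with a sample-wise Bayes factor scan of
occipito-temporal ERP cluster voltages covering the P1/N170/N250 range.

`rinoise` implements this paradigm end to end: stimulus generation, the
default Bayesian paired test, the behavioral pipeline, the ERP pipeline, and
a synthetic-data generator with known ground truth so every stage can be
validated by parameter recovery rather than by eye.

## Stimulus generation

### Amplitude-spectrum matching

`match_set_statistics()` replaces each image's Fourier magnitude with the
set-average magnitude while keeping phases. One substitution equalizes all
three low-level properties at once: the DC magnitude carries mean luminance,
and by Parseval's theorem the non-DC magnitudes carry the pixel variance
(RMS contrast, defined here as the pixel standard deviation). No iterative
histogram specification is attempted; that is a deliberate reduction of
scope to the two properties that matter for this paradigm.

### Phase scrambling

`phase_scramble()` mixes the original phase field with a random one:

$$\phi_{out} = \phi_{orig} + (1 - c)\,\mathrm{wrap}(\phi_{rand} - \phi_{orig}),$$

with wrap mapping to $(-\pi, \pi]$ — interpolation along the shortest
circular arc. The rule is continuous in the coherence $c$ and exact at both
endpoints ($c = 1$ reproduces the input to machine precision; $c = 0$ is a
fully random phase field). Published descriptions of the scrambling
technique do not pin down the mixing formula (weighted phase vs weighted
complex interpolation); the circular-arc choice is this package's own
documented decision, made for its endpoint exactness and continuity.

Three numerical details matter:

* The random field is the phase of the FFT of white Gaussian noise, which is
  Hermitian by construction, so the inverse transform is real (residual
  imaginary part below 1e-10 of signal).
* The DC and Nyquist rows/columns keep their original phases. Their
  self-conjugate bins admit only phases $0/\pi$, where a fractional mix
  would break Hermitian symmetry; leaving the whole rows unrandomized is the
  simplest rule that is exact for every $c$.
* After inversion the image is clipped to $[0, 1]$ and the clipped fraction
  reported, rather than rescaled: rescaling would silently undo the
  cross-level luminance matching. Amplitude conservation is therefore exact
  *before* this final range restriction (and holds to 1e-9 relative in the
  tests), not after it.

Each image × level cell receives an independent random phase field keyed by
(image, level, base seed), matching per-trial stimulus independence, and
`render_stimulus_set()` writes deterministic PNGs plus a CSV manifest.

## The default Bayesian paired test

All contrasts use the JZS (Jeffreys–Zellner–Siow) default Bayes factor for a
one-sample test applied to within-participant differences: a Cauchy prior of
scale $r$ on the standardized effect size and Jeffreys prior on the
variance, giving

$$BF_{10} = \frac{\int_0^\infty (1+Ng)^{-1/2}
  \left[1 + \frac{t^2}{(1+Ng)\nu}\right]^{-(\nu+1)/2} \pi(g)\,dg}
  {\left[1 + t^2/\nu\right]^{-(\nu+1)/2}},
  \qquad g \sim \mathrm{InvGamma}(\tfrac12, \tfrac{r^2}{2}),\ \nu = n-1.$$

Numerical choices:

* the prior scale defaults to $r = \sqrt{2}/2$ ("medium"), the conventional
  default of the established Bayes-factor software for paired designs — the
  choice required to reproduce numbers computed with that default;
* the integral is evaluated on a log-transformed $g$ axis entirely in log
  space (relative tolerance 1e-10), so Bayes factors beyond $10^6$ — which
  occur in strong RT contrasts — are returned without overflow;
* accuracy contrasts treat per-participant condition proportions as
  continuous paired observations, untransformed; the output metadata records
  both the prior-scale provenance and the absence of a transform, since
  neither is something a reader could infer from the Bayes factor alone.

The implementation is validated two ways: against a brute-force quadrature
oracle on the raw $g$ axis (`pracma::quadgk`, no log transform), agreeing
within 0.5% over a $(t, n)$ grid, and against frozen values from an
unrelated implementation of the same integral, agreeing to ~1e-4.

Evidence labels use the study's boundaries: behavioral evidence for a
difference at $BF_{10} > 3$, EEG evidence at the deliberately raised
$BF_{10} > 10$ (the only false-positive control applied across the many
per-sample comparisons — raising the boundary, not correcting it), and null
evidence at $BF_{10} \le 0.33$ in both contexts. The "greater than"
boundaries are strict.

## Behavioral pipeline

The stated filtering rules are applied literally:

* trials with RT shorter than 100 ms or longer than 2000 ms are excluded —
  strict exclusions, so the bounds themselves are retained;
* participants below 75% pooled accuracy in the 100% coherence condition are
  rejected (0.75 itself passes);
* accuracy is correct responses divided by accepted trials, and mean RT is
  taken over correct accepted trials only, untransformed — both from the
  same accepted-trial set.

The signal detection analysis at one coherence level treats responses naming
the signal race (WE by default) as "signal" responses: incorrect responses
to EA faces enter as WE false alarms. Rates of exactly 0 or 1 are replaced
per participant by $1/(2N)$ and $1 - 1/(2N)$ — standard practice where the
original analysis is silent. $d' = z(H) - z(FA)$; the criterion is reported
as $C = +(z(H)+z(FA))/2$ so that $C > 0$ means a bias *toward* the signal
race, the reading under which a positive group criterion at 10% coherence
describes a WE guessing bias. Note that swapping the signal race leaves $d'$
unchanged (since $z(1-f) - z(1-h) = z(h) - z(f)$) and negates only $C$.

Bootstrap intervals resample participants — the unit of analysis — with
replacement (percentile method, default $B = 2000$), and are deterministic
under a fixed seed.

## ERP pipeline

Preprocessing follows the stated chain: 0.1–30 Hz band-pass, baseline
correction to the −100–0 ms mean, common-average reference, and rejection of
trials exceeding ±100 µV (strictly) on any channel within 0–500 ms
post-stimulus. Choices the chain's description leaves open:

* **Filter realization.** A 4th-order Butterworth applied forward and
  backward (zero phase), so component latencies are not shifted. Each trace
  is demeaned before filtering: a 0.1 Hz high-pass has a 10 s period, far
  longer than an epoch, and on epoched data the filter transient would
  otherwise dominate — demeaning makes the DC rejection actual rather than
  asymptotic. Edges are handled by odd-reflection padding. The filter is
  applied as one vectorized pass across all traces of a cohort
  (`preprocess_cohort()`), which is what makes 100-cohort simulation studies
  practical on one CPU.
* **Sample-to-ms convention.** Sample $k$ maps to
  $t = (k - k_0)/f_s \cdot 1000$; the 0 ms sample is included in the scan
  and window bounds are inclusive. The scan covers 0–420 ms, stopping before
  motor-preparation activity.
* **Degenerate samples.** A sample whose paired differences are all zero has
  no t statistic; it is recorded as missing, never interpolated.
* **Clusters.** The two occipito-temporal clusters hold exactly eight
  sensors each. Real montages differ in labels, so membership is
  configurable (`electrode_cluster()`); the synthetic montage defines its
  clusters explicitly and `bf_topomap()` provides the per-electrode
  complement.
* **Bad channels.** Spherical-spline interpolation (Perrin-style, order
  $m = 4$, 50 Legendre terms) from the remaining sensors; montages with more
  than 25% bad channels are refused. Eye-blink ICA is out of scope: the
  pipeline accepts externally cleaned data, and the synthetic generator
  emits blink-free epochs (optionally with simple planted deflections to
  exercise the voltage rejection).

Evidence windows are maximal contiguous runs of samples with
$BF_{10} > 10$, summarized by onset/offset, mean and max BF, the time of the
max, and the sign of the voltage difference; single-sample windows are
legitimate and reported, as are null-evidence runs at $BF_{10} \le 0.33$.

## Synthetic-data generator

### Behavior

Each simulated trial: with probability `lapse` (0.03) the participant
guesses; otherwise they *perceive* the race with probability
$\pi_r(c) = \mathrm{logistic}(k_r (c - c_{50,r}))$ and respond correctly;
guesses name WE with probability $\beta$ (0.58). Accuracy in a cell is
therefore $p_r(c) = \tilde\pi_r(c) + (1 - \tilde\pi_r(c))\,g_r$ with
$\tilde\pi = (1-\mathrm{lapse})\pi$ and $g_{WE} = \beta$,
$g_{EA} = 1-\beta$; the guessing floor is 0.5 only when $\beta = 0.5$.
Defaults ($k_{EA} = 0.45$, $c_{50,EA} = 18.1$; $k_{WE} = 0.143$,
$c_{50,WE} = 26$) were chosen once so the closed-form cell means emulate the
published group pattern: chance-with-WE-bias at 10%, an EA accuracy
advantage emerging at 20% (~0.83 vs ~0.70) and peaking near 30%, and
ceiling convergence at 60–100%. RTs are shifted lognormal (floor 250 ms,
keeping virtually all draws inside the 100–2000 ms acceptance band), with
location decreasing in coherence and an EA speed-up applied from the 20%
onset (55 ms at 20%, peaking at 90 ms at 30%, 0 at 100%), plus
participant-level random effects on intercept, ORCA magnitude and threshold.
An `outlier_rate` plants out-of-range RTs for testing the filter.

### ERP

Epochs are built from three Gaussian-in-time components — P1 (+, 94 ms),
N170 (−, 165 ms), N250 (−, 290 ms) — with scalp weight maps falling off
with angular distance from occipito-temporal foci, scaled by a structure
gain that is 0 at 10% coherence and 1 at 100% (so face-evoked structure
vanishes at the lowest level, and the 100%-vs-10% contrast localizes to the
cluster electrodes by construction). Race effects are flat-topped windows
with raised-cosine ramps added to one race's epochs on the cluster channels
of one or both hemispheres; per participant the amplitude is
$\Delta + N(0, \sigma_b)$. The default schedule mirrors the qualitative
published pattern (late-N170 EA effect at 20%, N250 EA effects at 30–60%,
P1 EA effects at 60/100%, WE N170/N250 effects at 100%) — these are
synthetic emulations, not the study's data. Noise is $1/f^{\alpha}$
($\alpha = 1$) plus a white floor (30% of variance), independent across
channels and trials, normalized to a per-sample SD; participants carry
lognormal amplitude scaling (SD 0.2) and Gaussian latency shifts (SD 10 ms)
on the base components (not on injected race effects, which must stay
recoverable). These noise values are standard EEG phenomenology chosen as
config defaults, not claims about any particular dataset.

What the generator does **not** emulate: spatially correlated sensor noise,
real blink/EMG artifacts (only simple planted deflections), latency-varying
single-trial components, or any physiological forward model. Passing tests
therefore validate the *pipeline's* statistics and plumbing, not its
behavior on raw laboratory recordings.

### Calibrating a planted effect size

The recovery studies plant a participant-level standardized effect
$d = \Delta_{\mathrm{eff}} / \sigma_{\mathrm{tot}}$ in the *measured*
contrast. Two deterministic attenuations intervene between the injected
amplitude and the measured one: the common-average reference scales a
focal injection on $m$ of $K$ channels by $f = 1 - m/K$ (scaling
$\Delta$ and $\sigma_b$ alike), and trial noise adds variance
$2\sigma_\varepsilon^2$ with
$\sigma_\varepsilon = \sigma_{\mathrm{noise}}/\sqrt{8\,n_{\mathrm{trials}}}$
per condition (8 = cluster size). The generator therefore plants

$$\Delta = d_{\mathrm{target}}
  \sqrt{\sigma_b^2 + 2(\sigma_\varepsilon / f)^2},$$

so the realized d equals the target by construction. With $d = 0.8$ at
$n = 36$ the single-sample probability of clearing the $BF_{10} > 10$
boundary (t ≈ 3.11) is ≈ 0.94, which is why the 90% recovery criterion is
attainable and not an accident of tuning.

### Problem sizes

Simulation studies (recovery and null calibration, 100 cohorts each) run at
a reduced geometry chosen as this package's own trade-off between fidelity
and turnaround: 24 channels (8 + 8 cluster + 8 spread), 16 trials per
condition, 256 Hz, epochs −100–500 ms, sensor noise 1.5 µV. The generator's
*defaults* remain the study-scale design (36 participants, 60 trials per
cell, 1024 Hz, −100–1000 ms epochs, 7 coherence levels), and all geometry is
configurable. The bundled `run_pipeline()` demo uses a smaller cohort still.

## Known limitations

* Bayes factors are for the paired two-condition contrast only; no
  multi-factor ANOVA-style Bayes factors or one-sided priors.
* Accuracy Bayes factors analyze untransformed proportions, faithful to a
  difference-in-means analysis; near-ceiling cells violate normality and the
  Bayes factor there should be read qualitatively.
* The epoch container is an in-memory array with RDS/CSV serialization;
  importers for vendor formats (e.g. EEGLAB epoch files) are not provided.
* The null-calibration figure (<2% of samples past $BF_{10} > 10$ on
  effect-free cohorts) is a report under the generator's assumptions, not a
  false-positive guarantee for correlated real-EEG noise.
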