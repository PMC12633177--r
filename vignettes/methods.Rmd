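---
title: "Inter-brain synchrony for dyadic fNIRS: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-brain synchrony for dyadic fNIRS: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dyadsync` implements an analysis chain for two-person (hyperscanning)
fNIRS experiments: from raw two-wavelength light intensity per
source-detector channel, through quality control and motion correction, to
a per-dyad, per-channel-pair **inter-brain synchrony (IBS)** statistic and
the group-level statistics that compare it across clinical groups and
relate it to behavior. Because clinical hyperscanning datasets are rarely
shareable, the package ships a synthetic-dyad generator with known ground
truth; every stage of the pipeline is validated against it.

This vignette explains the models and conventions behind each stage, the
parameters that matter, the design choices made where the methodology is
genuinely open, and what the simulation-based validation does and does not
show.

## The synthetic dyad generator

`generate_dyad()` simulates one mother-child dyad. Each subject's long
(3 cm) channels carry, in hemoglobin units:

* a **neural component**: a band-limited Gaussian process inside the
  configured coupling band plus an out-of-band component over 0-0.5 Hz
  (defaults: 0.2 uM each);
* a **superficial (scalp) component** shared across the subject's
  channels: cardiac (1.2 Hz, 0.3 uM), respiratory (0.3 Hz, 0.1 uM) and
  Mayer-wave (0.1 Hz, 0.15 uM) sinusoids with random phase plus a slow
  drift, entering long channels at `scalp_gain` (default 0.5) and short
  (0.8 cm) channels at gain 1;
* white measurement noise (0.04 uM).

HbR is modelled as -HbO/3 for the neural part and as a weak (+0.1)
volume-like copy of the scalp component: arterial pulsation raises both
chromophores, which is what makes the cardiac beat appear in phase at both
wavelengths and is the physical basis of the scalp-coupling-index check.
Concentrations are mapped to optical density through the modified
Beer-Lambert forward model (standard molar extinction coefficients at
760/850 nm, DPF 6, distances 3/0.8 cm) and to raw counts as
`I = baseline * exp(-dOD)`, so the optical-density conversion in the
pipeline inverts the generative model exactly.

**Cross-brain coupling.** Homologous long channels of the two subjects
share a band-limited process `c(t)`. With shared-variance fraction `f` and
independent band residuals, the magnitude-squared coherence of the two
channels inside the band is `f^2`; setting `f = sqrt(strength)` therefore
calibrates the injected band coherence to `strength` in closed form. The
band-limited processes carry a raised-cosine spectral envelope over the
outer 30% of the band's log-width on each side: a band-pass-*filtered*
process has soft spectral edges, and a brick-wall mask would ring in time.
Smoothing in the coherence estimator biases measured values upward at low
coherence, so measured band averages sit above the injected target by the
estimator's bias floor; all validation claims are therefore comparative
(monotonicity, coupled vs. uncoupled, recovery of *which* bins/pairs
differ) rather than claims about absolute coherence values.

**Motion artifacts** are spikes (1-3 samples, 5-20 x the channel's OD
standard deviation) and step baseline shifts, at Poisson times
(`artifact_rate` per minute), applied coherently to both wavelengths --
the two artifact classes that derivative-based repair targets.

**What the generator does not emulate:** optode-specific coupling optics,
serially correlated physiological rhythms (the sinusoids have fixed
frequency), hemodynamic response functions locked to task events, or any
cortical geometry. Passing the validation suite shows the *pipeline*
recovers known structure under realistic spectral conditions; it is not
evidence about any specific clinical population.

`generate_cohort()` assembles groups A/B/C (defaults 33/18/12 dyads,
mirroring an affected / matched-control / typically-developing design),
applies per-group coupling deltas on designated channel pairs, draws
behavioral scores (symptom totals on a T-score-like scale; a task score),
and generates a CHAT transcript per child from a latent verbal-ability
scalar. At the default `level = "hemo"` the dyad signals are produced
directly at the artifact-free hemodynamic level -- the quantity the
coherence stage consumes -- which keeps cohort-scale simulation fast;
`level = "raw"` runs the full intensity-level generator so the
preprocessing chain can be exercised end to end.

## Preprocessing

The chain is fixed: CV filter -> optical density -> TDDR -> wavelet filter
-> SCI filter -> Beer-Lambert -> short-separation regression.

* **CV filter.** Channel coefficient of variation of raw intensity,
  computed with the *population* standard deviation (documented
  convention), maximum over the two wavelengths; channels above 0.1 are
  excluded.
* **Optical density.** `-log(I/ref)` with `ref` the geometric temporal
  mean, which makes the converted series exactly zero-mean and inverts the
  generator's intensity model.
* **TDDR.** The temporal-derivative-distribution repair estimates a robust
  centre and scale (Tukey biweight mean, 1.4826 x MAD, tuning constant
  4.685) of the first differences and rebuilds the signal as the
  cumulative sum of repaired derivatives. Two repair rules are provided.
  The default **trim** rule leaves every inlier derivative untouched and
  zeroes outliers: artifact-free signal passes through unchanged, spikes
  and steps are removed essentially completely. The literature's soft
  biweight weighting is available (`weighting = "biweight"`, optionally
  with a 0.5 Hz `split_hz`); we found that integrating softly shrunk noisy
  derivatives re-colors measurement noise into spurious low-frequency
  drift (tens of percent RMSE on clean signal), while restricting the
  repair to a low-pass band leaves the fast component of sharp spikes in
  place -- both poor trades for this pipeline, hence the trim default.
* **Wavelet filter.** A periodic Daubechies-4 DWT (depth
  `min(6, floor(log2 n) - 3)`); per level, detail coefficients with
  magnitude above `k * IQR/1.349` (default `k = 4`) are zeroed. Isolated
  artifact energy concentrates in few large coefficients per level while
  distributed signal sets the robust scale, so the filter attenuates
  residual spikes and sharp steps and, being orthonormal with
  coefficients only zeroed, can never increase signal energy.
* **SCI filter.** Both wavelengths are band-passed to the cardiac band
  (0.5-2.5 Hz, a conventional choice; the threshold 0.8 and band are
  configurable) and correlated at zero lag; channels below threshold are
  excluded. A channel pair with either member excluded is dropped from the
  dyad's coherence analysis.
* **Beer-Lambert.** Per time point, the 2x2 linear system in
  (HbO, HbR) is solved exactly; scale-only parameters (DPF, distance)
  affect units, never coherence.
* **Short-separation regression.** Each long channel is regressed (OLS
  with intercept) on the subject's surviving short channels, per
  chromophore; the residual is the analysis signal. Residuals are
  orthogonal to the regressors by construction. With no surviving short
  channel the long channel passes through, demeaned, with a warning.

On artifact-free synthetic dyads the full chain recovers the injected
neural HbO with correlation above 0.95 per channel.

## Wavelet coherence and IBS

The continuous wavelet transform uses the analytic Morlet wavelet
(`omega0 = 6`, 12 voices per octave, 0.01-0.7 Hz by default -- the upper
edge excludes cardiac physiology), implemented as circular
cross-correlation of the zero-padded, demeaned signal with time-sampled
scaled wavelets; the cone of influence uses the standard `sqrt(2) * scale`
e-folding distance. Coherence follows the usual smoothed-cross-spectrum
form: all spectra are scale-normalised, smoothed in time with a Gaussian
of standard deviation equal to the scale and, in the standalone `wtc()`
estimator, across scale with a 0.6-octave boxcar.

Three numerical conventions matter downstream:

* **Wavelet selectivity in the selection path.** The Morlet spectral
  standard deviation is `~log2(1 + 1/omega0)` octaves -- about 0.24
  octave at the conventional `omega0 = 6`, i.e. three bin spacings at 12
  voices/octave. A per-bin selection stage built on that kernel smears any
  band edge across several bins, so the cohort path defaults to
  `omega0 = 8` (~0.17 octave), trading time resolution it does not need
  (spectra are time-averaged anyway) for the frequency selectivity that
  bin-level inference does need. The standalone `wtc()` keeps
  `omega0 = 6`.
* **Time-only smoothing in the selection path.** The cohort pipeline's
  purpose is to find the *frequency bins* with task-related coherence;
  smoothing across scale blurs exactly that resolution. The cohort path
  (`cohort_coherence()` and everything built on it) therefore smooths in
  time only; the 0.6-octave scale boxcar remains the default for the
  standalone estimator, where variance reduction is usually preferred.
* **Estimability trim.** A frequency bin whose in-COI span is shorter than
  two scales contributes a "time average" built from a single effectively
  independent value; such bins showed inflated one-sided selection rates
  in calibration runs and are dropped from cohort analyses (kept as `NA`
  in the standalone estimator).

**Permutation null.** Each of `n_perm` null samples (default 1000) pairs a
subject-1 signal with a uniformly drawn non-partner subject-2 signal and
recomputes the time-averaged spectrum through the identical path. This
shuffled-pairing null preserves each subject's autospectrum and is the
standard hyperscanning null; duplicate pairings are computed once and
carried with multiplicities. Per frequency bin, an independent two-sample
t-test (classical pooled variance; Welch by flag) compares real against
null coherence values on the Fisher-z scale (atanh variance-stabilizes
coherence and removes the skew of bounded values; raw-coherence mode by
flag), one-sided (task-related bins are those with
*elevated* coherence; two-sided by flag). Bins with `p < 0.05` form the
mask; masks are per channel pair by default, with a pooled global mode
available -- the main ambiguity in how such pipelines are described in the
literature, hence both. With an empty mask the pipeline falls back to all
bins with data (with a warning), and `n_perm = 0` skips selection
entirely.

**IBS.** `z = atanh(mean coherence over masked bins)`, with coherence
clipped at `1 - 1e-6` so self-pairs stay finite.

## Transcript metrics

`parse_chat()` reads CHAT-dialect speaker tiers, strips bracketed
annotation codes, `&`-prefixed non-words and unintelligible markers, and
treats sentence-final `. ! ?` as utterance terminators. Morpheme counting
is a fixed, documented approximation of Brown's conventions: contracted
auxiliaries/negations count separately; regular `-s`/`-es`, `-ed`, `-ing`
add one morpheme when the remaining stem is plausible; a shipped lexicon
of irregular forms and per-suffix exceptions counts as single morphemes.
Exact CLAN parity is a non-goal. The four metrics are MLU (morphemes per
utterance), TNW (word tokens, fillers excluded by default), WPS (words per
sentence) and CPS (1 + surface subordinating markers per sentence, from a
fixed marker list rather than parsing). The transcript generator makes
utterance length, inflection use, subordination and utterance count
monotone in a latent verbal-ability scalar, with a floor of 1-2
morphemes per utterance at zero ability.

## Group statistics

Per channel pair, one-way (equal-variance) ANOVA of IBS across groups;
two-tailed post-hoc t-tests (Welch by default -- group sizes like 33/18/12
make pooled variance fragile); Benjamini-Hochberg FDR at 0.05 across
channel pairs within a task (the correction family is configurable, and
whether the ANOVA or post-hoc p-values carry the correction is a mode
switch, since both readings of the usual description are defensible).
Communication metrics run through the same chain with the FDR family being
the four metrics. For channel pairs flagged as atypical, Kendall's tau-b
relates IBS to each communication metric and to the symptom score within
the affected group.

## Validation design and problem sizes

The validation suite and `scripts/acceptance.R` recompute, from scratch:

1. coherence identities (self-coherence 1 inside the COI, symmetry) and
   agreement with an explicit-convolution brute-force implementation;
2. type-I calibration of bin selection: 500 uncoupled cohorts of 8 dyads,
   120 s blocks, 200 permutations, 6 voices/octave -- the mean per-bin
   selection rate should match the nominal 0.05 within two binomial
   standard errors with cohorts as the independent unit (bins within a
   cohort share signals);
3. band recovery: coupling at 0.05-0.1 Hz, strength 0.6, 20 dyads, 240 s
   blocks, 12 voices -- at least 80% of in-band and at most 10% of
   out-of-band bins selected, averaged over 20 cohorts. The residual
   out-of-band selections sit directly on the band shoulders: the Morlet
   spectral width (~0.17 octave at the selection path's `omega0 = 8`)
   bounds any such estimator's edge sharpness, which is what motivated
   the selectivity-oriented defaults of the cohort path described above;
4. group recovery: 15/15/15 dyads, one of six channel pairs carrying a
   +0.3 coupling delta over a 0.15 baseline, 360 s blocks (the length of a
   full cooperative-task block) -- the affected pair must be flagged by
   the full ANOVA/post-hoc/FDR chain in at least 80% of 20 cohorts with
   false flags at an FDR-consistent rate. Shorter blocks were examined and
   rejected at design time: band-averaged coherence from 120 s carries too
   few degrees of freedom to resolve a 0.3 delta at these group sizes;
5. preprocessing closed forms (Beer-Lambert and optical-density round
   trips, TDDR spike reduction >= 90% with clean RMSE < 5%, SCI sign
   cases, exact CV exclusion sets);
6. statistics oracles: BH against the literal step-up rule on all subsets
   of 8 p-values, tau-b against O(n^2) pair counting, null ANOVA
   rejection rate at 0.05 over 2000 draws;
7. hand-computed transcript metrics and their monotonicity in latent
   verbal ability (rank correlation > 0.8 over a 100-point grid);
8. Kendall recovery at study scale: symptom scores generated with
   tau = 0.4 against one pair's coupling, 33 dyads, 180 s blocks, 50
   cohorts -- the mean estimated tau between pipeline IBS and symptoms
   must land within 0.15 of the target. The estimate is attenuated
   (typically ~0.3) by IBS estimation noise, exactly as a finite-length
   recording attenuates any rank correlation against a noisy covariate.

Problem sizes (block lengths, permutation counts, voices) are the
package's own choices for these studies and are stated above; they trade
Monte-Carlo precision against desk-scale runtimes without changing what
is being demonstrated.

## Known limitations

* Coherence values are reported without bias correction; comparisons
  across configurations with different smoothing or block lengths are not
  meaningful in absolute terms.
* The morpheme and clause rules are surface approximations; transcripts
  with heavy code-switching, neologisms, or non-English material will be
  mis-scored.
* The permutation null assumes exchangeability of non-partner pairings;
  systematic cohort-wide rhythms (e.g., a shared task pacing) would
  violate it and inflate apparent IBS, a caveat inherited from the
  shuffled-pair design itself.
* Time-resolved (sliding-window) IBS and directed coupling measures are
  out of scope.
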