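# dyadsync

Inter-brain synchrony (IBS) analysis for dyadic fNIRS hyperscanning.

When two people interact while both wear fNIRS optodes, the coupling
between their cortical hemodynamics — inter-brain synchrony — is a
candidate marker of social engagement, and atypical IBS patterns are of
direct interest in neurodevelopmental conditions studied through
mother–child interaction. `dyadsync` implements the full analysis chain
such studies need, for researchers who have dyadic two-wavelength fNIRS
recordings (or want to simulate them):

* **Preprocessing / QC**: coefficient-of-variation channel exclusion,
  optical-density conversion, temporal derivative distribution repair
  (TDDR), wavelet-based artifact filtering, scalp-coupling-index (SCI)
  exclusion, the modified Beer–Lambert law, and short-separation
  regression of superficial physiology.
* **IBS**: Morlet wavelet transform coherence (WTC) per dyadic channel
  pair, permutation selection of task-related frequency bins against a
  shuffled non-partner null, and a Fisher-z IBS statistic per dyad ×
  channel pair × task.
* **Child-language metrics** from CHAT-style transcripts: MLU (morphemes
  per utterance), TNW (total words), WPS (words per sentence), CPS
  (clauses per sentence).
* **Group statistics**: one-way ANOVA across groups with two-tailed
  post-hoc t-tests, Benjamini–Hochberg FDR, and Kendall correlations of
  IBS with behavior and symptom scores.
* **A synthetic-dyad generator** with known ground truth (coupling band
  and strength, physiological noise, motion artifacts, scalp component,
  latent verbal ability) so the whole chain is testable without clinical
  data.

## The statistic at the core

For channels $x$ (subject 1) and $y$ (subject 2), wavelet coherence at
scale $s$ and time $t$ is

$$R^2(s,t) = \frac{\left|S\!\left(s^{-1} W_x W_y^*\right)\right|^2}
{S\!\left(s^{-1}|W_x|^2\right)\, S\!\left(s^{-1}|W_y|^2\right)}$$

with $W$ the analytic Morlet CWT ($\omega_0 = 6$) and $S$ smoothing in
time (Gaussian of SD equal to the scale). Coherence is averaged over the
task window inside the cone of influence, per frequency bin. Bins where
the real dyads' coherence exceeds that of shuffled non-partner pairings
(one-sided t-test, $p < .05$, against $n_\mathrm{perm}$ permutation
samples) form the task-related mask, and

$$\mathrm{IBS} = \operatorname{atanh}\!\big(\overline{R^2}_{\text{masked bins}}\big)$$

is the Fisher-z synchrony value entering group statistics.

## Worked example

Simulate a three-group cohort (15 dyads per group, six homologous channel
pairs, 240-s blocks) in which group A carries a +0.3 coupling delta on
channel pair 3, then run the IBS and statistics stages:

```r
library(dyadsync)

spec <- dyad_spec(n_channels_long = 6, n_channels_short = 1,
                  duration_s = 240, coupling_strength = 0.15,
                  artifact_rate = 0)
cohort <- generate_cohort(c(A = 15, B = 15, C = 15), spec = spec,
                          effect_map = list(A = c("3" = 0.3)), seed = 42)
ibs <- ibs_pipeline(cohort, n_perm = 100, voices = 6, seed = 42)
metrics <- cohort_metrics(cohort)
scores <- data.frame(dyad = seq_along(cohort$dyads),
                     symptom = sapply(cohort$dyads, `[[`, "symptom"))
analysis <- run_full_analysis(ibs$table, metrics = metrics, scores = scores)
analysis
```

```
ibs_analysis: 6 channel pairs tested, 1 significant after BH-FDR (alpha = 0.05, on anova p-values)
 pair        F           p          q significant
    3 6.911568 0.002541771 0.01525063        TRUE
communication metrics:
 metric        F            p            q significant
    MLU 22.90053 1.882522e-07 2.510029e-07        TRUE
    TNW 26.82379 3.119480e-08 1.247792e-07        TRUE
    WPS 23.92382 1.160365e-07 2.320730e-07        TRUE
    CPS 15.90786 7.196280e-06 7.196280e-06        TRUE
Kendall correlations (group A, flagged channels):
 pair variable        tau          p  n
    3      MLU -0.3636405 0.05972487 15
    3      TNW -0.3750173 0.05302179 15
...
```

The pipeline flags exactly the channel pair that carries the injected
group difference (pair 3, FDR-adjusted q = 0.015) and finds the expected
group differences in all four communication metrics (the generator gives
group A children lower latent verbal ability). The Kendall block
illustrates the correlation stage: no IBS–behavior association was
injected in this cohort, and none of the taus is meaningfully different
from zero at n = 15. `plot(analysis, ibs$table)` draws the group boxplots
for the flagged pair.

Raw recordings travel as a plain-text bundle
(`write_recording()` / `read_recording()`); `preprocess_dyad()` /
`preprocess_cohort()` take raw intensity to superficial-regressed HbO/HbR;
`run_pipeline()` drives simulation → IBS → statistics from a single YAML
configuration and writes config-hash-stamped CSV outputs.

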