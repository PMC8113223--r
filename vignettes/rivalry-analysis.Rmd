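---
title: "Continuous-report binocular rivalry: data reduction, inference, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-report binocular rivalry: data reduction, inference, and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brivalry)
```

## The measurement model

In a continuous-report binocular rivalry trial, two dissimilar images (here a
happy and a neutral expression of the same face) are presented one to each
eye, and conscious perception alternates stochastically between them. The
observer codes the currently dominant percept in real time by holding one of
three adjacent keys: one for each clear percept and a middle key for a mixed
(piecemeal) percept. `brivalry` reduces the resulting keypress log to three
standard components per trial:

* **Initial percept (IP)** — the label of the first *clear* (non-mixed)
  dominance interval; a mixed report does not count. A trial with no clear
  report has IP `none`.
* **Onset resolution time (ORT)** — seconds from trial onset to the onset of
  that first clear interval: the time the visual system needed to resolve
  the initial ambiguity. Undefined when IP is `none`.
* **Cumulative time (CT)** — total reported dominance per label within the
  trial. By construction `CT(happy) + CT(neutral) + CT(mixed) + unreported
  time = trial duration`, and this conservation identity is asserted to
  `1e-9` s throughout the test suite.

### Parsing conventions

Raw logs do not say whether observers *held* keys for the duration of a
percept or *toggled* on each switch, and different laboratories do both. The
parser therefore exposes a dialect switch:

* `hold` (default): a percept is dominant while its key is held. When
  several keys are held at once — which happens routinely, since observers
  press the next key slightly before releasing the previous one — the most
  recent press wins, and an earlier still-held key resumes when the later
  one is released.
* `toggle`: each press switches the report until the next press; releases
  are ignored.

The hold convention with last-key-wins is the natural reading of
press/release logs from three adjacent keys, so it is the default. Both
parsers are validated against a brute-force oracle
(`grid_oracle_metrics()`) that rasterizes the trial onto a 1-ms grid and
applies the convention literally at each grid cell; parser and oracle must
agree on per-label occupancy to within one grid step per event. Because the
oracle only sees grid midpoints, a clear interval narrower than 1 ms can
fall between cells; the tests accept an IP disagreement only in exactly that
situation.

Times are seconds from trial onset everywhere inside the package;
milliseconds exist only as an input dialect (`event_dialect(time_unit =
"ms")`). A missing release means the key was still down at trial end and is
imputed at the trial duration — under hold-to-report semantics the percept
evidently persisted. Events are clipped to `[0, duration]`, zero-length
intervals are dropped, and results are invariant to the ordering of input
rows.

### Trials without a report

Observers occasionally fail to code a trial. Such "uncoded" trials are kept
in the session (validation flags them as warnings, not errors) but are
excluded listwise from every metric denominator: the absence of a report is
not evidence that no percept occurred, so imputing zeros would bias CT
downward.

## Subject-level aggregation and exclusions

Trial metrics are averaged per subject x mimicry condition x label. Mean ORT
for a label averages only the trials whose IP equals that label, so a
subject who never saw, say, a neutral initial percept under blocked mimicry
has an undefined cell. The ORT analysis is a fully-within 2 (mimicry) x 2
(IP) ANOVA and needs complete cells, so such subjects are excluded from the
ORT stage only (`apply_ort_exclusions()`); CT analyses keep all subjects.
ORT is log-transformed (natural log of seconds) before the ANOVA; because
repeated-measures contrasts cancel additive constants, the base and unit of
the log affect nothing. An exact-zero ORT (a press at trial onset) is
floored at 1 ms before the log; the tests verify the floor changes nothing
when no zero ORTs exist.

## The inferential battery

* `rm_anova()` — classical fully-within-subject ANOVA for one or two within
  factors, computed via the multivariate route (`car::Anova`, type III, on
  an intercept-only multivariate linear model). For any effect involving a
  factor with three levels the Greenhouse–Geisser epsilon is reported with
  epsilon-scaled (fractional) degrees of freedom and the corrected p value,
  alongside the uncorrected test; two-level effects are spherical by
  construction. The test suite checks the decomposition against an explicit
  design-matrix projection oracle at `1e-8` and the `F = t^2` identity on
  two-level factors.
* `gg_epsilon()` — the Box/Greenhouse–Geisser epsilon from the
  double-centered cell covariance, clamped to `[1/(k-1), 1]`; equals 1 under
  compound symmetry.
* `paired_t()` — paired t with Cohen's `d_z`. When all differences are
  exactly zero the statistic is defined by continuity as `t = 0, p = 1`; a
  nonzero mean with zero variance is an error.
* `bonferroni_adjust()` — `min(1, p * m)` with the family size `m` explicit,
  never inferred from vector length; the CT post-hoc family defaults to 3
  (one blocked-vs-free contrast per reported content).
* `jzs_bf10_paired()` — the default JZS Bayes factor for paired designs:
  marginal likelihood of the observed t under a Cauchy(0, r) prior on the
  standardized effect, over its central-t density under the null. The prior
  scale defaults to `sqrt(2)/2` ("medium"); it is a configuration knob and
  is recorded in every output because published Bayes factors rarely state
  it. The one-dimensional integral uses the tangent substitution that maps
  the Cauchy prior to a uniform density on a finite interval, with a
  reported relative error bound (`<= 1e-6` in all tested regimes); tests
  compare against an independent 200,001-node Simpson integrator.
* `fit_ip_logistic()` — random-intercept logistic regression of IP (happy
  vs. neutral) on mimicry, fitted by adaptive Gauss–Hermite quadrature
  (`lme4::glmer`, 20 nodes by default; 1 node gives the Laplace fallback).
  With the variance constrained to zero it reduces to pooled logistic
  regression, whose slope is the closed-form 2x2 log odds ratio — the tests
  assert that reduction to `1e-6` and recover a known slope from simulated
  heterogeneous subjects.
* `pearson_cor()` — Pearson correlation reported with the `n - 2` df
  convention. The pipeline's questionnaire stage emits these flagged
  `exploratory = TRUE, corrected = FALSE`: sixteen correlations (2
  questionnaires x 2 metrics x 2 conditions x 2 labels) are a screening
  analysis, not confirmatory tests, and silent non-adjustment would be
  misleading.

### Post-hoc convention

Post-hoc contrasts are classical paired t tests on subject-cell means, with
Bonferroni adjustment over the declared family. Published analyses of this
design sometimes show pooled/Welch-style fractional error dfs, which suggest
marginal contrasts from a mixed model; that variant is deliberately not the
default here because the estimating procedure behind such dfs is rarely
fully specified. The package's convention is stated in the output rather
than silently matched to any particular publication.

## Power analysis

`power_paired_t()` is the exact noncentral-t power
`1 - F_nct(t_crit; df = n - 1, ncp = d sqrt(n))` (two-sided versions count
both tails). `required_n()` returns the smallest integer n reaching the
target power together with the fractional root and the normal-approximation
size `((z_alpha + z_power)/d)^2`, because published sample sizes are
variously derived from either convention — and for moderate effects the two
integers can legitimately differ by 1–2. `sample_size_audit()` tabulates
both sidedness conventions at once. For example, at `d = 0.478` the
one-sided normal approximation gives 28 while the exact computation requires
one more subject; the audit reports both rather than reconciling them.

## The synthetic-data generator

`simulate_study()` exists so that every stage of the pipeline can be tested
end to end, with known ground truth, at the full design size. It emulates
the standard design: 28 subjects, 2 mimicry conditions (order
counterbalanced across subjects) x 2 blocks x 8 trials of 15 s, four rival
stimuli twice per block in random order, the happy/neutral key assignment
counterbalanced across blocks with the middle key always coding mixed, and
TAS-20/IRI questionnaire totals plus valence/arousal stimulus ratings.

Each trial is an alternating renewal process:

1. an initial unresolved period (the latent ORT), lognormal with median
   1.2 s and log-SD 0.5 — onset resolution times in face rivalry are
   right-skewed and mostly 0.5–3 s;
2. a first resolved percept, happy with probability 0.72 (tilted per subject
   by a latent happy-dominance factor), matching the strong happy bias such
   stimuli show in initial percepts;
3. alternating happy/neutral dominance epochs with gamma-distributed
   durations. Gamma durations with shape 3–4 are the standard empirical
   description of rivalry dominance periods; shape 3 is used with scales
   1.15 s (happy) and 0.42 s (neutral), calibrated once so that grand-mean
   per-trial CT approximates the summary structure typical of
   happy-vs-neutral face rivalry (happy about 7.5–7.9 s, neutral about
   2.6–2.7 s under free mimicry, about 72% happy initial percepts);
4. optional mixed interludes between epochs (probability 0.7, lognormal with
   median 1 s);
5. serialization to key events with Gaussian report-latency jitter (SD
   0.05 s) that never reorders a press/release pair; an epoch still dominant
   at trial end is emitted with a missing release.

Between-subject heterogeneity is multiplicative on the duration scales
(log-SD 0.25), driven by a latent happy-dominance factor that also
correlates with the simulated TAS-20 score (`rho_tas_emotion`, default
-0.4: more alexithymic subjects show less happy dominance, the direction
such exploratory correlations have been reported in).

### The injected condition effect

The condition-by-percept effect of interest — longer neutral dominance when
mimicry is blocked — is injected on the *neutral duration scale* in the
blocked condition, not on switch rates, mirroring the interpretation that
blocking mimicry stabilizes neutral percepts. The target is expressed in
interpretable units: `blocked_neutral_ct_delta_s` (default 0.70 s) is the
desired increment of per-trial mean neutral CT. Because truncation at 15 s
and competition with the happy percept make the mapping from scale
multiplier to realized CT nonlinear, `calibrate_neutral_multiplier()` finds
the multiplier by bisection on a Monte-Carlo estimate (8,000 trials per
evaluation, common random numbers so the objective is deterministic).
Setting the delta to 0 gives the null model with multiplier exactly 1.

### Randomness and determinism

Every random draw derives from the master seed through per-unit
Mersenne-Twister streams seeded by a multiplicative hash of (seed, subject,
block, trial), so a single trial can be regenerated in isolation and a study
is bit-reproducible on one platform. Re-running `run_analysis()` on an
identical configuration reproduces every number; the run manifest records
the seed, the conventions in force, and a configuration hash.

### What the generator does and does not emulate

It reproduces the summary-level statistical structure the analysis consumes:
CT/ORT/IP distributions of realistic magnitude, a happy-dominance bias,
within-subject condition effects of controlled size, counterbalancing, and
questionnaire correlations. It does **not** model the neural dynamics of
rivalry (no adaptation, no serial correlation between successive dominance
durations, no Levelt-type contrast dependence), stimulus identity effects,
practice or fatigue across blocks, or response errors other than Gaussian
latency jitter. Passing tests therefore demonstrate that the pipeline
recovers what it is supposed to recover from data *of this structure*; they
do not certify the generator as a model of real rivalry data.

## Calibration of the full pipeline

Two simulation studies in the acceptance tests characterize the battery as a
whole, at problem sizes chosen to keep the default test run short:

* **Type-I error**: with a symmetric null generator (identical gamma
  parameters for both labels, `p_first_happy = 0.5`, delta 0), the
  GG-corrected mimicry x content interaction test is run on 500 replicate
  studies of 10 subjects x 4 trials per block; its rejection rate must fall
  inside the 99% binomial band around 0.05.
* **Effect recovery**: with the default 0.70-s injected effect, the
  blocked-vs-free neutral CT post-hoc difference is averaged over 20
  replicate studies at the full default size; the mean must lie within two
  replicate-level standard errors of 0.70 s.

## Known limitations

* The ANOVA requires complete, balanced subject x cell tables; incomplete
  designs fail loudly with the offending subjects and cells named rather
  than being silently dropped or imputed.
* Mixed-model post-hoc contrasts (fractional-df marginal contrasts) are not
  implemented; post-hocs are classical paired contrasts on subject means.
* The logistic stage models only a random intercept — no random slopes and
  no crossed stimulus effects.
* The simulator's dominance durations are independent draws; any analysis of
  sequential dependence between alternations is out of scope.
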