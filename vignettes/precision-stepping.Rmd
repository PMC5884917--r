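---
title: "Precision stepping on a treadmill: models, scoring and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision stepping on a treadmill: models, scoring and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precstep)
```

## The task

A walker on an instrumented treadmill (belt at 3 km/h, force platform
sampling the center of pressure at 1000 samples/s, optical markers at
150 samples/s) steps on targets projected onto the belt. Targets appear 2 m
ahead and ride the belt toward the walker; they are spaced one preferred
step length (L) apart in the walking direction and 20 cm center-to-center
mediolaterally, scaled to the shoe. In *perturbed* blocks a minority of
targets jumps forward or backward by 40% of L while the walker is already
committed to the step. The jump is triggered when the target's distance
from the walker's center of pressure (COP) equals a preset *available
response distance* (ARD): 80, 100, 130 or 200% of L for forward shifts,
130% only for backward shifts (catch trials that discourage anticipation
and are excluded from analysis). Short ARDs leave little distance — hence
little time — to re-aim the step.

Performance is scored per step as the signed anteroposterior (AP) distance
between the foot center and the target center at *midstance*, positive for
overshoots. Two summary measures per condition follow: the mean signed
error, normalized to L, and the *variability*

$$\mathrm{Variability} \;=\; \sqrt{\frac{\sum e^2 - (\sum e)^2/k}{k}}\;\%\ L,$$

the population (divide-by-$k$) standard deviation of the raw errors,
expressed as a percentage of L. Both conventions — raw errors averaged
first and normalized afterwards, and the divide-by-$k$ form — are
deliberate and preserved exactly; `condition_summary()` is tested against
an independent brute-force oracle at $10^{-12}$.

## Protocol generation

An unperturbed block is 59 non-shifting targets. A perturbed block is 248
targets containing exactly 40 shifts: 8 repetitions of each of the five
shift types (four forward ARDs and the backward catch type), 4 per foot,
with 5–7 non-shifted targets between consecutive shifts. A session is one
unperturbed plus three perturbed blocks in seeded random order (120 shifts
per session).

The printed constraints over-determine the gap schedule: 39 inter-shift
gaps of mean 6 would need 234 fillers, while 248 − 40 = 208 are available.
`generate_perturbed_block()` therefore samples gaps uniformly on {5, 6, 7},
then decrements randomly chosen gaps toward 5 until the lead-in (fixed at
the minimum gap) plus all gaps fit, leaving a free tail after the last
shift. Because the stepping feet alternate with target index, the 40 shift
slots must split 20/20 across index parity for the 4-per-foot balance to be
possible; the gap vector is resampled until they do, and shift types are
then dealt 4 + 4 within each parity class. Everything is deterministic
under the seed.

## The synthetic walker

The simulator is the package's ground-truth generator, not a biomechanical
model. Its choices:

* **Cadence** is locked to the belt: step period $T = L/v$, so the walker
  tracks belt-fixed targets without drifting. Stance lasts $1.2\,T$ (duty
  factor 0.6), giving 20% double-support phases; single support spans
  $[t_{strike}+0.2T,\,t_{strike}+T]$ and midstance sits at its center.
* **Stance feet ride the belt** at $-v$; both foot and target translate
  together, so the foot–target AP distance is constant through stance —
  this invariance is what makes scoring at midstance equal the landing
  error, and it is property-tested.
* **Swing** is minimum-jerk in AP with a half-sine vertical clearance.
  Only landing positions and event times matter downstream, so swing shape
  is cosmetic.
* **Landings**: the foot-center landing position equals the (displaced,
  when shifted) target center at the strike instant plus a signed error
  drawn from $N(\mathrm{bias}\cdot L,\ (\sigma\,\kappa(\mathrm{ard})\,L)^2)$.
  The inflation $\kappa(\mathrm{ard}) = 1 + 0.5\,\max(0, 1.5 -
  \mathrm{ard})/0.7$ is non-increasing and equals 1 at ARD 200%; its shape
  is a calibration choice, not an empirical quantity.
* **COP synthesis**: during single support the COP advances linearly from
  heel to toe under the stance foot, reaching 45% of the shoe length on
  either side of the foot center (push-off carries the COP into the toe
  region); during double support it transfers on a straight line between
  feet. This reproduces the classic butterfly the event detector relies
  on.
* **Shift onsets** are realized at the first noiseless COP sample where
  the target's lab-frame distance from the COP drops to ARD × L. With
  gait variability the criterion can remain unmet until the landing is
  imminent; the projector then shifts at the last pre-landing sample.
  Onset times are written to the trial's target log — the analogue of the
  projector software log — which is what scoring reads; the `GroundTruth`
  record stays a pure test oracle.
* **Noise** is additive white Gaussian on every marker channel (default
  1 mm) and on both COP channels (default 2 mm). Real optical and
  force-plate noise is colored and gait variability is structured
  (timing, width, and amplitude co-vary); passing tests therefore show
  correctness of the pipeline's arithmetic and detection logic under
  idealized signals, not robustness to every real-world artifact.

## Event detection

The ML COP alternates between two single-support plateaus joined by rapid
double-support transfers. `detect_events()` segments the signal by
hysteresis around the midline at half the butterfly amplitude, discards
edge segments truncated by the recording, and fits a least-squares line to
each transfer ramp (samples within 75% of the amplitude). The line's
crossings of the two plateau levels date the destination foot's strike
(transfer onset) and the source foot's toe-off (transfer completion). On
noiseless synthetic gait the recovered times are exact to floating point;
with 2 mm COP noise they stay within ~1 ms, comfortably inside the 10 ms
(noiseless) and 20 ms (noisy) acceptance conventions — conventions of this
package, not empirical values. Preferred step length is the mean
belt-compensated AP COP distance between successive strikes over 20
strides and recovers the configured L within 1%.

Degenerate inputs fail loudly: a monotone ML trace has no butterfly
(amplitude or plateau-count error), and an interior stance lacking
bracketing contralateral events raises an "unpaired events" error naming
the stance. A zero-length single support (toe-off coinciding with the
contralateral strike) is returned but flagged `degenerate`.

## Statistics

* `pearson_corr()` wraps the standard two-tailed product-moment test.
* `partial_corr()` double-residualizes both variables on the covariates
  and tests the residual correlation on $n - 2 - c$ degrees of freedom.
* `rm_ancova()` implements the mixed design with one within-subject factor
  (the four forward ARDs) and a continuous covariate (age): the covariate
  is tested on subject means with df $(1, n-2)$; within effects are tested
  on orthonormal contrasts with df $(k-1, (k-1)(n-2))$ and
  Greenhouse–Geisser correction,
  $\hat\epsilon = \mathrm{tr}(S)^2/((k-1)\,\mathrm{tr}(S^2))$ estimated
  from the pooled error covariance of the contrasts. With $k = 4$ and
  $n = 30$ the corrected dfs keep the ratio $df_2/df_1 = 28$; the
  implementation is cross-checked against `car::Anova()` in the tests.
  Worth knowing: $\hat\epsilon$ is biased low at modest $n$ even under
  perfect sphericity (≈ 0.90 at $n = 30$), which is a property of the
  estimator, not a bug; the Monte-Carlo sphericity check in the tests
  therefore uses $n = 100$. Under the null the GG-corrected within test
  rejects at ≈ 0.04–0.06 at $\alpha = 0.05$.
* `fdr_bh()` applies Benjamini–Hochberg step-up control; the family is
  whatever vector the caller passes, because reasonable family definitions
  (per dependent variable, per hemisphere, per region group) vary and the
  package does not guess.
* `permutation_pearson()` gives the two-sided permutation p value
  $(1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(n_{perm}+1)$, 5000 permutations by
  default.

Brain measures enter only as precomputed per-subject columns of the cohort
table (`analyze_cohort(measures = ...)`); no imaging computation is in
scope.

## Calibration of the cohort defaults

The default subject model makes the per-step landing SD decline linearly
with age, $\sigma(a) = 0.060 - 0.0020\,a$ (fractions of L), with
between-subject SD 0.0067 and a floor at 0.005. For $n = 30$ subjects aged
uniformly 9–18.5 years and 59 unperturbed steps each, the population
correlation between age and measured unperturbed variability is then

$$r \approx \frac{b\,\mathrm{sd}(a)}
{\sqrt{b^2\mathrm{var}(a) + \tau^2 + \sigma^2/(2k)}}
\approx \frac{-0.0055}{0.0091} \approx -0.60,$$

where the $\sigma^2/(2k)$ term is the sampling noise of a population-SD
estimate from $k = 59$ steps. The constants were fixed from this analytic
target; simulation (200 seeds) recovers a mean sample correlation of about
−0.59, negative in every run. The landing bias defaults to −1% L
(age-invariant, small habitual undershoot) with 1% between-subject SD, and
preferred step length grows mildly with age
($L = 0.40 + 0.008\,a$ m), which cancels out of all normalized measures.

## Problem sizes and numerical choices

The test suite and the acceptance script work at the design's native block
sizes (59- and 248-target blocks, full sessions for cohort work), with
signal-level checks on single trials and score-level simulation for the
200-seed recovery and 500-cohort null-calibration runs — the score-level
path draws landing errors directly from the subject model and skips signal
synthesis, which is exact for these purposes because the signal chain is
separately shown to reproduce true errors to ~$10^{-12}$ m. Times are kept
in absolute seconds; interpolation of marker channels tolerates gaps up to
33 ms (five samples); variability radicands are clamped at zero against
floating-point cancellation; all randomness flows through explicit seeds,
restored after use.

## Known limitations

* The walker never misses, trips, or adjusts timing; responses to shifts
  change only the landing distribution, not cadence.
* ML error, timing error, and success/failure classification of shift
  responses are not modeled or scored.
* The COP model is piecewise linear; real butterflies curve. The event
  detector is validated against this generator, not against clinical
  force-plate data.
* Very late shift triggers (ARD criterion unmet before landing) are
  realized at the last pre-landing sample rather than rejected; the log
  records the realized time.
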