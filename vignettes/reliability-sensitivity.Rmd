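---
title: "Test-retest reliability and sensitivity of strength and power tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability and sensitivity of strength and power tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relsens)
options(relsens.quiet = TRUE)
```

## The problem

Longitudinal training and intervention studies rest on performance tests
repeated weeks apart. Before a change in a score can be attributed to
training, two questions must be answered for the test itself: how
reproducible is it across sessions (reliability), and how small a change can
it resolve above its own noise (sensitivity)? `relsens` implements the full
analysis chain for trial-based strength and power tests — isometric
maximal voluntary contractions (knee extension, handgrip), countermovement
jumps (jump height, peak power), and reactive hop sets (set peak force,
average contact time) — measured over repeated sessions.

## From trials to session scores

The raw unit is one trial: subject $i$, session $j$, trial $t$, value
$y_{ijt}$ in the variable's native unit (Nm, kg, cm, W/kg, kN, s). Sessions
are summarized by one of three rules:

* **Avg** — the mean of the session's trials,
* **Hv** — the highest trial value (force, torque, height, power),
* **Lv** — the lowest trial value (contact time, where shorter is better).

Reactive hops are special: a session consists of two sets of up to ten
hops, and hops invalidated by heel contact are removed before anything else
happens. Each set is reduced to its peak force (maximum over valid hops) and
its average contact time (mean over valid hops); those two set values then
act as the session's "trials". An optional contact-time cut
(`max_contact_time`, e.g. 0.25 s for a strict fast stretch-shortening-cycle
criterion) can remove slow hops as well, but is off by default because the
standard protocol filters only heel contacts.

Scores for one variable and rule form a complete $n \times k$ matrix
(subjects by sessions); subjects missing a requested session are dropped
with a warning. All statistics operate on this matrix, for all sessions
together and for each session pair, so a pair's result never depends on data
outside the pair.

## Reliability

**Relative reliability** is the two-way absolute-agreement intraclass
correlation (McGraw–Wong). With row, column, and residual mean squares
$MS_R$, $MS_C$, $MS_E$ from the two-way decomposition,

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

and the mean-of-$k$ form ICC($A$,$k$) follows by the Spearman–Brown step
$k\rho/(1+(k-1)\rho)$. The single form is paired with best-value scores (one
measurement), the mean form with session averages. Confidence intervals use
the F-based method with a Satterthwaite approximation for the denominator
degrees of freedom; the mean-form interval transforms the single-form
bounds. Estimates are classified on the Koo–Li bands (poor < 0.50,
moderate 0.50–0.75, good up to 0.90, excellent > 0.90; the band edges are
read literally, so 0.50 and 0.75 are moderate and 0.90 is good). Negative
estimates are reported as computed — clamping to zero would hide degenerate
data.

Two models ("two-way random" vs "two-way mixed") share this absolute-
agreement point estimate, and the interval model is a genuinely open choice;
this package uses the McGraw–Wong agreement interval throughout, which is
what the widely used ICC implementations produce, and cross-checks it
against a parametric bootstrap in the test suite. The two constructions
agree qualitatively (substantially overlapping intervals), not to fine
tolerances at small $n$ — they are different interval types, which is why
the tests assert overlap rather than bound-for-bound equality.

**Absolute reliability** is the within-subject coefficient of variation. The
formula SD/mean × 100 does not by itself fix the pooling level; since the
quantity of interest is within-subject variation, the default computes each
subject's CV across the sessions of the comparison (sample SD) and averages
over subjects. A pooled variant (`cv_method = "pooled"`) is available.

**Systematic bias** (learning or time effects) is tested with the
repeated-measures ANOVA on session: $F = MS_C/MS_E$ with $(k-1)$ and
$(n-1)(k-1)$ degrees of freedom. For $k = 2$ this is exactly the squared
paired $t$ statistic. No sphericity correction is applied by default for
$k = 3$ (a Greenhouse–Geisser adjustment would only matter for strongly
heterogeneous covariance, and the standard analysis of this design reports
the uncorrected test); no correction is made across the many variables and
comparisons either, which is deliberate and should be kept in mind when
reading the significance markers.

Shapiro–Wilk (per session) and Levene (across sessions, classic
mean-centered; median-centering available) gates are advisory: failures are
logged, never fatal, because the downstream estimators remain defined.

## Sensitivity

With the pooled SD (root of the mean per-session variance — for a complete
matrix with equal $n$ this equals pooling centered cells) and pooled mean
(mean of session means) over the compared sessions:

* $\mathrm{SEm} = SD_{pooled}\sqrt{1-\mathrm{ICC}}$, the measurement noise
  floor, with $\mathrm{SEm}\% = \mathrm{SEm}/\overline{x}_{pooled}\times100$;
* $\mathrm{SWC} = 0.2 \times SD_{pooled}$, the smallest worthwhile change
  (0.2 standardizes a "small" effect; the multiplier is configurable);
* $\mathrm{MD} = \mathrm{SEm}\times1.96\times\sqrt{2} \approx
  2.772\,\mathrm{SEm}$, the minimal difference two measurements must exceed
  to signal a real change at 95% confidence.

A measurement is **sensitive** when $\mathrm{SEm} < \mathrm{SWC}$ (strict).
For fixed pooled SD this flips exactly at $\mathrm{ICC} = 1 - 0.2^2 = 0.96$,
a closed-form fact the tests exercise. The ICC fed into SEm is the point
estimate of the form matching the score rule (mean form for Avg, single
form for Hv/Lv), so each reported row pairs one ICC with one SEm.

```{r chain}
sim <- simulated_study(seed = 42)
rep <- suppressWarnings(run_analysis(sim$dataset, variables = "grip_force"))
rep$sensitivity[, c("rule", "comparison", "sem", "sem_pct", "swc", "md",
                    "sensitive")]
```

## The synthetic study generator

No raw dataset accompanies the published study this package's reference
tables come from, so every stage is exercised against generated data with
known truth. Trial values follow

$$y_{ijt} = \mu + \delta_j + b_i + s_{ij} + e_{ijt},$$

with Gaussian subject effects $b_i$ (SD $\sigma_b$), fixed session shifts
$\delta_j$ (fixed, not random, because that is what a systematic bias is),
subject-by-session interaction $s_{ij}$ (SD $\sigma_s$), and trial noise
$e_{ijt}$ (SD $\sigma_e$). At the session-average level the implied true
single-measure ICC is

$$\rho_1 = \frac{\sigma_b^2}
  {\sigma_b^2 + \theta_\delta^2 + \sigma_s^2 + \sigma_e^2/T},$$

with $\theta_\delta^2$ the sample variance of the shifts — session shifts
penalize *agreement* even though they leave consistency untouched. Every
generated dataset carries this truth record alongside. One master seed
drives per-variable substreams, so adding a variable never perturbs
another's draws.

The fixture `simulated_study()` fixes the study conditions: 17 subjects,
three sessions, three trials (two hop sets of ten hops, 5% heel-contact
probability), grand means and between-subject SDs at the published session
descriptives (e.g. knee extension ≈ 256 ± 90 Nm, jump height ≈ 44 ± 11 cm,
hop peak force ≈ 3.5 ± 1 kN), trial noise placed so session-level CVs land
in the published 2–8% band, a fixed learning shift on hop peak force
(+0.10 and +0.33 kN on the later sessions, the published drift), and an
interaction-dominated low-ICC regime for contact time. Sessions of the
other variables are generated exchangeable (no drift), anchored at the
first session's published mean, because the study found no systematic bias
there. Subject effects in the fixture are centered so the simulated cohort
sits at the published scale; unconditional draws (`center_subjects =
FALSE`) are the default everywhere else. Trial-level noise magnitudes are
not identifiable from session-level CVs alone; the chosen values are one
realistic allocation, which is exactly what passing tests do and do not
certify.

What the generator does **not** emulate: force–time waveforms, fatigue
within a session, non-Gaussian biology (beyond an optional lognormal noise
switch used to exercise the normality gate), or inter-day drift richer than
fixed shifts. Results on real athletes can differ in all of those ways.

## Numerical and design choices

* Perfect agreement ($MS_E = MS_C = 0$) returns ICC 1 with a collapsed
  interval and a logged note; an all-constant matrix is an error.
* A zero residual with a session effect makes the bias F infinite; it is
  reported significant with $p = 0$ and flagged degenerate.
* Ties in Hv/Lv return the value, not an index; scores are order-invariant.
* The sensitivity-verdict boundary is a floating-point tie
  ($\sqrt{m^2}$ vs $m$), so tests bracket it at $\pm10^{-9}$ instead of
  probing the point.
* Report tables round as published (ICC to 3 decimals, percentages to 1,
  units at each variable's precision); full-precision sidecars are always
  written for machine consumption.
* Published-table cross-checks (`reference_relations()`) propagate half a
  unit of last printed place through each formula; 183 of 192 cells
  reproduce, and the nine that do not (all knee-extension SWC cells, plus
  one jump-height SEm% cell whose printed MD and MD% imply the recomputed
  value) are flagged inconsistent rather than patched.

The validation suite runs at deliberately chosen sizes: 200 random matrices
($n$ 3–10, $k$ 2–4) against two independent mean-square oracles,
$10^5$-draw parametric bootstrap interval cross-checks on 6×3 fixtures, and
500-replicate recovery and power studies at the study's own $n = 17$,
$k = 3$ — large enough for ±0.02 bias and coverage checks on the ICC and
for power > 0.8 on a half-SD late-session shift, small enough to run
routinely.

## Limitations

Session labels order lexically by default (override `session_order` for
anything else). The pipeline treats sessions as a repeated factor without
modeling the unequal calendar gaps (one week vs eight); a drift model over
real time is out of scope. ICC interval coverage is asymptotically nominal
under the Gaussian two-way model — heavy-tailed data pass through the
gates as warnings, not corrections. And the sensitivity verdict inherits
the conventionality of the 0.2 multiplier: a test that is "not sensitive"
at 0.2 may be perfectly usable for larger target effects.
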