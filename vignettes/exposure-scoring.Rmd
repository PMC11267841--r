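---
title: "Scoring actual exposure to a fluid-balance control strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring actual exposure to a fluid-balance control strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icufidelity)
library(dplyr)
```

## The problem

Stepped-wedge trials of complex ICU interventions are vulnerable to two
implementation failures that bias intention-to-treat estimates towards the
null: *contamination* (clinicians applying the intervention's behaviours
during the control period) and *suboptimal fidelity* (failing to apply them
during the intervention period). A process evaluation quantifies both with a
single per-patient index: a **score of actual exposure** to the strategy,
computed identically in both periods from routinely collected patient-day
data. This package implements that score for a daily-weighing fluid-balance
control strategy, together with the descriptive reach, dose/fidelity and
mechanisms-of-change summaries that surround it, and a synthetic cohort
generator so the whole pipeline is testable without access to trial data.

## The score

For each patient, each ICU day in a scoring window from Day 2 to Day 14
after admission (Day 1 = admission day) is classified:

* **Overloaded** — the measured weight strictly exceeds a day-indexed
  threshold: admission weight + 2 kg on Day 2, admission weight on
  Days 3–7, admission weight − 2 kg on Days 8–14. Days without a weigh-in
  have *unknown* status.
* **Contraindicated** — arterial hypotension, serum sodium > 155 mmol/L,
  serum potassium < 2.8 mmol/L, or renal dysfunction at or above the RIFLE
  "risk" level. All inequalities are strict, exactly as stated in the
  protocol; a value exactly at a cut-off does not trigger it.
* **Compliant response** — intake restricted by at least 30% relative to
  the previous day, diuretics prescribed, or ultrafiltration performed.

A **deviation** is an overloaded, non-contraindicated day with no compliant
response. With $d$ deviations over $n$ window days of the stay, $w$ of which
were weighed:

$$\text{raw} = 100\left(1 - \frac{d}{n}\right), \qquad
  \text{final} = \text{raw} \times \frac{w}{n}.$$

The final score runs from 0 (minimal exposure: nothing observable was done)
to 100 (maximal exposure: weighed daily, every actionable overload treated).
Mean scores per ICU and period quantify contamination (control period) and
fidelity/dose (intervention period).

```{r}
score_exposure(example_stay())[, c("n_deviations", "n_window_days",
                                   "weigh_proportion", "final_score")]
```

## Reading choices the protocol leaves open

The score's verbal definition leaves several constructions open; the
package fixes them as follows.

* **Denominator.** "Number of days spent in the ICU" is read as the days of
  the stay falling inside the Day 2–14 window, because deviations are only
  defined inside that window; a full-length-of-stay denominator would
  mechanically inflate scores for long stays. `scoring_rules(denominator =
  "full_los")` switches to the alternative reading.
* **Window length.** The Day 2–14 window is sometimes described as a
  "12-day" period although the inclusive span is 13 days; the package uses
  the inclusive 13-day window rather than silently shortening it.
* **Unweighed days** cannot yield deviations (overload is unobservable);
  the weigh-in proportion is the sole penalty for missing weights. A
  patient never weighed in the window scores 0 regardless of treatment.
* **Contraindication gating** is day-level and response-agnostic: a
  contraindicated overloaded day is never a deviation, even if nothing at
  all was done.
* **Boundary conventions.** Overload requires weight strictly above the
  threshold; a 30% restriction exactly at the boundary counts as compliant.
  Because 0.7 of a value is not exactly representable in binary floating
  point, the restriction comparison carries a 1e-9 mL absolute tolerance.
* **Missing previous-day intake** (Day 2 without a Day 1 record, or a gap)
  makes the restriction branch unevaluable — it contributes `FALSE` while
  diuretics/ultrafiltration still count. A previous intake of zero is
  likewise treated as non-evaluable rather than as an infinite restriction.
* **Albumin**, although part of the broader clinical strategy, is not in
  the compliant-response set, which lists only restriction, diuretics and
  ultrafiltration; restriction is assessed on volumes only, matching the
  collected intake variable.
* **Stays shorter than the window start** have an undefined score and are
  excluded from group means with a warning rather than imputed as 0.

## Expected weighing

Fidelity is also described by weekly weigh-ins per patient
($7 \times \text{weigh-ins}/\text{LOS}$) and by achieved-over-expected
weighing. "Expected" is period-dependent: the control period's standard of
care is weekly weighing, so one weigh-in is expected per started 7-day
block of the stay and every weigh-in of the stay counts as achieved —
control values far above 100% therefore measure weighing beyond the
standard of care (a contamination signal). The intervention period expects
one weigh-in per day of the stay inside the Day 2–14 window, with achieved
counted over those days. This is the only reading under which
control-period achieved/expected percentages of several hundred percent,
as observed in practice, are arithmetically possible.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the score consumes: 12 ICUs
(A–L) crossed with a control and an intervention period. Per (ICU, period)
the generator draws, for each patient:

* **Length of stay** from a negative binomial (mean 10 days, dispersion 4)
  truncated at 3 days, so every stay enters the scoring window — mirroring
  enrolment restricted to patients still in the ICU beyond 48 h.
* **Admission weight** from a normal (75, 12 kg) truncated at 35 kg.
* A **true weight trajectory**: fluid accumulates at 0.5 kg/day after
  admission and whenever overload goes untreated; a compliant response
  removes the same amount. Weigh-ins occur on Day 1 always and on later
  days with probability `p_weigh`, observed with 0.3 kg Gaussian noise.
* **Responses**: on days where overload is *observed* (weighed above
  threshold) and not contraindicated, a compliant response is drawn with
  probability `p_adhere`, its type from a 0.6/0.3/0.1
  restriction/diuretics/ultrafiltration mixture. A restriction response
  cuts intake 35% below the previous day, clearly inside the compliant
  region; other days revert to a 2500 mL baseline intake.
* **Contraindications**: labs or RIFLE drawn inside a contraindication
  range with daily probability 0.10, hypotension with daily probability
  0.20 (so most patients experience at least one episode over a 10-day
  stay, as is typical in this population).

Contamination and fidelity are both expressed through `p_weigh`/`p_adhere`
alone: control-period values span 0.30–0.72 and 0.25–0.65 across ICUs
(weekly weigh-in averages of roughly 2–5 and partial adherence — i.e.
contaminated standard of care), intervention-period values span 0.67–0.85
and 0.60–0.95 (high but suboptimal fidelity). These spreads were chosen
once to bracket the between-ICU heterogeneity reported for this kind of
multicentre trial and are not tuned thereafter. No distributional facts
about intake volumes or weighing noise are available for the real cohorts;
those defaults are nominal values a critical-care clinician would accept
as plausible, and they are documented as such.

Each stay runs on a private RNG substream derived by hashing
(master seed, ICU, period, patient index), so cohorts are byte-reproducible
and adding patients or groups never perturbs previously generated stays.

What the generator does *not* emulate: mortality and informative
discharge, correlation between severity and weighing difficulty, dose
titration of diuretics, renal-replacement fluid management, or secular
trends across stepped-wedge steps. Passing tests on simulated cohorts
therefore validate the *computational pipeline* — not the clinical realism
of any particular parameter value.

## Numerical and design notes

* Group summaries use arithmetic means and sample standard deviations
  (n − 1); single-patient groups report `NA` SDs rather than 0.
* Cohen's kappa is the unweighted (nominal) form, appropriate for thematic
  codes; when both coders are degenerate on the same single label
  (chance agreement 1, which forces observed agreement 1) kappa is defined
  as 1.
* The rendered report rounds to one decimal, matching how such tables are
  published; machine-readable CSVs keep full precision and round-trip
  losslessly.
* Every pipeline output embeds the seed and a configuration hash in a
  leading `#` comment line, and identical (configuration, seed) pairs
  yield byte-identical outputs.

### Validation strategy and problem sizes

The test suite validates the scorer against an independently coded naive
day-loop oracle on 100 randomised stays (exact agreement required), checks
monotonicity (repairing a deviation can only raise the score; dropping a
weigh-in can only lower the weighing proportion), and exercises boundary
cohorts (`p_adhere = p_weigh = 1` scores exactly 100 everywhere;
`p_weigh = 0` scores exactly 0). A degenerate generator mode
(`force_overload = TRUE`) pins every patient 1 kg above threshold on every
window day over a full 14-day stay with no measurement noise; with
weighing probability $p_w$, response probability $p_a$ and $n = 13$ window
days the mean final score has the exact expectation

$$E[\text{final}] = 100\,p_w\,\frac{n - (n-1)\,p_w(1-p_a) - (1-p_a)}{n},$$

which the simulation recovers to within Monte-Carlo error. Note that this
differs from the simpler product of expectations
$100\,(1-p_w(1-p_a))\,p_w$ by $100\,p_w(1-p_w)(1-p_a)/n$ (about one score
point at $p_w = p_a = 0.3$): the per-patient deviation rate and weighing
proportion are negatively correlated because deviations can only be
observed on weighed days, and the mean of the product is not the product
of the means.

Simulation-based checks use 1,000–2,000 patients per condition, and the
default pipeline configuration simulates 50 patients per (ICU, period)
against a planned enrolment of 60 — sizes comparable to the real
multicentre cohorts while keeping every check fast on a single CPU.

## Limitations

The exposure score is descriptive: it quantifies delivery, not effect, and
supports no per-protocol causal estimate (no CACE/IV machinery is
provided). Missing weights are penalised, not imputed. The generator's
parameter defaults are plausible rather than estimated — only the
qualitative contrasts it is designed to produce (intervention scores above
control everywhere, control weighing above the weekly expectation, larger
weight loss under the intervention) should be read as calibrated.
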