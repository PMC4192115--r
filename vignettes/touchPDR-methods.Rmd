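---
title: "Methods: task engine, scoring conventions and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task engine, scoring conventions and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchPDR)
```

This vignette is the package's own account of its science: the protocol it
implements, the behavioral model behind the synthetic cohorts, the scoring
conventions with their edge cases, and the numerical choices in the exact
statistics. It states no empirical result that the test suite does not
itself compute.

## The protocol

The package models the staged touchscreen protocol used for visual
discrimination testing of small animals, one session per day:

1. **STEP1** — habituation, one 20-minute free session.
2. **STEP2** — initial image training: two identical images for up to 30 s;
   a touch is rewarded immediately (75 µl), otherwise an automatic reward
   (25 µl) follows the timeout. Two completion routes exist because animals
   adopt two strategies: active screen interaction (30 trials within
   20 minutes, one session) or passive reward collection (30 trials within
   the 30-minute cap in 3 consecutive sessions, with screen interaction
   then learned in STEP3).
3. **STEP3** — one image versus a blank window at a scheduled side; blank
   touches are logged as errors but the trial only ends on the image touch.
   Criterion: 30 trials in under 30 minutes.
4. **STEP4** — as STEP3 plus trial initiation by a reward-tray entry.
5. **STEP5** — incorrect touches now end the trial, marked by a 500 ms
   2000 Hz tone and a 15 s inter-trial interval (ITI) instead of 10 s.
   Criterion: 30 trials within 30 minutes at ≥ 80 % accuracy on 2
   consecutive days.
6. **PD / PDR** — two-stimulus discrimination with the STEP5 contingencies;
   criterion ≥ 80 % correct in 2 consecutive sessions (30 trials maximum
   per session). The reversal swaps the rewarded stimulus.

**Side scheduling.** PD/PDR (and single-image training) sessions present
the rewarded stimulus 15× left and 15× right with no more than 3
consecutive same-side trials. `generate_side_sequence()` rejection-samples
uniformly random permutations of the side multiset until the run constraint
holds, which makes the distribution exactly uniform over the valid set (the
protocol literature says only "pseudo-random"; uniformity is the natural
canonical choice and is what the tests verify against a
dynamic-programming enumeration of the valid set). For the standard
session roughly one permutation in three is accepted, so rejection cost is
negligible.

**The simulated clock.** Sessions end at 30 trials or 30 minutes,
whichever comes first. Per trial the clock accumulates: tray-entry
initiation latency (STEP4 onward), response latency (or the 30 s timeout in
STEP2), reward-collection latency on rewarded trials, and the ITI. A trial
whose response would fall beyond the 30-minute cap is discarded and the
session is closed at the cap — sessions may therefore hold fewer than 30
trials, which the scoring must (and does) represent, since published
per-animal totals include non-multiples of 30. Replaying a session's event
log reproduces its duration exactly; this is asserted in the tests.

Two timing conventions are the package's own, since the protocol text
gives no timing model: the trailing ITI of the last trial is included in
the session duration, and the tray-entry initiation time is drawn from the
same log-normal model as the reward-collection latency (both are visits to
the reward tray).

## Scoring conventions

* **Stimulus-bias screen.** The first PD session is screened with an exact
  two-sided binomial test (minimum-likelihood summation, the
  `binom.test()` convention) of the positive-stimulus touch count against
  chance, α = 0.05 two-sided (the protocol literature reports "preference
  or aversion", i.e. both tails, without stating α). At n = 30 both the
  summation and the tail-doubling conventions give the same cutoffs, ≥ 21
  or ≤ 9 of 30, so the choice between them does not affect any screening
  decision at the standard session length. A perfect first session *is*
  flagged as a preference — the screen is purely binomial, and the flag
  records the direction.
* **Criterion counts include the criterion sessions.** "Sessions to
  criterion" is the index of the second qualifying session; trials and
  errors are summed over sessions 1..that index. Incomplete sessions count
  as sessions and contribute their trials. For the 80 % criterion an
  incomplete session may itself qualify (the protocol caps, but does not
  require, 30 trials); for the 50 % reversal criterion the two qualifying
  sessions must be complete, which is explicit in the definition of that
  measure.
* **Perseveration phase.** Following the binomial-criterion definition,
  every reversal session whose error count (touches of the formerly
  rewarded stimulus) shows a significant binomial bias toward it belongs
  to the perseveration phase, and the perseverative error count is the
  error total over those sessions. The package reads "all sessions"
  literally (flagged sessions need not be contiguous); a
  `persev_mode = "contiguous"` switch restricts to the initial flagged run
  for strict fidelity to the original formulation of the measure.
* **Latencies** are pooled trial-level means per phase (response latency
  over all trials; reward latency over rewarded trials only), not means of
  session means; a `latency_mode` switch provides the other convention.
* **Medians** are the standard order-statistic convention (mean of the two
  middle values for even n). Note that a few medians printed in the study
  this package mirrors differ slightly from the standard convention
  applied to its own per-animal table (e.g. reversal-trials medians 390 /
  617 versus computed 385.5 / 608.5); the package implements the standard
  convention and does not chase those printed values.

## Exact statistics

Group comparisons use the Mann–Whitney U with the pair-count definition
(ties contribute ½), `U = min(U1, U2)`. The exact p-value is computed with
ties taken into account: midranks are doubled to integer scores, and the
null distribution of the group-A score sum over all `choose(n, n_a)` group
assignments is built by a rank-score shift dynamic program (a
generating-function convolution over items, bounded by the score total).
The two-sided p doubles the smaller one-sided tail, capped at 1 — the
convention of common exact-test software. Exact enumeration is used up to
`n_a * n_b <= 400`, which covers the 20-vs-10 and 15-vs-9 designs of the
packaged study at well under a millisecond each; larger designs fall back
to the normal approximation with tie correction and continuity correction,
and the `method` field records the route. Assignment counts in the dynamic
program stay far below 2^53, so double-precision integer arithmetic is
exact.

The tests verify the exact p against full enumeration of every group
assignment on all partitions with `n_a + n_b <= 10`, and the large-sample
route against the classical tie-corrected approximation. Spearman's
correlation is the Pearson correlation of midranks with the two-sided t
approximation on n − 2 degrees of freedom (exact permutation is not
implemented; at the n = 24 design the approximation is adequate and the
coefficient itself is exact).

No multiple-testing correction is applied in the replication report,
matching the analysis it mirrors; the report says so in its `note` field.
Sex contrasts within the small aged group are computed but labelled
underpowered rather than suppressed.

## The behavioral model

The cohort simulator is *not* a cognitive model of any species; it is the
minimal mechanism that produces the phenomena the analysis pipeline must
handle: learning curves that cross the 80 % criterion, spontaneous image
bias in some subjects, below-chance accuracy immediately after reversal
followed by recovery, age differences in learning speed and perseverance,
and right-skewed latencies.

Each subject is a two-learning-rate delta-rule learner over stimulus
values with lapse-mixed logistic choice (parameters: `alpha_pos`,
`alpha_neg`, `beta`, `side_bias`, `stim_bias`, `lapse`, log-normal latency
parameters). Values carry over from PD into the reversal (no reset), which
is the mechanism behind the below-chance first reversal session: a subject
that just satisfied the 80 % criterion holds a value gap of roughly
`logit(0.85)/beta` and therefore starts the reversal near 10–15 % correct.
Because the value gap keeps growing during the two criterion sessions, the
simulated first-reversal accuracy tends to sit somewhat below typically
observed values (~20 %); the package only relies on the qualitative
property (below chance for converged subjects), which the acceptance tests
measure. The training-step discrimination (image versus blank) is
perceptually trivial, so it uses a separate, faster learning rate
`alpha_train` shared by both age groups — consistent with the observation
that training duration shows no systematic age effect while the
discrimination tasks do. Setting `alpha_neg = 0` disables error-driven
unlearning and yields unbounded perseveration; the tests use this for a
sensitivity check.

**Default population distributions** (chosen once, as the package's
standing study conditions): young `alpha ~ N(0.004, 0.0015)`, aged
`alpha ~ N(0.002, 0.0008)` (clamped away from 0), `beta ~ N(6, 1.5)` /
`N(5.5, 1.5)`, `lapse ~ N(0.04, 0.02)`, `side_bias ~ N(0, 0.25)`, response
latencies log-normal around 4 s (young) / 5.5 s (aged), reward latencies
around 1.5 s / 1.9 s, a 20 % chance of an initial image bias of size 0.4,
and a 100-session cap per phase (comfortably above the slowest published
animal at 60 reversal sessions). The learning-rate scale was set so that
simulated trials-to-criterion and perseveration counts land on the same
order as the published per-animal table (young PD criterion around
150–200 trials, reversal perseveration errors in the low hundreds); the
halved aged rates then produce the aged impairment in both tasks and both
perseveration measures. With these defaults a full 20/10 cohort simulates
in a few seconds and no subject is truncated.

**What the simulator does not emulate.** Within-session fatigue or
satiation, session-to-session motivation drift, forgetting between days,
stimulus-specific salience differences, and the heavy upper tail of real
training durations (real animals took 6–71 training days; simulated
training compresses to near the protocol minimum because engagement, not
discrimination, is the real bottleneck and is only coarsely modelled).
Passing tests on simulated cohorts therefore demonstrate correctness of
the pipeline's scoring and statistics under the modelled mechanisms, not
behavioral realism of any particular subject.

## Numerical and design notes

* Every stochastic operation takes an explicit seed; a cohort's master
  seed derives all per-subject seeds, and the manifest records them, so
  any subject can be re-simulated in isolation.
* Session indices are 1-based everywhere, matching the "2 consecutive
  sessions" phrasing of the criteria.
* The trial-log CSV dialect is pinned: comma separator, `.` decimal,
  UTF-8, `NA` for missing; reading validates the schema, rejects negative
  latencies with line numbers and refuses duplicate
  (subject, phase, session, trial) keys.
* The fixture table is transcribed at the printed precision and is
  integrity-checked on every load (row, group, sex and bias-flag counts,
  internal count invariants); it is never modified in memory — exclusions
  happen at analysis time with provenance in the report.
* Degenerate inputs: all-tied samples give `U = n_a n_b / 2`, p = 1; a
  constant sample in the Spearman correlation yields `NA` with the t step
  skipped; empty inputs are errors, truncated phases yield `NA` summary
  fields with explicit reached-flags instead.

## Problem sizes used in the tests

Scheduler uniformity is tested with 10^5 draws against the fully
enumerated valid set of the 10-trial, 5/5, max-run-3 instance; Mann-Whitney
exactness against full enumeration over all partitions with
`n_a + n_b <= 10`; the simulator's distributional guarantees over 100
independent 20/10 cohorts (direction of the age effect, one-sided power at
the published design, and the below-chance first reversal) plus 20 paired
runs for the `alpha_neg` sensitivity check. These sizes keep the complete
suite within a few minutes on one CPU while leaving the Monte-Carlo
assertions statistically stable.
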