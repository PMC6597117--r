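---
title: "Memory-trace models for the Object Space Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-trace models for the Object Space Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(objspace)
```

## The task

The Object Space Task probes whether rodents form memories of *spatial
statistics* accumulated over many events, rather than of single episodes.
An animal explores two objects at two of four corner locations; objects
change every trial, so only the configuration of locations carries
information. Three conditions differ in what can be learned:

* **stable** — both locations fixed during sample trials; one object is
  displaced at the delayed test. Recency memory of the last trial is
  sufficient.
* **overlapping** — one location fixed, the other moved every trial, and
  the *last sample trial equals the test configuration*. Recency memory
  predicts indifference at test; only cumulative memory of "one corner is
  always occupied" predicts a preference for the less-often-shown side.
* **random** — balanced pseudo-random pairs; nothing to extract.

Protocols: rats run 5 sample trials in one day with a test 24 h later;
mice run 5 (or 3) sample trials per day for 4 days plus a day-5 test, and
an extended 4-week overlapping variant embeds 3-day and 5-day delayed
tests (trials 26 and 76 repeat the preceding configuration).

## Schedules and counterbalancing

`generate_session()` builds one session; `generate_cohort()` rotates
stable-role locations, moving locations and condition orders across
animals, and guarantees that within an animal the stable-role corner
differs between its stable and overlapping sessions (avoiding trained
place preferences). Slots are *roles*, not fixed corners: slot 1 is the
stable role, slot 2 the novel role (displaced at the stable test, moving
in overlapping). In the random condition no reference exists in the
design, so slot 1 is a fixed pseudo-stable reference chosen by the
counterbalance parity of the session; across a counterbalanced cohort the
expected DI is 0 by symmetry.

The pseudo-random schedule is constrained rather than i.i.d.: per
training day every corner is used equally often over the object slots
(max − min ≤ 1 over the 10 slots of a 5-trial day), every corner appears
within the first 3 trials, the last 2 trials of a 5-trial day jointly use
each corner exactly once, and no two consecutive trials repeat a
configuration ("runs" would let recency mimic accumulation). With 3
trials per day the last-2-trials rule is ill-posed (6 slots cannot hold 4
corners exactly once twice over), so the coverage rule is applied to the
whole day instead. Constraints are enforced by rejection sampling with a
10,000-attempt cap — the constraint set is tiny, so a CSP solver would be
overkill; infeasible requests fail with the violated rule named.
`validate_schedule()` re-checks every invariant and is tested as a
round-trip property over conditions, protocols and seeds.

## The model family

For each object slot $o$ and location $l$ the model keeps a memory trace
$m_t(o, l)$, a leaky count of observations, updated each trial with
learning rate $\alpha \in [0, 1]$:

$$m_{t+1}(o, l) = (1 - \alpha)\, m_t(o, l) + \alpha\, \delta_{o,l}.$$

Per object the trace is normalized to a distribution over the four
corners and its Shannon entropy $S_t(o)$ (nats; at most $\ln 4$) measures
the model's uncertainty about that object's usual place. Exploration is
allocated by a Boltzmann softmax over the two entropies with gain
$\beta$:

$$P(o_k) = \frac{e^{\beta S(o_k)}}{e^{\beta S(o_1)} + e^{\beta S(o_2)}},$$

so $\beta > 0$ seeks the uncertain object (neophilia) and $\beta < 0$
avoids it. With two objects this reduces to a logistic in
$\beta\,(S_1 - S_2)$, computed in that form so extreme $\beta$ reaches
the 0/1 limits without overflow.

Variants add overnight dynamics between training days:
$m \leftarrow m + (1 - \gamma)(m_0 - m)$, one step per elapsed night
(weekends and pre-test delays count their calendar nights). M1 has
$(\alpha, \beta)$ and $m_0 = 0$; M2 adds $\gamma$; M3 frees $m_0$ as
well; M4 frees $m_0$ without forgetting.

### Numerical conventions

* **Update-then-predict.** The allocation for trial $t$ is computed from
  the trace *after* it is updated with trial $t$'s observation. This is
  what lets a displacement raise the displaced object's entropy in the
  very trial where it is first seen — the mechanism behind the positive
  stable-condition test DI and its peak near $\alpha = 0.5$ (the updated
  row is then an even mix of old and new location, maximizing entropy).
  Predicting from the pre-trial trace would make the stable test DI
  identically zero at every $\alpha$, contradicting the behavior the
  model exists to explain.
* **All-zero trace rows** normalize to the uniform distribution
  ($S = \ln 4$), so the first trial of a session is always allocated
  0.5/0.5 and the convention is continuous with $m_0 \to 0$.
* **Logarithms** are natural throughout; any base change is absorbed by a
  rescaling of $\beta$, so fits are invariant.
* **Entropy** uses $0 \ln 0 = 0$ and the identity
  $-\sum p \ln p = \ln(\mathrm{tot}) - \sum m \ln m / \mathrm{tot}$ in
  the inner loop.
* **Probability clamping** to $[10^{-12}, 1 - 10^{-12}]$ before any log
  in the likelihood.

## Fitting

The data enter as per-trial proportions $q_t$ of time on the slot-1
object. The chance comparison presupposes a likelihood under which the
50/50 model scores $N \ln 0.5$ regardless of the data; the minimal such
choice is the proportion-weighted Bernoulli cross-entropy

$$LL = \sum_t q_t \ln p_t + (1 - q_t) \ln(1 - p_t),$$

which `fit_ost()` maximizes by Nelder–Mead from many random starts
($\alpha, \gamma$ uniform on their range via a logit transform, $\beta$
heavy-tailed Cauchy×5 since its range is unbounded, $m_0$ log-uniform —
the log scale because fitted attractors can far exceed 1). A
deterministic start at the chance model ($\alpha = 0.5, \beta = 0$)
guarantees $LL_{opt} \ge N \ln 0.5$, hence pseudo-R²
$= 1 - LL_{opt}/LL_0 \ge 0$. Trials with zero exploration are skipped and
counted. A time-weighted likelihood variant (each trial's term multiplied
by its total seconds) is available behind `weight_by_time`.

Session fits feed a likelihood-ratio test against chance (χ² with the
model's free-parameter count as df — the df convention is ours, as none
is standard for this comparison) and model comparison by per-session
$AIC = 2k - 2LL$ and $BIC = k \ln n - 2LL$ summed over sessions
(k = 2, 3, 4, 3 for M1–M4). Sessions with $|\beta| \ge 1000$ are flagged
as outliers and excluded from parameter summaries but retained in the
criterion sums. Fits are per session (one animal × one condition).

Whether the original analysis updated traces with the test trial before
its prediction, and whether overnight forgetting spans the pre-test
delay, are not documented; both are enabled here (the delay handling can
be disabled with `forget_test_delay = FALSE`).

## Behavioral statistics

`discrimination_index()` implements
$DI = (t_{novel} - t_{stable})/(t_{novel} + t_{stable})$; with role-based
slots the novel reference is always slot 2 (the to-be-moved slot during
stable samples, so no preference is expected there before the test).
Test trials carry both a first-5-minute score (the default analysis
window) and a full-10-minute score. Animals whose session-mean total
exploration falls below 5 s are excluded and listed. One-sample t tests
against chance use `stats::t.test` (a constant-zero sample is reported as
t = 0, p = 1 rather than an error). `rm_anova()` runs the univariate
repeated-measures ANOVA through `stats::aov` Error strata — uncorrected
integer dfs, matching the 2-day and 5-day analyses — with a
Greenhouse–Geisser option through `car::Anova` for the 4-week week
factor. Incomplete designs are rejected with the missing cells named;
missing trials are never imputed. Tests are two-sided without
multiple-testing correction.

## Simulation and the synthetic generator

`simulate_session()` turns allocations into behavior; with zero noise it
is a pure function of schedule and parameters, which keeps the
mechanism-level reproductions deterministic: at the reference parameters
$\alpha = 0.6, \beta = 0.2$ the overlapping condition shows a positive,
building DI that survives the test trial, the random condition averages
to zero over counterbalanced sessions, $\alpha \ge 0.9$ abolishes the
overlapping test DI, and the stable test DI peaks near $\alpha = 0.5$
(`sweep_parameters()`).

`generate_dataset()` adds what real cohorts have and simulations lack:
per-animal parameter heterogeneity ($\alpha$ logit-normal so draws stay
in (0, 1), default median 0.6; $\beta$ Gaussian, default N(5, 2²) — a
clearly neophilic population that makes recovery measurable), additive
truncated-Gaussian proportion noise (default sd 0.05), lognormal total
exploration times around a habituation profile (base 35 s with mild
within-day decline, chosen as typical of 5-minute object-exploration
trials), and optional planted low explorers that trigger the 5-s
exclusion rule. Every session's noise flows from a recorded substream
seed, so the truth table alone regenerates the behavior byte-for-byte.

The generator emulates the *statistical structure* the analysis assumes —
proportions driven by a latent (α, β) agent over real schedules,
heterogeneity, habituation trends, exclusions. It does not emulate
spatial embodiment (trajectories, dwell maps, thigmotaxis), object
identity effects, or within-trial dynamics; passing tests therefore
validate the pipeline's correctness and calibration, not any claim about
animals.

## Problem sizes and design choices in the checks

The test suite runs at desk scale, chosen so each check is informative
but quick: grid-versus-optimizer equivalence on 6-trial sessions with a
200 × 200 (α, β) grid; parameter recovery on a 30-animal, 21-trial
overlapping cohort with 200 optimizer starts (recovery is measured in the
overlapping condition because α is structurally identifiable only where
recent and remote trials carry different information — in stable the
likelihood is nearly flat in α, as the task analysis itself notes);
model recovery over 20 replicate 4-animal cohorts; null calibration over
100 replicate cohorts (ANOVA) and 100 null sessions (likelihood-ratio
test). `scripts/acceptance.R` re-runs the same computations from a
command-line seed.

## Known limitations

* The likelihood's functional form for continuous proportions is a
  modelling choice; alternatives (e.g. a Beta observation model) would
  change absolute LL values, though not the chance-model anchor.
* AIC/BIC totals are summed per-session criteria; published table-level
  magnitudes depend on aggregation details that are not reconstructible
  from the stated formulas, so only the *ranking* of models is treated as
  meaningful.
* The supplementary-spreadsheet adapter expects CSV exports with a
  user-supplied column map; it does not parse workbook files.
* Only the 2-object × 4-location geometry is exercised, and the 4-week
  protocol is defined for the overlapping condition alone, mirroring the
  experimental designs.
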