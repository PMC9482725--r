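---
title: "Two-phase recalibration of colorectal neoplasia microsimulations"
author: "neocalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase recalibration of colorectal neoplasia microsimulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocalib)
```

## The problem

Individual-based state-transition models of colorectal cancer (CRC)
natural history simulate, person by person, the occurrence of
precancerous polyps (here all called *adenomas*) and their progression
along the adenoma-carcinoma sequence: non-advanced adenoma
(state `NON`), advanced adenoma (`ADV`), and cancerous neoplasia
(`CRC`), without reversal.  When new observational evidence arrives —
for instance sex-specific prevalence from a large screening-colonoscopy
registry — the model's free parameters must be *re*-estimated so that
its simulated prevalences match the new benchmarks.  Two features make
this hard: the parameter vectors are moderately high-dimensional (19
and 8 parameters for the two engines bundled here), and each objective
evaluation is a stochastic simulation, so the loss surface is both
expensive and noisy.

`neocalib` implements a two-phase answer.  Phase 1 performs cheap global
sampling around a *baseline design* (the prior point estimates) to find
a promising start; phase 2 spends the remaining evaluation budget on a
derivative-free Nelder-Mead simplex search, either over the full
parameter space or *sequentially* over ordered parameter blocks that
follow the adenoma-carcinoma sequence.

## The two engines

Both engines simulate a single-birth-year cohort (default: 1000
same-sex individuals born 1949, followed to age 79) with death ages
drawn from a life table, and both assume adenomas occur and grow
independently of one another.

**Cycle engine (19 parameters).**  A discrete-time Markov
microsimulation in 3-month cycles.  Its parameters form three blocks
along the disease sequence: *initiation* (base per-cycle occurrence
probability, five age-band multipliers for ages 20–39, 40–49, 50–59,
60–69 and 70+, and the log-sd of a lognormal per-person risk
multiplier), *early* (per-cycle advance probabilities through early
adenoma stages I–IV plus two multiplicative modifiers), and *advanced*
(two advanced-stage advance probabilities, the per-cycle cancer
transition probability, and one modifier each).  Stage dwells are
geometric, so the engine simulates each adenoma's first-entry times
directly and can expand them back to per-cycle state codes
(`cycle_state_matrix()`).  The three modifiers deliberately overlap
with the probabilities they scale: near-redundant parameters are a
realistic feature of large natural-history models and a stress test
for the calibration.

**Event engine (8 parameters).**  A discrete-event simulation in
continuous time.  Each individual draws a lifetime risk multiplier
$r \in (0,1)$ from a Johnson SB distribution with shape pair
$(\gamma_0, \delta_0)$; adenomas then occur as a nonhomogeneous Poisson
process with hazard $r\,h(a)$, where $h(a)$ is a fixed engine constant
(zero before age 20, rising linearly to 0.05/person-year at age 60,
flat thereafter).  Each adenoma is classed progressive non-advanced
(`P_NON`, 30%), non-progressive non-advanced (`NP_NON`, 69%) or
immediately cancerous (1%).  Dwell times to the next state are Johnson
SB: $(\gamma_1, \delta_1)$ on $(0, 30)$ years for `P_NON` to `ADV`,
$(\gamma_2, \delta_2)$ on $(0, 60)$ years for `NP_NON` (so most
non-progressive adenomas never advance within a lifetime), and
$(\gamma_3, \delta_3)$ on $(0, 25)$ years for `ADV` to `CRC`.  The
Johnson SB variate is
$X = \xi + \lambda / (1 + e^{-(Z-\gamma)/\delta})$ with $Z$ standard
normal — bounded support with flexible shape, which is why it is the
conventional dwell-time family in event-driven CRC models.  Only the
four $(\delta_i, \gamma_i)$ pairs are calibrated; $\xi$, $\lambda$, the
hazard profile and the class probabilities are fixed constants.

**Baselines.**  The packaged `baseline_design()` vectors were chosen
once so that the simulated prevalences are of the same order as
published screening-colonoscopy benchmarks for ages 55–79 (advanced
adenoma roughly 4–10%, cancerous neoplasia roughly 0.3–2.5%, males
above females).  Both engines overshoot `ADV`/`CRC` somewhat at the
oldest ages — neither has enough age structure in late progression to
flatten the curve, a limitation shared by the model class.  They are
study conditions, not estimates of any real population.

**Mortality.**  The packaged life table is *synthetic*: a
Gompertz–Makeham hazard with a 0.5%-per-calendar-year improvement
factor, covering birth year 1949 to age 100 (`synthetic_life_table()`).
Any life table with columns `year,age,qx` can be substituted.

## From trace to loss

Each simulation emits a trace of time-stamped events per individual.
`compute_prevalence()` evaluates every individual's cumulative state
("has had") at the midpoint of each 5-year age group (57.5, 62.5, 67.5,
72.5, 77.5) among those alive at that age, with precedence
`CRC > ADV > NON > HEALTHY`.  Midpoint evaluation is a deliberate
choice: for a single-birth-year cohort the five groups are snapshots of
the same cohort at five ages, and the midpoint is deterministic and
age-consistent.  Aggregates over groups are alive-count-weighted means
(configurable to simple means); target tables read from CSV carry no
alive counts, so their packaged aggregates are simple means.

The calibration loss is the weighted sum of squared relative errors on
the three aggregate prevalences,
$L = \sum_s w_s ((p_s - t_s)/t_s)^2$, with default weights
$(w_{NON}, w_{ADV}, w_{CRC}) = (1, 1, 4)$.  The cancer weight must
dominate (a mis-fit of the rare but consequential state should cost
most); 4 realises that without drowning the other two states, and all
weights are configurable.  The packaged registry-derived target fixture
(`inst/extdata/brenner_targets.csv`) carries `ADV` and `CRC` only, so
losses against it run in two-state mode; synthetic targets carry all
three states.

One call to `evaluate_design()` — however many simulation replications
`R` it averages — counts as **one** function evaluation in every budget.
Replication streams depend only on the seed and the replication index
(*common random numbers*), never on the design, so the objective seen
by the optimiser is deterministic for a fixed seed and comparisons
between designs are low-noise.

## Phase 1: global sampling

*Cycle engine.*  Each parameter's range is its baseline ±20%.
`lhs_sample()` draws 100 Latin-hypercube designs (every parameter's 100
equal strata hit exactly once) and `screen_first_passing()` evaluates
them **in sampling order**, returning the first design whose three
aggregate relative errors are all within 10%.  If none passes, the
minimum-loss design is returned with a `fallback` flag.

*Event engine.*  `progressive_search()` follows the adenoma-carcinoma
sequence over the four shape pairs.  Ranges are ±40% for each
$\delta_i$ but ±20% for each $\gamma_i$, because the prevalence
responses are far more sensitive to $\delta$ than to the paired
$\gamma$.  Stage 1 evaluates a centred 5×5 grid on
$(\delta_0, \gamma_0)$ (the risk distribution must be right first),
accepting designs with every per-age-group relative error within 15%.
Stages 2–4 draw 10-point orthogonally stratified samples (ten even
intervals per dimension, each covered exactly once) on
$(\delta_1, \gamma_1)$, then $(\delta_2, \gamma_2)$ — progressive
non-advanced adenomas contribute far more `ADV` transitions, so their
pair is perturbed first — then $(\delta_3, \gamma_3)$, with aggregate
criteria of 10% on `NON` and `ADV` and finally 5% on `CRC`.  Each stage
freezes the previously selected values and carries the minimum-loss
acceptable design forward; the already-evaluated incumbent competes in
every stage's selection (at no extra evaluation cost), so the incumbent
loss never increases between stages.  Where several candidates pass,
only the best is carried (carrying all would multiply the cost of every
later stage).  The default plan costs 25 + 10 + 10 + 10 = 55
evaluations.  Interactive, expert-guided discarding of candidates is
replaced throughout by the explicit criterion-plus-argmin rule.

## Phase 2: budgeted Nelder-Mead

`nelder_mead()` is an in-package simplex search with the long-standing
`fminsearch` conventions: reflection 1, expansion 2, contraction 0.5,
shrink 0.5, x- and f-tolerances $10^{-4}$, and an initial simplex built
by perturbing each start coordinate by 5% (0.00025 where a coordinate
is zero).  It adds exact budget accounting — every objective call is
counted, the search stops the instant the budget is exhausted, and the
returned solution is the best vertex *ever evaluated*, which matters
when a budget interrupts an iteration.  Non-finite objective values are
treated as $+\infty$ (vertex rejected); ties between equal-loss
vertices break to the lowest index.  The search runs in unconstrained
coordinates: log for positive parameters (the $\delta_i$, rates,
multipliers) and logit for per-cycle probabilities, so no proposed
design is ever invalid and no penalty terms are needed.

`full_space_strategy()` runs one simplex over all parameters.
`sequential_strategy()` runs one simplex per parameter block in the
sensitivity order (event: risk, `P_NON`, `NP_NON`, advanced; cycle:
initiation, early, advanced), freezing the other coordinates at the
incumbent; the budget is split equally across blocks with the remainder
going to the first (most sensitive) block.  On separable objectives the
two strategies agree; under tight budgets the sequential variant makes
progress in each low-dimensional subspace instead of slowly deforming a
20-vertex simplex.

`calibrate()` chains the phases: phase-1 evaluations count against the
same effort, and a run whose phase 1 consumed the entire effort is
flagged `excluded` (the benchmark summary omits such runs, mirroring
the usual reporting convention for this comparison).  The reported
solution of a run is the best design ever evaluated, so the reported
loss equals the minimum of the trajectory.

## The benchmark and the synthetic-target generator

`generate_synthetic_targets()` simulates a *known* design and emits its
averaged prevalences as targets, enabling closed-loop self-tests: with
common random numbers the truth scores exactly zero, and the loss of
the truth against targets from an *independent* stream measures the
Monte-Carlo floor — the resolution limit below which losses are noise.

`run_comparison()` stages the strategy comparison: per run, targets are
generated from a ground-truth design, each strategy calibrates from the
baseline under each effort, and final losses are summarised as
mean (sd) over included runs.  The default ground truth is the baseline
displaced by 5% per parameter (for the event engine $\delta_i$ scaled
down and $\gamma_i$ up — scaling both the same way would leave the
Johnson SB medians, which depend on $\gamma/\delta$, nearly unchanged).
Five percent is a deliberate study condition: it emulates a moderate
"new population" update, far enough that the baseline mis-fits, close
enough that the ±20% search space genuinely contains the truth — with a
much larger displacement phase-1 screening can never meet its 10%
criterion and every two-phase run is excluded.  By default the
benchmark evaluates with streams *independent* of the target streams
(`crn = FALSE`, realism: one cannot share noise with nature), searches
with `R = 1` replication per evaluation and re-scores each run's best
design with `R = 10` for reporting.

Problem sizes used by the packaged self-tests — cohorts of 500–1000,
efforts of 100–200, 10 runs per cell — were chosen as the smallest
sizes at which the phase-1 criteria and the strategy ordering are
informative rather than noise-dominated.

## What the synthetic tests do and do not show

The synthetic-target loop shows that the procedure *recovers what the
engines can represent*: screening finds 10%-fits, the progressive plan
meets its staged criteria, sequential search beats a straightforward
simplex under tight budgets, and recovered designs score within a small
multiple of the Monte-Carlo floor.  It cannot show that either engine
is an adequate model of real colorectal neoplasia: the engines are
desk-scale stand-ins, the life table is synthetic, and real targets
(the packaged registry fixture) expose structural mis-fit — notably the
late-age overshoot — that no parameter setting removes.  Screening,
polypectomy, surveillance, stage at diagnosis and costs are out of
scope throughout.

## Numerical choices and degenerate inputs

* Relative errors are undefined for zero targets: target loading
  rejects nonpositive cells, and synthetic generation flags a state
  with zero aggregate prevalence as unusable (with a warning) rather
  than dividing by zero; per-age-group cells with zero targets are
  dropped from the per-group criteria.
* An age group with nobody alive at its midpoint is a degenerate-cohort
  error, not a silent `NaN`.
* Every stochastic function takes an explicit seed, restores the
  caller's RNG state, and derives per-individual substreams by an
  integer hash of (seed, replication, individual id) — so traces are
  bit-reproducible and enlarging a cohort never perturbs earlier
  individuals.  Death ages and discrete counts are drawn by inversion
  (`qpois`/`qbinom` on a uniform), which makes occurrence pathwise
  monotone in the hazard under common random numbers.
* All intervals are closed on the left and open on the right; ages are
  continuous years in the event engine and 3-month cycle indices
  (converted to years at first entry) in the cycle engine.

## Known limitations

The sequential strategy inherits Nelder-Mead's local character: it can
stall in a subspace if the block ordering misrepresents the true
sensitivities.  The loss weights are a modelling choice with no
data-driven defence — multi-objective formulations are a natural next
step but out of scope.  The cycle engine's modifier parameters are
intentionally near-redundant, so recovered *parameters* need not match
the truth even when recovered *responses* do; all recovery claims here
are about loss, not about parameter identification.
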