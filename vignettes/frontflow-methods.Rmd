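---
title: "Modeling the hospital front end: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the hospital front end: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontflow)
```

## The system being modeled

Every outpatient of a large public hospital passes through the front-end
department — the queue-ticket machine, the triage station and the
medical-record department (MRD) — before reaching an outpatient clinic. The
ticket machine opens at 05:00 and closes at 14:50; counters keep serving
until the last ticketed patient has left. Patients fall into four types:

1. walk-ins without an appointment,
2. university staff and students,
3. non-registered privilege holders or patients changing their profile,
4. patients with a government privilege (e.g. universal health coverage).

Types 1–2 have their blood pressure checked, are triaged by a nurse
(type-specific nurse pools), fill an information form if they are new
patients, and then contact a medical-record counter. Types 3–4 go straight
from the ticket machine to the counter. The performance measure is the
length of stay (LOS): ticket issuance to leaving the department.

`frontflow` rebuilds this system as a terminating discrete-event simulation,
scores each simulated patient's LOS as a satisfaction percentage, optimizes
integer staffing schedules under a fuzzy bi-objective (operating cost versus
mean satisfaction), and provides the statistical machinery to compare
routing scenarios and turn the comparison into a staffing recommendation.

## Stochastic inputs

All defaults are the elicited/fitted values of the motivating case study.

**Arrivals.** Interarrival times are piecewise (shifted) exponential:
`EXPO(10)` minutes from 05:00–06:00, `0.5 + EXPO(1.24)` from 06:00–10:30,
and `EXPO(2.67)` from 10:30–15:00. The segment in force is the one
containing the previous arrival instant; a draw that crosses a boundary is
kept as drawn. Piecewise-exact thinning would change arrival counts by well
under the sampling noise of a day and is deliberately not used.

**Type mix.** The type shares change over five two-hour windows (e.g. the
type-4 share grows from 46% before 07:00 to 54% after 09:00). The window is
looked up by ticket time, independent of the arrival segmentation — the two
tables use different period grids by construction.

**Service times** (seconds): blood pressure constant 49; triage
`25 + EXPO(71.2)`; information form constant 300; counters for types 1–2
`14 + WEIB(47.4, 0.94)` (scale, shape), type 3 `TRIA(84, 146.8, 251)`,
type 4 `TRIA(59, 72.8, 197)`. Triangular draws use the inverse CDF so a
single uniform stream reproduces them exactly. Blood pressure and the form
are modeled as self-service delays (no staffed server): the staffing
schedules of the case study list only triage nurses and counter operators.

**New-patient share.** The share of new patients is not published. The
default is 0, which matches the verification anchor (the published no-queue
LOS sums exclude the 300-second form step); it is configurable (`p_new`).

## The simulation kernel

The kernel is a classic event-calendar design: events are ordered by
`(time, insertion sequence)`, so simultaneous events fire in insertion order
and a replication is a deterministic function of its seed. Resource pools
hold integer servers with FIFO waiting queues. Staffing levels change at the
period boundaries (07, 09, 11, 13 o'clock); changes are non-preemptive — a
capacity drop never interrupts a service, the excess busy servers drain as
services finish, and no new service starts until the busy count falls below
the new capacity. When a schedule has no explicit 05:00–07:00 column, the
07–09 staffing applies from opening.

Each stochastic source (arrivals, type assignment, new-patient flags, each
station's service law) draws from its own named substream derived from the
replication seed. Two schedules evaluated under the same seed therefore see
identical arrival patterns and service demands — common random numbers,
which makes paired schedule comparisons much sharper.

A replication terminates when the calendar empties: every ticketed patient
has left, so entering and leaving counts match by construction, and the
reported day length is at least the 600-minute working day. No warm-up is
discarded — the department genuinely starts the day empty, and the whole
day is the object of study. A hard cap (default 2000 simulated minutes)
converts a non-emptying system (e.g. a required station scheduled with zero
capacity) into a diagnostic error instead of an infinite loop.

## Routing scenarios at the medical-record department

* **Dedicated** (the current situation): a patient may only use the counter
  bank of their own type.
* **One-stop**: all counters form one pooled bank serving every type.
* **Partially shared**: the own-type bank has priority; if all its servers
  are busy, the patient overflows to the *other* counter type that has an
  idle server and the lowest utilization, where utilization is cumulative
  busy server-time (including the elapsed part of services in progress)
  divided by scheduled server-time, evaluated at the routing instant; ties
  break toward the lowest type index. If no allowed counter is idle the
  patient queues at the own-type bank and stays there (no jockeying —
  routing happens once, at entry).

Counter kind `M12` (a counter usable by types 1 and 2) appears in published
staffing schedules and is accepted in cost and feasibility arithmetic, but
the day simulator works with per-type banks (`M1`–`M4`) or the pooled bank
(`M`); a run configured with staffed `M12` counters is rejected with a
named validation error rather than silently reinterpreted.

## From length of stay to satisfaction

Experts (the department chief and four senior nurses) specified, per type,
optimistic / most-likely / pessimistic values of LOS and of the matching
satisfaction score; each triple is read as a triangular distribution, e.g.
type 2: LOS (15, 30, 60) minutes against scores (100, 75, 50) percent. A
patient's LOS is standardized by the LOS triangle's mean and SD and mapped
with the score triangle's mean and SD, in the negative direction:

$$P_j = \mathrm{clamp}\!\left(\mu_s - \sigma_s\,
  \frac{\mathrm{LOS}_j - \mu_L}{\sigma_L},\; 0,\; 100\right)$$

The clamp enforces the 0–100% score contract; inside the clamps the map is
strictly decreasing, so a longer stay never scores higher. The original
study standardizes with moments "computed from the collected data", which
are unpublished; the package defaults to the moments of the elicited
triangles themselves ($\mu = (a+m+b)/3$,
$\sigma^2 = (a^2+m^2+b^2-am-ab-mb)/18$), the only reproducible choice, and
accepts user-supplied empirical moments (`score_mapping(..., source =
"empirical")`). Consequently absolute satisfaction levels are calibratable
but not value-matched to the published optimization tables, whose mapping
constants are not printed. A degenerate triple (zero spread) makes the
standardization undefined and is rejected.

The satisfaction objective of a run is the plain mean of the per-patient
scores; the cost objective is
$Z_1 = \sum_t \sum_i c_{i,t}\, n_{i,t}$ for staffing levels $n_{i,t}$ and
per-period unit costs $c_{i,t}$. The case study publishes only aggregate
daily costs, so $c_{i,t}$ is required configuration; bundled examples use
unit costs.

## Fuzzy weighted max–min staffing optimization

Cost and satisfaction are incommensurable, so each objective $Z_k$ is
normalized onto $[0,1]$ between its pessimistic extreme $Z_k^-$-side and
optimistic extreme taken from the two single-objective optimizations:

$$f_k = \frac{Z_k^+ - Z_k}{Z_k^+ - Z_k^-} \;(\text{min objective}), \qquad
  f_k = \frac{Z_k - Z_k^-}{Z_k^+ - Z_k^-} \;(\text{max objective}).$$

Because the extremes come from separate stochastic runs, a value can fall
outside its band; memberships are clipped into $[0,1]$, where the formula
is otherwise undefined. The weighted max–min model maximizes the
achievement level $\lambda \in [0,1]$ subject to
$w_k \lambda \le f_k$, i.e. $\lambda = \min(1, \min_k f_k / w_k)$, with the
five weight pairs (0.8, 0.2), (0.2, 0.8), (0.6, 0.4), (0.4, 0.6),
(0.5, 0.5) as the default sensitivity grid.

The search over integer schedules is a black-box heuristic in the spirit of
the commercial scatter-search optimizers used with simulation packages
(whose internals are proprietary): candidate schedules are proposed by
randomized ±1 neighborhood moves with periodic uniform restarts, infeasible
candidates (counter totals above the physical capacity $A$, also
unpublished and therefore required configuration) are rejected without
simulation, and the search stops after 100 consecutive evaluated candidates
without improvement. An exhaustive proposal mode enumerates the lattice,
which makes the search exact on small instances — that equivalence, against
an independent brute-force oracle, is part of the test suite. Each
evaluation averages 8 replications, the replication count that met the 5%
relative-error criterion in the original study. Replaying the bundled
published solutions through the membership/λ arithmetic reproduces λ = 1
for 14 of the 15 multi-objective rows; the one-stop scenario at weights
(0.8, 0.2) has a satisfaction membership of ≈0.157 < 0.2, contradicting its
reported level — the package flags this row as a known inconsistency
rather than passing or repairing it. λ is implemented as the search
objective, recomputable exactly from the reported objective values.

## Verification, validation and replication sizing

**Verification** pushes one patient per type through the model with
constant (mean) service times and ample capacity; the simulated LOS must
equal the manual sum of mean service times along the flow path exactly
(within 1e−9). The sums are 3.47, 3.47, 2.677 and 1.83 minutes for types
1–4. The type-3 value prints as 2.68 at two decimals while the study prints
2.67 — the triangular mean (84+146.8+251)/3 = 160.6 s is 2.6767 min, so the
published figure appears truncated rather than rounded; the package reports
the computed value and documents the 0.01-minute discrepancy.

**Validation** compares simulated per-type LOS against the observed
reference statistics with a two-sided unequal-variance (Welch) t-test — the
observed per-type SDs differ substantially, so the pooled-variance variant
would be hard to defend. Equal summary statistics give p = 1 by convention.

**Replication sizing** takes pilot per-replication means, forms the
t-based 95% confidence half-width, and projects half-width ∝ 1/√n to find
the smallest replication count whose relative error meets the target (5%
default). The original study's reported reduction from 10 to 8 replications
cannot be reproduced from published data and is not asserted; the package
keeps 8 as the default evaluation replication count and 10 as the
comparison-layout count, mirroring the study's own (inconsistent) usage.

## Scenario comparison and the decision guidelines

Per-replication mean satisfaction scores from all cases (weight settings)
and scenarios are compared by a fixed-effects ANOVA with main effects Case
and Scenario, the replication as a block, and the Case×Scenario
interaction; the full 7-case × 4-scenario × 10-replication layout has 279
total and 18 interaction degrees of freedom. A constant response makes
every F undefined; the package reports F as `NA` and p as 1 (no evidence of
any effect). Tukey HSD p-values come from the studentized range
distribution, and the compact letter display uses the insert-and-absorb
algorithm, so sharing a letter is exactly equivalent to a non-significant
pairwise difference — a property the tests check against direct pairwise
p-values.

The decision guidelines map (satisfaction change, cost change) versus the
unoptimized benchmark onto nine recommendations. "Unchanged" satisfaction
means sharing at least one Tukey letter with the benchmark row; cost is
deterministic given a schedule, so its change is an exact comparison. Case
selection for a minimum acceptable score finds the letter group whose range
of means contains the threshold (or the nearest higher group), takes its
cheapest case, then replaces it with any cheaper case from a
higher-scoring group. On the bundled comparison table a 70% threshold
selects the one-stop scenario with satisfaction weight 0.6 at 4422 Baht/day.

## What the defaults do and do not reproduce

With the published staffing row (6 + 3 triage nurses, counters 3/3/2/10)
the simulated front end is fast: waiting is minimal and the mean LOS is a
few minutes, so satisfaction saturates near 100%. The observed LOS
statistics of the real department (means of 25–56 minutes) include delays
the published model inputs cannot generate — the staffing baseline behind
them is unpublished. Aggregate anchors that depend on that baseline (the
observed-LOS validation means, the 5296.5 Baht/day baseline cost, the
85.81% baseline satisfaction, and the published optimal schedules, which
also need the unpublished $c_{i,t}$ and $A$) are therefore bundled as
reference fixtures for the arithmetic and decision layers, not regenerated
by simulation. What the simulation layer *is* held to: exact no-queue
verification, distribution recovery, conservation and FIFO discipline,
seed determinism, and the classical pooling property (one-stop mean LOS ≤
dedicated at equal total counters, tested as a paired 95% confidence
comparison over 30 replications under deliberately tight staffing so that
queues actually form).

## Problem sizes used in the shipped checks

The test suite and the reproduction script use one-day replications (about
250–300 patients each), 30-replication paired comparisons, 10⁵-draw
distribution-recovery checks, 10⁶-draw triangular moment checks, and a
9-point staffing lattice for the exact-search equivalence — sizes chosen so
the full suite exercises every claim in minutes on a single core while
keeping Monte-Carlo noise far below the tested tolerances.
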