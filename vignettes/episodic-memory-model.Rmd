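---
title: "A queryable what/when/where value memory and its foraging simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A queryable what/when/where value memory and its foraging simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuttlemem)
```

## The model

`cuttlemem` models episodic-like memory as a single three-dimensional array
of expected values, `epimem[what, when, where]`, indexed by object kind,
hour of day, and grid cell. The array is initialized to zero and is the
agent's only learned state. Its three operations are deliberately minimal:

* **Query.** Any subset of the three indices may be fixed; the readout is a
  snapshot of the values over the free dimensions (`query()`). Aggregates
  of slices — the per-object maximum, the per-object sum, or per-region
  sums — are what the decision policies consume. Because the array is
  persistent, querying an hour other than the current one reads the
  remembered (or anticipated) value landscape at that time: a rudimentary
  mechanical analogue of mental time travel (`landscape()`,
  `export_landscape()`).
* **Delta-rule learning** (`delta_update()`). On an outcome with signed
  reward $r$, the single entry addressed by the event's what/when/where
  tuple moves by $\Delta v = \alpha\,(r - v)$. Iterated under a constant
  reward the entry converges geometrically to $r$; from zero, $n$ updates
  give $r\,(1-(1-\alpha)^n)$, which the test suite checks against an
  explicit iteration oracle to $10^{-12}$. All values therefore remain
  inside $[\min(0, r_{\min}), \max(0, r_{\max})]$ — here $[-8, 4]$ — which
  the suite asserts across whole simulated runs.
* **Softmax selection** (`softmax_probs()`, `softmax_choice()`). An action
  with value $v_i$ is sampled with probability
  $e^{\beta v_i} / \sum_j e^{\beta v_j}$, computed with max-subtraction so
  that large summed values cannot overflow. A presentation of this rule
  that places $\beta$ as a multiplicative factor outside the exponential
  makes it cancel between numerator and denominator; we implement the
  conventional inverse-temperature form with $\beta$ inside the exponent.
  At the parameterization used throughout ($\beta = 1$) the two coincide
  exactly, so no behavioral result depends on this choice.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| $\alpha$ | 0.10 | Learning rate (unitless, in (0, 1]). One rewarded visit moves a zero entry 10% of the way to the reward; convergence to within 5% of $r$ takes ~29 visits. |
| $\beta$ | 1.0 | Softmax inverse temperature (unitless, ≥ 0). 0 gives uniform choice; the simulations never change it. |
| rewards | crab +1, shrimp +4 | Relative prey preference; the 4:1 ratio makes a converged shrimp memory dominate a converged crab memory through the exponential. |
| predator penalty | −8 | Stored signed so that capture memories *repel*: region sums fall below zero near danger and the object-centric hide value $-\sum$ predator slice is positive. The magnitude (twice the shrimp reward) makes one capture outweigh two shrimp meals. |
| roam value | 0.5 | Fixed value of undirected exploration. Above 0 so a naive agent explores; below any converged prey value so exploration fades with knowledge. |
| vision | < 2 cells | Chebyshev bound: the agent perceives (and eats, and suffers capture within) its 3×3 neighbourhood. |
| predator vision | < 4 cells | The predator detects a non-hidden agent within its 7×7 neighbourhood and then chases greedily. |
| hours, steps | 3 (or 6) hours × 100 steps | One decision per hour; the step budget bounds each foraging bout. |

## The simulated worlds

**Two-phase foraging** (`run_elm()`): 8×8 grid; the agent re-enters at
(0, 4) each hour; crab fixed at (7, 0) and always available; shrimp fixed
at (7, 7), available every hour for days 0–49 (phase 1) and only at hour
index 2 — the "3-hour delay" — from day 50 (phase 2). Actions: hunt crab,
hunt shrimp (greedy walk to the remembered best cell, then local random
walk), roam (random 8-directional walk). Any available prey within vision
is eaten, updating the memory at the prey's cell for the current hour and
ending the hour.

**Predator–prey** (`run_pp()`): 12×12 grid tiled by nine 4×4 regions
(row-major ids 0–8); agent re-enters at (6, 0) each hour. Shrimp placed
uniformly anew each hour in region 6 at hours 2–5; crab likewise in region
8 at hours 0–5; predator at hours 1–3, entering uniformly on the left side
(x < 6; the bound is a `pp_config()` parameter). The predator wanders randomly,
chases on sight, and catches a non-hidden agent within vision (< 2),
writing the −8 penalty at the agent's cell — the agent remembers *where it
was attacked*. One event (eat or be eaten) at most per hour; afterwards the
agent idles until the next hour.

Two query policies map the same memory onto actions:

* *what* (object-centric): values are the per-object slice sums at the
  current hour, plus hide $= -\sum$ predator slice, plus roam; a hunt walks
  to the centre of the region holding the chosen object's best remembered
  cell, then roams inside that region.
* *where* (region-centric): values are the nine signed per-region sums
  (prey attract, capture memories repel), plus roam. A region action
  travels to the region's centre cell and roams within it.

**Hours are 0-based throughout.** Prose that counts delays from one (a
"1-hour" or "3-hour delay", or "hours 5 and 6" of a 6-hour day) maps to
hour indices 0, 2, and 4–5 respectively; the predator-free shrimp hours
are indices 4 and 5.

## Extinction: the one genuinely open design area

The core learning rule updates memory only on rewarded (or punished)
encounters. By itself that cannot produce the phase-2 behavioral switch:
the shrimp value learned in phase 1 would persist at the short delays
forever. Some unrewarded decrement is required, and its scope turned out to
be the single most consequential design choice in the package. The
implemented rule, exposed as the `extinction` config switch, is:

1. **Prey memory decays only when hunted.** When the agent hunts object
   $o$ and a remembered (nonzero) cell of $o$ at the current hour enters
   its vision while $o$ is not actually there, that cell receives one
   $r = 0$ update (a factor $1-\alpha$) for the hour. A failed search is
   the informative null trial — the classic extinction paradigm. Roaming
   or region-directed movement past a remembered prey site is *not* a
   search for it and decays nothing.
2. **Danger memory decays on safe passage.** A remembered predator cell
   that the non-hidden agent sees while nothing happens receives the same
   single $r = 0$ update. (A remembered cell with the predator actually on
   it is a capture, not an extinction trial, since the catch radius equals
   the vision radius.)
3. **Nothing decays while hiding** — a camouflaged agent makes no updates
   of any kind.

Both broader and narrower rules were evaluated and fail the replication:
applying prey extinction during *all* actions flattens the region-centric
mode's region values to the level of the fixed roam value (prey are
re-placed within their region every hour, so remembered cells are usually
"empty"), leaving roaming permanently competitive and the crab/shrimp
ordering inverted; conversely, never decaying predator memory lets capture
penalties accumulate without bound inside the crab region, which the agent
then avoids in alternation, again suppressing the opportunistic crab
hunting and the decline of roaming that the experiments report. The
hunted-prey/safe-passage split reproduces all figure-level findings and has
a coherent reading: both decrements are driven by *verified absence of the
specific thing the memory is about*.

## The where-mode action set

The object-centric mode has four actions (hunt crab, hunt shrimp, hide,
roam). Whether the region-centric mode should also offer hide is
underdetermined by the behavioral findings it must reproduce, which report
only region choices. We exclude hide from the region-centric action set by
default, for a structural reason: no learning occurs while hiding, so a
danger-valued hide is an
*absorbing state* — once $-\sum$ predator slice exceeds every region sum at
a predator hour, no experience can ever overtake it, the agent hides at
hours 1–3 indefinitely, and the mode's defining opportunistic behavior
(risky crab hunting, occasional captures) cannot arise. With
`pp_config(where_hide = TRUE)` the 11-action variant remains available for
comparison.

## Numerical and procedural conventions

* **Distance is Chebyshev** everywhere: with 8-directional unit moves,
  "steps" equals $\max(|\Delta x|, |\Delta y|)$, so "vision < 2" is the
  3×3 neighbourhood. Greedy travel (`step_toward()`) moves by the per-axis
  signs and provably reaches the target in exactly that many steps.
* **Boundary handling**: random steps choose uniformly among the 8
  directions, then clip to the grid (or region) rectangle; from a corner
  some draws collapse onto in-bounds cells. Clipping is simpler than
  re-sampling and its bias is irrelevant at these scales.
* **Ties** in `argmax_cell()` break to the smallest flat index —
  deterministic and platform-independent; a fresh all-zero memory hunts
  toward cell 0.
* **Within-timestep order**: agent moves, predator moves, then events
  resolve (prey first, then capture; at most one event per hour).
* **Hide hours short-circuit**: nothing can happen to a camouflaged agent
  and per-hour placements do not persist, so the engine records the hour
  without stepping it. This changes only the number of RNG draws consumed,
  not any distribution.
* **Region centres**: a 4×4 block has no central cell; we use the floor
  convention (offset +1, +1). Any fixed interior cell works because the
  agent roams the region after arriving.
* **Quantiles** in `boxplot_summary()` are linear-interpolation type 7
  (R's default), with 1.5×IQR whiskers clipped to the data.
* **Seeding**: run $k$ (0-based) of a scenario uses `base_seed + k`, one
  generator stream per run, so runs are order-independent and every
  artifact is reproducible from the manifest (`write_manifest()`).
* **Dumps** (`write_memory()`) print values with 17 significant digits and
  round-trip bit-exactly.

## What the simulations do and do not establish

The generator *is* the stated world of the original experiments: point
objects on small grids, a perfect internal hour clock, a priori knowledge
of how to navigate to a remembered cell, stationary prey within an hour,
and a single predator with greedy pursuit. A green acceptance suite
establishes that the memory model reproduces the *behavioral findings of
those simulated designs* — the phase-2 choice switch, risk-averse
object-centric foraging, opportunistic region-centric foraging, declining
exploration — under the published parameters, at the published scale
(100 seeded runs), with the stochastic criteria expressed as
medians/means across runs.

It does not establish anything about cuttlefish neurobiology, about
robustness to parameters not varied here ($\alpha$, $\beta$, rewards,
grid geometry), or about richer environments (moving prey, multiple
predators, energy budgets, path planning under obstacles), all of which
are out of scope. Known limitations worth keeping in mind: the memory
does not scale (dense 3-D array), time is a discrete exogenous index with
no uncertainty, and extinction semantics — though constrained by the
replication as argued above — are not uniquely determined by the source
description.
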