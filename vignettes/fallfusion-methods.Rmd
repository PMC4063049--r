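---
title: "Context-aware fall-risk assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware fall-risk assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallfusion)
```

## The problem

Falls are the dominant cause of injury among elderly people living alone.
Wearable impact detectors are cheap and sensitive but fire on many
high-impact non-falls (sitting down heavily, stumbling, dropping the
device), while ambient-sensor systems know *what the person is doing* but
not whether they fell. `fallfusion` implements the standard three-layer
remedy: an accelerometer-threshold fall detector, an interval-algebra
activity-recognition engine over environmental sensors, and a discrete
dynamic Bayesian network (DBN) that fuses both evidence channels per time
slice into a posterior fall-risk probability, used to confirm or reject
the raw alarms.

## The wearable detector

For a belt-worn tri-axial accelerometer sampled at `sample_rate` Hz the
detector computes, over sliding windows, the impact statistic

$$\mathrm{Act} \;=\; E\!\left[\,\lvert \nu_a^2 - E[\nu_a^2] \rvert\,\right],
\qquad \nu_a = \sqrt{a_x^2 + a_y^2 + a_z^2},$$

the mean absolute deviation of the squared acceleration magnitude. It is
zero at rest regardless of posture, small under gait, and large during an
impact; because it depends only on the magnitude it is invariant to device
rotation and scales quadratically with acceleration. When
`Act >= act_threshold` the detector pauses, waits `orientation_delay`
seconds, averages `orientation_window` seconds of quiet samples, and
computes the Euler angles

$$\mathrm{roll} = \arcsin(a_x/g), \qquad \mathrm{pitch} = \arcsin(a_z/g),$$

with the ratios clamped to $[-1,1]$ because dynamic accelerations exceed
$g$. An alarm fires only when the posture is horizontal
(`|roll| >= 60` or `|pitch| >= 60` degrees by default); this gate is what
suppresses high-impact non-falls followed by an upright recovery. The fall
direction is read off the dominant horizontal-plane axis at the
peak-magnitude sample (+z forward, −z backward, +x right, −x left, ties to
the z axis; the mapping is configurable because device mounting
conventions differ). Alarms carry the last observed pulse, oxygen
saturation and location as pass-through payload.

Numeric thresholds are package defaults, not published values: with
per-axis noise of 0.1 m/s², rest keeps `Act` near 2 (m/s²)², gait
modulation near 20, and the synthetic impact pulse in the hundreds, so the
default `act_threshold = 80` separates the regimes with an order of
magnitude on either side.

## Activity recognition

Environmental sensors (stove, tap, bed pressure, TV power, presence) are
*down-sampled* into labeled temporal intervals: maximal runs over which a
predicate holds (e.g. temperature ≥ 40), with runs separated by less than
`min_gap` seconds merged. Activities are then inferred by rules in Allen's
interval algebra of the form

```
Cooking = Stove  ∧  Cooking during Kitchen
```

the inferred activity inherits the extent of its *anchor* interval (the
stove-on period) provided each constraint holds against some instance of
its target label. We use closed intervals with exact endpoint comparisons,
so exactly one of the thirteen Allen relations holds for any pair of
proper intervals; degenerate (zero-length) intervals are rejected. Because
household sensors often coincide at endpoints, a named alias `within`
(= during ∨ starts ∨ finishes ∨ equals) is accepted in rules alongside
strict `during`. Extraction keeps, per activity, the maximum-duration
interval, ties broken by earliest start.

## The fusion network

The default model has seven binary variables per time slice: hidden
fall-risk `FA` and observables `Sl` (sleeping), `Sh` (showering), `C`
(cooking), `TV`, `Tr` (training) and `FE` (the wearable's raw fall
event). Within a slice every observable is a child of `FA`; across slices
`FA → FA` (consecutive falls are improbable, so the self-transition is
strongly inhibiting), `Sh → Sl` (sleep tends to follow a shower) and
`Tr → Sh`, `Tr → C` (showers and cooking tend to follow training). The
two-slice parameterization repeats for every later slice; nodes without
inter-slice parents reuse their slice-1 table.

CPTs are stored child-last, in column-major order, states coded 1 = false,
2 = true — exactly the printed row order of a conventional conditional
probability table, e.g. `P(Sl = true | FA = true) = 0.1`. The shipped
slice-2 showering table contains two columns that do not normalize; the
loader repairs such binary columns by keeping the child = false entry and
complementing it, warning loudly (the false-row entries follow the pattern
of the consistent cooking table, so they are the ones trusted).

Unprinted parameters are explicit package defaults in
`inst/extdata/default_model.yaml`: prior `P(FA=true) = 0.2`, transition
`P(FA_t | FA_{t-1}) = 0.10 / 0.05` (false/true), detector channel
`P(FE=true | FA) = 0.05 / 0.9`, elevated training risk
`P(Tr=true | FA) = 0.2 / 0.7`, and slice-1 showering/cooking columns taken
from the `Tr_prev = false` columns of their slice-2 tables. They were
chosen once, by the qualitative constraints above, and are all
overridable.

## Exact inference

The joint distribution factorizes over slices; all queries are
marginalizations of it. The package runs exact inference over the
*interface* — the set of nodes with outgoing inter-slice edges
(`FA, Sh, Tr` in the default model, 8 joint states) — passing forward and
backward messages between pairs of neighboring slices. Each slice update
enumerates only the slice's unobserved nodes (≤ 2⁷ rows), so filtering,
smoothing, prediction and EM are linear in the horizon. Messages are
renormalized per slice and the normalizers accumulate the log-likelihood,
avoiding underflow on long recordings.

A brute-force enumeration oracle (`enumerate_posterior`) sums the joint
over every completion of the evidence and is guarded at
`n_nodes × T ≤ 24` variables; the test suite checks the interface
algorithm against it elementwise below 1e-9 over randomized models and
evidence, which is the package's correctness argument. MAP sequences
(`viterbi_map`) use max-product messages over the same interface with
backward maxima and greedy forward selection, which yields the
lexicographically smallest maximizer under exact ties (false < true,
slices major); tie detection uses a 1e-12 relative tolerance.

EM (`em_learn`) re-estimates every CPT from sequences with missing
entries: exact forward/backward per sequence, expected counts per CPT
cell, renormalization with a 1e-6 pseudocount to avoid zero-probability
lock-in. Tied tables pool counts across slices. The log-likelihood trace
is non-decreasing and complete data converge in one step to empirical
frequencies.

## Fusion and decisions

Continuous time is discretized into slices of `slice_duration` seconds
(slice *t* covers `[(t−1)d, td)`; the slice unit is a free modeling
choice — a minute for a demonstration, an hour for long-term monitoring).
An activity is observed true in a slice when its interval covers at least
half the slice; a fall event when an alarm timestamp lies in the slice;
everything else stays *unobserved* rather than false. The posterior trace
`P(FA_t | evidence)` is computed by smoothing by default (post-hoc
assessment; filtering gives the causal/online view), conditioning jointly
on all observed nodes of each slice — the "explaining away" configuration.
A slice with a fall event is confirmed as an emergency when its posterior
reaches `risk_level`, rejected otherwise. The default 0.7 was chosen to
separate confirmed from rejected alarms in the reference operating point
and is deliberately a flexible parameter. A per-activity summary reports
slice counts and min/max/mean posteriors, and each alarm verdict carries
its conditioning and neighboring activities.

## What the generators emulate

The simulation scenario follows the standard design: `T = 100` slices,
exactly one activity observed per slice (drawn from an ancestral sample of
the model, or cycling deterministically), and a fall event injected at
every 10th slice — hence `floor(T / fe_period)` = 10 fall events, the
deterministic count the acceptance script recomputes.

The accelerometer generator synthesizes upright rest (gravity on the y
axis), gait, true falls (impact pulse then lying, gravity on the x axis)
and *faked* falls (impact then upright recovery). Templates are separable
by construction: on them the detector attains sensitivity and specificity
1, which validates the gating logic, **not** field performance — real
falls have heterogeneous impact signatures, postures and confounders that
no template captures. The environmental generator emits, per scheduled
activity, an anchor device sensor over the exact extent and a presence
sensor padded by 2 s, so the context engine recovers the schedule exactly;
real sensor data are noisy, overlapping and incomplete in ways these
events are not. Passing round-trips therefore demonstrate internal
consistency of detector, rules and generators, and nothing about
real-world accuracy.

The shipped demonstration fixture scripts four activities over seven
one-minute slices with two detector-triggering falls — one faked during
television, one real during training. Under the default model the fused
posterior rejects the television alarm and confirms the training alarm at
risk level 0.7, reproducing the qualitative outcome the system is designed
for.

## Experiment sizes and numerical choices

The test suite fixes every seed. Oracle equivalence runs 100 randomized
compact models (one hidden chain plus up to two coupled observables) at
horizons ≤ 3, where enumeration is cheap, plus the full 7-node model at
its guard limit. The EM recovery experiment uses 5,000 slices as 2,500
two-slice sequences of a compact three-node model with 15% of entries
missing at random and balanced parent marginals: many short sequences are
essential because slice-1 tables only receive counts at the first slice of
a sequence, and the balanced design keeps every CPT cell above ~500
effective observations so that ±0.05 recovery has a comfortable
statistical margin. Sampling consistency uses 10⁵ ancestral slices
(±0.02 band). All randomized checks are reproducible via their fixed
seeds; CPT columns are validated to sum to 1 within 1e-9 at load.

## Limitations

* The network structure and all unprinted parameters are subjective
  choices, not learned from data; `em_learn` exists precisely to replace
  them given recordings.
* Binary activity nodes cannot represent durations or intensities within
  a slice; the ≥ 50% overlap rule discards short activities.
* The context engine does no constraint propagation: rules are evaluated
  pairwise per anchor instance, which is complete for the shipped
  anchor-plus-constraints rule form but not for general interval-algebra
  networks.
* Physiological channels (pulse, SpO₂) are pass-through payload only;
  they do not enter the network.
* Exact interface inference is exponential in the interface size; the
  default model's interface has 3 nodes, and models with many
  inter-connected nodes would need approximate methods that are out of
  scope here.
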