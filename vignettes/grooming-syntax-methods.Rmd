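---
title: "Methods: Markov syntax analysis of grooming ethograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov syntax analysis of grooming ethograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethosyntax)
```

## The problem and the data model

Dusted *Drosophila melanogaster* groom by stringing together stereotyped
actions — front leg rubbing (`f`), head cleaning (`h`), abdomen cleaning
(`a`), back leg rubbing (`b`), wing cleaning (`w`) — interspersed with
walking (`wk`) and rare standing (`s`). A video classifier emits one label
per frame at 30 Hz; `ethosyntax` analyzes the *syntax* of these streams at
three temporal scales:

* **bouts** (hundreds of milliseconds to seconds): run-length encoding of the
  frame stream yields an ordered list of (action, duration) bouts in which
  consecutive bouts always differ in action;
* **motifs** (seconds to tens of seconds): maximal runs of bouts executed
  with one leg pair — anterior (`f`, `h`) or posterior (`a`, `b`, `w`);
* **the progression** (minutes): a population-level drift from
  anterior-dominated grooming to posterior grooming and walking, reaching an
  approximate steady state after about 13 minutes.

## De-noising and duration binning

Bouts shorter than 167 ms (about one leg sweep) are treated as classifier
artifacts: `remove_short_bouts()` deletes them, drops their time from the
record (the deleted fraction is reported, not redistributed), and merges
same-action bouts left adjacent in a single pass. The single pass preserves
the consecutive-distinct invariant that self-transition-free Markov counting
requires; we deliberately do not re-filter merged bouts, so a merged bout may
be longer than the threshold even if its parts were not. Standing is removed
afterwards (`drop_action()`); the order is configurable via
`denoise_ethogram(standing_first = )` because the upstream convention is not
fixed by the data.

Duration enters the state space through per-action equal-occupancy bins
(`fit_binning_scheme()`): edges sit at the k/n empirical quantiles of each
action's pooled durations, realized as midpoints between bracketing order
statistics. Categories are half-open on the left, `[low, high)`, so a
duration exactly at a threshold goes to the upper bin — deterministic and
consistent with standard quantile binning. With heavy ties exact balance can
be impossible; the achieved per-action occupancy deviation is reported in the
scheme's `occupancy_deviation` attribute rather than silently ignored.
Defaults are three bins (short/medium/long) and a 167 ms threshold; both are
configurable (four and five bins reproduce the same qualitative structure).

## Markov models and model comparison

On the product state space of actions and duration categories (6, 12 or 18
states), `mle_transition_matrix()` implements the maximum-likelihood
first-order chain estimate: entry (i, j) is the transition count n_ij divided
by the row total. Same-action entries are structurally zero (discretization
forbids self-transitions) and rows with no observations are flagged
unsupported rather than NaN. Counting pools flies but never crosses fly
boundaries.

Likelihoods are the standard sum of log transition probabilities over
consecutive bout pairs, in nats. Model comparison uses
`BIC = ln(n)·k − 2·ln L`, lower better. Two free-parameter conventions are
provided: *structural* (default) counts each supported row's structurally
allowed entries minus one normalization constraint, i.e. `v − n_bins − 1` per
row; *observed* counts strictly positive entries minus supported rows. The
structural convention is ordering-insensitive to sampling zeros, which is why
it is the default; unsupported rows contribute no parameters under either.
For the analytic null models, which are parameterized by fewer quantities
than a full matrix, `null_free_parameters()` supplies the natural counts: an
action-level transition matrix plus per-action duration distributions for the
duration-permuted null, and the state marginal alone for the order-permuted
null.

A practical consequence of the structural convention worth knowing: with 18
states the MLE carries 252 parameters against the duration-permuted null's
36, so the MLE only wins on BIC once the cohort supplies roughly 4×10^4
transitions. The package's acceptance checks therefore run the BIC-ordering
comparison at the study's scale (92 flies, ~10^5 transitions), where the
ordering MLE < duration-permuted < order-permuted is robust.

`split_phases()` supports the boundary rules used across the analyses:
a fixed time in minutes; the across-fly average of each fly's
half-bout-count time (which lands near 13 minutes on drifted cohorts); first
and last N bouts per fly (N = 200 for fitting the renewal process's edge
matrices); and first/last thirds. A bout straddling a time boundary belongs
to the phase containing its start, keeping bouts atomic.

## Permutation null models

Two nulls isolate the contributions of action order and bout duration:

* **duration-permuted** — action order preserved, duration categories
  shuffled within each action: entry ((i,c) → (j,d)) =
  P(action j | action i) × P(category d | action j);
* **order-permuted** — durations ride with their bouts but bout order is
  destroyed: every row is proportional to the state marginal P(j).

Both are computed analytically from `marginal_statistics()` (the
infinite-permutation limit) and by Monte Carlo (`monte_carlo_null()`), always
permuting within fly. P(category | action) is read as conditional on the
destination action, following the per-action reading of the duration
marginal; both nulls therefore have identical rows within each action block,
and the duration-permuted null preserves the MLE's action-level block mass
exactly.

Order permutation can place same-action bouts adjacently, which real
discretized data cannot contain. The analytic null zeroes same-action
columns and renormalizes (`renormalize_self = TRUE`, the default), giving
m_j/(m − m_A) in bout-count terms; the Monte-Carlo counter correspondingly
*skips* same-action adjacent pairs. Under this matched pair of conventions
the exhaustive-enumeration oracle (average transition counts over all
orderings, then normalize) equals the analytic matrix to machine precision,
which is how the test suite pins both implementations. An unnormalized
variant is exposed for comparison but does not satisfy the row-stochastic
contract.

Two finite-sample caveats, verified by the test suite rather than assumed:
the Monte-Carlo mean of per-permutation MLE matrices converges to the pooled
analytic formula only when per-fly marginals match the pooled marginals
(permutations are within-fly), so the oracle-equivalence tests use cohorts
whose flies share one bout composition in different orders; and the mean of
ratios differs from the ratio of means at O(1/n), which is negligible at the
tested sizes.

## The nonstationary Markov renewal process

The generative model (`mrp_model()`) combines Markov transitions with
renewal-process dwell times: after each bout, the next state is drawn from
the row of a time-varying matrix

M(t) = ((t_s − t)/t_s)·M_early + (t/t_s)·M_late for t ≤ t_s, and M_late
afterwards,

with t in minutes and t_s = 13 by default; the duration of the new bout is
drawn from that state's duration distribution, which does not change over
time (early- and late-phase durations are statistically indistinguishable in
the data this emulates). M_early and M_late are fit to the pooled first and
last 200 bouts per fly (`build_mrp_from_cohort()`), well-separated because a
recording averages around a thousand bouts.

Three choices the formulation leaves open, and how they are resolved here:

* **Clock**: M(t) is evaluated at the elapsed time when the transition is
  drawn, i.e. the start of the new bout — the simplest consistent choice.
* **Duration conditioning**: durations are drawn per *state* (action and
  category) — the transition already prescribes the category, so drawing
  from the unconditional per-action distribution could contradict it. Fitted
  models use the empirical pool of each state's durations; the synthetic
  generator uses per-category truncated log-normals.
* **End of record**: the final bout is truncated at `total_time`, so every
  simulated fly has exactly the same recording length (27.8 min by default).

The initial state is drawn from the empirical first-bout distribution when
fitted from data, and from a uniform distribution over anterior states in the
synthetic generator (grooming onset is anterior-dominated).

## What the synthetic generator emulates — and what it does not

`ground_truth_spec()` states the synthetic world once: 92 flies, 27.8-minute
recordings at 30 Hz, six actions, three duration bins. Bout durations follow
per-action log-normals with modes near 1 s for the anterior actions, near
250 ms for abdomen and wing cleaning, and intermediate for back leg rubbing —
parametric stand-ins for the empirical shapes, chosen qualitatively, not
measured values. Durations are floored at 0.2 s so that the 167 ms artifact
filter deletes *only* injected noise; this makes the de-noising recovery test
exact but means the generator does not emulate genuine sub-threshold
behavior. Transition structure: anterior rows send 0.88 of their mass to the
other anterior action and posterior rows 0.70 into the posterior block;
within-motif category coupling is symmetric for the anterior pair with a
dominant long-to-long transition, and asymmetric, short-biased, for the
posterior triplet. The drift tilts walking and posterior escape mass between
phases (anterior block 0.88 early, 0.78 late) over a 13-minute horizon.
A `duration_coupling = "independent"` variant severs the category coupling to
provide the duration-independent world that the BIC comparison must *not*
reward.

Classifier error is emulated only as random 1–4-frame label insertions
(`inject_label_noise()`); real classifier confusion is structured
(action-dependent, boundary-concentrated), so a green noise-recovery test
establishes the accounting of the de-noising step, not robustness to real
misclassification. Per-fly seeds derive deterministically from the cohort
seed (`seed + fly index`), so cohorts are reproducible fly by fly.

## Numerical conventions

Natural logarithms throughout. Row-stochasticity is enforced at 1e-9 in the
matrix constructor and exact renormalization guards against floating-point
drift in the analytic nulls. Degenerate inputs are reported, not silently
absorbed: an emptied ethogram warns; a correlation over fewer than two points
or zero variance is `NA`; a zero-probability observed transition makes the
log-likelihood `-Inf` and lists the offending transitions; an absorbing
state aborts a simulation with the state and time. One formulation note: the
source formulation of the likelihood sums probabilities rather than log
probabilities, which cannot feed `−2·log(L)`; the package implements the
standard log-likelihood.

## Known limitations

* First-order chains only; higher-order or hidden-state structure is out of
  scope, as are entrywise hypothesis tests on transition probabilities.
* The interpolation drift is a phenomenological stand-in for declining
  sensory input; no irritant dynamics are modeled.
* Equal-occupancy binning ties break balance on heavily tied data; the
  deviation is reported but not repaired.
* The walking action receives duration categories by default; pass a reduced
  action set to `build_state_space()` to exclude it.
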