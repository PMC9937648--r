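---
title: "Analysing dyadic coordination in transparent Bach-or-Stravinsky games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dyadic coordination in transparent Bach-or-Stravinsky games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bosgame)
```

## The game and its observables

`bosgame` analyses iterated dyadic sessions of a Bach-or-Stravinsky (BoS)
coordination game played in a *transparent* setting: two agents face each
other across a display, each repeatedly chooses one of two colour targets,
and each can see the partner's unfolding reach before committing to their
own. Selecting the individually preferred colour ("own") is worth 2 base
reward units, selecting the partner's colour 1 unit, and landing on the
same physical target adds a coordination bonus of 2 to both. Coordinated
trials therefore pay 4/3 (unequally), mutual insistence pays 2/2, and
mutual accommodation 1/1. The side on which each colour appears is
randomised, balanced in sets of 18 trials (six positions, three
occurrences each), so colour- and side-based conventions are statistically
distinguishable.

All sides in the package are *objective*: agent A's frame is used for both
agents, so equal objective sides always mean the same physical target. A
session is a `bos_session`: an ordered per-trial table (layout, both
agents' sides and colour-category choices, rewards, release/acquisition
timestamps, a visibility flag) plus pair metadata, round-trippable through
a plain TSV dialect (`write_session()` / `read_session()`).

## Choice metrics

`fco()` and `fcl()` report the fraction of trials an agent chose its own
colour and the objective left side, as a session scalar and as a running
series. The running window is **trailing** (the value at trial *t*
averages trials *t-7 … t*, undefined for the first seven trials): a causal
window needs no edge padding and never mixes future choices into the
value at *t*. With `w = 8` the series takes only the values 0, 1/8, …, 1.
Steady-state analyses use the last 200 trials (`last_n()`), a convention
that skips the initial exploration period; shorter sessions are analysed
whole and flagged rather than rejected, because real recordings and
opaque-barrier segments can be short.

## Mutual information and its surrogate null

Dependence between the agents' choice series is measured by the plug-in
("naive") mutual-information estimator on the 2 x 2 contingency table of
simultaneous choices, in bits, separately for physical colour and
objective side (`naive_mi()`). For binary series the estimator is exact
enough at session lengths of a few hundred trials; its well-known positive
bias on independent series is approximately 1/(2N ln 2) bits and is
verified by simulation in the test suite.

Significance (`mi_significance()`) cannot use a simple permutation null:
choice series are strongly autocorrelated (runs of a convention,
turn-taking blocks), and shuffling would destroy that structure and
overstate significance. The null must keep each agent's own dynamics and
only break the coupling between agents. We therefore use Whittle
surrogates: resampled series that preserve the observed first-order
transition counts and the initial symbol exactly. For a binary series the
admissible set is parametrised by the two run-length compositions, so a
uniform draw of those compositions yields an exact uniform sample without
rejection - this defining transition-count property, not any particular
published construction detail, is what the tests assert. Surrogates of
the two agents are drawn independently; the MI threshold is the 0.99
quantile of surrogate-pair MI values (one-sided, `alpha = 0.01`, 1000
pairs by default).

One degenerate case needs an explicit rule. If the two observed series
are an exact in-sample bijection with nonzero entropy (e.g. perfect
lockstep alternation), the transition counts determine the sequence
uniquely, every surrogate pair reproduces the observed MI, and a strict
exceedance rule could never fire even though the dependence is perfect.
Such exact bijections are therefore reported significant; constant series
(MI = 0) remain non-significant. The clause has essentially zero
probability of firing under independence, so the null calibration
(false-positive rate ~ alpha, verified in the tests) is untouched.

## Random-play baseline and the dynamic coordination reward

The *reward for playing randomly* (RPR, `rpr()`) is the expected mean
joint reward if the two agents' colour choices were independent **given
the layout**, keeping each agent's side-conditional choice probabilities.
The conditioning matters: a pair that statically coordinates on one side
earns 3.5, and its random-play baseline must also be 3.5 (the side
convention itself carries no trial-by-trial coordination), which only
holds if the baseline respects the layout dependence of the choices.
Operationally the baseline is equivalent to permuting each agent's
choices across trials *within* red-left and red-right layout strata
(`permute_choices()`), and the closed form is cross-checked against that
stratified permutation by Monte Carlo in the tests.

The *dynamic coordination reward* is `DCR = R_actual - RPR`, in [-1, 1]:
+1 for perfect turn-taking, -1 for strict anti-coordination alternation,
0 for any static convention. Inside `dcr()` the RPR is evaluated from the
agents' FCO/FCL with the layout probabilities fixed at their design value
0.5, via the exact reconstruction `P[2,left] = (FCO + FCL - Q_right)/2`
(all four per-agent probabilities follow from the marginal and layout
constraints).

The confidence interval combines the two estimated ingredients of the
statistic. FCO and FCL are binomial proportions, so the baseline
uncertainty is captured by evaluating RPR at the 16 corners of the
4-dimensional box of `fraction +/- z sqrt(p(1-p)/n)` (RPR is multilinear
in the four fractions, hence extremal at corners; corners are clipped to
[0, 1]). The observed mean joint reward is itself a sample mean, so the
corner range is widened on each side by `z * sd(joint reward)/sqrt(n)`.
The second term is essential: without it the interval reflects only
baseline uncertainty and, under a true random-play null, rejects far more
often than its nominal level - the package's permutation-null test
(shuffled sessions must cover zero in at least 95% of replicates) fails
at roughly 80% coverage with the corners alone and is comfortably
satisfied with the combined interval. Adding the two half-widths rather
than their quadrature is deliberately conservative. The confidence level
is a free parameter (`ci_z`, default 1.96); the calibration property, not
the specific level, is what the suite enforces.

`classify_strategy()` places a session on the MI plane: *dynamic
turn-taking* requires a significant DCR above 0.2 (strict, as a
configurable threshold) with both MI colour and MI side significant;
*static colour* is significant MI side without MI colour (both agents
track one colour across sides) plus a dominant colour among coordinated
trials; *static side* is the mirror image; *uncoordinated* means the
coordination fraction does not exceed the random-play expectation
(one-sided binomial test at 0.05); everything else is *unclassified*. The
dominance check (default 0.75 of coordinated trials) prevents, e.g., a
mutually insistent pair - whose side series are perfectly
anti-correlated and hence MI-side significant - from being called a
colour convention on the strength of zero coordinated trials.

## Action times and action visibility

From the release and acquisition timestamps, `action_time()` computes the
movement time and the action time (the halfway point of the reach), the
moment at which a reach becomes readable by the partner. Three Welch
(Satterthwaite) two-sample tests (`at_tests()`) probe temporal
leader-follower structure: overall AT of A vs B; the per-trial difference
`AT_A - AT_B` in trials coordinated on A's versus B's colour; and the
absolute difference in coordinated versus uncoordinated trials. Welch
tests are delegated to `stats::t.test(var.equal = FALSE)`; the test suite
pins them against the closed-form formulas to 1e-10.

The probability that the slower agent saw the faster agent's choice is
modelled as a logistic function of the action-time difference,
`psee(dt) = 1/(1 + exp(-k (dt - dt0)))` with defaults `k = 0.04` per ms
and `dt0 = 50` ms, so `psee(50) = 0.5` and `psee(150) = 0.98`. For agent
*i* the argument is `dt = AT_i - AT_partner`: positive when *i* is slower
and could watch. `visibility_correlation()` relates this per-trial
visibility to the agent's following indicator (choosing the partner's
colour, i.e. `1 - FCO` at trial level) by Pearson correlation, raw and
after trailing 8-trial smoothing of both series; since smoothing inflates
autocorrelation, a shuffle-based null for the raw correlation is also
available. `psee_robustness()` re-evaluates the correlation over the
standard 6 + 5 grid of `dt0` and `k` values.

## Switching behaviour

`segment_coordination()` partitions a session into maximal blocks of
constant coordination mode (coordination on A's colour, on B's colour, or
uncoordinated runs, labelled own-own / other-other / mixed). A *seamless
switch* (`seamless_switches()`) is a pair of consecutive coordinated
trials with different coordination colours, counted per boundary; the
agent with the smaller action time on the switch trial itself is the
faster agent (that is the trial on which the classified choice is made),
and its choice classifies the switch as selfish (own colour) or
benevolent. Ties and missing timestamps leave a switch unattributed.
Verdicts against the selfish/benevolent diagonal use an exact binomial
95% interval on the benevolent proportion versus 0.5 - the verdict, not
any particular contour geometry, is the tested surface.
`uncoordinated_classes()` applies the same logic to own-own versus
other-other trials, and `transition_at_profile()` averages each agent's
action times around entries into and exits from coordination (default
+/- 3 trials), recovering injected speed-up/slow-down effects in the
tests.

## The session simulator

`simulate_session()` generates dyadic sessions with the strategic
structure the analyses are designed to detect, and is itself first-class,
tested code. The policy repertoire covers fixed colour, fixed objective
side, trial-by-trial and block turn-taking, a scripted confederate
alternating colours in blocks of approximately 20 trials (with optional
jitter, as a free parameter), a Bernoulli baseline, and a
leader-follower wrapper: each trial both agents draw provisional action
times; if the slower agent plays leader-follower and the trial is
transparent, it copies the faster agent's physical target with
probability `psee(dt) * follow_fidelity`, and its realised action time
becomes the leader's plus a 150 ms reaction lag (so the AT-difference
histograms show the waiting signature). Exact provisional ties are broken
by a coin flip - a zero-measure event under continuous draws, but the
rule keeps the simulator total.

Action and movement times are truncated normal draws (floor 50 ms, which
keeps all times strictly positive and release strictly before
acquisition); the defaults (movement 314 +/- 104 ms) follow typical human
reach parameters in touch-screen tasks. Realised timestamps are rounded
to whole milliseconds so a TSV round trip is bit-exact. Each session
consumes a single RNG stream keyed by its seed, with the draw order
documented in `?simulate_session`; every analysis function that uses
randomness takes its own seed and restores the caller's RNG state.

What the generator deliberately does **not** emulate: learning and
strategy drift within or across sessions (policies are stationary),
social signalling outside the reach channel, and deliberate waiting that
is not gated by the provisional action-time draw. Two consequences
matter for interpreting green tests. First, passing the parameter-recovery
suites shows the estimators detect the encoded structure, not that real
dyads behave this way. Second, in stationary simulated sessions trailing
smoothing does not systematically *increase* the visibility-following
correlation; in real sessions it typically does, because real following
waxes and wanes slowly and smoothing suppresses trial-level noise
relative to that shared slow component. The package reports both raw and
smoothed coefficients and treats neither as privileged.

## Numerical choices and degenerate inputs

* MI: `0 log 0` terms contribute zero; results are clamped at 0 against
  floating-point cancellation; surrogate thresholds use the empirical
  order statistic (type-1 quantile).
* RPR rejects sessions in which a layout probability is zero (the
  conditional probabilities are undefined); DCR corner fractions and
  reconstructed probabilities are clipped to [0, 1].
* Welch tests with fewer than two usable trials per group, correlations
  on constant series, and switch verdicts without attributed switches are
  flagged (`computable = FALSE`, `undefined = TRUE`, `not_applicable`)
  rather than silently dropped; trials missing either agent's timestamps
  are excluded pairwise from all AT analyses.
* A session length that is not a multiple of 18 ends with a truncated
  freshly-shuffled balanced block: near-balance is preserved without
  rejecting arbitrary session lengths.
* The aligned-phase convention for paired turn-taking strategies (who
  starts on whose colour) is an explicit parameter (`first`), since two
  independently phased alternators would anti-coordinate forever.

## Problem sizes used in the validation suite

The test suite favours exact, desk-scale constructions: the analytic
anchors (DCR of +1/-1/0, MI of 0/1, RPR 2.5, joint rewards 2 and 3.5) use
exactly counterbalanced 200-trial sessions; estimator-vs-oracle
equivalence is exhaustive over all contingency tables up to n = 10 and
all 256 length-8 sequences for surrogate transition counts; the MI
false-positive calibration uses 500 independent 200-trial datasets with
500 surrogate pairs each; permutation-null coverage and the Monte-Carlo
RPR cross-check use 200-500 stratified permutations of 200-trial
sessions; and leader-follower parameter recovery uses five fidelity
levels times twenty 300-trial replicate sessions.

## A worked example

```{r example, eval = FALSE}
cfg <- analysis_config(n_surrogates = 300, seed = 1)
s <- simulate_session(strategy_trial_turn_taking(),
                      strategy_trial_turn_taking(), 400, seed = 20)
b <- analyze_session(s, cfg)
b$dyadic$classification   # "dynamic_turn_taking"
b$dyadic$dcr$dcr          # ~1: all surplus reward is dynamic coordination
b$choice$joint_reward     # 3.5, the maximum
```

## Known limitations

The classifier's dominance and DCR thresholds are conventions exposed as
configuration, not estimated quantities; sessions mixing strategies
mid-way (the interesting transitional cases in real data) are
deliberately out of the stationary simulator's scope and tend to come out
`unclassified`; and the DCR interval is conservative by construction, so
borderline dynamic coordination (DCR just above 0.2 in short sessions)
may be reported non-significant.
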