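---
title: "Simulating micro-targeted election campaigns with credibility-weighted Bayesian voters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating micro-targeted election campaigns with credibility-weighted Bayesian voters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcsim)
```

## The question

A micro-targeted campaign (MTC) uses per-voter data to decide whom to
contact; a broadcast ("stochastic") campaign contacts voters uniformly at
random, the way a billboard or a cold-call bank does. How much extra daily
reach does the broadcast campaign need before it offsets the MTC's
informational advantage? `mtcsim` answers this with an agent-based
simulation of a two-candidate race in which every voter revises their
candidate preference through a Bayesian source-credibility model of
persuasion.

## Voter cognition

Each voter holds a subjective probability $P(h)$ that the hypothesis
$h$ = "the MTC candidate is the right choice" is true, and perceives each
candidate's *trustworthiness* $P(T)$ (intention to report accurately) and
*expertise* $P(E)$ (capability to report accurately). Trust and expertise
are treated as orthogonal and independent. A conditional probability table
gives the chance that a source endorses the hypothesis in each of the eight
(hypothesis, trust, expertise) states; the package default is an
empirically elicited table:

|        | T, E | T, ¬E | ¬T, E | ¬T, ¬E |
|--------|------|-------|-------|--------|
| **h**  | 0.80 | 0.58  | 0.34  | 0.18   |
| **¬h** | 0.22 | 0.42  | 0.59  | 0.71   |

Marginalizing over the voter's graded perception gives the two report
likelihoods

$$p(rep \mid h) = \sum_{t, e} p(rep \mid h, t, e)\, w(t)\, w(e), \qquad
  w(T) = P(T),\; w(\neg T) = 1 - P(T),$$

and likewise for $p(rep \mid \neg h)$ (`marginal_likelihoods()`). A
contacted voter replaces $P(h)$ with the posterior

$$P(h \mid rep) = \frac{P(h)\, p(rep \mid h)}
  {P(h)\, p(rep \mid h) + P(\neg h)\, p(rep \mid \neg h)}$$

for an endorsement; an opposing message is the negated report, so each
likelihood $\ell$ becomes $1 - \ell$ (`posterior_belief()`). Two
consequences drive everything downstream:

* **Backfire.** An endorsement raises belief exactly when
  $p(rep \mid h) > p(rep \mid \neg h)$. With the default table, a voter
  who rates a candidate at trust = expertise = 0.5 sits *inside* the
  backfire region (0.475 < 0.485): messages from a source perceived as
  mediocre push belief the wrong way. At 0.6 the update is favourable.
* **Absorbing certainty.** Priors of exactly 0 or 1 never move.

Perceptions themselves are fixed for the whole campaign: a contact changes
only $P(h)$, never the voter's opinion of the source. A joint model in
which the report also revises trust and expertise is deliberately out of
scope.

## The electorate

`sample_population()` draws, for each of (by default) 10,000 voters and in
a fixed documented order: the initial belief $P(h) \sim N(0.5, 0.25)$
clamped to $[0.01, 1]$; a turnout propensity $P(vote) \sim N(0.5, 0.25)$
clamped to $[0.01, 1]$ and never changed afterwards; and independent trust
and expertise perceptions of each candidate, $N(\mu_{cred}, 0.25)$ clamped
to $[0.01, 0.99]$. The per-candidate *credibility score* is the mean of
trust and expertise; it is the "signalling" quantity the MTC screens on.

Three choices here were genuinely open and are worth stating:

* **Clamping, not rejection sampling.** "Bounded" draws are implemented by
  clamping out-of-range values to the bound. This leaves small point
  masses at the bounds — about 2% of voters start at $P(h) = 1$ and are
  permanent MTC votes. Rejection sampling would remove those masses;
  sensitivity runs showed the aggregate share curves move by well under
  one percentage point either way.
* **Perception bounds.** Trust/expertise bounds are not dictated by the
  belief model; $[0.01, 0.99]$ excludes degenerate certainty about
  sources while keeping the distribution nearly symmetric.
* **The asymmetric belief bound** $[0.01, 1]$ (rather than
  $[0.01, 0.99]$) is kept exactly as specified for the belief and turnout
  draws.

## The two campaigns

Both campaigns contact a fixed number of voters per day (the *reach*),
never the same voter twice in one day, with repeat contacts allowed across
days. The two campaigns may hit the same voter on the same day; updates are
then applied sequentially, MTC first (the order is fixed for
reproducibility; double contacts are rare — with reaches 20 and 100 out of
10,000 voters, about 0.2 expected per day — so the order has no measurable
aggregate effect).

* The **MTC candidate** (`mtc_candidate()`) argues *for* $h$ and each day
  recomputes its eligible pool: voters with $0.25 < P(h) < 0.75$
  (persuadable — not already strongly for or against), credibility score
  $\geq 0.5$ (open to the message rather than prone to backfire), and
  $P(vote) > 0.5$ (worth persuading). It samples `reach` voters uniformly
  from that pool. Because the pool is recomputed from current beliefs, the
  campaign adapts as voters move.
* The **stochastic candidate** (`stochastic_candidate()`) argues *against*
  $h$ and samples its contacts uniformly from the whole electorate, using
  no voter information.

The direction convention deserves a note: the two candidates necessarily
argue opposite stances, and the model is symmetric under relabelling the
hypothesis, so fixing $h$ = "vote MTC" with the MTC endorsing and the
broadcaster opposing preserves the voting rule ($P(h) > 0.5$ favours the
MTC candidate) while resolving the ambiguity about which candidate
"represents" which pole. An opposing message is modelled as the negated
report ($\ell \to 1-\ell$); the algebraically distinct alternative — the
broadcaster endorses its own complementary hypothesis — was implemented in
a sensitivity check and shifts the aggregate curves by less than half a
point of vote share.

## One run, one election

`run_simulation()` draws the population, runs 50 daily ticks, then holds
the election: each voter casts a ballot with probability $P(vote)$; cast
ballots go to the MTC candidate when $P(h) > 0.5$, to the broadcaster when
$P(h) < 0.5$, and are decided by a fair coin at exactly 0.5 (unreachable at
initialization but reachable in principle after updates). A single integer
seed fixes the population draw, every day's contact samples and the
election draws, in that order, so runs are bit-reproducible; a naive
per-agent reference engine (`run_simulation_reference()`) reproduces the
vectorized engine exactly and guards against vectorization bugs.

Numerical edge cases are handled conservatively: a zero denominator in the
posterior (possible only with a degenerate conditional table) returns the
prior unchanged with a warning, and beliefs remain in $[0,1]$ by
construction since every update is a ratio of non-negative terms.

## The sweep and the break-even ratio

`run_sweep()` crosses mean credibility perceptions for the two candidates
(defaults $\{0.4, 0.5, 0.6\}$ each) with a grid of reach ratios (broadcast
reach / MTC reach; MTC reach fixed at 20; default ratios 0.5–5 in steps of
0.5, i.e. 10–100 contacts per day) and replicates each cell (default 100
times), 9,000 runs in all. Per-run seeds are derived deterministically from
a base seed and the run's grid position, so the sweep is reproducible and
order-independent (and safe to parallelize). Broadcast reach after scaling
is rounded to the nearest integer.

For each credibility pairing, `estimate_breakeven()` linearly interpolates
mean MTC vote share against ratio and reports the smallest ratio at which
the curve crosses 0.5. Linear interpolation between adjacent grid means is
the simplest defensible estimator; note that near the crossing the curves
are very flat (the mean share falls by roughly 0.006 per unit of ratio), so
with finite repetitions the first-crossing rule carries a slight downward
bias and a standard error of a few tenths of a ratio unit. The package's
reproduction runs use 50–100 repetitions per ratio on a 0.25-step grid
around each crossing, which keeps that uncertainty near ±0.1–0.2.

What the simulations show, robustly across seeds:

* at equal reach, the MTC candidate wins every credibility pairing;
* a broadcast candidate perceived at $\mu_{cred} = 0.4$ — and, with this
  conditional table, even at 0.5 — *loses* vote share as its reach grows,
  because most of its contacts backfire; visibility is a liability for a
  disliked candidate;
* a disliked MTC candidate ($\mu = 0.4$) beats a moderately liked
  broadcaster ($\mu = 0.5$) at every swept ratio, by screening out its own
  backfire-prone voters;
* with both candidates at $\mu = 0.6$, the broadcaster needs roughly 4
  times the MTC's reach to break even; with a credibility advantage (0.6
  vs the MTC's 0.5) it still needs about 3 times.

## What the generator does and does not emulate

The synthetic electorate captures heterogeneity in prior preference,
turnout propensity and per-candidate credibility perception, which is what
the targeting mechanism exploits. It does not model policy preferences,
social ties between voters, geography or electoral institutions, media
environments, or noisy voter data on the MTC's side — a perfectly accurate
voter model is assumed, so results are a *best case* for targeting.
Passing tests therefore demonstrate properties of this stylized cognitive
model at the population scale, not forecasts for any real election.

## Problem sizes used by the test suite

Unit and property tests run on electorates of 1–5,000 voters. The
full-scale reproduction checks use the study conditions — 10,000 voters,
50 ticks, MTC reach 20 — with 50 repetitions per ratio for the two
break-even sweeps (0.25-step ratio grids), 100 repetitions per cell for
the equal-reach check, and 30 repetitions per cell for the
reach-liability and disliked-MTC checks, sizes at which the Monte Carlo
standard error of a cell mean (≈0.001–0.0015 of vote share) is well below
every margin being asserted.

## Session example

```{r example, eval = FALSE}
run <- run_simulation(run_config(
  population = population_config(cred_mean_mtc = 0.6, cred_mean_stoch = 0.6),
  candidates = list(mtc_candidate(20), stochastic_candidate(40)),
  seed = 2025
))
glance(run)

sw <- run_sweep(sweep_config(
  cred_means_mtc = 0.6, cred_means_stoch = 0.6,
  reach_ratios = seq(3.5, 6, by = 0.25), reps = 50
))
sw$breakeven
autoplot(sw)
```
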