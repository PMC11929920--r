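---
title: "Designing allocation mechanisms for a common-pool trust game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing allocation mechanisms for a common-pool trust game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The game

`commonpool` studies a repeated multiplayer trust game built around a
regenerating common-pool resource. A social planner (the *mechanism*)
controls a pool of size $R_t$, capped at a carrying capacity $R_0$. Each
round it allocates endowments $e_{i,t}$ to $p$ players (with
$\sum_i e_{i,t} \le R_t$); each player freely returns a reciprocation
$0 \le c_{i,t} \le e_{i,t}$ to the pool, keeping the surplus
$s_{i,t} = e_{i,t} - c_{i,t}$. Reciprocations earn interest at growth
factor $r$, and the pool updates as

$$R_{t+1} = \min\!\big(R_0,\; R_t - \textstyle\sum_i e_{i,t} + (1+r)\sum_i c_{i,t}\big).$$

The planner's objective is aggregate welfare, $\sum_i \sum_t s_{i,t}$.
Throughout we use the default configuration $p = 4$, $R_0 = 200$,
$r = 0.4$ and a 40-round horizon; a geometric termination rule (minimum 25
rounds, then a 0.2 per-round end probability) is available via
`game_config(min_rounds =, end_prob =)` for sessions of consecutive games.

Two structural facts shape everything else. First, if every player returns
the fraction $1/(1+r)$ of each endowment, the interest exactly restores
what was allocated, so the pool is sustained indefinitely while each player
keeps the fraction $r/(1+r)$ — about 29% at $r = 0.4$
(`sustainable_keep_fraction()`). Second, the pool cannot recover from zero:
once depleted, no further allocation or surplus is possible, so short-run
greed destroys all future welfare.

Interface conventions mirror a human-facing implementation: offers below
one resource unit cannot be acted on (the recipient keeps the amount and is
forced to reciprocate zero), and an integer-contribution mode restricts
reciprocations to whole units. The unit threshold (default 1.0) is shared
by the analysis definitions of *active players*, *pool depletion* and
*exclusions*, and is configurable.

## Hand-coded mechanisms

The weighted baseline family mixes an equal and a proportional allocation
with weight $w$:

$$e_{i,t} = w\,\frac{R_t}{p} + (1-w)\,R_t\,\frac{c_{i,t-1}}{\sum_j c_{j,t-1}},$$

with an equal split on the opening round. `mechanism_equal()` ($w=1$),
`mechanism_mixed()` ($w=0.5$) and `mechanism_proportional()` ($w=0$) are
the named members. Design choices worth stating:

* **Zero-denominator rule.** When nobody reciprocated on the previous
  round, the proportional term allocates zero to everyone (so at $w = 0$
  the whole group is excluded and the entire pool is retained).
  This extends the poverty-trap logic of proportionality — a defector is
  instantly and permanently excluded — to the degenerate group case.
* **Residual fraction.** The family optionally withholds a fraction of the
  pool (0–40%) from allocation, mirroring an early data-collection
  parameter; it defaults to 0 because fully allocating mechanisms dominate.
* The random baseline draws $p+1$ proportions from a flat Dirichlet each
  round: four offers plus a retained share.

The *interpolating* baseline conditions equality on abundance: the mixing
weight is a power law of the normalised pool, $w = (R/R_0)^k$. At a full
pool it is exactly equal; for large $k$ it is essentially proportional
anywhere below the cap. `calibrate_interpolating_exponent()` grid-searches
$k$ over $\log k \in \{-5, -4.9, \dots, 5\}$ (natural logs — the grid then
contains a candidate near the exponent 22 that this family is known to
select) by simulated surplus, breaking ties toward the larger, more
proportional exponent, since the high-exponent regime is the interesting
one. Candidates are compared on matched player draws and episode seeds so
the comparison is paired.

## Synthetic players

Scripted archetypes stand in for human participants so that every stage of
the pipeline runs with no external data:

* **Sustainer** — always returns $1/(1+r)$ of its offer, the largest
  self-sustaining reciprocation; optional truncated-Gaussian noise on the
  fraction.
* **Free rider** — returns a fixed (default zero) fraction; an optional
  `cooperate_rounds` parameter makes it play sustainably for a number of
  opening rounds first, so corpora can contain defection events at
  controlled times.
* **Conditional cooperator** — matches the mean reciprocation fraction its
  co-players showed on the previous round, starting from the sustainable
  fraction. Co-players whose previous offer was below one unit are ignored
  in that mean: their zero was forced by the interface, not chosen, so it
  carries no behavioural signal. When no co-player acted observably the
  previous target is kept.
* **Grim trigger** — cooperates at the sustainable fraction until it ever
  observes a co-player's fraction below a threshold (default 0.1), then
  returns zero forever. Its action depends on the whole history rather
  than the last round, which is exactly what makes it useful: it gives the
  imitation learner something that *requires* memory.

Noise is always applied to the reciprocation *fraction* and truncated to
$[0, 1]$, never to the amount, so the contract $0 \le c \le e$ holds by
construction. `generate_fixture_logs()` assembles corpora by sampling a
mechanism (including the weighted family with $w \sim U(0,1)$, as in the
original data-collection design) and a player set per game.

## Behavioural cloning

Virtual players are recurrent probabilistic policies trained by supervised
imitation on episode logs. The observation is everything a seated player
sees: the current round's offers to all players, everyone's previous-round
contribution, and the pool — $2p + 1 = 9$ values, divided by the
normaliser 200 and rotated so the focal player sits in slot 1 (each player
sees themself as "player 1"). The network is two fully connected encoder
layers, a GRU memory core, two fully connected decoder layers and a linear
head with $N$ logits.

The action head is a *categorical-uniform* distribution: the $N$ bins
partition the proportion of the offer reciprocated, a bin is chosen from
the logits, and the continuous action is drawn uniformly within the bin,
$c = e\,(b + u)/N$. We read the bins as partitioning $[0,1]$ in proportion
space (the literal index interval would produce proportions above 1).
$N$ defaults to 10 and is configurable, as are all widths (64/64 encoder
and decoder with a GRU of 32 at full scale; tests run smaller). Training
minimises masked cross-entropy by back-propagation through time with Adam
and an exponentially annealed learning rate (multiply by 0.95 every 1000
updates from 5e-4 to a 5e-6 floor, the reference recipe). Rounds where the
focal offer is below one unit are excluded from the loss — the action
there is forced, so it says nothing about the player.

Inference modes: `argmax_uniform` (modal bin, ties to the lowest index,
then uniform within the bin — the reference inference), `sample_full`
(categorical draw first), and `expectation` (the deterministic mean
action, used to make rollouts differentiable). Note a small structural
bias of `argmax_uniform`: if the data concentrate in one bin, the rollout
mean is the bin centre (e.g. 0.75 for bin 7 of 10) rather than the data
mean (0.714 for noisy sustainers); at $N = 10$ this bias is at most
$1/(2N) = 0.05$ and is visible in the clone-recovery check.

Ensembles are assembled by simulation-based selection: each checkpoint
plays games with four copies of itself under the hand-coded baselines
(scoring high surplus is good) and under the random mechanism (scoring
high surplus there indicates exploiting arbitrary allocations, and is
penalised with weight $\lambda$); the top $m$ checkpoints form the
ensemble, sampled with replacement into episode slots during mechanism
training, or pinned one-per-slot for analysis.

## The graph-network mechanism

The learned planner is a permutation-equivariant graph network. Players
are vertices of a fully connected directed graph carrying (previous
endowment, previous contribution, pool), all normalised; edges start
empty; the global attribute is the pool. A block updates edges, then
nodes (from summed incoming updated edges), then the global attribute,
with the same functions shared across edges and nodes — weight sharing
plus sum aggregation gives equivariance and a uniform opening move by
construction, properties the test suite checks for arbitrary parameters.
Block 1 uses single nonlinear layers of width 32; block 2 uses a
nonlinear edge layer (32), a node update through a GRU memory of size 16
(persistent across rounds within an episode) followed by a nonlinear 32
layer and a linear scalar head, and a global update through a nonlinear
32 layer and a linear scalar head. The four node scalars and the global
scalar are softmax-normalised into five allocation weights; multiplied by
the pool they give the four offers and the retained amount, so
feasibility ($\sum e + \text{retained} = R$) is exact at every round. A
memoryless variant replaces the GRU with a dense layer of the same width.

Training is gradient ascent on cumulative surplus through the entire
rollout: the pool update, the mechanism and the players are all
differentiable, so the objective's gradient is exact rather than
estimated. Two gradient modes exist because the virtual players are
stochastic: `expected_action` replaces each player's draw with its mean
action, making rollouts deterministic and runs bitwise reproducible (the
default); `pathwise_sample` keeps sampled proportions and differentiates
through them, matching a sample-gradient treatment of the
categorical-uniform distribution. The sub-unit offer rule enters the
rollout as a constant gate (its own gradient is zero); this is the one
genuine non-smoothness of the environment, discussed under limitations.
Adam with the annealed schedule (reference recipe 1e-3 decaying 0.05
every 1000 steps to 1e-5) trains the weights; checkpoints are scored by
mean surplus on a fixed set of evaluation seeds (32 at full scale, fewer
in tests — fixed seeds make checkpoint ranking stable), and selection
takes the highest scorer with ties to the later checkpoint. A retraining
preset with a larger memory and a bigger clone pool is a configuration,
not separate code.

## Analysis suite

`episode_metrics()` and friends compute the descriptive quantities used to
compare mechanisms: total and per-player surplus; the Gini coefficient of
aggregate player surplus (mean absolute pairwise difference over twice the
mean, defined as 0 for an all-zero vector — after a collapse nobody gets
anything, which is perfect equality); mean *active players* (offers of at
least one unit); the *depletion trial* (first round the pool drops below
one unit, or the horizon); and a sustained/depleted split at the same
threshold. `exclusion_events()` finds runs of sub-unit offers that follow
an inclusion, flagging runs that reach the final trial as never
reincluded; a sub-unit offer on the very first trial is poverty, not an
exclusion. `lagged_offer_regression()` regresses, per trial, the offer on
the focal player's reciprocations at lags $-4..+4$ (players pooled within
trial across games — the per-player alternative is noisier and was the
open choice), reporting per-lag medians; zero-variance regressors get zero
weight rather than failing, because constant-offer mechanisms are
legitimate inputs. The proportional mechanism's profile concentrates at
lag $-1$ by construction, a pattern the tests verify.

## What the synthetic fixtures do and do not show

The fixture generator reproduces the *structure* of gameplay data —
heterogeneous reciprocation styles, defections and poverty traps, offers
spanning equal to proportional regimes — but not the richness of human
behaviour: no end-game effects, no learning across games, no reaction to
instructions, and archetype noise is i.i.d. Gaussian on fractions rather
than human variability. Passing tests therefore demonstrate that the
pipeline is correct and that its components behave as designed (clones
recover the populations they imitate; the trained mechanism improves the
objective and beats the equal baseline on populations with free riders);
they do not reproduce effect sizes measured on human cohorts, which
require the deposited human dataset as input. The pipeline accepts such a
dataset through the same JSON Lines reader used for fixtures.

## Numerical choices and problem sizes

* Feasibility and conservation tolerances are 1e-9 relative; offer
  overshoot from floating arithmetic is rescaled, never errored.
* Geometric episode lengths are `min_rounds` plus a geometric count of
  post-minimum survivals at probability `1 - end_prob` (expectation 29 at
  25/0.2). The empirical mean reported for human sessions under this rule
  is slightly lower; the rule as stated is what is implemented.
* Argmax ties break to the lowest bin; checkpoint-selection ties to the
  later checkpoint; calibration ties to the larger exponent.
* All randomness threads through explicit seeds; every training loop
  restores the caller's RNG state. Fixture corpora, clone training and
  expected-action mechanism training are bitwise reproducible.
* Desk-scale sizes used by the test suite and the acceptance script:
  200/120 fixture games for clone recovery, 80 games for the grim memory
  check, 300–400 imitation updates at widths 32/16, 150 mechanism updates
  at width 16 with 4 evaluation seeds, 8 episodes per calibration
  candidate over the 101-point grid. Full-scale defaults (reference
  learning schedules, widths 64/32, 500k/700k updates) remain available
  through the same configuration objects.

## Known limitations

* The sub-unit gate makes the training objective piecewise smooth. The
  gradient cannot see the benefit of pushing a free rider's offer *below*
  the unit threshold (which would remove them from conditional
  cooperators' imitation targets), so desk-scale training reliably
  improves over its initialisation and over the equal baseline but may
  settle short of the exclusion policies that grid search or longer
  stochastic training discover.
* The autodiff tape is minimal by design (matrix ops with hand-written
  adjoints, gradient-checked); it favours clarity and reproducibility
  over speed, which is why the documented desk scales are modest.
* Lag regressions pool players within trials; mechanisms whose policies
  differ qualitatively per player would need the per-player variant.
* Clone ensembles are only as good as their training corpus; selection by
  baseline-vs-random surplus is a heuristic filter, not a guarantee of
  behavioural fidelity out of distribution.

## Reproducing the headline numbers

`scripts/acceptance.R` reruns the full desk-scale pipeline — the
sustainability constant, interpolation weights, baseline comparisons,
exponent calibration, clone recovery and mechanism training — from a
single seed and writes the resulting quantities to JSON. See the README
for the exact invocation.
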