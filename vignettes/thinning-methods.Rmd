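---
title: "Rejection-based simulation of heterogeneous, non-Markovian systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rejection-based simulation of heterogeneous, non-Markovian systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicsim)
```

## The problem

The classical Gillespie stochastic simulation algorithm is exact for
Markovian reaction networks: propensities depend only on the current state,
waiting times are exponential, and agents of one species are statistically
identical.  Many biological and social systems violate all three
assumptions at once.  Cells carry individual receptor affinities; nascent
transcripts carry individual elongation clocks with Gamma-distributed
completion times; people interact in bursts separated by heavy-tailed
quiescent periods.  Enumerating every agent (or agent pair) as its own
reaction channel restores heterogeneity but makes each step cost O(N) or
O(log N) with queue-based variants.

`mosaicsim` implements the alternative: thinning (rejection sampling) of
the superposed process.  Track only a dominating rate
$\lambda_{\max} \ge \max_j \lambda_j(t_j)$ over the $N$ live processes,
where $t_j = T - \tau_j$ is the elapsed time since process $j$ last fired
(only the timestamp $\tau_j$ is stored).  Each iteration:

1. refresh $\lambda_{\max}$;
2. advance the global clock by $\Delta t = \ln(1/u) / (N \lambda_{\max})$,
   $u \sim U(0,1]$;
3. propose one process uniformly (probability $1/N$);
4. accept with probability $\lambda_j(t_j) / \lambda_{\max}$, resetting
   $\tau_j \leftarrow T$ and applying the model's state update on
   acceptance; a rejected iteration changes nothing but the clock.

Proposals cost O(1) regardless of $N$; the price is the rejection factor
$r$, the mean number of candidate iterations per accepted event, which
grows linearly in $\lambda_{\max}/\lambda_0$ (bound over mean event rate)
and is independent of system size.

## Waiting-time families and dominating rates

Every process carries an inter-event-time distribution (IED) exposed
through its hazard $\lambda(t) = \psi(t) / (1 - F(t))$.  The engine needs
an upper bound on the hazard, and the right strategy depends on the
hazard's shape:

* **Bounded** (exponential; Gamma with shape > 1, bounded by its asymptote
  `shape * lambda0`; Pareto, bounded by `alpha / t_min`; log-normal,
  bounded at its numerically located mode; delayed exponential): a
  constant analytic bound, fixed for the whole run.
* **Increasing unbounded** (Weibull with shape > 1): the process with the
  oldest clock dominates; the bound is its hazard at the current elapsed
  time, and the identity of the oldest clock changes only when it fires.
* **Decreasing unbounded** (Weibull or Gamma with shape < 1): the bound
  diverges whenever a clock resets, so thinning degenerates; such channels
  are refused unless the user supplies an explicit bound.
* **Piecewise/custom**: user-supplied interval bounds.

The Gamma hazard is evaluated in log space through the regularized upper
incomplete gamma function, so it is stable at arguments far into the tail.
The Pareto hazard is defined as 0 before `t_min` (no event can occur
before the minimum waiting time) and $\alpha/t$ afterwards, which is why a
constant bound works.

## Exactness, and the finite-step approximation

With the candidate's hazard evaluated at the *post-advance* elapsed time
and a bound that dominates it there, thinning is exact — this is the
classical Lewis–Shedler result, and it is the package default
(`hazard_eval = "updated"`).  A widely used variant evaluates the hazard
with the clock frozen at the iteration start.  The evaluation then lags
the true elapsed time by one increment (mean $1/(N\lambda_{\max})$), and
the per-candidate acceptance distortion is

$$\mathbb{E}[\text{error}] \sim
  \frac{\langle \lambda' \rangle}{N\,\lambda_{\max}^2},
  \qquad \langle\lambda'\rangle = \int_0^\infty \lambda'(t)\,\psi(t)\,dt ,$$

vanishing quadratically as the bound is raised while the cost grows only
linearly.  The engine exposes this semantics as `hazard_eval = "stale"` so
the accuracy–efficiency trade-off can be measured; the acceptance suite
verifies the quadratic law on the per-candidate error.  Note the
distinction: the Earth Mover's Distance between simulated and analytic
inter-event times is a per-*event* error and scales as
$1/\lambda_{\max}$, because each accepted event consumes
$r \propto \lambda_{\max}$ candidates.  Under the default semantics both
vanish to the Monte-Carlo floor at any valid bound.

A bound that fails to dominate the hazard is a *hard error*, never a
silent clip: clipping the acceptance ratio at 1 would bias the sampled
IED invisibly.  (An `adaptive_clip` policy exists for experimentation —
bound = multiplier × current maximum rate, overshoot clipped and counted —
but none of the shipped models use it.)

## Grouped bounds

The uniform proposal with one global bound is wasteful when channel
hazards span orders of magnitude: the global bound is dictated by the
fastest channel and every slow channel pays for it in rejections.  The
compiled model cores therefore group channels by kind and give each group
its own bound $\lambda^{(c)}_{\max}$, proposing group $c$ with probability
proportional to $n_c \lambda^{(c)}_{\max}$ and advancing time by
$\Delta t = \ln(1/u) / \sum_c n_c \lambda^{(c)}_{\max}$.  The
uniform-global scheme is the special case of equal group bounds, and the
acceptance rule within a group is unchanged, so exactness carries over.
Markovian channels (exponential hazards, possibly state-dependent rates
that are constant between events) use their current propensity as the
group bound and never reject.  With this arrangement the only rejecting
channel in the Hes1 model is the Gamma elongation step, and the
whole-model rejection factor settles near 1.6 independently of system
size.

## The three reference models

### Germinal-center affinity maturation (`run_gc`)

Agent-based B-cell selection with five exponential channels (rates per
hour, scale $\beta$):

| channel | rule | default rate |
|---|---|---|
| binding | free B + free T → bound pair | 0.146 per (B,T) pair |
| competition | bound pair + free challenger; accepted only if the challenger's affinity is *strictly* higher | 0.146 per (pair, challenger) |
| apoptosis | free B → ∅ | 0.084 per cell |
| unbinding | bound pair → division-ready B + free T | 2 per pair |
| division | division-ready B → two free daughters | 0.134 per cell |

Daughters update their affinity by $a \mapsto a + (u - a)/\beta$ with
$u \sim U[0,1]$ and $\beta = 10$, a contraction that keeps affinities in
$[0,1]$ and makes gains harder as affinity grows.  Affinities start at 0;
the defaults are $N_B = 1000$ cells, $N_T = 10$ T cells, 50 days.
Pairwise channels are never enumerated: a candidate (pair, challenger) is
drawn uniformly and thinned through the strict-affinity rule with the
fixed bound $\lambda_{BT}$, which is the whole point of the O(1) claim.
Interpretation choices that the channel list leaves open, declared here:
apoptosis applies to free cells only (bound and division-ready cells hold
or act on survival signals); both daughters receive independent affinity
updates; a displaced cell returns to the free pool immediately; clones
are indexed by founder cell; T cells are interchangeable.

### Hes1 delayed negative feedback (`run_hes1`)

Nascent RNA initiates at rate $\beta \, G(N_P)$ with the Hill repression
$G(N_P) = 1/(1 + (N_P/\beta)^{4.1})$, elongates with a per-molecule Gamma
hazard (shape 3, rate $3\lambda_0$, mean $1/\lambda_0 = 20$ min), matures
into mRNA, is translated at 0.01/min, and both mRNA and protein degrade
exponentially (0.029 and 0.031/min).  Resource limitation couples the
baseline rate to the transcript load,
$\lambda_0 = \tau_0^{-1} (1 + \gamma (N_N + N_M)/\beta)^{-1}$: with
$\gamma > 0$ every nascent molecule's hazard is rescaled *instantaneously*
as transcripts accumulate.  A delay-queue scheduler cannot express this —
it freezes each delay at initiation — which is why `delay_ssa_hes1()`
refuses $\gamma \ne 0$ and serves as the exact reference only in the
state-independent regime.  The elapsed elongation clocks are kept and the
hazard is re-evaluated with the *current* $\lambda_0$
(instantaneous-rate semantics); integrated-hazard rescaling is a
different modeling choice, not implemented.  Initial condition (not fixed
by the channel list): all counts zero; oscillation statistics in the
tests discard a 400-minute burn-in, and the period estimator is the
dominant spectral component of the replicate-averaged mRNA signal.  For
small systems `strict = TRUE` inflates the elongation bound so that
$N\lambda_{\max} \ge 20\lambda_0$, capping the mean candidate step at
$1/(20\lambda_0)$.

### Temporal contact networks (`run_facetoface`)

Each node carries a clock $t_i$ (time since its last interaction) and
Pareto activity with hazard $\alpha_A / t$ beyond
$t_{\min} = 2^{-1/\alpha_A}/\lambda_A$, where $\lambda_A$ is the
reciprocal *median* waiting time (finite even when the mean diverges).
Pairs form through the multiplicative kernel
$\Lambda_{ij} = \lambda_i(t_i)\lambda_j(t_j) / ((N_A - 1)\lambda_A)$,
bounded globally by
$\Lambda_{\max} = \lambda_{\max}^2 / ((N_A-1)\lambda_A)$ with
$\lambda_{\max} = \alpha_A / t_{\min}$; both participating clocks reset on
formation.  Active edges terminate through their own Pareto process, and
formation and termination channels share one thinning loop whose proposal
rate counts admissible (currently inactive) pairs plus active edges.
Defaults are the conference fit: 274 nodes, 7249 ticks,
$\alpha_A = 0.76$, $\lambda_A = 0.4$, $\alpha_\varnothing = 1.4$,
$\lambda_\varnothing = 0.61$.

Partner memory (variant B) multiplies the proposal weight of previous
partners by $w$ once the first node is drawn, leaving the acceptance rule
unchanged.  Routing the same preference through the kernel under uniform
proposals (bound $w\Lambda_{\max}$) targets similar dynamics but pays
roughly $w$ times more rejections; at $w = 1$ the two routes coincide
exactly, which the tests use as a cross-check.

Declared choices where the formulation is open: node clocks reset on
formation only (not on termination); a pair with an active edge is
excluded from formation proposals (at most one edge per pair); edges
still open at the horizon are reported censored at the horizon; all
clocks start fresh at $t = 0$.

**Known limitation — activity quenching.**  Under the default
parameterization the multiplicative kernel admits no stationary activity
level: the normalization uses the constant reciprocal-median rate
$\lambda_A$, while the population mean hazard of an aging Pareto ensemble
decays, so the two cannot balance and simulated activity is a burst that
progressively freezes.  A run at the default size produces a few hundred
contacts, concentrated early.  The *bulk* of the node-interduration
distribution nevertheless approaches the intrinsic Pareto law as the
network grows — the acceptance suite measures this with a
quantile-truncated Earth Mover's Distance — but long-horizon contact
volumes and dense aggregated graphs should not be expected from this
kernel.  Network-metric functions are therefore exercised on synthetic
contact fixtures as well as on simulated output.

## Validation statistics

* `emd_to_ied()` estimates the 1-D first Wasserstein distance on the
  quantile scale, $\int_0^1 |F_n^{-1} - F^{-1}|\,dp$, averaging over
  plotting positions.  For heavy-tailed references (Pareto with
  $\alpha \le 1$) the untruncated distance has infinite expectation, so a
  quantile-truncation argument restricts the integral; the truncation
  level is part of the diagnostic's definition.
* `error_diagnostic()` applies this to one channel of a finished run and
  refuses (rather than returning zero) below 100 accepted events.
* `rmsd_ensembles()` implements the trajectory-comparison protocol:
  1-minute binning (last value carried forward), replicate averaging,
  normalization by the system scale, RMSD over grid points and species.
  The replicate-to-replicate RMSD between two independent reference
  ensembles defines the noise baseline.  The full protocol scales the
  ensemble size as $10^4/\sqrt\beta$; the shipped tests use 50 replicates
  at $\beta = 25$ over 500 minutes and require the cross-simulator RMSD to
  stay within 1.5× the averaged baseline.
* `interaction_score_graph()` sums pairwise interaction durations,
  log-transforms (natural log; sums below one tick are floored at one so
  scores stay non-negative — both choices declared, since the transform's
  base and the sub-tick behavior are conventions), normalizes by the
  maximum, and keeps pairs with score > 0.4.  Scores are *not* invariant
  to a global change of time unit (the log shifts before normalization);
  their ordering is, and times are defined in data ticks.  With a single
  interacting pair the normalization makes its score exactly 1 — a
  degenerate but well-defined case.
* `aggregated_metrics()` reports average local clustering (isolates count
  as zero), global transitivity, edge density, degree assortativity, and
  Louvain modularity at resolution 1 averaged over 10 partition seeds
  (Louvain is stochastic); edgeless graphs report density 0 and `NA`
  elsewhere.

## Reproducibility and numerical conventions

One RNG stream per run (R's generator, seeded from the run seed) drives
the fixed draw order: time increment, candidate selection, acceptance —
the acceptance draw is a fresh deviate, independent of the increment's
(standard thinning; reusing the increment's deviate would correlate step
length with acceptance).  Identical seeds give bit-identical event logs in
both the R engine and the compiled cores.  Channel removal is
swap-and-pop, so uniform proposals always range over the live registry.
`t_end = 0` returns an empty log; negative horizons are errors; a run
whose population dies out ends early with an explicit extinction flag.
Time units are per-model (hours for the germinal center, minutes for
Hes1, data ticks for networks); the engine itself is unit-agnostic.

Problem sizes in the shipped suites were chosen so the full test run
completes in about a minute on one core while keeping every statistical
assertion's noise well inside its margin: renewal validations use
10⁴–4×10⁴ events, the Markovian-equivalence tests 10⁴ events, the
germinal-center acceptance check 10 replicates at full size
($N_B = 1000$, 50 days), and the Hes1 rejection-factor scan the full
$\beta \in \{25, 100, 400\}$ grid with 5 seeds each.

## A worked example

```{r, eval = FALSE}
library(mosaicsim)

# affinity maturation at the default study conditions
gc <- run_gc(n_b = 1000, n_t = 10, t_end_days = 50, seed = 1)
tail(gc$trajectory[, c("time", "n_total", "mean_affinity", "dominance")], 1)

# Hes1 rejection factor across system sizes
scan <- hes1_rejection_scan(betas = c(25, 100, 400), n_seeds = 2)
tapply(scan$r, scan$beta, mean)

# a single Gamma elongation channel against its renewal density
r <- mosaic_run(renewal_model(ied_gamma(3, 0.05)), t_end = Inf,
                seed = 1, max_steps = 32000)
c(mean = mean(interevent_times(r)),
  emd = error_diagnostic(r, ied_gamma(3, 0.05)))
```
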