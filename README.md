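# mosaicsim

Event-driven stochastic simulation for systems whose agents carry
**individual properties** and **non-exponential waiting times** — the two
features the classical Gillespie algorithm cannot express without
enumerating every agent (or agent pair) as its own reaction channel.

`mosaicsim` is aimed at modelers in systems biology and network science
who need exact-in-distribution, seed-reproducible trajectories for
agent-heterogeneous processes: per-cell receptor affinities under
competitive selection, per-molecule delay clocks under feedback, per-node
bursty activity in temporal contact networks.

## The algorithm

Each of the `N` live processes `j` keeps only the timestamp `τ_j` of its
last event; its elapsed time is `t_j = T − τ_j` and its instantaneous rate
(hazard) is `λ_j(t_j) = ψ_j(t_j) / (1 − F_j(t_j))` for an arbitrary
inter-event-time density `ψ_j`.  The engine tracks a dominating rate
`λ_max ≥ max_j λ_j(t_j)` and iterates:

1. advance the clock by `Δt = ln(1/u) / (N · λ_max)`, `u ~ U(0,1]`;
2. propose one process uniformly (`p_j = 1/N`);
3. accept with probability `λ_j(t_j) / λ_max`; on acceptance reset
   `τ_j ← T` and apply the model's state update, otherwise only the clock
   has moved.

This is thinning of the superposed point process: exact for any valid
bound, O(1) work per candidate event, no reaction queue.  The cost is the
rejection factor `r` (candidates per accepted event), which grows linearly
in `λ_max / λ_0` and is independent of system size.  Per-family bound
strategies (constant for Pareto/Gamma-shape>1/exponential, oldest-clock
for increasing Weibull, refusal with override for decreasing-unbounded
hazards) keep the bound maintenance O(1).

The package ships:

* `R/` engine: `mosaic_model()` / `mosaic_run()` (pure-R reference
  implementation), hazard families (`ied_gamma()`, `ied_pareto()`,
  `ied_weibull()`, …) with analytic bounds and exact oracle samplers;
* compiled cores for three reference models:
  `run_gc()` (germinal-center affinity maturation with pairwise
  competition), `run_hes1()` (Hes1 transcription with state-dependent
  Gamma elongation delays), `run_facetoface()` (non-Markovian temporal
  contact networks with optional partner memory);
* baselines: `gillespie_run()` (direct SSA) and `delay_ssa_hes1()`
  (delay-queue SSA, exact for state-independent delays);
* validation statistics: Earth Mover's Distance diagnostics
  (`emd_to_ied()`, `error_diagnostic()`), trajectory-ensemble RMSD
  (`rmsd_ensembles()`), temporal-network interdurations and
  aggregated-graph metrics (`interdurations()`,
  `interaction_score_graph()`, `aggregated_metrics()`);
* config/TSV IO and a thin CLI (`inst/scripts/mosaic`).

## A worked example

```r
library(mosaicsim)

# 50 days of affinity maturation: 1000 B cells, 10 T cells
gc <- run_gc(n_b = 1000, n_t = 10, t_end_days = 50, seed = 1)
tail(gc$trajectory[, c("time", "n_total", "mean_affinity", "dominance")], 1)
#>      time n_total mean_affinity dominance
#> 1201 1200     385     0.7123975 0.5766234
```

After 1200 hours the population has settled near 400 cells, the
population-mean receptor affinity has climbed from 0 to ≈ 0.71 (selection
through strictly-higher-affinity displacement plus contraction-mutation at
division), and the largest clonal family holds ≈ 58% of the living cells.

```r
# rejection factor of the Hes1 circuit, flat across system size
scan <- hes1_rejection_scan(betas = c(25, 100, 400), n_seeds = 2)
tapply(scan$r, scan$beta, mean)
#>       25      100      400
#> 1.546290 1.546388 1.548067
```

Candidate iterations per accepted event stay ≈ 1.55 whether the system
holds tens or thousands of molecules — the constant-cost signature of the
rejection scheme (only the Gamma elongation channel ever rejects).

```r
# one isolated elongation channel against its analytic renewal density
r <- mosaic_run(renewal_model(ied_gamma(3, 0.05)), t_end = Inf,
                seed = 1, max_steps = 32000)
c(mean = mean(interevent_times(r)), emd = error_diagnostic(r, ied_gamma(3, 0.05)))
#>       mean        emd
#> 20.1329050  0.1642802
```

The simulated inter-event times average 20.1 minutes against the analytic
mean of 20, with an Earth Mover's Distance of 0.16 minutes (0.8% of the
mean) to the exact Gamma density.

See `vignettes/thinning-methods.Rmd` for the model details, bound
strategies, exactness discussion, and declared conventions.

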