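# agonet

Analysis of agonistic-interaction event logs from group-housed animals:
do social-network centralities capture the same rank order as classical
dyadic dominance indices?

After pigs are rehoused and mixed, they fight until a dominance hierarchy
stabilises. Each recorded interaction carries an initiator and a receiver
and — when it ends with clear submission — a winner and a loser. `agonet`
computes, from such time-stamped logs:

* the dominance indices
  **DI1** = (wins − defeats)/(wins + defeats) and
  **DI2** = (wins·P<sub>won</sub> − defeats·P<sub>lost</sub>) /
  ((wins + defeats)·(n − 1)), where P<sub>won</sub>/P<sub>lost</sub> count
  distinct pen mates beaten / lost to and n is the group size; both range
  over [−1, +1] and are undefined for animals with no decisive fight;
* five centralities (raw/standardized in- and out-degree, ingoing and
  outgoing closeness with the Wasserman–Faust reachability correction, and
  directed betweenness normalized by (n−1)(n−2)) on two directed networks
  per pen: initiator→receiver (IR) and winner→loser (WL), with repeated
  edges aggregated;
* rising cumulative time-window series of all parameters with Spearman
  rank-correlation trajectories between indices and centralities;
* absolute differences between subsequent rank positions on a common
  [0, 1] scale, with fixed-effects contrasts of every parameter against
  DI2 and step-down Holm adjustment;
* a Mode-A PLS path model (path weighting scheme, bootstrap inference)
  in which an IR and a WL centrality block explain latent dominance
  measured by DI1 + DI2;
* a calibrated synthetic event-log generator — latent dominance scores,
  Bradley–Terry contests with an initiator advantage, exponentially
  decaying fight intensity — so the full pipeline runs and is testable
  with known ground truth and no farm data.

## Worked example

```r
library(agonet)

## a six-pig pen: pig 4 starts four fights but wins only two;
## pig 1 never fights
ev <- interaction_events(
  pen_id    = "PEX", t_obs = c(0.5, 1.0, 1.5, 2.0, 2.5),
  initiator = c("4", "6", "4", "4", "4"),
  receiver  = c("3", "3", "2", "5", "6"),
  winner    = c("4", "6", "4", "5", "6"),
  loser     = c("3", "3", "2", "4", "4"))
ros <- pen_roster("PEX", as.character(1:6))
dominance_indices(ev, ros)
#>   pen_id animal_id wins defeats p_won p_lost di1  di2
#> 1    PEX         1    0       0     0      0  NA   NA
#> 2    PEX         2    0       1     0      1  -1 -0.2
#> 3    PEX         3    0       2     0      2  -1 -0.4
#> 4    PEX         4    2       2     2      2   0  0.0
#> 5    PEX         5    1       0     1      0   1  0.2
#> 6    PEX         6    2       0     2      0   1  0.4
```

Pig 1 fought nobody, so its indices are missing (its centralities are
genuine zeros); pig 6 beat two distinct opponents and lost nothing, giving
the top DI2 of 0.4.

On simulated data the package's central comparison looks like this:

```r
cfg   <- generator_config("piglet", n_pens = 6, seed = 42)
study <- simulate_study(cfg)
panel <- compute_panels(study$events, study$roster,
                        schedule_preset("piglet"), windows = 28)
spearman_rho(panel$di2, panel$out_degree_WL)$rs   # 0.887
spearman_rho(panel$di2, panel$out_degree_IR)$rs   # 0.619

fit_pls(panel, default_pls_spec("piglet"))
#> PLS path model (Mode A, path weighting): n = 53 (0 dropped), converged in 4 iterations
#> Structural paths:
#>   C_IR -> D: -0.102
#>   C_WL -> D: 0.984
#> R-squared (D): 0.826
```

Out-degree in the winner–loser network tracks DI2 much more closely than
in the initiator–receiver network, and the PLS paths show the same
asymmetry: the WL centrality block carries nearly all the explained
variance of latent dominance. That is the package's headline diagnostic —
rank information lives in outcomes, not in mere initiative.

The full pipeline (panels, correlation series, rank-difference contrasts,
PLS, figures) runs from a config list or YAML file:

```r
res <- run_analyze(list(profile = "piglet", seed = 1, out_dir = "out",
                        generator = list(n_pens = 10)))
run_report(res, "report")
```

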