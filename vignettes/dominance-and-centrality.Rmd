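---
title: "Dominance indices and network centralities on agonistic event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance indices and network centralities on agonistic event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agonet)
```

## The problem

When pigs are regrouped, they fight until a dominance hierarchy settles.
Each observed agonistic interaction has an initiator and a receiver, and —
when one animal shows clear submissive behaviour — a winner and a loser.
Two traditions summarise the resulting rank structure:

* **Dyadic dominance indices.** DI1 is the win-defeat balance
  $(w - d)/(w + d)$; DI2 additionally weights by the numbers of *distinct*
  pen mates beaten ($P_{won}$) or lost to ($P_{lost}$) and the group size
  $n$: $\bigl(w\,P_{won} - d\,P_{lost}\bigr) / \bigl((w + d)(n-1)\bigr)$.
  Both live on $[-1, +1]$ and are undefined for animals with no decisive
  interaction — missingness is deliberately distinct from a zero.
* **Network centralities.** Directed graphs over the pen roster, either
  initiator→receiver (IR) or winner→loser (WL), with multiple edges between
  an ordered pair aggregated. On these we compute raw and standardized
  in/out-degree, ingoing/outgoing closeness, and betweenness.

The package quantifies how far the centralities reproduce the rank order
given by the indices: Spearman correlation series on rising cumulative
time windows, absolute differences between subsequent rank positions with
Holm-adjusted contrasts against DI2, and a PLS path model in which
centrality blocks explain latent dominance.

## Conventions that needed a decision

**Closeness on disconnected digraphs.** Pens start almost edgeless, so the
graphs are disconnected for many windows. We use the reachable-subset
convention: for node $v$, with $R$ the set of other nodes connected to $v$
in the relevant direction and $s$ their summed geodesic distances,
closeness is $(|R|/s)\cdot(|R|/(n-1))$, i.e. the inverse mean distance
scaled by the reachable fraction (the Wasserman–Faust correction, the
default of the standard network libraries). Isolated nodes score 0.

**Betweenness normalization.** Directed convention: endpoints excluded,
fractional counting over all geodesics, divided by $(n-1)(n-2)$. The
implementation is Brandes' accumulation algorithm; the test suite proves it
equal to exhaustive geodesic enumeration on all 3–4-node digraphs and a
thousand random digraphs up to seven nodes.

**Distinct-opponent counts.** An opponent both beaten and lost to counts in
$P_{won}$ *and* $P_{lost}$; the index formula does not exclude the overlap
and the symmetric choice keeps DI1's antisymmetry under role swap provable.

**Windows.** Analyses are indexed by *cumulative observed hours* with
unobserved gaps removed (presets: 6 + 11 + 11 = 28 h for weaned piglets,
6 + 11 = 17 h for fatteners and gilts; wall-clock positions are derived,
never stored). Window $k$ holds events with $t \le k$; a boundary event
belongs to the earlier window. Every window is recomputed from scratch
from its event subset — no incremental updates, so nesting consistency is
testable.

**Spearman series.** Average ranks for ties, Pearson on the ranks, p-value
from the $t$ approximation with $n-2$ degrees of freedom, pairwise deletion
of animals lacking an index. Flags use unadjusted two-sided $p<0.05$;
Holm correction is reserved for the rank-difference contrasts, matching how
the two analyses are conventionally reported. Correlations are computed
pooled across pens (default reported series) and per pen; pooling is the
default because a per-window coefficient for a whole age group is the
quantity of interest, but both are emitted so the choice is inspectable.

**Rank differences.** Parameters are first mapped to a common $[0,1]$
scale — indices affinely via $(x+1)/2$, centralities pass through — because
differences are only comparable across parameters on a shared bounded
range. Per pen and parameter, values are sorted descending and subsequent
differences taken up to comparison 8:9 (piglets), 20:21 (fatteners) or
18:19 (gilts), where observations for lower ranks become scarce. The
contrasts against DI2 come from a fixed-effects least-squares model
`abs_diff ~ parameter * comparison` with pens as replicates, cell-mean
contrasts with the pooled residual variance, and step-down Holm adjustment
over the whole parameter-vs-DI2 family. A mixed model with a pen random
effect would be the field's default; we use the fixed-effects analogue
because no random-effects structure beyond these fixed effects is
identified for this design, and OLS keeps every number exactly
reproducible. The deviation is recorded in the output metadata.

**PLS path model.** Mode A (reflective) measurement with the path
weighting scheme: outer weights start at +1; latent scores are
standardized weighted sums; inner proxies weight predecessors by
multiple-regression coefficients and successors by correlations; Mode A
updates weights as indicator–proxy correlations; convergence is a maximum
absolute weight change below `tol` (default 1e-7, cap 300 iterations).
Afterwards loadings are indicator–score correlations, structural paths are
OLS among scores, and the quality gates are indicator reliability
(loading² > 0.7), composite reliability (0.6–0.9 in exploratory use;
higher values flag redundant indicators), AVE (> 0.5) and the $R^2$ bands
0.25/0.50/0.75. Sign indeterminacy is fixed by forcing each score to
correlate positively with its block's first indicator — also the bootstrap
alignment rule, applied identically in every replicate. Bootstrap SEs are
replicate standard deviations (default 5000 resamples) and p-values use
$t = \hat\gamma/SE$ with $n-1$ df. Path coefficients are plain regression
coefficients and are never clamped: with collinear exogenous blocks a
standardized path above 1 with a negative companion is a legitimate
outcome, and a regression test constructs one.

Only complete cases enter the PLS fit (isolated animals have no index);
the dropped count is reported. The default model measures dominance by
DI1 + DI2 and each centrality block by out-degree and outgoing closeness,
adding IR betweenness for the fattener and gilt models.

## What the generator emulates — and what it does not

`generator_config()` + `simulate_study()` produce event logs with known
ground truth so every stage is testable without farm data. Per pen:
latent dominance $\theta_i \sim N(0,1)$; event count Poisson with mean
$n \cdot \text{target}/2$ (targets 18.4 / 5.9 / 5.3 interactions per
animal for piglet / fattener / gilt presets, each interaction counted for
both participants); event times from an inhomogeneous Poisson process with
intensity $\propto e^{-t/\tau}$, $\tau = 3$ h by default, reproducing the
steep post-mixing decay in fighting; initiator sampled
$\propto e^{\alpha\theta}$; receiver uniform among pen mates (so in-degree
carries rank information only through outcomes; a `receiver_bias` option
exists); initiator wins with probability
$\text{logit}^{-1}\bigl(\beta(\theta_i - \theta_r) + \delta\bigr)$ — a
Bradley–Terry contest with an initiator offset, the minimal model that
both yields initiator-win proportions above one half and admits a
recoverable rank order; outcomes are indecisive with probability 0.1 (the
true exclusion rate is unreported, so this is a plain assumption).

Defaults $\beta = 2$, $\alpha = 0.5$, $\delta = 0.25$ were fixed once so
that the simulated initiator-win proportion sits in the observed 0.55–0.66
band while initiators remain moderately rank-biased; group-size
distributions (truncated rounded normals 8.9 ± 0.6 on 6–11, 20.9 ± 1.7 on
17–25, 20.8 ± 3.4 on 16–27) and pen counts (93/26/12) follow the study
design. Per-pen seeds derive deterministically from the master seed, so
identical configurations are byte-identical.

Known departures from real pens: no familiarity structure, body-weight or
sex effects; stationary $\alpha, \beta, \delta$ (real initiator-win
proportions drift over hours); exponential decay front-loads fighting more
than observed isolation trajectories suggest, so the simulated
isolated-animal fraction falls faster than on farms. Passing tests
therefore show the *pipeline* is correct and that the qualitative findings
(WL out-degree tracking DI2 better than IR out-degree, negative in-degree
correlations) follow from an outcome-driven hierarchy — they do not
reproduce farm-data coefficients, which depend on unmodelled structure.

## Numerical and degenerate-input choices

* Missing indices propagate as `NA`, never zero; centralities of isolated
  animals are genuine zeros.
* Correlation entries with fewer than 3 complete pairs or a constant
  vector are flagged `defined = FALSE`, not interpolated.
* Tied standardized values are ordered by animal id before differencing —
  the difference is unaffected, the output order deterministic.
* Perfect monotone concordance returns $p = 0$ rather than evaluating the
  $t$ statistic at $|r_s| = 1$.
* Empty cells in the contrast grid are skipped; a single contributing pen
  is an error (no residual degrees of freedom).
* A constant indicator is an error in the PLS fit; non-convergence is a
  flag, and failed bootstrap replicates are counted with a warning above
  5%.

## Problem sizes used in the shipped tests

The validation suite runs the full piglet design (93 pens) over 20 seeds
for the correlation-ordering property, 50 seeds at $n = 500$ for PLS
parameter recovery (mean absolute path bias below 0.05), 20 null-model
seeds at $n = 200$ with 500 bootstrap replicates, the exhaustive 3–4-node
digraph suites plus 1000 random digraphs up to 7 nodes for the centrality
oracles, and 1000 random vectors for the Spearman oracle. These sizes give
Monte-Carlo error comfortably below the asserted margins while keeping the
suite quick to run.

## A short worked example

```{r}
cfg <- generator_config("piglet", n_pens = 6, seed = 42)
study <- simulate_study(cfg)
panel <- compute_panels(study$events, study$roster,
                        schedule_preset("piglet"), windows = 28)
spearman_rho(panel$di2, panel$out_degree_WL)$rs
spearman_rho(panel$di2, panel$out_degree_IR)$rs

fit <- fit_pls(panel, default_pls_spec("piglet"))
fit
```

The winner-loser out-degree correlates with DI2 markedly more strongly
than the initiator-receiver out-degree — outcomes, not mere initiative,
carry the rank information — and the PLS model shows the same asymmetry in
its paths.

## Limitations

The rank-difference contrasts use a fixed-effects stand-in for a mixed
model (above); hierarchy linearity is assumed, not tested (no Landau $h$ or
transitivity machinery); networks are unweighted after aggregation; and no
alternative ranking schemes (Elo, David's score) are provided. The
generator's realism caveats above bound what simulation-based checks can
certify.
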