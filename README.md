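# deltaboost

Delta log-normal boosted regression trees for spatial abundance modelling
and Marine Protected Area (MPA) decision support.

## What it is for

Survey catch rates (CPUE) of data-poor species — marine elasmobranchs are
the motivating case — are mostly exact zeros with a long right tail where
positive. deltaboost models such data with the fisheries-standard **delta
(hurdle) log-normal** approach, using boosted regression trees (BRTs) for
both parts:

* **occurrence**: a bernoulli tree ensemble on presence/absence over all
  stations, giving `p` per prediction cell;
* **positive abundance**: a Gaussian tree ensemble on `log(CPUE)` over the
  positive catches, giving a log-scale prediction `f`.

The per-cell abundance index is

```
combined_index = p × s·exp(f),      s = mean(exp(log-scale residuals))
```

where `s` is **Duan's smearing estimator**, correcting the retransformation
bias of naive exponentiation. Hyperparameters — tree complexity `tc`,
learning rate `lr`, bag fraction `bf` — are searched on a nested grid with
cross-validated early stopping; the selected fits can be simplified by
backward elimination (1-SE rule).

Around the model sit the tools a survey-to-management workflow needs:

| function | purpose |
| --- | --- |
| `bfcheck()` | smallest feasible bag fraction before a long run |
| `delta_fit()` / `predict()` | the delta BRT model and its prediction surface |
| `relative_influence()`, `partial_dependence()`, `interaction_strength()`, `model_report()` | model interrogation and the audit report |
| `rsb_scores()` | per-cell survey representativeness of the prediction grid |
| `combine_subsets()` | unit-max-scaled multi-species conservation surfaces |
| `closure_spec()` / `cascade_closures()` | greedy candidate MPAs protecting escapement-biomass targets `(1 − HRMSY) × B` while tracking fishing-effort displacement |
| `run_loops()` / `cv_surface()` | between-run coefficient of variation of predictions |
| `gen_landscape()` / `gen_survey()` / `gen_effort()` | synthetic study systems with known truth |

Everything is tibble-in / tibble-out and pipeable; fitted models have
`tidy()`, `glance()` and `autoplot()` methods; maps render with ggplot2. A
thin command-line wrapper ships at `inst/cli/deltaboost.R` with subcommands
`synth`, `bfcheck`, `fit`, `rsb`, `map`, `cons`, `valuemap`, `loop`.

## Worked example

```r
library(deltaboost)

# a synthetic survey with known truth: 40x40 cells, 1000 stations,
# ~60% zero catches, long-tailed positives
land    <- gen_landscape(40, 40, seed = 1)
samples <- gen_survey(land$grid, land$truth, n_stations = 1000, seed = 1)

fit <- delta_fit(samples, "cpue",
                 config = brt_config(tc = 2, lr = 0.01, bf = 0.5,
                                     cv_folds = 5, seed = 1,
                                     simplify = FALSE))
fit
#> <delta_fit> response: cpue (delta log-normal)
#>  occurrence : tc 2 lr 0.01 bf 0.5 trees 500 AUC 0.854
#>  abundance  : tc 2 lr 0.01 bf 0.5 trees 650 pseudo-R2 0.719
#>  smearing factor: 1.2004

surf <- predict(fit, land$grid)
cor(surf$combined_index, land$truth$true_abundance)
#> [1] 0.9354014
```

The printout reads: the occurrence ensemble separates zero from positive
stations with training AUC 0.85; the log-abundance ensemble explains ~72%
of log-catch variance; smearing inflates exponentiated predictions by
~20% to undo retransformation bias. The fitted surface correlates at
r = 0.94 with the true expected abundance — the two active covariates of
the generator carry the influence:

```r
tidy(fit)
#> # A tibble: 8 × 3
#>   component variable influence
#> 1 binary    x1          48.2
#> 2 binary    x2          38.2
#> ...
```

A candidate closure protecting 92% of a stock's biomass while tracking
effort displacement:

```r
grid2 <- land$grid
grid2$cpue   <- surf$combined_index
grid2$effort <- gen_effort(land$grid, land$truth, correlation = 0.3,
                           seed = 1)
plan <- cascade_closures(grid2,
                         closure_spec("cpue", hrmsy = 0.08,
                                      scheme = "combination"))
plan$species_stats[, c("bpa_target", "protected_final",
                       "effort_overlap_pct")]
autoplot(plan)
```

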