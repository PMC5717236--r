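# prefperf

Preference–performance analysis for phytophagous insect communities.

## The scientific problem

In most phytophagous insects the larvae are far less mobile than the adults,
so offspring fitness hinges on the plant the mother chooses for oviposition.
The *mother-knows-best* hypothesis predicts a positive correlation between
adult oviposition preference and larval performance — and theory predicts the
correlation should be stronger for specialists, which are adapted to survive
on few hosts, than for generalists, which fare tolerably on many. `prefperf`
implements the statistical machinery to test this within a single community:
the motivating design is six tephritid fruit-fly species (two cucurbit
specialists, four generalists) assayed on 29 host plants from 15 families,
with preference measured as eggs laid in 24 h no-choice trials (6 replicates
per species × fruit) and performance as larval survival — the proportion of
single-larva cups yielding a pupa (30–50 cups per cell).

The package is aimed at community ecologists and entomologists who have (or
want to simulate) replicate-level host-use assays and need the full chain
from tidy tables to publishable test statistics.

## The statistics at its core

* **Diet breadth as a Hill number.** A species' host-use profile
  `p = (p_1, …, p_S)` is summarised by the numbers equivalent of Shannon
  entropy, `D = exp(−Σ p_j ln p_j)` (Hill diversity of order `q = 1`) — the
  number of *equally common* hosts that would produce the same entropy. This
  turns the specialist/generalist dichotomy into a continuous degree of
  specialisation.
* **Matrix bootstrap.** Uncertainty comes from rebuilding the
  plants × species interaction matrix `B = 1000` times, drawing one
  oviposition replicate and five survival cups per cell (without
  replacement), and recomputing per-species alpha each time.
* **Pearson correlations** for (i) preference-alpha vs performance-alpha
  across species, (ii) per-species mean eggs vs survival across hosts and
  (iii) choice vs no-choice consistency, with two-sided p-values from the
  `t(n−2)` reference distribution.
* **Quasi-Poisson analysis of deviance.** Egg counts are modelled with a
  Poisson log-linear mean and dispersion `φ` estimated from Pearson
  residuals; terms are tested sequentially by
  `F = (Δdev/Δdf)/φ̂`, e.g. `eggs ~ survival × guild` for the
  specialist/generalist contrast, with zero-removal sensitivity refits.
* **A synthetic community generator** with known preference simplices,
  known survival probabilities and a tunable preference–performance
  coupling, so every estimator can be validated against ground truth.

## Worked example

```r
library(prefperf)
sim <- generate_community(community_config(seed = 42))
est <- alpha_distributions(sim$dataset, resampling_plan(n_matrices = 1000, seed = 42))
classify_by_alpha(est, sim$dataset$roster)
#>                 species a_priori_guild assigned_guild mean_alpha separation_score agrees
#> 1       Dacus_demmerezi     specialist     specialist   5.495538                1   TRUE
#> 2 Zeugodacus_cucurbitae     specialist     specialist   4.998941                1   TRUE
#> 3    Ceratitis_catoirii     generalist     generalist  12.735119                1   TRUE
#> 4    Ceratitis_capitata     generalist     generalist  14.066729                1   TRUE
#> 5    Ceratitis_quilicii     generalist     generalist  16.090619                1   TRUE
#> 6     Bactrocera_zonata     generalist     generalist  16.246299                1   TRUE
```

The two specialists behave as if they used ~5 equally common hosts, the
generalists 13–16; in every one of the 1000 resampled matrices every
generalist's alpha exceeded every specialist's (separation score 1), so the
largest-gap classification reproduces the a-priori guilds exactly.

```r
alpha_pref_perf_correlation(est)
#> Pearson r = 0.965 (n = 6, t = 7.343 on 4 df, two-sided p = 0.001832)
```

Species that prefer more hosts also survive on more hosts.

```r
suite <- model_suite(sim$dataset, est)
print(suite$guild_coupling, digits = 4)
#> Analysis of deviance (quasi-Poisson, dispersion 484.045, n = 174)
#>             term delta_dev delta_df df_residual     F         p      signature
#> 1       survival      9953        1         172 20.56 1.086e-05 ddev_{1,172} = 9952.59
#> 2          guild      2198        1         171  4.54 3.455e-02 ddev_{1,171} = 2197.61
#> 3 survival:guild      6395        1         170 13.21 3.685e-04 ddev_{1,170} = 6394.63
```

The `survival:guild` interaction (`Δdev` on 1 and 170 df) says the
egg–survival relationship differs between guilds. Per species:

```r
species_pref_perf_correlation(sim$dataset, "Zeugodacus_cucurbitae")
#> Pearson r = 0.665 (n = 29, t = 4.629 on 27 df, two-sided p = 8.257e-05)
species_pref_perf_correlation(sim$dataset, "Ceratitis_quilicii")
#> Pearson r = 0.040 (n = 29, t = 0.208 on 27 df, two-sided p = 0.837)
```

— a strong positive preference–performance correlation for the specialist,
none for the generalist, exactly the structure the generator encodes
(coupling slope 2.5 for specialists, 0 for generalists).

`run_pipeline(pipeline_config(...))` chains all of the above and writes
`diversity_estimates.tsv`, `alpha_samples.tsv`, `classification.tsv`,
`correlations.tsv`, `deviance_tables.tsv` and a JSON run manifest;
`inst/scripts/prefperf.R` wraps it for shell use.

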