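# spatipv

Spatially aware analysis of drought exposure and binary survey outcomes —
built for the question of whether drought changes a woman's probability of
reporting intimate-partner violence (IPV) in geolocated household surveys,
and for anyone who needs to keep spatial autocorrelation from
manufacturing false positives in survey-plus-climate regressions.

## What it does

Drought and survey outcomes are both spatially structured: nearby clusters
share rainfall history and unmeasured social context, so a naive logistic
regression wildly overstates its effective sample size. `spatipv`
implements the full defensive pipeline:

1. **Drought exposure** — trailing 12-month rainfall at each cluster's
   nearest grid cell, ranked (mid-rank) against the same calendar window
   in all prior years; categories *moderate* [10%, 30%), *severe*
   [2.5%, 10%), *extreme* [0, 2.5%), plus a binary *drought < 30%*
   indicator.
2. **Model** — penalized logistic regression

   logit p = β₀ + Xβ + β_d x_d + δ_survey + s(lat, lon)

   with individual/household covariates X, survey fixed effects δ, and a
   low-rank thin-plate spline on the sphere s(·) (radial basis
   η(c) = c² log c of chord distance at K knots; smoothing parameter by
   AIC = deviance + 2·edf).
3. **Diagnostics** — Moran's I on Pearson residuals,
   I = (n/S₀)·Σ wᵢⱼ zᵢ zⱼ / Σ zᵢ², with spatial weights computed
   *on the fly* in C++ in row blocks, so the n × n weights matrix is never
   materialized (peak memory O(block_size · n)).
4. **Selection** — fit an increasing knot ladder (0, 50, 100, 500, 1000,
   1500) and keep the smallest basis whose residuals show no significant
   Moran autocorrelation at α = 0.05.
5. **Effects** — average marginal effects of each drought level in
   percentage points (counterfactual toggle, spatial term held fixed),
   simulation-based standard errors, Bonferroni thresholds (α/12
   continental, α/4 subgroup tables), and subgroup analyses by wealth
   quintile, employment, water source and urbanization.
6. **Synthetic data + studies** — a generator for DHS-like respondents with
   a known drought effect and a spatially correlated latent risk field,
   plus one-command simulation studies of the Type-I-error phenomenon and
   of effect recovery.

## Worked example

```r
library(spatipv)

grid <- generate_rainfall_grid(lat_range = c(0, 8), lon_range = c(30, 38),
                               res_deg = 1, n_years = 30,
                               annual_range_km = 150, seed = 4)
cfg <- simulation_config(n_surveys = 3, n_clusters_per_survey = 40,
                         n_women_per_cluster = 20,
                         beta_drought = c(moderate = 0.25, severe = 0.4,
                                          extreme = 0.6),
                         spatial_sd = 0.5, seed = 2)
rec <- generate_population(cfg, grid)
table(rec$drought_category)
#>     none moderate   severe  extreme
#>     1140      800      300      160

b <- run_full_analysis(rec, outcomes = "physical", ladder = c(0, 25, 50),
                       n_draws = 500, seed = 3)
b$physical$selection
#> selection_result: selected 25 knots (alpha = 0.05)
#>  knots      edf      aic    moran_I      moran_p status
#>      0 23.00000 2699.063 0.02186925 0.0002155904     ok
#>     25 33.23189 2675.650 0.00536207 0.3373150223     ok
b$physical$ame
#>    outcome    level  ame   se p_value threshold significant
#> 1 physical moderate 4.36 2.42  0.0715   0.00417       FALSE
#> 2 physical   severe 1.42 3.08  0.6448   0.00417       FALSE
#> 3 physical  extreme 9.71 4.52  0.0318   0.00417       FALSE
b$physical$comparison$aic_diff
#> [1] 23.41345
```

Reading the output: the no-spline model (rung 0) leaves significant
residual autocorrelation (Moran p ≈ 2e-4), so the ladder escalates to 25
knots, where the residuals pass (p ≈ 0.34) — and the spline model is also
the better fit (AIC improves by 23.4). The AME column says, e.g., that
toggling every woman from no drought to extreme drought raises the
predicted probability of physical violence by 9.7 percentage points in
this synthetic world, but no level survives the Bonferroni threshold
0.05/12 ≈ 0.0042 at this sample size.

The headline simulation studies are single calls:

```r
run_type1_study(n_replicates = 500, seed = 1)    # naive vs spline rejection
run_recovery_study(n_replicates = 500, seed = 1) # bias and coverage of AME
```

## Command line

```sh
Rscript -e 'spatipv::run_cli()' simulate --config cfg.json --out out/ --seed 7
Rscript -e 'spatipv::run_cli()' classify --grid out/rainfall.csv \
    --respondents out/respondents.csv --out out/classified.csv
Rscript -e 'spatipv::run_cli()' select --design out/classified.csv \
    --outcome physical --ladder 0,50,100 --out selection.json
```

Rainfall cubes travel as long-format CSV (`year,month,lat,lon,mm` with a
units header); respondent tables as CSV with documented factor levels;
model and selection output as JSON. See the methods vignette
(`vignettes/spatial-drought-methods.Rmd`) for the model details, numerical
choices and the design of the synthetic world.
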