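# ecointegrity

Anthropogenic threat surfaces and the ecological integrity of river
networks: a tested R pipeline for freshwater conservation geoinformatics.

## What it does, and for whom

Conservation planners working over large watersheds often only have maps
of human activities — settlements, mining, agriculture, hydroelectric and
thermoelectric plants, oil infrastructure, water withdrawals, aquaculture,
roads — and need to know whether those maps can stand in for expensive
in-situ measurements of river condition. `ecointegrity` implements the
full validation chain:

1. **Threat surfaces.** Each threat category carries a magnitude of impact
   *m* ∈ (0,1] and a maximum impact distance *D*; a feature contributes
   *m*(1 − *d*/*D*)₊ at distance *d* (Euclidean edge distance, *d* = 0
   inside polygons), evaluated at the centers of ~0.25 km² pixels.
   Overlapping buffers add, capped at 1. A complete default registry of
   nine threats and their categories ships with the package
   (`default_threat_registry()`).
2. **Ecological Integrity Index (EII).** Per-site composite in [0,1]:
   the mean (or 2:1:1 biology-weighted mean) of a biotic component
   (family-tolerance index and average score per taxon), a habitat
   component (riparian-quality and fluvial-habitat indices) and a
   physical-chemical component (inverted deviations of pH, conductivity,
   dissolved oxygen, temperature from reference values), every parameter
   min–max scaled so 1 = reference condition.
3. **Models linking the two.** Moran's I screening; all-subsets Gaussian
   linear model selection under AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with
   subsets capped at 7 terms (local scale) or 2 (microbasin scale) and any
   pair with |Pearson r| > 0.7 excluded; repeated 7-fold cross-validated
   R²; projection of the best model onto the full grid or microbasin set.
4. **Synthetic landscapes.** A seeded generator
   (`generate_landscape()`) with the statistical structure the analysis
   assumes — nine threat layers, a concave mountain-to-lowland terrain,
   140 sites, EII = β₀ + Σβx + ε with noise calibrated to a target
   analytic R² — so selection and cross-validation machinery can be
   validated by parameter recovery, without any external data.

## Worked example

```r
library(ecointegrity)

ls <- generate_landscape(synthetic_config(seed = 7))
ls
#> synthetic_landscape: 140 sites on a 80 x 80 grid, 62 features, sigma = 0.0884 (0 clamped)

# spatial independence of the simulated integrity values
w <- inverse_distance_weights(cbind(ls$sites$x, ls$sites$y))
unlist(morans_i(ls$sites$eii, w)[c("I", "expected", "z")])
#>            I     expected            z
#>  0.127638736 -0.007194245  0.859034034

# scenario b: local-scale EII ~ threats + environment
rep <- run_scenario(ls$sites, ls$surfaces, ls$env, scenario = "b")
rep
#> scenario b (local scale, n = 140): best = {human_settlements, mining, oil, roads, elevation, slope}
#>                term coefficient    se       p significance
#> 1       (Intercept)       0.765 0.019 1.6e-77          ***
#> 2 human_settlements      -0.183 0.031 2.1e-08          ***
#> 3            mining       0.081 0.038 3.4e-02            *
#> 4               oil      -0.133 0.051 1.0e-02            *
#> 5             roads      -0.114 0.030 2.3e-04          ***
#> 6         elevation      -0.172 0.037 7.4e-06          ***
#> 7             slope       0.140 0.034 6.9e-05          ***
#> mean R2 (cross-validation) = 0.35 (SD 0.15)
```

The report reads like a coefficient table from a study of this kind: the
selected subset, OLS coefficients on 0–1 scaled predictors with standard
errors and t-test p-values, and the mean held-out R² over 7 folds × 20
repeats. Here every term of the generator's true model (settlements
−0.165, roads −0.121, oil −0.136, elevation −0.176, slope +0.199,
intercept 0.762) is recovered within sampling error; AICc also admits one
weak spurious term (mining), the usual price of information-criterion
selection at n = 140. `rep$selection$table` holds the full
AICc candidate table; `rep$prediction` is the predicted-EII surface,
clamp count included.

The same stages run from the command line on files:

```sh
Rscript -e 'ecointegrity::pipeline_cli()' simulate  --config cfg.json --out run/
Rscript -e 'ecointegrity::pipeline_cli()' moran     --config cfg.json --in run/ --out run/
Rscript -e 'ecointegrity::pipeline_cli()' model     --config cfg.json --in run/ --out run/
```

Subcommands: `simulate`, `build-threats`, `eii`, `moran`, `aggregate`,
`model`, `cv`, `predict`, `run-all`, `validate`. Exit codes: 0 success,
2 config validation failure, 1 runtime failure. Each run writes a
`manifest.json` (config snapshot, seeds, output checksums); identical
config + seeds reproduce byte-identical outputs.

## Layout

```
R/                  implementation (threat mapping, integrity index,
                    spatial stats, modeling, synthetic data, pipeline/CLI)
inst/extdata/       shipped threat registry (CSV) and default config (JSON)
tests/testthat/     unit + property tests, oracle helpers, acceptance suite
scripts/acceptance.R
vignettes/          methods vignette (model, assumptions, design choices)
```
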