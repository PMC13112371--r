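# healthgravnet

Quantifying coordinated health development across the cities of an urban
agglomeration: composite health indices, an improved inter-city gravity
model, and correlation-network analysis of collaboration structure, with a
built-in validation protocol and a synthetic study-area generator.

## Who this is for

Researchers in regional health governance and spatial epidemiology who want
to measure how health resources and development co-evolve across the cities
of a functional region (e.g. Beijing–Tianjin–Hebei or the Yangtze River
Delta), classify the region's collaboration structure, and stress-test the
underlying spatial-interaction model — without depending on restricted
yearbook data, which the synthetic generator stands in for.

## The model

Per city and year, an **Urban Health Index** aggregates min-max
standardized indicators (hospitals, practicing physicians, hospital beds,
per-capita health expenditure, GDP) with entropy weights:
`UHI_i(t) = Σ_j w_j x'_ij(t)`. Pairwise collaborative attraction follows an
improved gravity model

```
G_ij(t) = c · UHI_i(t)·UHI_j(t) / d_ij^γ · exp(−Δt_ij/T) · (1 − θ·min(UHI)/max(UHI))
```

with distance decay (γ = 1.8), travel-time decay (T = 2 h) and a
resource-complementarity factor (θ = 0.3) that suppresses gravity between
cities with similar health levels. Correlating each city's node-strength
series `S_i(t) = Σ_j G_ij(t)` over years, thresholding at τ = 0.6, and
computing degree centrality `C_D(i) = Σ_j g_ij/(n−1)` plus Freeman
centralization yields a collaboration network that a rule cascade
classifies as *unipolar*, *polycentric*, *core-periphery*,
*dual-core segmented*, or *indeterminate*. A regional **Health
Collaborative Development Index** (AHP-weighted, with policy-support
intensity scored from classified policy documents) tracks region-level
coordination. Model validation uses leave-one-agglomeration-out
cross-validation (log-space least squares for `c`, `γ`, `θ`) and
sensitivity analysis of total network gravity to γ and T.

## Worked example

```r
library(healthgravnet)

area <- generate_study_area(default_study_spec(seed = 1))
area
#> Synthetic study area: 64 cities in 4 agglomerations, 2005-2023
#>   planted structure: none
#>   policy documents: 210   seed: 1

report <- loocv(area)
report
#> Leave-one-agglomeration-out cross-validation
#>   agglomeration     c gamma theta    rmse     r2
#> 1           BTH 0.999 1.800 0.301 0.00464 0.9987
#> 2           YRD 1.004 1.801 0.301 0.00287 0.9987
#> 3           PRD 1.001 1.800 0.301 0.00437 0.9986
#> 4            CY 0.999 1.799 0.301 0.00619 0.9985
#> worst fold: RMSE = 0.0062, R2 = 0.9985 (seed 1)
```

Each row is one held-out agglomeration: the gravity parameters refit on the
other three (recovering the generating values c = 1, γ = 1.8, θ = 0.3
from reference observations with 3% multiplicative noise), and the
held-out prediction error on min-max-normalized gravity — RMSE well under
0.05 and R² well above 0.92 in every fold, i.e. the model generalizes
across agglomerations.

Classifying a planted single-core region:

```r
planted <- plant_structure(archetype_spec("unipolar", seed = 1), "unipolar")
net <- build_collaboration_network(study_gravity(planted)[[1]])
u <- study_uhi(planted)
last <- u[u$year == max(u$year), ]
classify_structure(net, setNames(last$uhi, last$city))
#> Collaboration network: 13 cities, 12 edges (tau = 0.6)
#>   centralization: 1.000   structure: unipolar
#>   hubs: AGG01
```

The planted dominant core is recovered as the single hub of a star-shaped
(centralization 1) network.

The full pipeline — synthetic data, UHI, policy intensity, HCDI, gravity,
network, validation — runs end-to-end with artifacts and a manifest on
disk:

```r
cfg <- pipeline_config(spec = default_study_spec(seed = 1), output_dir = "out")
run_pipeline(cfg)   # writes panel/uhi/hcdi/gravity CSVs + network and validation JSON
```

## Layout

- `R/` — implementation: study-area generator (`generate_study_area`,
  `plant_structure`), indices (`standardize_panel`, `entropy_weights`,
  `compute_uhi`), AHP/HCDI (`ahp_weights`, `compute_hcdi`), policy scoring
  (`score_policy`, `aggregate_policy_intensity`), gravity
  (`compute_gravity`, `sensitivity_profile`), network
  (`build_collaboration_network`, `classify_structure`), validation
  (`fit_gravity_params`, `loocv`), pipeline (`run_pipeline`).
- `vignettes/health-collaboration-networks.Rmd` — methods: model
  assumptions, parameter choices, generator design, numerical edge cases,
  limitations.
- `tests/testthat/` — unit, property and acceptance tests.
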