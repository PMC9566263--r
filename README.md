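# aerequity

Dynamic PM2.5 exposure, walkability and equity analysis on gridded cities.

Static exposure assessment assigns every resident the pollutant
concentration at their home unit. But populations move — working-age
residents spend weekday hours at workplaces whose air differs from their
residential air — so the static number misstates the burden, and misstates
it differently for different age groups. `aerequity` implements a dynamic
assessment pipeline for block- and community-scale PM2.5 exposure and the
equity questions that follow: which places, and which people, carry the
burden.

The pipeline, stage by stage:

1. **Concentration surfaces.** Hourly geographically weighted regression of
   station PM2.5 on five covariates,

   `PM2.5_it = β0(u_i) + β1(u_i)·AOD_it + β2(u_i)·POP_it + β3(u_i)·NDVI_i +
   β4(u_i)·ROAD_i + β5(u_i)·NP_i + ε_it`,

   with Gaussian-kernel local fits and cross-validated bandwidth; prediction
   onto a 1000 m fishnet by inverse-distance interpolation of the local
   coefficients; ordinary kriging of the fishnet values; area-weighted
   block averaging.
2. **Exposure under mobility.** Block exposure intensity
   `E_j = Σ_h P_jh · A_jh` (concentration × population density, summed over
   polluted hours), and community time-activity-weighted concentration
   `POD_i = Σ_g P_g(ΣCO_g + ΣCD_g) / (ΣP_g · 24)` per day from
   origin-destination commuting groups: elderly (65+) and children (0–6)
   home-bound, workers (19–59) at the workplace weekdays 8:00–18:00.
3. **Walkability.** A 16-point facility-based walk score: category weights
   decayed by distance bands (0/25/88/100% at 500/1000/1500 m), then by
   street form (block length + intersection density, ≤ 10%), aggregated to
   units by population weight.
4. **Risk typologies.** Hourly equal-count tertile scoring of exposure
   intensity (168 assignments summed, re-tertiled) crossed with Jenks
   natural-breaks walkability levels; community typologies from Jenks
   classes of POD × age-group proportion.
5. **Equity.** Lorenz curves and Gini coefficients of exposure burden over
   vulnerable populations, and global + local bivariate Moran's I (LISA)
   with conditional permutation inference on queen-contiguity weights.

A synthetic monocentric city generator (commuting flows, age gradients,
spatially varying coefficient fields with known truth) makes the whole
pipeline runnable and testable without any external data. It is first-class,
tested code: parameter-recovery tests run the estimators against its latent
truth.

## Worked example

```r
library(aerequity)

cfg <- pipeline_config(out_dir = "aerequity-demo", seed = 7)
run_pipeline(cfg)
#> run_manifest: 6 stages (simulate, surface, exposure, walkscore, classify, equity), 21 files

pod <- read.csv("aerequity-demo/pod_communities.csv")
eq  <- jsonlite::read_json("aerequity-demo/equity.json")
r2  <- read.csv("aerequity-demo/gwr_r2.csv")
```

On this default city (20 × 20 km, 120 blocks, 40 communities, 10 stations,
one week of hours, seed 7) the run prints:

- `mean r2 0.974, min 0.924` — the hourly GWR fits; every hour clears
  R² = 0.6.
- `dynamic 66.20, static 66.07` (µg/m³) — the population-weighted
  time-activity mean exceeds the residence-only mean: commuting carries
  workers into the dirtier employment core, and the static method
  underestimates exposure.
- `elderly: gini 0.032, I 0.322, z 3.20, p 0.002` — weighted concentration
  and elderly counts cluster together spatially (both are centre-high), and
  the clustering is highly significant under 999 permutations;
  `children: gini 0.033, I 0.161, z 1.66, p 0.109` — the peripheral child
  population shows no significant association.
- The block typology observes 7 of the 9 possible labels, e.g. 3
  `high-high` blocks (high exposure *and* high walkability — the busy,
  walkable, polluted core) and 39 `low-low` blocks at the periphery.

Individual stages are exposed as plain functions (`fit_gwr`, `krige`,
`weighted_concentration`, `base_index`, `jenks_breaks`, `bivariate_moran`,
…) and as a CLI:

```sh
exec/aerequity run-all --config city.yaml --out run1 --seed 7
exec/aerequity equity  --config city.yaml --out run1   # re-runs one stage
```

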