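# nestspacing

Territoriality analysis of raptor nest spacing in patchy forest landscapes.

Territorial raptors defend a minimum distance between con-specific breeding
pairs, and that distance shrinks where habitat quality is high. Nest spacing
therefore measures what a bare census cannot: whether a landscape — in the
motivating case a eucalyptus-dominated *novel ecosystem* in NW Spain —
actually supports reproducing populations of forest top predators (northern
goshawk, Eurasian sparrowhawk, common buzzard). `nestspacing` is for
spatial ecologists who have mapped active nests over one or more breeding
seasons and want to quantify territorial structure and habitat preference,
and to benchmark their population against published ones.

## What it computes

Given a landscape of forest patches (polygons with forest type and
elevation) and nest records (coordinates with active years):

* **Nearest-neighbour distances (NND)** between active con-specific nests,
  annually and between use-weighted territory centroids multi-annually.
* **A habitat-constrained Monte-Carlo null model**: per year with *n*
  nests, 100 iterations of *n − 1* random "nests" whose forest-type
  proportions match the observed ones, restricted to patches at least as
  large as the smallest used patch and no higher than the highest nest;
  each observed nest's distance to the nearest random nest gives the
  chance-expected NND.
* **Mixed-model evidence for territorial spacing**: a gamma GLMM (log
  link) on pooled NNDs — fixed factor observed/simulated, random
  intercepts year, territory, nest — against the same model without the
  fixed factor, compared by small-sample AICc:
  `Δᵢ = AICc₀ − AICc₁ ≥ 6` ⇒ territorial. Coefficients are reported on
  the response scale: α (predicted mean simulated NND) and β (predicted
  observed − simulated difference).
* **G regularity index** `G = exp(mean(ln d²)) / mean(d²)`; above 0.65 =
  regular spacing, otherwise random.
* **Ivlev electivity** `S = (r − p)/(r + p)` (nest use % vs forest-area
  availability %), **breeding density** (pairs/100 km²), **percentile
  rank** of mean NND among literature populations, across-year **one-way
  ANOVA** of NNDs and the **Pearson trend** of annual nest counts.
* **Exclusion ranges**: distance classes in which observed nests never
  occur although the null model places them there.
* A **synthetic study system** — grid-mosaic landscapes at configurable
  forest-type proportions and multi-year hard-core nest patterns with
  habitat preference and territory persistence — so the whole pipeline is
  testable against known ground truth. The survey's aggregate tables
  (forest-type use, annual counts, territory totals) are bundled; its nest
  coordinates were never deposited.

## Worked example

Simulate a territorial population (12 territories, 1500 m hard core,
preferring the mature eucalyptus types) on a 10 × 10 km mosaic, and test it
against its habitat-matched null:

```r
library(nestspacing)

land <- generate_landscape(landscape_config(extent_m = c(10000, 10000),
                                            cell_size_m = 500, seed = 1))
pc <- pattern_config("goshawk", n_territories = 12, hard_core_m = 1500,
                     preferred_types = c(`1` = 39.2, `2` = 43.1, `3` = 5.9),
                     years = 2004:2008, annual_activity_prob = 1,
                     nest_switch_prob = 0.1, switch_radius_m = 150, seed = 2)
nests <- assign_nests_to_patches(generate_nest_pattern(land, pc), land)
sets  <- annual_nest_sets(nests)
obs   <- lapply(sets, nearest_neighbour_distances)
obs[["2004"]]
#> <nnd_result> n = 12, mean = 2470.0 m (SE 209.5), range 1687.8-3988.5 m

props <- observed_type_proportions(nests)
sims <- lapply(seq_along(sets), function(k)
  simulate_null_nnds(sets[[k]], land,
    null_model_config(props, min_patch_ha = 4.1, max_elevation_m = 600,
                      n_iterations = 100, seed = 10 + k)))
names(sims) <- names(sets)

compare_observed_vs_null(
  nnd_observation_table(obs, sims, setNames(nests$territory_id, nests$nest_id)),
  backend = "auto")
#> <model_comparison> lognormal backend, n = 6060
#>   AICc null 13186.1  full 13151.4  delta_i 34.7  -> territorial spacing (delta >= 6)
#>   alpha (mean simulated NND) 1352.53 +/- 83.44 m
#>   beta (observed - simulated) 1018.63 +/- 227.19 m

g_index(obs[["2004"]])
#> <g_index> g = 0.863 (regular; threshold 0.65, n = 12)

histogram_comparison(obs, sims)
#> <histogram_comparison> 14 bins of 500 m, 5 year(s)
#>   exclusion range: below 1500 m
```

Reading the output: observed nests sit ~1000 m (β) farther apart than the
habitat-matched chance expectation of ~1350 m (α), the AICc difference of
34.7 far exceeds the 6-point evidence threshold, spacing is regular
(G = 0.86 > 0.65), and no observed distance falls below 1500 m although the
null model places nests there — exactly the hard core the generator used.
(The comparison fell back to the log-normal backend here because the gamma
fit's variance components sat near a boundary; the `backend` field always
records which model produced the numbers.)

`run_pipeline(run_config(mode = "synthetic", seed = 1))` chains all of the
above (plus electivity, densities, trends, literature ranking) for three
emulated species and writes a JSON report; with `mode = "user-data"` it
does the same from your own GeoJSON landscape and nest CSV.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the package's result tables
under `results/`:

| script | what it does |
|---|---|
| `01_case_study_tables.R` | electivity, densities and count trends from the bundled survey tables |
| `02_simulate.R` | generates the synthetic landscape + nest patterns, checks realised proportions and hard cores |
| `03_territoriality.R` | full pipeline on the synthetic system (null model, GLMMs, G, exclusion ranges) |
| `04_literature_ranking.R` | percentile ranks against synthetic literature compilations |

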