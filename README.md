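# microsholl

Quantification toolkit for microglial population dynamics around
amyloid-β plaques in 2-D histology fields.

In amyloid-depositing brains, microglia cluster around plaques and expand
by local proliferation. Turning segmented sections (tables of plaque and
cell positions) into numbers raises a set of small methodological
problems this package solves deterministically:

- **Plaque-centric radial profiling** — an adaptation of Sholl analysis:
  concentric rings of fixed width (default 20 µm) grown from each
  plaque's boundary, with three stopping rules (contact with a
  neighbouring plaque, the tissue border, density returning to a
  reference wild-type level) plus a safety cap. A cell straddling a ring
  boundary is attributed to the ring containing **> 50% of its disk
  area**, computed from exact circle–circle lens areas. Ring densities
  (cells/mm²) are aggregated across plaques as mean ± SEM per distance
  bin.
- **Proliferation / turnover arithmetic** — the proliferation index
  PI = (lineage⁺ label⁺)/lineage⁺, its linear extrapolation
  PI × (horizon/window) to a cumulative turnover fraction, and the death
  fraction implied by the balance N_end = N_start (1 + births − deaths).
  A 1.9% daily index over a 28-day horizon gives 0.532 — "53% of the
  population proliferates in 4 weeks".
- **Marker statistics** — per-cell reporter intensity vs distance to the
  nearest plaque (Pearson r and Spearman ρ, with an explicit
  zero-variance flag) and percent-positive (stained) area of an
  intensity grid at a user-supplied threshold.
- **Study statistics** — 2^−ΔΔCt relative expression with a multi-gene
  geometric-mean normalization factor and a 5-cycle housekeeping-spread
  quality screen; limit-of-detection-censored immunoassay fold changes
  (N/D when more than half the samples are censored, LOD/2 substitution
  otherwise, signed ±fold convention); tie-corrected Kendall tau-b for
  ordinal severity correlations; T-maze spontaneous-alternation scoring
  with failed-trial exclusion.
- **Synthetic histology** — a seeded generator producing plaque tables
  (hard-core Poisson process) and cell tables (inhomogeneous Poisson
  process with exponential enrichment near plaque boundaries,
  distance-dependent proliferation labelling, and a decaying reporter
  intensity), so every analysis is testable without tissue data.

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(microsholl)

# a 2 x 2 mm synthetic field at default (9-month-model-like) conditions
sim <- simulate_field(simulation_config(seed = 1))
nrow(sim$plaques)   # 15 plaques  (~4.4 / mm^2)
nrow(sim$cells)     # 1381 microglia

# profile every plaque, treating the others as neighbours
profs <- profile_field(sim$cells, sim$plaques,
                       field_spec(2000, 2000, reference_density = 0))
glance(profs[[1]])
#>   plaque_id  step n_annuli final_outer_r cells_inside_plaque total_cells stop_reason
#> 1 P1           20        8          180.                   2          44 max_radius

head(aggregate_profiles(profs), 5)
#>   bin distance_um mean_density       sem n_plaques
#> 1   1          10     939.7965 151.17255        15
#> 2   2          30     710.8952  83.77678        15
#> 3   3          50     617.2769  82.94046        15
#> 4   4          70     469.9690  85.30477        15
#> 5   5          90     358.8531  53.42011         9
```

Ring 1 (10 µm from the plaque edge) is ~3× the 300 cells/mm² background
and density decays toward it with distance — the plaque-associated
clustering the profiler is built to measure. `autoplot()` on the
aggregate draws the mean ± SEM bar profile.

```r
# turnover: 19 BrdU+ of 1000 Iba1+ cells, 1-day label, 4-week horizon,
# stable population size
tidy(proliferation_summary(19, 1000, population_fold_change = 1.0))
#>   n_double_positive n_total    pi ... cumulative_fraction capped ... death_fraction
#> 1                19    1000 0.019 ...               0.532  FALSE ...          0.532
```

53% of the population is estimated to proliferate over the 4 weeks; with
no net growth, an equal fraction must die — compensatory turnover.

```r
# reporter intensity falls with distance to the nearest plaque centre
intensity_distance_correlation(sim$cells, sim$plaques)
#>    pearson_r spearman_rho    n reference undefined
#> 1 -0.5511331   -0.5842948 1381    centre     FALSE
```

A thin command-line wrapper over the same functions ships in
`inst/cli/microsholl.R` (`profile`, `turnover`, `correlate`, `area`,
`simulate`, `alternation` subcommands).

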