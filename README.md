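# gillnetr

Tools for quantifying an illegal gillnet fishery and judging whether it
could overexploit the population it targets. The package grew out of the
data-poor situation typical of protected inland waters: no catch records, no
ageing program with large samples, no fishery-independent time series — just
shoreline debris surveys, a small multi-mesh gillnet monitoring program, and
a handful of life-history parameters. `gillnetr` turns those three sources
of evidence into reproducible numbers:

1. **Derelict-gear surveys** (`transect_density()`, `pooled_density()`,
   `mesh_composition()`, `accumulation_change()`): linear densities of
   lost or discarded gillnet and hook-and-line gear along shoreline
   transects, the mesh sizes fishers actually use, and between-year
   re-accumulation after cleanup — an indirect index of ongoing illegal
   fishing.
2. **Gillnet monitoring** (`panel_cpue_table()`, `set_cpue_table()`,
   `optimal_mesh()`, `fit_length_weight()`, `trend_test()`): catch per unit
   effort by mesh panel and by net-night, the mesh that maximizes catch,
   and year trends in abundance and body size fitted as linear mixed models
   with site random intercepts and likelihood-ratio tests (via `lme4`).
3. **Data-poor stock assessment** (`fit_vb()`, `catch_curve()`,
   `natural_mortality()`, `fishing_mortality()`, `fmsy_from_m()`, `msy()`,
   `effort_requirements()`, `assessment_table()`): the chain

   L(t) = L∞(1 − e^(−K(t − t₀)))  →  Z from a length-converted catch curve
   (Z = −slope of ln(N/Δt) on relative age over the trailing arm)  →
   M from life-history invariants (M = 4.899·t_max^−0.916,
   M = 4.118·K^0.73·L∞^−0.33, M = 1.79·GSI)  →  F = Z − M  →
   F_MSY = 0.87·M  →  MSY = (1 − e^(−F_MSY))·B  →  the nights, fishers and
   share of resident families needed to take that yield.

A synthetic-data module (`simulate_population()`, `simulate_catch_survey()`,
`simulate_debris()`) generates populations, surveys and debris fields with
the statistical structure the analyses assume, so every stage is testable
end to end without field data. `run_pipeline()` ties the stages together
over validated CSV inputs.

## Worked example

```r
library(gillnetr)

# natural mortality -> sustainable-yield -> effort chain for a grayling-like
# stock (Z = 0.42 from a catch curve; 4.4 kg/ha over 276,000 ha)
tbl <- assessment_table(m = c(hoenig_nls = 0.37, pauly_nls_t = 0.27,
                              gunderson = 0.30))
format_assessment(tbl)[, c("method", "m", "f", "f_msy", "msy_kg",
                           "nights", "fishers", "percent_families")]
#> # A tibble: 3 × 8
#>   method          m     f f_msy msy_kg nights fishers percent_families
#>   <chr>       <dbl> <dbl> <dbl>  <dbl>  <dbl>   <dbl>            <dbl>
#> 1 hoenig_nls   0.37  0.05  0.32 334239  22283    222.8             14.7
#> 2 pauly_nls_t  0.27  0.15  0.23 254235  16949    169.5             11.2
#> 3 gunderson    0.3   0.12  0.26 278971  18598    186                12.3
```

Read across the first row: a longevity-based natural mortality of 0.37/yr
implies F_MSY = 0.32/yr, an annual sustainable yield of ~334 t, and —
at 15 kg per 50-m net-night and 100 nights per fisher-year — about 22
thousand net-nights, i.e. roughly 220 fishers or 15% of resident families.
Current fishing mortality (F = Z − M = 0.05–0.15) sits below F_MSY, but the
effort needed to exceed it is modest.

```r
# recover total mortality from a simulated length sample
lh <- grayling_life_history()
pop <- simulate_population(population_sim_config(lh, z = 0.42,
                                                 n_fish = 5000, seed = 1))
catch_curve(pop$length_mm, lh)
#> Length-converted catch curve: Z = 0.438 /yr (SE 0.015, r^2 = 0.975, 24 bins)
```

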