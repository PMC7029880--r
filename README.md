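# traitcooccur

Trait-based inference of community assembly mechanisms from species
co-occurrence.

## What it does, and for whom

Community ecologists routinely ask which process structures an assemblage:
**environmental filtering** (the abiotic environment admits only species with
suitable trait values, so co-occurring species are functionally *similar*),
**competitive exclusion / limiting similarity** (competition is strongest
among functionally similar species, so co-occurring species are functionally
*dissimilar*), or **neutral assembly** (occupancy is independent of traits).
`traitcooccur` implements a pairwise approach to this question for
presence-absence data — designed with European ant communities sampled at
continental, biogeographic-region and local (bait) scales in mind, but
applicable to any species-by-sampling-unit incidence data with a mixed-type
trait table.

For every unordered species pair the package computes:

1. **Co-occurrence** — the Jaccard index over sampling units,

   `JI_ab = AB / (A + B + AB)`,

   where `A` and `B` count units holding only species *a* or only species
   *b*, and `AB` counts units holding both. `JI = 0` means the pair never
   co-occurs; `JI = 1` means identical occupancy.

2. **Functional dissimilarity** — Gower's mixed-type dissimilarity for nine
   trait sets: all six traits together, the three *ecological tolerance*
   traits (number of queens, colony size (log), brood cycle), the three
   *ecological niche* traits (fuzzy-coded diet, diurnality, worker size),
   and each trait singly. Quantitative components are normalized by the
   trait's range over the **full species pool** (fixed once, so a pair's
   dissimilarity is identical at every scale); categorical components use
   simple matching; fuzzy-coded proportions use half the Manhattan distance.
   Composite sets are unweighted means of their single-trait components.

3. **The two-step hurdle analysis** relating the two:
   * *binary co-occurrence analysis* — a binomial-logit GLM of the indicator
     `JI > 0` on dissimilarity, fitted only in matrices with more than five
     never-co-occurring pairs (`n0 >= 6`);
   * *co-occurrence strength analysis* — OLS of `ln(JI)` on dissimilarity
     over the pairs with `JI > 0`.

   Each fitted slope is classified: significant negative →
   `environmental_filtering`; significant positive → `competition`;
   otherwise `neutral`.

A planner enumerates the full grid (matrices x nine trait sets x two
analysis types, with the `n0` eligibility rule), and a synthetic community
simulator generates species pools and communities under explicit neutral,
filtering and limiting-similarity rules so the whole pipeline can be
validated by slope-sign recovery and type-I calibration.

## Worked example

The package ships a small synthetic fixture: a 12-species pool and a
40-bait local matrix assembled under the *filtering* mechanism (so
co-occurring species should share tolerance-trait values).

```r
library(traitcooccur)

occ    <- system.file("extdata", "synthetic_occurrence.csv", package = "traitcooccur")
trt    <- system.file("extdata", "synthetic_traits.csv",     package = "traitcooccur")
schema <- read_trait_schema(system.file("extdata", "ant_schema.yaml",
                                        package = "traitcooccur"))

mat    <- read_occurrence(occ, scale_label = "local", name = "synthetic_site")
traits <- read_traits(trt, schema)   # applies the declared log transform

out <- analyze_assembly(list(mat), traits)
out$plan
#> Analysis plan: 18 analyses over 1 matrices
#>  scale_label analysis_type n_analyses
#>        local        binary          9
#>        local      strength          9

subset(out$results, trait_set %in% c("all_traits", "tolerance", "niche"),
       select = c(trait_set, analysis_type, estimate, std_error, p_value, mechanism))
#>    trait_set analysis_type estimate std_error  p_value               mechanism
#> 1 all_traits        binary -2.64832    1.7118 0.121846                 neutral
#> 2 all_traits      strength  0.31738    0.4868 0.517705                 neutral
#> 3  tolerance        binary -3.89098    1.3714 0.004551 environmental_filtering
#> 4  tolerance      strength  0.07224    0.3665 0.844656                 neutral
#> 5      niche        binary  1.40351    1.4526 0.333958                 neutral
#> 6      niche      strength  0.42915    0.4457 0.340763                 neutral
```

Of the 66 species pairs, 19 never co-occur (`n0 = 19 >= 6`), so the binary
analyses are eligible. The binary tolerance-trait slope is negative and
significant (estimate -3.89, p = 0.0046): pairs of species that are more
dissimilar in tolerance traits are less likely to ever co-occur — recovered
as `environmental_filtering`, which is exactly the mechanism that generated
the fixture. The niche-trait and strength analyses are non-significant, as
expected when filtering acts on the tolerance axis and mainly on *whether*
(not how strongly) species co-occur.

Simulation-based validation of the whole pipeline:

```r
cfg <- scenario_config("filtering", n_species = 40, n_units = 60, seed = 202)
recovery_experiment(cfg, replicates = 100, trait_sets_used = "tolerance")
#> binary fits: mean slope -1.23, 99-100% negative, ~77% classified
#> environmental_filtering at alpha = 0.05
```

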