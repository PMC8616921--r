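# biomasspart

Partitioning between-site differences in community biomass into richness,
composition, and context effects.

## The problem

Community biomass varies enormously from site to site. When a reef (or any
community whose function is roughly additive over species) holds less fish
biomass than its best neighbour, how much of the gap is because it has
*fewer* species, how much because it has *different* species, and how much
is everything else — environment, resources, abundance shifts within the
species both sites share? `biomasspart` answers this with an exact additive
partition of the pairwise biomass difference, plus the spatial pipeline,
ratio statistics, and null model needed to apply it to a whole survey. It is
aimed at community ecologists working with site-by-species biomass matrices
from standardized surveys (e.g. underwater visual census data with
length-to-biomass conversion).

## The partition

For a reference community *B* and comparison community *F*, classify species
as unique to *B* (count *s*<sub>uB</sub>), shared (*s*<sub>c</sub>), or
unique to *F* (*s*<sub>uF</sub>), with mean biomass per species
*z̄*<sub>uB</sub>, *z̄*<sub>cB</sub>, *z̄*<sub>cF</sub>, *z̄*<sub>uF</sub>
(shared species averaged separately at each site). With
δ<sub>B</sub> = *z̄*<sub>uB</sub> − *z̄*<sub>cB</sub> and
δ<sub>F</sub> = *z̄*<sub>uF</sub> − *z̄*<sub>cF</sub>, the total difference
ΔT = T<sub>F</sub> − T<sub>B</sub> splits exactly as

    ΔT = −s_uB·z̄_cB  − s_uB·δ_B  + s_uF·z̄_cF  + s_uF·δ_F  + s_c·(z̄_cF − z̄_cB)
          RICH-L        COMP-L       RICH-G        COMP-G       CDE

* **RICH-L / RICH-G** — biomass expected to be lost/gained from the *number*
  of absent/extra species, were each an average shared species.
* **COMP-L / COMP-G** — the extra change because those species deviate from
  the shared-species average (species *identity*).
* **CDE** — the context-dependent effect: biomass change among shared
  species only, i.e. everything that is not a membership change.
* **DIV** = RICH-L + COMP-L + RICH-G + COMP-G, the total diversity effect.

Components are usually reported after scaling by the sum of their absolute
values, so each pair lives on the interval (−1, 1) regardless of absolute
biomass. The Q statistic (COMP-L + RICH-L)/RICH-L = *z̄*<sub>uB</sub>/*z̄*<sub>cB</sub>
summarizes how much unique species out- or under-contribute relative to
shared ones, and an alternative partition measured against the
whole-community mean (`fox_kerr_partition()`) provides an independent
cross-check: the two partitions must agree exactly on CDE and DIV.

## A worked example

```r
library(biomasspart)
b <- c(grouper = 10, parrotfish = 6, damselfish = 2)   # reference site
f <- c(parrotfish = 4, damselfish = 4, wrasse = 1)     # comparison site
d <- partition_pair(b, f)
print(d)
#> Pair decomposition of biomass difference
#>   species: 1 unique to reference, 2 shared, 1 unique to comparison
#>   totals:  T_B = 18, T_F = 9, difference = -9
#> rich_l comp_l rich_g comp_g    cde
#>     -4     -6      4     -3      0
#>   DIV = -9, CDE = 0
```

The comparison site is 9 units lighter. Losing one species "worth" the
shared average costs 4 (RICH-L); that the lost grouper is much heavier than
average costs another 6 (COMP-L); gaining the wrasse adds the shared average
4 (RICH-G) minus 3 because wrasse are small (COMP-G); shared species have
the same mean at both sites, so CDE = 0. The five terms sum to −9 exactly.
`q_statistic(d)` returns 2.5: species unique to the reference carry 2.5
times the biomass of an average shared species.

The full spatial pipeline on a synthetic survey in which large-bodied
species are concentrated at high-biomass sites:

```r
sim <- generate_metacommunity(generator_config(composition_bias = 8, seed = 1))
res <- run_pipeline(sim$matrix, radius_km = 100)
print(res)
#> pipeline_result: radius 100 km, 106 pairs (104 in included sets), aggregation 'raw'
#>   component    mean     se  ci_low ci_high   n
#> 1    rich_l -0.1020 0.0104 -0.1223 -0.0817 104
#> 2    comp_l -0.4597 0.0556 -0.5686 -0.3507 104
#> 3    rich_g  0.0507 0.0064  0.0382  0.0632 104
#> 4    comp_g -0.0490 0.0062 -0.0611 -0.0368 104
#> 5       cde -0.1726 0.0230 -0.2177 -0.1276 104
```

Composition loss dominates (mean scaled COMP-L = −0.46): nearby sites fall
short of their highest-biomass neighbour mostly because they lack its
disproportionately large species — exactly the structure this generator
builds in. `null_test()` re-runs the pipeline on randomized-composition
matrices (richness and per-capita contribution ranges held at observed
values) to check that such a result is not an artifact of picking the
highest-biomass site as the reference.

## Command line

A thin CLI wraps the same functions:

```sh
exec/biomasspart simulate --n-sites 60 --seed 7 --out survey.csv --coords-out coords.csv
exec/biomasspart pipeline --matrix m.csv --coords c.csv --radius 100 --out pairs.csv
exec/biomasspart summarize --pairs pairs.csv --stat div-cde --n-boot 5000 --seed 17
exec/biomasspart nullsim --survey survey.csv --reps 1000 --seed 42 --radius 100
```

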