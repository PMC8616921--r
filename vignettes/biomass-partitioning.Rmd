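---
title: "Partitioning biomass differences between communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning biomass differences between communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomasspart)
```

## The model and its assumptions

The package partitions the difference in an additive community function —
here standing-stock biomass — between two communities. Additivity is the one
substantive assumption: total biomass is the sum of per-species
contributions, so the difference between sites can be attributed species by
species. Species present at both sites ("shared" species) define the frame
of reference: their per-species mean is what an interchangeable, "average"
species contributes at that site. Given the species counts unique to the
reference ($s_{uB}$), shared ($s_c$), and unique to the comparison
($s_{uF}$), and the group means $\bar z_{uB}, \bar z_{cB}, \bar z_{cF},
\bar z_{uF}$, the identity

$$\Delta T = T_F - T_B =
\underbrace{-s_{uB}\bar z_{cB}}_{\text{RICH-L}}
\underbrace{-s_{uB}(\bar z_{uB}-\bar z_{cB})}_{\text{COMP-L}}
\underbrace{+s_{uF}\bar z_{cF}}_{\text{RICH-G}}
\underbrace{+s_{uF}(\bar z_{uF}-\bar z_{cF})}_{\text{COMP-G}}
\underbrace{+s_c(\bar z_{cF}-\bar z_{cB})}_{\text{CDE}}$$

holds exactly. It is an accounting identity, not a mechanistic model: it
says nothing about *why* a species is absent, only how its absence moves the
books. The decomposition is undefined when the two communities share no
species ($s_c = 0$, no frame of reference); `partition_pair()` raises an
error there, and the pipeline skips such pairs with a warning and counts
them — applications should check that skipped pairs are rare, as overlap
around 50% makes them essentially impossible.

Two edge conventions: means over empty groups are defined as 0, so the
corresponding terms vanish rather than propagate `NaN`; and a pair of
identical communities scales to the all-zero vector (its raw components are
all 0, and we treat 0/0 as carrying no signal). `RICH-L` can exceed the
total reference biomass when shared species are much heavier than unique
ones; the raw value is left uncorrected — scaled components are the primary
surface — but the case is flagged per pair (`rich_l_exceeds_tb`) and counted
in pipeline diagnostics so users can audit its influence.

An alternative partition (`fox_kerr_partition()`) measures unique species
against the *whole-community* mean $T_B/s_B$ instead of the shared-species
mean. The two partitions distribute the diversity effect differently between
richness and composition but agree exactly on CDE and, because both sum to
the same $\Delta T$, on DIV. We prefer the shared-species frame because it
works with the unique-versus-shared deviation directly; the other partition
is retained as an independent cross-check and every test of one validates
the other through the CDE/DIV identities.

## The spatial pipeline

Sites are ordered by decreasing total biomass and paired greedily: the
heaviest unused site becomes a reference and claims every unused site within
a great-circle radius (haversine on a 6371-km sphere) as comparisons; all of
them leave the pool. Ties in total biomass break lexicographically by site
id so reruns are identical. Choosing the heaviest site as reference makes
$\Delta T \le 0$ for every pair, which simplifies interpretation (losses are
losses) at the cost of a selection effect that the null model (below) is
designed to quantify.

Sets with fewer than `min_comparisons` (default 5) comparisons are excluded
from aggregation. Their sites are still consumed: the removal rule is
unconditional, and returning them to the pool would let one site appear
under several references, reintroducing the pseudo-replication the removal
exists to prevent. A flag could make exclusion-with-return available, but we
deliberately kept one behaviour; the inclusion decision for every reference
is logged by the CLI.

Aggregation offers two modes: `"raw"` (grand mean over all pairs, the
default, showing the full spread of individual comparisons) and
`"per-reference"` (mean within each reference first, then across
references, protecting against references with many comparisons dominating).
Confidence intervals on component means use the normal approximation
(mean ± 1.96·SE), appropriate for the dozens-to-thousands of pairs the
pipeline produces.

## Ratio statistics

Per-pair ratios (DIV/CDE and Q) are averaged as geometric means to avoid the
upward bias of arithmetically averaging ratios, with percentile bootstrap
95% intervals (default 5000 resamples; the method is the plain percentile
bootstrap, chosen for simplicity over BCa since the log-scale point estimate
is already near-median-unbiased). Non-positive ratios have no logarithm;
when exclusion is requested they are dropped once, before the point
estimate, and resampling then operates on the retained positive values —
equivalently, exclusion applies to both the original data and every
bootstrap sample. The resampling unit is the pair; per-reference resampling
would be a one-line change but pair-level matches the raw aggregation mode.
`q_statistic()` is reported as missing when $s_{uB}=0$ or $\bar z_{cB}=0$
rather than inventing a value.

## The randomized-composition null model

Setting the heaviest site as reference biases COMP-L negative even in a
world where species identity is random: the heaviest site is likely heavy
*because* of an unusual species draw. The null model asks whether the
observed composition effects exceed that artifact. Each replicate rebuilds
the matrix with composition random but three things held at observed values:
per-site richness, each species' mean per-capita contribution (biomass over
abundance, averaged across occupied sites), and each species' observed
integer abundance range (sampled uniformly, inclusive of both bounds;
species seen once have a degenerate range). A "maximum richness" matrix with
every species everywhere is subsampled per site to exactly the observed
richness.

By default the greedy pairing is recomputed for every replicate —
randomization reshuffles which site is heaviest, and the reference-selection
artifact we are testing lives in that selection step, so freezing the
observed pairing would assume away part of the question. A `"freeze"` mode
reuses the observed sets for users who want the complementary,
conditional-on-pairing question.

Significance is reported two ways per component: a one-sample one-tailed
*t*-test of the replicate means against the observed mean, and the
distribution-free empirical tail proportion
$(1 + \#\{\text{null at least as extreme}\})/(n_{reps}+1)$, with the tail
direction set by the sign of the observed deviation from the null mean. The
*t*-test treats the replicate means as a sample and is the conventional
choice; the empirical proportion makes no distributional assumption and is
bounded below by $1/(n_{reps}+1)$, so both are logged and the empirical one
is used in our own tests. In the fully degenerate case (every replicate
identical and equal to the observed value) both conventions return 1.

## The synthetic generator

`generate_metacommunity()` produces the data every test runs on, emulating
the statistical structure the method assumes in real reef surveys:

* **Geography.** Sites scatter around cluster centres (default 120 sites,
  10 clusters, spread 30 km, 2000-km extent) because survey sites are
  patchy in reality; this is what gives the 100-km radius several
  independent comparison sets rather than one giant one.
* **Body size and biomass.** Each species draws one log-normal body length
  (meanlog `log(20)`, sdlog 0.8, in cm); biomass per individual is the fixed
  allometry $0.01\,L^3$, so cubing makes per-species biomass heavy-tailed,
  as body-size-driven biomass is. Abundance is shifted negative binomial
  (mean 20, size 1), capturing schooling-type overdispersion.
* **Richness and overlap.** A latent site productivity $u \sim U(0,1)$ sets
  richness linearly across the default range, which is itself derived from
  the overlap target: with exchangeable composition two sites of richness
  $r$ share an expected $r/\text{pool}$ of their species, so centring
  richness on `target_overlap * pool_size` (default 50 of 100) delivers the
  ~50% pairwise overlap typical of nearby reef sites with no hidden
  occupancy structure. This matters for the null model: at
  `composition_bias = 0` the generator satisfies the null's exchangeability
  assumption *exactly*, which is what makes the null-calibration test
  meaningful.
* **Composition bias.** Species are drawn without replacement with weights
  $\exp(b\,(u-\tfrac12)\,z)$, $z$ the standardized log body length. At
  $b=0$ selection is uniform; at $b=8$ (used as the "strong bias" condition)
  the weights at the productivity extremes are effectively size-ranked, so
  large species occur almost only at productive — hence high-biomass,
  high-richness — sites. Raising $b$ monotonically deepens the pipeline's
  mean scaled COMP-L.

What the generator does *not* emulate: environmental covariates, distance
decay of similarity (composition is spatially unstructured given
productivity), observation error in fish sizing, and taxonomic problems.
Passing tests therefore demonstrate the correctness of the accounting, the
pairing, and the null machinery — not robustness to survey artifacts.

## Numerical choices and problem sizes

Conservation checks use a relative tolerance of $10^{-9}$ against
$\max(|T_B|,|T_F|,1)$; in practice the identity holds to machine precision
(the acceptance script audits this, typically $\sim 10^{-15}$). Distances
use the haversine formula with Earth radius 6371 km. All randomness flows
from explicit seeds: the generator seeds once, the null model derives one
sub-seed per replicate from its master seed so replicates are independent
and reproducible, and bootstrap functions take an optional seed.

The shipped tests run the pipeline on 30-site/40-species communities for
structural checks and on the full default conditions (120 sites, 100
species) for the null-model calibration and power checks, which use 200
replicates each — enough to resolve an empirical p of 1/201 while keeping
the whole suite near two minutes. Transect collapsing divides by transects
*surveyed* (absence on a surveyed transect is a true zero), the reading of
"a single average value to account for differences in the number of
surveys"; an `occupied_only` switch provides the other convention since
survey protocols differ.

## Known limitations

The partition is descriptive: COMP-L measures how much absent species
deviate from the shared average, not why they are absent. CDE aggregates
every within-species change — abundance, size structure, environment — into
one number. Results depend on the radius and on the minimum-comparison rule;
both are parameters, and the package makes re-running across radii cheap.
Finally, the geometric-mean exclusion rule (dropping sign-discordant
DIV/CDE pairs) conditions the ratio on agreement in sign; the |DIV|/|CDE|
variant, which uses every pair, should be reported alongside it.
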