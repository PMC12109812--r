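# xcimosaic

Survival estimation and simulation for X-inactivation mosaic tissues.

## The problem

Random X-chromosome inactivation (XCI) silences one X per cell early in
female development, so a female tissue is a clonal mosaic of cells expressing
one or the other X. When one X carries a deleterious allele of an X-linked
gene (the motivating case is *CASK*, whose loss causes microcephaly with
pontine and cerebellar hypoplasia) and the other X carries a GFP reporter
linked to the normal allele, the GFP-positive fraction of a counted cell
population reveals how strongly the mutant-X-active lineage has been
eliminated during development: wild-type tissue sits near 50% GFP-positive,
while a tissue that purges mutant-X-active cells drifts towards 100%.

`xcimosaic` is for researchers who count reporter-positive and
reporter-negative cells in such mosaics (per animal, region and
developmental stage) and want to turn those counts into survival
probabilities with honest uncertainty — and for anyone who wants to test
that inference pipeline against a generative model with known truth.

## The model

Assume both lineages are produced in equal numbers at XCI commitment and
reporter-positive cells survive throughout development. If reporter-negative
cells survive to the observed stage with probability `P_survival`, the
expected GFP-positive fraction is

```
P_GFP+ = 1 / (1 + P_survival)        (forward model)
P_survival = 1 / P_GFP+ - 1          (estimator)
```

Staged over postnatal development with interval survivals `s_k` and an
initial reporter-positive fraction `p`, the stage-`t` positivity is
`p / (p + (1 - p) * prod(s[1:t]))`. On top of the cell-autonomous model the
package defines a linear cell-competition penalty: in mosaic tissue the
low-fitness lineage survives each interval with
`s_eff = s_base * (1 - kappa * phi_high)`, where `phi_high` is the tissue
fraction of normal cells — inert in a uniformly mutant tissue, which is what
makes a hemizygote-versus-heterozygote contrast identify `kappa`.

The package provides the estimator with per-animal aggregation, one-way
miscount (autofluorescence) correction and a seeded bootstrap
(`estimate_survival`, `correct_miscount`, `survival_by_group`); a stochastic
cohort simulator with clonal founder pools, staged elimination, competition
and counting noise (`sim_config`, `simulate_cohort`,
`simulate_paired_design`); a staged trajectory fitter
(`stage_trajectory`, `fit_trajectory`); the competition contrast
(`estimate_competition`, `compare_layer_thickness`); and the two-sample
protocol with Shapiro–Wilk gate, Student's t and asterisk tiers
(`two_sample_compare`).

## Worked example

```r
library(xcimosaic)

# A GFP positivity of 97.66% implies that only ~2.4% of the
# reporter-negative lineage survived:
estimate_survival(0.9766)
#> [1] 0.02396068

# Simulate a wild-type-like and a knockout-like cohort (8 animals,
# 500 cells counted each) and estimate survival per cohort:
cfg_wt  <- sim_config(n_animals = 8, stages = "adult",
                      survival = survival_spec(0.714), cohort = "WT",  seed = 101)
cfg_hko <- sim_config(n_animals = 8, stages = "adult",
                      survival = survival_spec(0.024), cohort = "hKO", seed = 102)
counts <- rbind(simulate_cohort(cfg_wt), simulate_cohort(cfg_hko))
survival_by_group(counts, seed = 1)
#> Per-animal survival estimates (P_survival = 1/P_GFP+ - 1, mean over animals)
#> method: raw; bootstrap: 2000 resamples, 95% studentized CI
#>  cohort region stage n_animals mean_gfp_pct sem_gfp_pct p_survival_mean
#>     hKO    cgc adult         8        97.78      0.2250         0.02279
#>      WT    cgc adult         8        58.82      0.8868         0.70260
#>  p_survival_sem  ci_low ci_high clipped_n
#>        0.002344 0.01516 0.02753         0
#>        0.025500 0.64670 0.76430         0
```

Each row is one cohort: the mean GFP positivity across animals (± SEM, in
percent), the survival probability of the reporter-negative lineage (mean of
per-animal estimates ± SEM), its bootstrap confidence interval, and how many
per-animal estimates exceeded 1 and were capped. The simulated truths (0.714
and 0.024) are inside both intervals.

Developmental kinetics — recover staged survival from a rising trajectory:

```r
traj_cfg <- sim_config(n_animals = 8, survival = survival_spec(0.02),
                       cohort = "hKO", seed = 103)
fit_trajectory(stage_trajectory(simulate_cohort(traj_cfg)))
#> Staged survival fit of a GFP-positivity trajectory
#>   initial reporter-positive fraction p = 0.5
#>   per-stage survival of the reporter-negative lineage:
#>     P6    P13    P20  adult
#> 0.9048 0.2576 0.3279 0.2195
#>   cumulative survival: 0.01678   weighted SSE: 1.27e-28
```

The fitted cumulative survival (~0.017) recovers the simulated truth
(0.02): nearly the whole reporter-negative granule-cell lineage is lost
across the postnatal stages.

A command-line front end over the same functions is at
`inst/cli/xcimosaic.R` (subcommands `simulate`, `estimate`, `trajectory`,
`compete`, `compare`).

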