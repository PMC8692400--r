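# reefnfix

Quantitative analysis of coral-associated dinitrogen (N₂) fixation from
dissolved ¹⁵N₂ tracer incubations, for reef biogeochemists and coral
microbiologists. The package covers the full tabular workflow of such a
study: isotope conversions, diazotroph-derived-nitrogen (DDN) assimilation
rates with detection limits, holobiont and reef-scale nitrogen budgets, and
relative diazotroph activity from paired DNA/RNA amplicon tables. A
synthetic-data generator with known ground truth makes every stage testable
without sequence downloads or instrument data.

## The model

Delta values are converted to atom percent ¹⁵N via

    A = 100 · R_air(δ·10⁻³ + 1) / (1 + R_air(δ·10⁻³ + 1)),   R_air = 0.003676,

and DDN assimilation of an enriched/control fragment pair is

    DDN = (1/Δt) · (A_e − A_c)/(A_15N2 − A_0) · [PN]      [µg N h⁻¹],

where `A_e`, `A_c` are the particulate atom% ¹⁵N of the enriched and paired
control fragment, `A_15N2` the measured label enrichment of the incubation
water, `A_0` the unlabeled-seawater atom%, and `[PN]` the fragment's
particulate nitrogen. A pair is *detected* when `A_e − A_c` exceeds 3 × the
SD of repeated control measurements; below-detection rates are zeroed before
averaging. Rates are standardized per surface area, dry weight or volume,
scaled into a holobiont budget against a daily N demand of 0.2% of dry
weight, and — on the amplicon side — microbial activity is summarized as
per-ASV RNA:DNA proportion ratios aggregated by taxonomic order, plus *nifH*
cluster (I–III vs IV/V) relative abundances.

## Worked example

```r
library(reefnfix)

# simulate a tracer experiment with known rates, then estimate them back
sim <- simulate_incubation_dataset(sim_config(seed = 7, noise_sd_atom_pct = 0))
fit <- ddn_rates(sim$samples)
summary(fit)
#> Group mean DDN rates (below-detection rates zeroed), measure: rate_per_area_ngN_cm2_h
#>   species  site compartment       mean           sd n n_detected
#>  Simulata SiteA        host 0.33333333 3.010254e-15 4          4
#>  Simulata SiteA       mucus 0.01666667 1.955330e-15 4          4
#>  Simulata SiteA    skeleton 3.33333333 3.922090e-15 4          4
#>  Simulata SiteA    symbiont 0.23333333 2.715086e-15 4          4

# holobiont budget: N contents in mg N cm-2, daily fixation in ug N cm-2 d-1
b <- holobiont_budget(0.26, 1.06,
                      tissue_fix = 2.22 / 100 * daily_n_demand(0.26),
                      skeletal_fix = 7.49 / 100 * daily_n_demand(1.06))
b$total_over_total_pct
#> [1] 6.45197
```

At zero noise the estimator recovers the configured per-fragment rates
exactly (the simulated skeleton rate, 0.10 µg N h⁻¹ over ~30 cm², is the
3.33 ng N cm⁻² h⁻¹ in the summary), and the budget reproduces a
"total fixation / total demand" of ≈6.45% from the example contents and
compartment percentages.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/reefnfix.R run --seed 1 --out out/
```

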