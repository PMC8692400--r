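---
title: "Methods: tracer rate estimation, nitrogen budgets and relative diazotroph activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer rate estimation, nitrogen budgets and relative diazotroph activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefnfix)
```

## Scope

`reefnfix` quantifies dinitrogen fixation associated with reef corals from
dissolved ^15^N~2~ tracer incubations, and places those rates in holobiont and
reef-scale nitrogen budgets. A companion amplicon workflow summarizes the
*relative activity* of coral-associated microbes from paired DNA/RNA libraries
(RNA:DNA ratios) and the composition of the *nifH* community by phylogenetic
cluster. Everything upstream of tabular data — sequencing, denoising,
taxonomic classification, cluster placement, surface-area photogrammetry,
nutrient chemistry — is out of scope and consumed as input.

## Isotope conversions

Isotope-ratio mass spectrometry reports per-mil delta values against air
N~2~ (nitrogen, $R_\mathrm{air} = 0.003676$) or PDB (carbon,
$R_\mathrm{PDB} = 0.011180$):

$$\delta = \left(\frac{R_\mathrm{sample}}{R_\mathrm{ref}} - 1\right)\times 1000.$$

Tracer arithmetic happens on the atom-percent scale,

$$A = 100\,\frac{R_\mathrm{air}(\delta\cdot 10^{-3}+1)}
                {1+R_\mathrm{air}(\delta\cdot 10^{-3}+1)},$$

a strictly increasing map whose exact algebraic inverse
(`delta_from_atom_percent()`) round-trips to below $10^{-10}$ per mil over the
whole working range ($\delta \in [-100, 50\,000]$); that bound is asserted in
the test suite. Natural abundance, $A_0 \approx 0.366254$ atom%, is the value
at $\delta = 0$ and is computed, never hard-coded.

## The rate estimator

For each enriched/control fragment pair,

$$\mathrm{DDN}_\mathrm{assimilation}
  = \frac{1}{\Delta t}\,
    \frac{A_e - A_c}{A_{^{15}\mathrm{N}_2} - A_0}\,[\mathrm{PN}],$$

with $A_e$, $A_c$ the particulate atom% ^15^N of the enriched and control
sample, $A_{^{15}\mathrm{N}_2}$ the measured label enrichment of that jar
(typically 8.5–11.5 atom%), and $[\mathrm{PN}]$ the particulate nitrogen of
the fragment (from the %N of the enriched sample, `pn_mass()`). Internal
canonical units are atom% (not fractions), µg N, hours, cm², g dry weight and
litres; standardizations (`standardize_rate()`) and the hour/day and
ethylene-to-N (×2/3) conversions are centralized so unit slips cannot creep
into cross-study comparisons.

Decisions where the procedure was genuinely open:

* **Pairing.** Enriched and control fragments are paired by colony within
  species × site × compartment, matching the one-enriched/one-control-per-
  colony design. A missing mate falls back to the group-mean control atom%
  with a warning rather than dropping the pair.
* **Detection.** A pair is *detected* when $A_e - A_c$ exceeds 3 × the sample
  SD of repeated control measurements. Whether "repeated" means analytical or
  biological replicates is ambiguous; the default pools biological control
  replicates within species × site × compartment, and the pooling scope is an
  argument (`pool_by`). Below-detection rates — including negative excesses,
  which are retained through the computation — are replaced by zero before
  group averaging (`summarize_group_rates()`), the conservative convention.
* **A~0~.** A measured unlabeled-seawater atom% is used when supplied;
  otherwise the $\delta = 0$ value.

Under the generator's Gaussian noise model the excess of a true-zero pair is
$N(0, 2\sigma^2)$ while the threshold estimates $3\sigma$, so the one-sided
false-call probability is $\Phi^c(3/\sqrt{2}) \approx 1.7\%$ — the closed-form
oracle against which the detection rule is calibrated in the acceptance suite
(10,000 simulated null pairs, agreement within 3 binomial standard errors).

## Nitrogen budgets

Daily nitrogen demand of a compartment is modeled as a fixed fraction of its
standing N stock: `demand = growth_fraction × N_content`, default 0.2% of dry
weight per day for both tissue and skeleton — the literature value for coral
tissue growth in low light. Endolithic growth is probably slower, so skeletal
demand (and hence the denominator of the skeletal ratio) is likely
overestimated; the skeletal N content also includes inorganic N. Both caveats
travel with the output rather than being "corrected", since no defensible
correction exists.

`holobiont_budget()` reports four percentages: fixation/demand within each
compartment, total/total, and total fixation against tissue demand alone (the
bound if all skeletal DDN were translocated upward). The total/total value is
algebraically the demand-weighted mean of the compartment ratios — an exact
identity property-tested on 1,000 random draws, together with invariance of
every percentage under common rescaling of contents and rates.

The reef-scale operations expose their geometry explicitly instead of
hard-coding unrecoverable constants: `mucus_watercolumn_contribution()` takes
the areal coral cover, a 3D-surface-per-planar-cover factor (default 1) and
the water depth (default 5 m, the approximate reef depth of the motivating
sites), and converts ng N cm^−2^ h^−1^ to nmol N l^−1^ d^−1^ with
N = 14.0067 g/mol. Published reef-budget figures depend on supplementary
per-site parameters and are therefore not regression targets; the operations
are validated by unit arithmetic and linearity properties instead.

## Relative diazotroph activity

"Normalization" of amplicon replicates is not further specified in the field's
reporting; the package uses total-sum scaling to proportions and deliberately
omits rarefaction (nondeterministic, information-discarding). Replicates are
normalized first and their proportion vectors averaged (`merge_replicates()`),
so unequal library sizes cannot weight replicates unequally. RNA:DNA ratios
are computed per ASV only where the ASV has nonzero proportion in both merged
libraries — absent ASVs are excluded, never imputed — and aggregated as
mean ± SD with *n* within taxonomic orders per species × compartment
(`aggregate_by_rank()`). Because rRNA copy number and growth physiology
confound these ratios, every mean is reported with its SD and *n*; a
single-ASV taxon is flagged rather than given a fabricated spread.

*nifH* cluster labels (I–V, or `none` for non-*nifH* markers) are consumed
from the taxonomy table; only Clusters I–III contain genuine nitrogen fixers.
`cluster_relative_abundance()` reports the share of Clusters I–III within the
*nifH* community and the composition within those clusters, on per-sample
proportions averaged over the group so that sequencing depth never weights
the composition. `min_abundance_filter()` implements the strict `> threshold`
raw-count screen (default 10) used for seawater *nifH* ASVs.

## The synthetic-data generator

The generator exists so that every downstream stage has known ground truth.
`simulate_incubation_dataset()` inverts the rate equation: the noiseless
enriched atom% is $A_0 + r\,\Delta t\,(A_{^{15}\mathrm{N}_2} - A_0)/PN$, with
label enrichment drawn uniformly from 8.5–11.5 atom% per jar and additive
Gaussian noise (default SD $5\times10^{-4}$ atom%) on both members of each
pair. The noise default is a choice: published instrumental precision
(<0.16‰ on the delta scale) bounds only part of the within-pair variability,
so the default was set once where some but not all pairs of the slower
compartments clear the detection limit — mirroring the partial detectability
typical of field incubations. Default design: 4 colonies × 4 compartments ×
{enriched, control}, 24 h, PN = 500 µg per fragment, per-fragment rates
(µg N h^−1^) skeleton 0.10, host 0.010, symbiont 0.007, mucus 0.0005, which
put per-area rates of a ~30 cm² fragment in the published ranges. Draw order
is fixed (jar labels, control noise, enriched noise, δ^13^C), so output is a
pure function of the seed.

`simulate_paired_amplicon_tables()` draws DNA relative abundances from a flat
Dirichlet, multiplies by per-ASV activity factors and renormalizes to get
expected RNA proportions. With `dispersion > 0`, per-sample log-normal
perturbation is followed by a multinomial draw at a fixed library size (the
simplest count model consistent with proportion-based analysis); with
`dispersion = 0` the exact expected counts are emitted — possibly
non-integer — so the closed-form recovery
$\mathrm{ratio}_i = m_i / \sum_j p_j m_j$ holds exactly and is asserted to
$10^{-9}$.

What the generator does *not* emulate — compositional zero-inflation, taxon
correlation structure, chimeras, primer bias, tidal or light forcing —
bounds what passing tests show: they validate the estimators' arithmetic,
calibration and invariances, not robustness to every artifact of real
sequence data.

## Problem sizes and numerical choices

Property suites use 100–1,000 random draws; unbiasedness of the rate
estimator is checked on 1,000 independent noisy pairs (|bias| < 3 SE) and
detection calibration on 10,000 null pairs — sizes at which the binomial
standard error is small against the effect being excluded, while the whole
suite stays interactive. Tolerances: exact identities at 10^−10^–10^−12^
(floating-point headroom over the analytic value), published worked examples
at the precision they were printed with. Degenerate inputs fail fast with
classed validation errors (empty libraries name the sample, vocabulary errors
name the row) so the command-line wrapper can distinguish configuration
mistakes (exit 2) from runtime failures (exit 1).
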