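# htculture

Analysis tools for high-throughput dilution-to-extinction culturing (HTC)
experiments on marine bacterioplankton, screened by 16S rRNA gene amplicon
sequencing.

In an HTC experiment, seawater is diluted until each 2-ml well of a
microtiter plate receives on average `X` cells (typically around 5), hundreds
of wells are incubated, and wells showing growth are sequenced. Because each
culture is barcoded and sequenced like a miniature community, the amplicon
sequence variant (ASV) profile of every well tells you whether it holds a
monoculture, a mixed culture, or no discernible dominant organism — and the
fraction of positive wells tells you how culturable the source community is.

`htculture` covers the full desk side of such an experiment:

- **Simulation** — a Poisson extinction model of well inoculation
  (`simulate_wells()`, `simulate_reads()`, `simulate_environment()`), with
  closed-form oracles (`expected_positive_fraction()`,
  `expected_pure_well_fraction()`), so every downstream step is testable
  without sequence data.
- **Curation** — the per-culture `< 20` reads filter
  (`curate_culture_counts()`), environmental chloroplast and low-count
  removal (`curate_environment()`), and within-sample proportions
  (`relative_abundance()`).
- **Classification** — the monoculture / mixed / no-dominant /
  no-amplification screening rules (`classify_culture()`,
  `classify_cultures()`) and a deterministic culture-collection registry
  (`assign_isolate_ids()`).
- **Culturability statistics** — percent culturability with exact 95%
  confidence limits (`culturability()`, `experiment_summary()`,
  `clopper_pearson()`).
- **Comparison** — cultured-versus-environment ASV sets
  (`venn_membership()`), collection summaries by taxonomic group
  (`group_summary()`), and mixed-culture co-occurrence (`cooccurrence()`).
- **Pipeline** — `run_pipeline()` runs simulate → curate → classify →
  culturability → compare from one YAML config, deterministically.

## The statistic at the core

With wells inoculated with a mean of `X` cells, cell numbers per well are
Poisson, so a community with per-cell viability `V` leaves a well sterile
with probability `exp(-V·X)`. Inverting the observed positive fraction `p`
gives

```
V = -ln(1 - p) / X
```

Exact 95% limits come from the Clopper–Pearson binomial interval for `p`
(beta-quantile form), inserted back into the same equation. Positives are
counted two ways: monocultures only, and monocultures plus mixed cultures.

## Worked example

A fresh-seawater experiment with 576 inoculated wells at 5 cells per well,
in which screening identified 54 monocultures and 29 mixed cultures:

```r
library(htculture)

calls <- tibble::tibble(
  sample_id = sprintf("w%03d", 1:83),
  experiment = "fresh_seawater",
  category = c(rep("monoculture", 54), rep("mixed", 29))
)
glance(experiment_summary(calls, n_wells = 576, X = 5))
#> # A tibble: 2 × 5
#>   experiment     scope           x_pos n_wells culturability_pct
#>   <chr>          <chr>           <int>   <int> <chr>
#> 1 fresh_seawater mono_plus_mixed    83     576 3.1 (2.5, 3.9)
#> 2 fresh_seawater mono_only          54     576 2.0 (1.5, 2.6)
```

Reading: 83 of 576 wells yielded a mono- or mixed culture (p = 0.144), so
3.1% of the inoculated cells were culturable under these conditions, with
exact 95% limits 2.5%–3.9%; counting only monocultures gives 2.0%
(1.5%–2.6%).

A fully synthetic experiment, end to end:

```r
comm <- community_profile(tibble::tibble(
  taxon_id = c("ASV001", "ASV002", "ASV003"),
  abundance = c(0.5, 0.3, 0.2),
  viability = c(0.03, 0.05, 0.00)
))
sim <- simulate_experiment(comm, htc_design(576, 5), seed = 1)
calls <- classify_cultures(curate_culture_counts(sim$counts), sim$metadata)
category_tally(calls)
experiment_summary(calls, n_wells = 576, X = 5)
```

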