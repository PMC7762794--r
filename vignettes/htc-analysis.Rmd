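---
title: "Dilution-to-extinction culturing: model, curation rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dilution-to-extinction culturing: model, curation rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htculture)
```

## The extinction model

High-throughput dilution culturing dilutes a water sample until each well of
a microtiter plate receives on average $X$ cells, then scores wells for
growth. Because pipetting a dilute suspension is a thinning of a point
process, the realised number of cells per well is Poisson($X$), not exactly
$X$; this is both the physically correct model and the regime in which the
classical viability formula is exact. If a fraction $V$ of cells can grow to
detection, viable cells per well are Poisson($V X$), a well stays sterile
with probability $e^{-VX}$, and the observed positive fraction $p$ inverts
to

$$V = \frac{-\ln(1 - p)}{X}.$$

`culturability()` implements this inversion. Exact 95% limits come from the
Clopper–Pearson interval for $p$ — the beta-quantile form
$[\,q_{\beta}(\alpha/2;\,x,\,n-x+1),\; q_{\beta}(1-\alpha/2;\,x+1,\,n-x)\,]$,
equivalent to inverting the binomial tail tests — pushed through the same
equation. Since $-\ln(1-p)/X$ is strictly increasing in $p$, the interval
maps monotonically and retains its exact coverage. A plate with every well
positive gives $p = 1$ and a flagged infinite estimate rather than an error:
the data then only bound $V$ from below.

Two statistics are reported per experiment: positives counted as
monocultures only, and as monocultures plus mixed cultures. The denominator
is the number of *inoculated* wells, not the number of sequenced cultures:
wells that grew but were lost before sequencing still belong to the
denominator, and wells whose curated libraries are empty
(`no_amplification`) are not positives. `experiment_summary()` applies both
conventions; the denominator is an explicit argument because screening
attrition (growth-positive wells that never yielded an amplicon library) is
outside the model.

## The simulator

`simulate_wells()` draws viable founders of taxon $t$ as
Poisson($X a_t v_t$) — Poisson thinning of abundance-weighted inoculation —
independently across taxa and wells. A well is positive iff it has at least
one viable founder; the flow-cytometry growth threshold (about $10^4$ cells
ml$^{-1}$) is collapsed into this single Bernoulli outcome because growth
kinetics contribute nothing to the statistics computed here.

`simulate_reads()` models the amplicon screen. Per positive well, total
depth is lognormal, moment-matched to mean 14,047 and SD 8,014 reads and
truncated by rejection to [679, 57,557] — the per-culture depth profile
typical of multiplexed MiSeq screens of this size; only mean, SD and range
are specified, so the lognormal is a modelling choice, and `depth_sd = 0`
degenerates to a constant depth (used by tests that need noiseless
composition). Read composition is multinomial with probabilities
proportional to founder counts: equal per-taxon growth, because no growth
kinetics are specified anywhere in the design; an optional
`growth_weights` argument exists for sensitivity analysis. A
`contamination` fraction (default 0.005) of probability mass is reassigned
to community taxa by abundance, sized so that spurious ASVs usually land
below the 20-read curation filter at median depth — the filter is therefore
exercised realistically rather than vacuously. Negative wells produce
all-zero rows, which downstream becomes the `no_amplification` category.

What the simulator does *not* emulate: sequence-level error (it starts at
denoised ASV counts), chimeras, PCR bias, taxon-specific growth rates,
death between screenings, or wells that grew but failed at PCR. Passing
tests therefore validate the statistical pipeline, not the wet-lab or
read-processing stages.

Closed forms back the simulator: `expected_positive_fraction()` gives
$1 - e^{-X \sum_t a_t v_t}$ and `expected_pure_well_fraction()` gives
$\sum_t (1 - e^{-\lambda_t}) \prod_{s \ne t} e^{-\lambda_s}$, the
probability a well is positive with all founders of one taxon. The test
suite holds simulation output to these oracles within three binomial
standard errors at $10^5$ wells, and checks that across 200 simulated
576-well experiments at uniform viability 0.031 the 95% interval covers the
truth in at least 90% of replicates with mean estimate within 5% relative.
Those problem sizes make the replicate checks statistically meaningful while
keeping a full test run short.

## Curation rules

Per culture, ASVs with fewer than 20 reads are discarded (set to zero)
independently in each sample — the filter is per culture, not across the
pooled run, because index cross-talk and low-level error scale per library.
Exactly 20 reads is kept ("fewer than 20"). Proportions are computed on the
post-curation totals; a sample whose curated total is zero is flagged, not
divided.

For the environmental sample, chloroplast ASVs (order-level call in the
lineage) are removed *first*, then the sub-20-read filter is applied. The
order matters only through the denominator of the relative abundances;
removing chloroplasts first makes "post-curation total" mean the bacterial
community, which is what collection summaries compare against. Curation is
idempotent and never increases a count, both enforced by property tests.

Control wells pass through curation but are excluded from classification
and statistics; a control with nonzero curated reads raises a contamination
warning rather than an error, since the right response is human review.

## Classification thresholds

Rules are applied to exact post-curation proportions, in order: zero total →
`no_amplification`; dominant $\ge$ 90% with no other ASV at $\ge$ 5% →
`monoculture`; dominant $\ge$ 90% with a companion $\ge$ 5%, or dominant in
[50%, 90%) → `mixed` (members: dominant plus every ASV $\ge$ 5%); otherwise
`no_dominant`. Three boundary decisions were genuinely open and are resolved
as follows:

- The 5% companion threshold is inclusive ($\ge$) everywhere, although the
  mixed-culture wording is sometimes stated as strictly greater: one
  coherent partition of the simplex beats two near-identical thresholds.
  `minor_inclusive = FALSE` restores the strict reading.
- A dominant at exactly 50% counts as mixed. Two ASVs at exactly 0.50 are
  resolved by higher raw read count, then lexicographic ASV id — fully
  deterministic.
- No rounding to whole percentages before comparison; thresholds bind on
  exact fractions.

A mixed call whose dominant sits in [50%, 90%) can, in principle, have no
companion reaching 5%; it remains `mixed` with a single member, since the
category is defined by the dominant's range. Member ASVs of mono- and mixed
cultures receive sequential isolate identifiers (`assign_isolate_ids()`,
default prefix `"HIMB"`), ordered by sample, then member proportion
descending, then ASV id — so registries are reproducible. Each isolate
record is one strain; two isolations of one ASV are two strains of one ASV.

## Numerical and reporting choices

Percentages are reported rounded half away from zero to one decimal
(`round_half_up()`), which reproduces all printed central values of the
benchmark experiments. One published interval is internally inconsistent at
that precision: for 50 positives of 480 wells at 5 cells, the lower limit
computes to 1.6% after rounding, matching the tabulated value, while the
running text of the same study prints 1.7%. The package reports its
computed value and makes no attempt to match both.

The classifier is verified against an independent sentence-level
restatement of the category rules on all 231 three-ASV proportion vectors
on a 0.05 grid, and the Clopper–Pearson limits against the defining tail
equations $P(K \ge x \mid p_{low}) = P(K \le x \mid p_{high}) = \alpha/2$
for every $x \le n \le 50$ (bisection oracle, $10^{-6}$ tolerance).

## Pipeline determinism

`run_pipeline()` consumes one YAML config (community, design, thresholds,
stage toggles, seed) and derives fixed per-stage substreams from the single
seed, so reruns are byte-identical — verified by checksum in the tests. All
outputs are staged in a temporary directory and committed to the output
directory only when every enabled stage has succeeded; a failing stage
leaves nothing behind. The manifest records package version, seed,
thresholds, and per-file row counts and checksums.

## Limitations

Single dilution level per experiment (no multi-dilution MPN), no Bayesian
intervals, no phylogenetics, no BIOM/HDF5 input, and no modelling of
subculture transfer. These are out of scope by design; the package's results
are those computable from ASV count tables and plate metadata alone.
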