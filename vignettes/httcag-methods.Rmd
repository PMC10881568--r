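---
title: "Methods: simulating and analysing HTT CAG repeat genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing HTT CAG repeat genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httcag)
```

## The scientific problem

The huntingtin gene (*HTT*) carries a CAG short tandem repeat whose
constitutional length places an allele in one of four clinical bands:
normal (≤ 26 repeats), intermediate (27–35), incomplete penetrance
(36–39) and full penetrance (≥ 40, Huntington disease). The DNA
mismatch-repair (MMR) pathway promotes somatic expansion of this
repeat, which raises the question whether MMR gene haploinsufficiency —
as found in Lynch syndrome carriers of heterozygous loss-of-function
variants in *MLH1*, *MSH2* or *MSH6* — measurably alters constitutional
repeat size at the population level.

The study design this package operationalizes compares Lynch-syndrome
genetic subgroups against controls on three read-outs:

1. the per-individual **sum of CAG repeats** (both alleles summed,
   because which *HTT* allele cosegregates with the MMR variant is
   unknown), compared by pooled two-sample Student t tests with a
   Bonferroni-adjusted significance threshold;
2. the fraction of individuals carrying an **intermediate allele**
   (27–35 repeats), plus a sensitivity re-analysis with those carriers
   removed;
3. the **somatic expansion index (EI)** derived from
   capillary-electrophoresis peak heights.

Because the underlying individual-level data are not openly available,
the package pairs the analysis layer with a synthetic-data layer: a
cohort generator and a peak-level electropherogram simulator whose
ground truth lets every downstream step be verified quantitatively.

## The allele model and cohort generator

Alleles are drawn from a discrete distribution on an integer support
(default 9–55 repeats). The default weights are a discretized truncated
log-normal with `meanlog = log(17)` and `sdlog = 0.30`, i.e. centred on
the population modal allele of about 17 repeats with a long right tail.
`sdlog = 0.30` was chosen so that roughly 6% of *alleles* fall in the
intermediate band, echoing the reported population frequency of
intermediate alleles (≈ 7%). A single-parameter log-normal cannot
simultaneously match that band frequency and the printed standard
deviation of the sum of repeats (≈ 4.5; the default model gives ≈ 7.5),
and we deliberately prioritized the band frequency because the carrier
tallies are exact reproduction targets while the group means and SDs
are not — they depend on the unavailable individual-level data and
serve only as qualitative calibration points. The model is a stand-in,
and both support and weights are configurable.

Two generator features matter for verification:

* **Exact carrier counts.** When a group requests `k` intermediate
  carriers out of `n`, carrier individuals get one allele drawn from
  the model conditioned on 27–35 and one conditioned on ≤ 26, and all
  remaining individuals are conditioned to carry no allele in 27–35.
  Counts are exact by construction, matching how the study reports
  exact tallies rather than rates.
* **Exact mean shifts.** A per-allele shift δ (possibly fractional,
  e.g. −0.75) is implemented on the weight table itself: mass at count
  *c* moves to *c* + ⌊δ⌋ with probability 1 − frac and to
  *c* + ⌊δ⌋ + 1 with probability frac. The analytic mean therefore
  shifts by exactly δ, and the expected sum of repeats by exactly 2δ —
  the property the parameter-recovery study leans on. When carriers are
  forced, the conditioning is applied to the shifted table.

One parent seed spawns a child stream per group, keyed by the group
label, so editing one group never perturbs the draws of another.

## The trace simulator

Simulation starts at the peak-table level (the entry point of the real
analysis is exported peak-height data, not raw fluorescence). For each
allele of main height *H* (default 1000; equal alleles superpose):

* **stutter** peaks at −1…−`stutter_depth` repeats with heights
  *H*·s^k (defaults s = 0.3, depth 3) — the PCR slippage artifact,
  modelled only leftward;
* **somatic expansion** peaks at +1, +2, … with heights
  *H*·λ·e^(k−1) (defaults λ = 0.25, e = 0.45), truncated below one
  height unit — modelled only rightward, since the expansion index
  considers only peaks right of the modal allele and somatic
  contraction is out of analytic scope;
* artifacts landing in the same repeat bin add; independent Gaussian
  height noise (sd 15) is applied and heights are clipped to
  (0, saturation].

Peaks are emitted in repeat units, in bp (`flank_bp + 3·repeat`) or in
raw migration units (an affine map of bp), with a GeneScan-500-style
ladder co-emitted for calibration. The two named flank profiles
(`bochum` = 54 bp, `lund` = 79 bp) stand in for the two primer sets of
the assays being emulated; neither published amplicon offset is
asserted as a constant — both are configuration.

The stutter and mosaicism magnitudes of the real samples are not
published; the defaults were fixed once against a single contract — the
assay's validated accuracy of ± 1 CAG repeat for alleles under 45
repeats — which the test suite checks end to end on ≥ 1,000 simulated
samples (≥ 99% of in-scope alleles within ± 1 repeat). What passing
that check shows is that the calling logic is correct under the
modelled artifact structure; it does not show robustness to artifacts
the simulator omits (size-dependent amplification bias, off-scale
peaks, dye pull-up, position jitter of the sizing itself).

## Calibration and allele calling

Ladder peaks are matched one-to-one to the size standard's fragments
(after dropping sub-threshold peaks; a count mismatch is an error that
names both counts) and define a monotone piecewise-linear raw→bp map,
extended linearly beyond the terminal knots using the end-segment
slopes. bp sizes convert to integers as `round((bp − flank)/3)`; R's
ties-to-even is the documented rounding convention — the clinical
rounding routine is not printed anywhere, and on exact simulated sizes
the choice never engages.

Calling anchors on the modal (highest) peak; ties resolve to the larger
repeat and are flagged. A candidate second allele is masked as stutter
if it sits within `stutter_depth` repeats left of the modal allele at
under `stutter_cut` (default 0.5) of the modal height, or as expansion
mosaicism if it sits right of the modal allele at under `expansion_cut`
(default 0.5). The tallest unmasked peak is the second allele; if none
survives, the call is homozygous and flagged, since a homozygote cannot
be distinguished from single-allele dropout at the peak level. The 0.5
cuts are design choices: default-simulated stutter (0.3 of main) is
always masked while a true heterozygous partner (≈ 1.0 of main) never
is; peaks within 20% of a cut raise QC flags instead of silently
flipping. Point estimates go downstream without error propagation,
mirroring the convention of excluding the ± 1 methodological error from
statistical calculations.

## The expansion index

For one profile with modal peak height *H* at repeat *m*, retained
peaks are the modal peak plus every peak at repeat > *m* with height
≥ *c*·*H* (default *c* = 0.20), and

EI = Σ h·(r − m) / Σ h over the retained set.

Dialect choices, made once and recorded in every report:

* The threshold value is not printed in the study (it defers to the
  instability-index literature), so *c* is a configuration key,
  applied uniformly — including to the right shoulder of the modal
  peak — and before normalization.
* The denominator includes the modal peak. This bounds the weights and
  makes EI = 0 exactly when no expansion peak is retained, which is the
  correct no-mosaicism limit.
* Modal-height ties resolve to the larger repeat (conservative: it can
  only reduce EI) and are flagged.
* In the pipeline, each sample's EI profile is anchored at the larger
  *called* allele (peaks at repeats ≥ that allele), so a heterozygote's
  short allele is never counted as an "expansion peak" of the modal
  allele. Without this restriction the λ = 0 limit would not be
  identically zero whenever the shorter allele happened to be modal.
* The "250 consecutively selected controls" of the original EI analysis
  are represented as a named reference subset (the first 250 control
  samples) used only as the comparison group in EI summaries — the
  study states no per-sample normalization against controls, so none is
  applied inside the statistic.

With the default threshold, expansion peaks below 0.20 of the modal
height are invisible to EI, so the default λ = 0.25 was chosen above
the threshold to give the index stable mass; the published mean EI
values (0.099–0.131) are not reproduction targets, and the default
simulation produces values of the same order but not those numbers.

## The statistical layer

The per-individual statistic is the sum of both CAG alleles. Group
comparisons use the pooled-variance Student t test computed from group
summaries — *not* Welch — because the printed p for the key comparison
(MLH1 vs controls, p = 0.014) is consistent with the pooled form
recomputed from the printed summaries (p = 0.0134). Bonferroni
correction is implemented as threshold adjustment (raw p compared
against α/m; 0.05/3 = 0.017 at three decimals), matching the stated
decision rule. Tests are two-sided with 95% CIs. Recomputing the CI
from rounded summaries cannot reproduce the printed interval exactly
(−2.766 to −0.310); the recomputed low end differs by ≈ 0.1, which is
the documented agreement level. Degenerate inputs (zero pooled
variance) are flagged rather than silently propagated.

The carrier tally counts individuals with ≥ 1 allele in 27–35 and
prints percentages at one decimal; note that 1/23 renders as 4.3. The
"without IA" re-analysis removes every carrier and reruns the identical
comparison code path.

## Reproducibility and problem sizes

All randomness flows from one seed: per-group child streams for the
cohort, a tagged child stream for trace noise. Re-running a
configuration reproduces every output byte for byte, and each output
file carries the configuration hash and seed. The shipped test and
acceptance problem sizes — 1,000-sample calling-accuracy runs, 100
replicate cohorts at the full published group sizes for shift recovery,
and 1,000 down-scaled (40 vs 40) replicates for type-I calibration —
were chosen as the smallest designs whose Monte-Carlo error is well
below the effects being checked.

```{r example}
spec <- cohort_spec(list(
  cohort_group("controls", 559, intermediate_carriers = 29),
  cohort_group("MLH1", 60, intermediate_carriers = 1, mean_shift = -0.75)
), seed = 20240221)
cohort <- generate_cohort(spec)
intermediate_carrier_tally(cohort$genotypes)
compare_groups(cohort$genotypes, reference = "controls",
               m_comparisons = 3)[, c("group_a", "t", "p", "significant")]
```

## Known limitations

* The allele model is a stand-in; no population allele-frequency table
  for the original control groups is available.
* The simulator omits raw-trace physics (jitter, pull-up, off-scale
  clipping beyond a hard saturation), so the ± 1-repeat contract is
  verified only under the modelled artifact structure.
* EI is not age-adjusted, and no intergenerational transmission,
  CAA-interruption structure, or linkage between the MMR variant and a
  specific *HTT* allele is modelled — the emulated study itself lacks
  the trio data that would require those.
* Group means and SDs of the sum of repeats, and mean EI levels, are
  qualitative calibration points only; the package makes no claim of
  reproducing them numerically.
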