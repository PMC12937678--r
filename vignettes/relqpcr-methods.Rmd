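---
title: "Methods: relative RT-qPCR quantification in relqpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative RT-qPCR quantification in relqpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relqpcr)
```

## The model

relqpcr implements the comparative 2^−ΔΔCq (Livak) model of relative
expression. For sample *s* and target gene *g*,

* ΔCq(s, g) = Cq(s, g) − mean over references r of Cq(s, r),
* ΔΔCq(s, g) = ΔCq(s, g) − ΔCq(calibrator, g),
* FC = 2^−ΔΔCq, log2FC = −ΔΔCq.

Two modelling assumptions matter. First, a **fixed amplification factor of
2 per cycle** for every assay. The package reports dilution-series
efficiencies (E = 10^(−1/slope)) for validation, but never applies
assay-specific correction: dilution series from fragmented FFPE templates
routinely show apparent efficiencies above 100% for matrix-related reasons,
so a fitted E would import artefact rather than remove bias. Second,
normalizing to "the geometric mean of the reference genes" is implemented
as the **arithmetic mean of their Cq values**. At E = 2 these are exactly
equivalent — the geometric mean of quantities 2^−Cq is 2^−mean(Cq) — and
the arithmetic form avoids a common implementation error (geometric
averaging of the Cq values themselves, which is a different and wrong
statistic).

The calibrator is the **median ΔCq of the designated calibrator samples**,
computed per target. With two calibrators the median is their midpoint, so
the two calibrator samples always receive log2FC values of equal magnitude
and opposite sign — a useful built-in check that the packaged example
cohort satisfies exactly.

## Replicate triage

Reactions run in technical triplicate are classified by three thresholds
(all configurable, defaults in parentheses):

* `gold_spread` (0.5 Cq): total spread for a fully consistent triplicate.
* `accept_spread` (0.8 Cq): relaxed spread accepted for FFPE-derived RNA,
  and the maximum difference allowed between the two most consistent
  replicates.
* `outlier_delta` (0.5 Cq): a third replicate deviating more than this from
  the mean of the most consistent pair is excluded as a technical outlier.

The decision order is: find the closest pair; if even it differs by more
than 0.8 Cq the reaction is `INVALID`; otherwise apply the outlier rule;
otherwise classify by total spread. The outlier rule is evaluated **before**
the 0.8-Cq total-spread acceptance because it is stated as unconditional in
standard FFPE practice; the reaction (24.00, 24.10, 24.90) is therefore
`OUTLIER_REMOVED` (the third replicate deviates 0.85 from the pair mean),
not `FFPE_ACCEPTED`. The converse situation — a consistent pair, a third
replicate within 0.5 Cq of its mean, yet total spread above 0.8 Cq — is
geometrically impossible, which the test suite confirms against a
brute-force rule oracle on gridded triplets.

Tie-breaking: when two pairs are equally close, the pair whose mean is
nearest the median of all three values wins, then lowest replicate indices.
This keeps the rule deterministic and symmetric under replicate
permutation; translation of all replicates by a constant shifts the mean
and changes nothing else.

Reactions with one absent replicate (no amplification) are classified on
the remaining pair; reactions without two present values are `INVALID` with
a message rather than an error, so a single bad well never aborts a run.

## Control wells and bridging

* NTC: pass when negative or late (Cq ≥ 37.5 within 40 cycles).
* NRT: pass only when negative (any signal suggests gDNA carryover).
* Internal control: the acceptance statement "ΔCq(sample − IC) < 2" names
  no reference IC, so the package interprets it as **deviation from the
  run-median IC Cq** below 2 Cq. This is a design choice, not the only
  reading; it is robust to a plate-wide shift and flags precisely the
  samples whose amplification deviates from their run.
* Inter-run bridging: samples re-measured across runs must agree within
  `bridge_tolerance` (default 1.0 Cq, the permissive end of the usual
  0.5–1 Cq band).

When a reaction is repeated on a later plate, the valid repeat **replaces**
the failed measurement in the Cq matrix; an invalid repeat never erases an
earlier valid result.

## Reference-gene stability

Four standard algorithms are computed on one shared complete-case sample
set (samples missing any candidate are dropped for all candidates, so the
four rank vectors are comparable):

* **geNorm** M: mean over partner genes of the SD across samples of the
  pairwise log2 ratio; iterative worst-gene exclusion is reported, but the
  rank vector entering the composite uses the single-pass M values so that
  every gene receives a strict 1..n rank (classic geNorm leaves the final
  two genes tied at 1.5, which a geometric-mean composite cannot use).
* **NormFinder**: by default the ungrouped variant (double-centred residual
  SD per gene), because composite web tools typically take no group input;
  the grouped variance-decomposition variant
  (sqrt of between-group variance estimate + mean within-group variance)
  is available via `groups =` and requires ≥ 2 samples per group.
* **BestKeeper**: raw-Cq SD and CV per gene plus Pearson correlation with
  the per-sample mean-Cq index; ranked by ascending SD.
* **Comparative ΔCq**: mean pairwise SD on raw Cq — numerically identical
  to geNorm M at E = 2, kept as a separate method because composite tools
  treat it as one.

The composite is the geometric mean of the four ranks; values ≲ 1.5
conventionally indicate good references.

One asymmetry deserves emphasis: the three log-ratio methods are invariant
to per-sample loading offsets, but **BestKeeper's raw-Cq SD is not**. In a
cohort with ~1 Cq loading spread, BestKeeper's SD is dominated by loading
for every candidate, and a moderately unstable gene (say 0.8 Cq extra
wobble) can win the BestKeeper rank by chance even while the other three
methods place it last. The composite then still usually, but not always,
ranks it last. The seeded simulations in the test suite quantify this:
with a spike of ≥ 1 Cq on cohort-sized sample sets the spiked candidate's
composite rank is last in ≥ 99 of 100 runs.

## Statistics

* **Kruskal–Wallis** uses the tie-corrected H with the chi-square
  approximation (`stats::kruskal.test`), the behaviour of the standard
  statistical packages this workflow targets. All-identical values are
  reported as H = 0, p = 1 rather than an error.
* **Mann–Whitney** defaults to the normal approximation on the
  tie-corrected variance **without continuity correction**; with the
  correction, borderline published values (e.g. 0.004 on the packaged
  cohort's TEAD4 contrast) shift to 0.005, which fixes the choice. An
  exact mode enumerates the full rank-sum distribution via a dynamic
  program over doubled average ranks (ties handled exactly) for
  n ≤ 25, reporting the doubled smaller tail capped at 1. The
  approximation is crude at 3–6 per group (tail deviations up to ~0.2)
  and agrees with the exact p within 0.03 from about 12 per group.
* **Benjamini–Hochberg** adjustment is applied within each test family
  (one family per test type across genes); raw and adjusted p-values are
  both reported, since published tables typically print raw values.
* **Spearman** rho is the Pearson correlation of average ranks with a
  t-approximation p-value; zero-variance input yields NA with a warning.

Full precision is carried end to end. Rounding happens only in writers:
fold changes and log2FC at 2 decimals, p-values at 3 decimals alongside a
full-precision column, using round-half-away-from-zero to match how
spreadsheets and instrument software print. A consequence worth knowing:
in a published table whose FC and log2FC columns were rounded
independently from one unrounded ΔΔCq, the columns are *not* exact
transforms of each other — log2 of a rounded FC can differ from the rounded
log2FC by up to 0.005/(FC·ln 2) + 0.005, and rounding can split or create
ties. The packaged example table is internally consistent in exactly this
sense, and the acceptance tests check it that way rather than with a flat
tolerance.

## The simulator

`simulate_cohort()` draws
Cq(sample j of group g, gene i, replicate k) =
baseline_i − effect(i, g) + loading_j + instability(i, j) + ε with
ε ~ N(0, replicate_sd²) and loading_j ~ N(0, loading_sd²). Defaults mirror
the packaged cohort's design: group sizes N:3/A:3/B1:5/B2:5/B3:5/TC:5, six
targets, four reference candidates (one with 0.8 Cq instability), gene
baselines drawn once from Uniform(22, 30), loading SD 1.0 Cq, replicate SD
0.15 Cq, 3% outlier reactions (one replicate shifted by Uniform(1, 3) Cq),
1% invalid reactions (replicates scattered 2 Cq apart so no consistent pair
survives), 5% late-signal NTCs. The default effect profile is the example
cohort's median log2FC matrix, so parameter-recovery tests ask the pipeline
to re-estimate exactly the kind of effects the workflow is meant to detect.
Effects enter with a negative sign on the Cq scale (higher expression =
lower Cq); reference genes carry no effect, so each sample's true log2FC
equals its group effect.

Calibrator-group reactions drawn invalid are re-emitted as a clean repeat
plate, mirroring what a real study must do — the calibrator anchors every
fold change and cannot be left missing. Non-calibrator invalid reactions
simply leave missing cells.

What the simulator does **not** emulate: melt curves and amplification
curves, per-gene efficiency heterogeneity (everything amplifies at E = 2 by
construction), plate-position effects, correlated degradation of specific
transcripts in FFPE blocks, and cellular-composition admixture. Passing
recovery tests therefore demonstrate correctness of the computational
pipeline under its own model, not robustness to every artefact of archival
tissue.

## Numerical and design choices

* Absent Cq ("no amplification") is `NA` throughout — a first-class state
  distinct from 0 and from the cycle limit, which NTC/NRT logic requires.
* Validation is total: input either becomes a checked `cq_dataset` or
  raises a typed error (`relqpcr_schema_error`, `relqpcr_integrity_error`,
  `relqpcr_range_error`, ...) naming the offending column/row; there is no
  partially-loaded state.
* Stability computations require ≥ 2 (pairwise methods) or ≥ 3
  (geNorm iteration, NormFinder) candidates and ≥ 3 complete samples;
  degenerate requests raise argument errors rather than returning NaN.
* A zero-variance BestKeeper index leaves correlations NA (reported, not
  dropped).
* Exact Mann–Whitney beyond 25 total observations is refused with a
  pointer to the normal approximation, keeping worst-case cost bounded.
* Test problem sizes were chosen to exercise every rule while keeping the
  default suite within a few minutes: 10,000 gridded triplets against the
  triage oracle, 100-run seeded batches for the stability and spike
  properties, and 200-cohort batches for the power (YAP1 effect profile,
  detected in ≥ 80% of runs at α = 0.05) and type-I (≤ 10% under the null)
  characteristics.

## Limitations

The workflow quantifies relative transcript abundance under a shared-E
model; it does not attempt efficiency-corrected (Pfaffl-type) or absolute
quantification, inter-plate calibrator scaling beyond the bridge check, or
any survival/outcome modelling. The grouped NormFinder variant implements
a standard variance-decomposition reading of the intra/inter-group model;
published NormFinder software differs in small details of its shrinkage,
so grouped stability values should be compared by rank rather than by
absolute value across implementations.
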