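---
title: "Methods: MLPA-based analysis of gross chromosomal rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLPA-based analysis of gross chromosomal rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpaGCR)
```

## The assay and its computational model

The chromosome V GCR assay selects yeast cells that lost a nonessential
terminal segment of chrV-L carrying counter-selectable markers. When a Ty1
element (*Ty912*) is inserted in that segment, the dominant repair outcome
is a nonreciprocal translocation: the broken chromosome V captures the
terminal segment of another arm via homologous recombination between
*Ty912* and an ectopic Ty1, Ty2 or solo delta element. The genomic
signature is therefore a copy-number 0 at the end of chrV-L plus a
copy-number 2 segment running from the target element to the telomere of
the donor arm, while the donor chromosome itself stays intact.

MLPA reads this signature out with pairs of ligation probes amplified by
universal primers; each probe pair yields a product of unique length whose
peak area on a capillary trace is proportional to locus dosage. The
package models everything downstream of the trace: panel design against an
annotation, dosage quantification, event classification, breakpoint
localization, and the rate/hotspot statistics used to compare strains.

Assumptions inherited from the assay: control samples are euploid; probe
efficiencies are sample-independent (they cancel in the control ratio);
dosage noise is multiplicative; every informative isolate carries the
chrV-L deletion; a duplication is terminal (element-to-telomere), so an
arm's telomeric probe is duplicated if and only if the arm carries a
translocation-associated duplication bounded at or centromeric to the
probe.

## Probe panels

Because the package carries no sequence, "unique sequence suitable for a
probe" is abstracted to a repeat-free window of at least `min_window`
(default 300 bp). A telomeric probe is placed mid-window between the most
distal element and the telomere; when that window is too short the probe
falls back immediately centromeric to the terminal element(s)
(`FALLBACK_CENTROMERIC`), which makes duplications bounded by those
skipped elements invisible — the origin of the panel's 250/254 = 98.4%
theoretical coverage on the shipped genome. Centromeric probes sit
centromeric to the arm's innermost element so that no terminal duplication
can cover them; a whole-chromosome duplication is then operationally
"call ≥ 2 at every probed locus of the chromosome". Arm-specific ladders
put one probe in every inter-element gap; elements closer than `collocate`
(default 1 kb) share flanking probes, which is why breakpoints localize to
small clusters (e.g. YCRWdelta8/9/10) rather than single elements.
Product lengths are assigned deterministically in panel order as an
arithmetic ladder with a 2 bp minimum gap (defaults 100–162 bp for 32
probes); the gap is the assay's design constraint, the start length is a
free convention.

## Copy-number calling

Two within-sample normalizations are implemented. Global-sum (default for
genome-wide panels) divides each area by the sample's total probe area and
is exactly invariant to per-sample scale. Anchor normalization (default
for arm ladders) divides by the most centromeric probe, assumed
single-copy; it is preferred on ladders because a terminal duplication can
span a large fraction of the probes and distort the global sum. With
`k/n` probes duplicated, the global-sum dosage ratio of a two-copy locus
is `2n/(n+k)`, which crosses the 1.5 rounding boundary at `k/n = 1/3`;
the two schemes therefore agree only while less than a third of a ladder
is duplicated, and the anchor scheme is the robust choice for hotspot
arms where most probes lie telomeric to the target.

The control-relative ratio is rounded half-away-from-zero to an integer
call. A cell is `AMBIGUOUS` when the ratio deviates from its nearest
integer by more than `tolerance` (default 0.3) — our operationalization of
"could not be unambiguously assigned"; the threshold is configurable
because the boundary between a noisy single-copy locus (ratio ≈ 1.3) and
a mixed colony (ratio ≈ 1.5) is a judgement call. At the simulator's
default 5% multiplicative CV a miscall requires an ~8-sigma excursion, so
call accuracy is effectively limited by systematic dosage shifts, not
noise.

## Classification and breakpoint localization

Classification is a pure function of the call matrix: chrV-L deletion
(telomeric call 0), whole-chromosome duplications first, then arm
duplications on the remaining arms, with `AMBIGUOUS` propagating from any
contributing cell and `NO_DUPLICATION` for deletion-only isolates.
Duplications detected at fallback probes carry a caveat (the terminal
elements are unprobed). Breakpoints are the unique 1 → ≥2 step of an arm
ladder; candidate targets are the annotated elements strictly between the
flanking probes, with `UNKNOWN` reported when that interval contains no
element rather than guessing. Product geometry follows target
orientation (telomere-oriented → monocentric; centromere-oriented →
dicentric intermediate, which must rearrange further to survive).
Non-monotone ladders are flagged `COMPLEX` but summarized at their most
centromeric step, matching how dicentric-derived products are tabulated.

## Rates and statistics

Per-culture fluctuation rates are summarized by the median and a
distribution-free order-statistic CI: `(x_(k), x_(n-k+1))` with exact
binomial coverage `1 − 2 P(Bin(n, 1/2) ≤ k−1)`; the narrowest interval
reaching 95% is reported, or the full range with its achieved coverage
when n is too small (93.75% at n = 5). The median is used because
jackpot cultures make the mean meaningless.

The observed duplication rate of an arm is the strain's total rate times
the fraction of its analyzed GCRs duplicating that arm. Expected rates
under a mutation that scales all arms uniformly are the control rates
times `S = Σ test / Σ control` (computed over duplication rates, not bulk
rates, so duplication-poor strains like rad52-type mutants are handled
correctly). Zero counts use upper limits: one hypothetical event's worth
of rate (`total rate / number of duplication-bearing GCRs`; an
`all_gcrs` denominator variant is provided since the phrase "number of
duplications" admits both readings). Arms are flagged significant when
the observed rate leaves the control rate scaled by the test strain's
bulk-rate fold CI; this CI-scaling construction is one reasonable
reading of an under-specified procedure and is exposed, not asserted
against any published p-value.

The multinomial goodness-of-fit test compares the Pearson chi-square of
observed per-arm counts against their catalog-share expectation to the
same statistic on `R` multinomial null draws, with empirical
`p = (k+1)/(R+1)` — at `R = 2000` a fully extreme observation prints
5.00e-4. The log-likelihood-ratio statistic is available as an option;
the choice matters little at cohort sizes of ~100. Ties count as
exceedances, making the test conservative, and the `(k+1)/(R+1)` form is
superuniform by construction; measured type-I error at alpha 0.05 over
2000 null cohorts is 0.04–0.06. Fisher, Wilcoxon, binomial and
hypergeometric tails are delegated to R's exact implementations.

Fold changes over a reference strain print with the convention that
reproduces strain-table reporting: folds below 1 round to one decimal,
folds at or above 1 round to the nearest integer and then to two
significant figures (119.05 → 120, 2.62 → 3, 19.05 → 19).

## What the synthetic data emulate — and what they do not

`make_fixture_annotation()` is constrained to the published aggregates of
the S288C repeat landscape: 254 Ty-related targets in Ty1+delta counting,
13 Ty2 elements, ~52% centromere-oriented elements, the four arms whose
terminal element abuts the telomere, and the exact structure of the four
hotspot arms (FS1/FS2 on chrIII-R, the two chrV-R clusters plus four
singleton loci, the chrXIV-L trio, the chrX-R tandem pair). Everything
else — per-arm counts, positions — is allocated proportionally to arm
length with seeded jitter, because the real per-arm counts are published
only graphically. Consequently per-arm catalog probabilities (and any
statistic built on them, such as single-arm overrepresentation p-values)
are fixture-specific; aggregate shares (69% on four arms, 63.2% in six
regions) are not, since they are driven by the encoded event counts.

The peak simulator draws lognormal probe efficiencies (sigma 0.3),
sample scales (sigma 0.2) and multiplicative measurement noise (CV 0.05
default), with a 2% background signal at zero-copy loci. It does not
emulate sizing errors beyond ±1 bp, peak overlap, stutter, or
inter-run drift — so passing tests demonstrate the calling logic and its
noise robustness, not instrument-level behaviour. The fluctuation
simulator uses the standard clone-size construction (Poisson number of
mutations, descendants `N/s` for a mutation at population size `s`),
which reproduces jackpot skew but ignores death, plating efficiency and
post-plating growth.

The deterministic fixture cohorts encode the published event counts
exactly (wild-type 112 = 73 hotspot + 33 other + 5 + 1; rad52-type
50 = 34 + 16; rtt109-type 49 with 11 aneuploids, one double). The
stochastic event models use those counts as maximum-likelihood category
probabilities. The ambiguous isolate is emulated as a 1.5-dosage locus
(a mixed colony), which is one plausible mechanism for an unassignable
sample, not the (unstated) original one.

## Numerical choices and problem sizes

Seeds are explicit everywhere and generators restore the caller's RNG
state. Ties at `x.5` round half away from zero; they are flagged
ambiguous at the default tolerance anyway. The Lea–Coulson per-culture
transform inverts `r/m − ln m = 1.24` by bisection (`uniroot`, tolerance
1e-12), mapping count 0 to rate 0; it is used for rate-recovery
calibration because the naive frequency `r/N` overestimates the rate by
a factor ~`ln(mN)` and is retained only as the simple default transform.
Calibration suites use: 200 isolates at CV 0.05 for call accuracy
(≥ 99% required), 2000 null cohorts x 2000 replicates for the
multinomial type-I error (0.05 ± 0.015), and 200 repetitions of 49
cultures at rate 1.7e-6 and population 1e7 — the scale of a real
fluctuation experiment in this assay — for CI coverage (≥ 90%). These
sizes keep the full suite under a minute while leaving Monte Carlo
margins well clear of the thresholds.

## Known limitations

Arm deletions other than chrV-L are reported but not modelled as assay
outcomes; secondary rearrangement paths of dicentric intermediates are
not reconstructed; junction sequences are out of scope. The classifier
cannot see an arm duplication stacked on a whole-chromosome duplication
of the same chromosome (calls ≥ 2 everywhere subsume it). GFF3 support
covers the dialect documented in `read_genome_annotation()`, not
arbitrary GFF3. The expected-rate significance flag depends on the
CI-scaling construction described above and should be treated as a
screening heuristic.
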