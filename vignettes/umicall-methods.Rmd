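---
title: "Barcode-aware low-fraction variant calling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-aware low-fraction variant calling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umicall)
```

## Why barcodes change the statistics

In targeted deep sequencing, a 1% variant is indistinguishable from the
base-calling error floor of individual reads (Q30 means one wrong base per
thousand). Molecular barcodes (UMIs) restructure the problem: every
original DNA molecule is tagged before amplification, so the reads sharing
a barcode are replicate measurements of one molecule. A real variant is
(i) consistent within its barcode families and (ii) carried by several
independent families, while sequencing and late-PCR errors scatter thinly
across reads and families. `umicall` formalises this with a two-level
model: a per-family Bayesian posterior, and an additive locus-level
evidence score.

## The per-family model

At a locus, the allele space Θ always contains the four nucleotides, plus
every indel allele observed in the reads, plus the reference; each element
receives the uniform prior 1/|Θ|. Indel alleles are held internally in an
anchored form (`+SEQ` = insertion after the locus base, `-SEQ` = deletion
of the following bases) and converted to the usual VCF left-anchored
REF/ALT representation only at the output boundary.

Given the candidate true allele X, the likelihood of the family's reads is
approximated by a weighted sum of two error channels:

* **Base-calling errors**: every read not matching X is explained by its
  own Phred error probability `e = 10^(-q/10)`, and every matching read
  contributes `1 - e`. This product is scaled by `c_p`, the prior
  probability that amplification introduced any error at the site
  (`pcr_cycles * pcr_per_cycle_error` = 30 × 10⁻⁶ = 3×10⁻⁵ by default).
* **PCR errors**: no base-calling error anywhere (product of `1 - e`),
  with the non-X reads explained by a heuristic PCR-error probability
  `10^(-6 (0.5 + n_Y) / Σ_Z (0.5 + n_Z))` minimised over the competing
  alleles Y ≠ X. The pseudo-count 0.5 keeps the exponent defined for
  alleles with no reads; the minimum is attained at the competing allele
  with most reads, and ties (broken A < C < G < T < indels for
  determinism) do not change the value.

The mixture weight `alpha` defaults to 0.5, which makes the posterior
identical to using the plain sum of the two terms — the test suite checks
this equivalence exactly. The min term is applied over all of Θ∖{X},
treating indel alleles on the same footing as substitutions.

Posteriors follow from Bayes' rule with the uniform prior. Everything is
computed in log space and normalised with a max-shifted log-sum-exp, so
families with extreme qualities cannot underflow to NaN; a family whose
likelihoods all vanish (possible only with quality 0 reads) falls back to
the uniform posterior. The complement `1 - P(X|BC)` is accumulated from
the competing alleles' likelihoods rather than by subtraction, so small
complements keep full relative precision.

## Locus-level evidence and candidate calling

Each family contributes `w_k = -log10(1 - P(A|BC_k))`, and the prediction
index is `I(A) = Σ_k w_k` — the `-log10` probability that no molecule
carries A, additive over families. Before taking the logarithm the
complement is floored at `posterior_clamp = 10⁻⁶`, so one molecule can
contribute at most 6 index units; this bounds the influence of any single
barcode (a clean fully-supporting family of 8 read pairs at Q30
contributes about 4.3 units, so the clamp binds only in pathological
cases). A non-reference allele with `I` at or above the threshold becomes
a candidate; a locus with zero usable families is emitted as a no-coverage
call rather than silently dropped.

Per-read-pair voting is enforced upstream: overlapping mates observing the
same locus are consolidated into one observation (agreeing mates keep the
higher quality; disagreeing mates are discarded), ambiguous bases (`N`)
are dropped, and positions inside a deletion carry no base observation
from that read.

## Pre- and post-processing filters

Read-level pre-filters reject unmapped/secondary/supplementary/QC-fail
records, mapping quality below 17, and (by default) non-proper pairs;
individual base observations below Q20 are dropped while the rest of the
read stays usable. Candidate-level post-filters annotate rather than
delete, so threshold sweeps can be done from the VCF:

* **StrongBarcode** — fewer than `m = 2` barcodes contribute at least
  `τ = 2.0` index units each for the candidate allele.
* **StrandBias** — two-sided Fisher exact test on the 2×2 table of
  ref/alt barcode counts by strand; fails only when p < 10⁻⁵ *and* the
  alt forward:reverse ratio (+0.5 continuity) exceeds 5-fold in a
  direction the reference does not. Barcode counts, not read counts, are
  used: families are the independent units, and a family's strand is its
  reads' majority strand.
* **Homopolymer / LowComplexity / Repeat** — the variant lies in or
  adjacent to a single-base run ≥ 8; the ±50 bp window has dinucleotide
  Shannon entropy below 1.0 bits; or ≥ 80% of the window is covered by a
  tandem repeat of period 2–6 (exhaustive scan, tracts of at least two
  units, single-base tracts excluded as they are the homopolymer case).
  At a contig edge the filters evaluate whatever window is available.

These thresholds are deliberate reconstructions of the filter *intent* —
the filter names are fixed, every value is exposed in `filter_config()`
and the key=value config file, and none of the quantitative acceptance
checks depends on matching any particular historical parameterisation.

## Cutoff selection and detection limits

The optimal prediction-index cutoff grows linearly with barcode depth.
`recommend_cutoff()` implements the three published fits —
`y = 14 + 0.012x` (20 FP/Mb), `y = 15 + 0.0092x` (50), `y = 13 + 0.0088x`
(100) — with ceiling rounding, which reproduces all 21 tabulated cells
exactly; other rates raise an explicit error rather than interpolate.

The detection limit `f*` at a locus is the smallest allele fraction such
that the alt-barcode count X ~ Binomial(d, f) reaches
`k = ceil(cutoff / Ī)` with probability ≥ 95%, where `Ī = 3.5` is the
typical index of a good barcode. The source text computes the cutoff from
the locus depth d while sampling from the run-average depth D, which
contradicts its own narrative (deeper runs ⇒ stricter cutoff; deeper loci
⇒ more power) — stated twice and visible in the accompanying figure. The
default (`convention = "narrative"`) therefore takes the cutoff from D and
samples from Binomial(d, f); `convention = "literal"` reproduces the
as-printed formula. The monotone tail probability is solved by bisection
to 10⁻⁵ with an exact binomial check at the solution, and the test suite
verifies agreement with a brute-force 10⁻⁴ grid scan on random parameter
draws. When even f = 1 cannot supply k barcodes the locus is flagged
undetectable. `detection_limit_track()` maps a per-base depth track to
`f*` (memoised over distinct depths) and writes bedGraph with adjacent
equal values merged; zero-depth bases are omitted.

## Barcode clustering

Barcode sequencing errors fragment families. Within a target region
(identical barcodes on different amplicons are different molecules),
barcodes within Levenshtein distance 1 are folded into a better-supported
barcode under the directional rule `count(a) ≥ 2·count(b) − 1`, absorbing
transitively outward from the highest-count seed; representative choice
and tie-breaks are deterministic (count, then lexicographic). Levenshtein
rather than Hamming distance was chosen so that length-changing barcode
errors also cluster; both the distance ceiling and the count ratio are
configurable. Clustering never increases the number of families and
conserves total read count.

## The simulator

`sim_config()` / `simulate_pileups()` emulate the error process of
barcoded single-primer amplicon sequencing, at the fidelity the model
cares about — molecules and reads, not chromatography:

* molecule count per locus ~ Poisson(D);
* each molecule carries the truth alt with probability f;
* a **first-cycle polymerase error** (10⁻⁶ per base) replaces the
  molecule's allele entirely — every read of the family inherits it, so it
  is indistinguishable from a real single-molecule variant by consensus.
  This deliberately reproduces the fundamental detection floor of
  single-strand barcode protocols;
* read pairs per molecule ~ 1 + Poisson(rpb − 1) (default mean 8.5,
  matching deep targeted runs) or constant;
* each read pair independently suffers a later-cycle PCR error
  (30 cycles × 10⁻⁶) and a base-calling error (10^(-q/10), Q30 default),
  uniform over the three other bases; strands are Bernoulli(0.5).

What it does **not** emulate: alignment and mapping artifacts, context-
dependent error spectra, FFPE-type DNA damage, barcode-sequence errors
(families are born clean; clustering is tested on constructed inputs),
per-cycle quality decay, and indel sequencing errors (substitution errors
apply to single-base alleles only). Tests passing on simulated data
therefore validate the statistical machinery under the model's own error
assumptions, not robustness to alignment pathology — the sequence-context
filters exist precisely because real data violate these assumptions in
repetitive regions.

Downsampling utilities mirror titration studies: `downsample_barcodes()`
thins whole families Bernoulli(fraction); `downsample_rpb()` keeps one
guaranteed read pair per family and thins the rest with probability
`(target − 1)/(mean − 1)`, hitting the target mean without emptying any
family. Both are seeded reconstructions of the usual procedures.

## The large-scale false-positive scan

Measuring a false-positive rate per megabase at barcode depth ~3000 means
~1.5×10⁹ families per half megabase — far beyond per-read simulation in
any language. `scan_background()` keeps the measurement honest by
aggregation rather than by shrinking the problem: per locus it draws the
molecule count, the first-cycle error molecules, and the PCR/base-calling
error reads from exactly the laws above; only the families containing
non-reference evidence are materialised (error reads land in families of
size-biased rpb) and scored through the same posterior engine as the
caller, including the weight such a family lends to the non-reference
alleles it does not contain; the all-reference families enter as their
expected evidence contribution (~10⁻⁵ index units each, four orders of
magnitude below any workable cutoff). Two approximations are documented
and deliberate: collisions of two error reads in one family are treated
as two families (per-locus index effect below 0.01 units at default error
rates), and the clean-family background enters as its expectation. A
small-scale test compares the scan against the full per-read pipeline on
the mean total non-reference index and finds agreement within a few
percent.

## Problem sizes and numerical choices

The stochastic validation uses 200 simulated 1% SNVs at D = 3000, rpb 8
(about five million read observations through the full per-read pipeline)
and 5×10⁵ wild-type loci through the scan; depth-degradation and
rpb-saturation checks reuse the same simulated data under downsampling.
These sizes give binomial standard errors comfortably inside the asserted
margins (sensitivity ≥ 0.85, FP/Mb ≤ 50) while keeping the whole suite in
a couple of minutes. Other numerics: likelihoods in natural-log space
with two-term log-sum-exp; posterior complements accumulated, not
subtracted; bisection tolerance 10⁻⁵ on allele fraction; all tie-breaks
(allele order, cluster seeds, filter label sort) deterministic so byte-
identical inputs and seeds give byte-identical VCF output (the file-date
header line is off by default).

## Known limitations

* Single-strand barcodes: first-cycle polymerase errors are a hard floor;
  duplex (two-strand) pairing is out of scope.
* Germline diploid genotyping, paired tumour/normal subtraction and
  multi-sample joint calling are non-goals.
* The cutoff equations are empirical fits over depths 500–3500 at three
  FPR levels; outside that range, or under different chemistry, they
  extrapolate and no interpolation between FPR levels is offered.
* The post-filter thresholds are reconstructed defaults and should be
  recalibrated for a new panel; the config file exposes all of them.
* Indel handling assumes the aligner produced consistent left-aligned
  indels; no realignment is attempted.
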