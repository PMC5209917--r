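# umicall

Barcode-aware Bayesian calling of low-fraction sequence variants.

## The problem

Somatic mutations of clinical interest — tumour heterogeneity, circulating
tumour DNA, early diagnostics — often sit at allele fractions around 1%,
below the raw error floor of short-read sequencing. When every original DNA
molecule is tagged with a unique molecular barcode (UMI) before
amplification, all reads sharing a barcode derive from one molecule, and
sequencing/PCR errors (which scatter across reads) can be separated from
real variants (which are consistent within a barcode family and replicated
across several families). `umicall` is for researchers analysing targeted
amplicon deep-sequencing data with molecular barcodes who want to call
SNVs and short indels down to ~1% allele fraction, together with principled
cutoff selection and per-locus detection-limit estimates.

## The model

At a locus covered by `N` mutually independent barcode families, each
family `BC_k` is scored by Bayes' rule with a uniform prior over the
allele space `Θ` (the four nucleotides, observed indel alleles, and the
reference):

    P(X | BC_k) = P(BC_k | X) P(X) / Σ_{X'∈Θ} P(BC_k | X') P(X')

The family likelihood is a weighted sum of a base-calling-error term and a
PCR-error term. With `n_Y` reads of allele `Y` at Phred error
probabilities `e_(Y)i = 10^(-q/10)`:

    P(BC_k | X) ≈ α C_p Π_Y Π_i e_(Y)i^(1-I(Y=X)) (1-e_(Y)i)^(I(Y=X))
                + (1-α) Π_Y Π_i (1-e_(Y)i) · min_{Y≠X} 10^(-6(0.5+n_Y)/Σ_Z(0.5+n_Z))

where `α = 0.5` (equivalent to an unweighted sum of the two terms) and
`C_p = 3×10⁻⁵` is the PCR-error prior (30 cycles × 10⁻⁶ per-cycle error).
Per-family posteriors aggregate into the locus-level **prediction index**

    I(A) = -Σ_{k=1..N} log10(1 - P(A | BC_k))

the `-log10` probability that no molecule carries `A`. A non-reference
allele whose index reaches the cutoff is a candidate variant, then
screened by strong-barcode, strand-bias and sequence-context
(homopolymer / low-complexity / tandem-repeat) filters — annotated in the
VCF FILTER column, never silently dropped.

The cutoff is recommended from the barcode depth `x` and the tolerated
false-positive rate: `y = ceil(14 + 0.012 x)` at 20 FP/Mb (analogous
equations at 50 and 100 FP/Mb), and the locus detection limit `f*` is the
smallest allele fraction whose alt-barcode count, binomial in the locus
barcode depth, reaches the required minimum with 95% probability.

## Worked example

Simulate five 1% SNVs at barcode depth ~1200 with 8 read pairs per
barcode, pick the cutoff for 20 FP/Mb, and call:

```r
library(umicall)
cfg   <- sim_config(region_length = 5000L, mean_barcode_depth = 1200, rpb_mean = 8)
ref   <- simulate_reference(cfg, seed = 42)
truth <- simulate_truth(cfg, ref, n_snv = 5, fractions = 0.01, seed = 43)
obs   <- simulate_pileups(truth, cfg, ref, seed = 44)

thr   <- recommend_cutoff(20, mean_barcode_depth(obs))  # 29 at depth 1171
calls <- call_pileups(obs, threshold = thr, reference = setNames(ref, cfg$contig))
calls[, c("contig", "pos", "ref", "alt", "qual", "umt", "vmt", "vmf", "filter")]
#>    contig   pos    ref    alt     qual   umt   vmt         vmf filter
#> 1:   sim1  1002      A      G 60.87688  1222    14 0.011456628   PASS
#> 2:   sim1  1952      A      T 44.25167  1200    10 0.008333333   PASS
#> 3:   sim1  2152      T      C 34.69684  1135     8 0.007048458   PASS
#> 4:   sim1  3252      T      G 46.23243  1145    11 0.009606987   PASS
#> 5:   sim1  3352      G      C 51.48826  1153    13 0.011274935   PASS

evaluate_calls(calls, truth, target_size = 5000)
#>    threshold    tp    fp    fn sensitivity fp_per_mb   ppv
#> 1:        29     5     0     0           1         0     1

detection_limit(1200, 1200)   # lowest callable fraction at this depth
#> [1] 0.01200104
```

Each row is one candidate allele: `qual` is the prediction index `I(alt)`,
`umt` the barcode depth, `vmt`/`vmf` the alt-supporting barcode count and
fraction, and `filter` the post-filter verdict. All five planted variants
are recovered with no false positives, and the detection limit confirms
that 1% variants are just within reach at this depth.

The same workflow is available from a shell via `exec/umicall`
(subcommands `call`, `simulate`, `recommend-cutoff`, `detection-limit`,
`evaluate`), reading SAM/BAM + BED + FASTA or the plain-text pileup
table, and writing VCF 4.2 and bedGraph tracks.

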