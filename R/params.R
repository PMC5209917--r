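#' Model parameters for the per-barcode allele model
#'
#' Bundles the tunable constants of the per-barcode Bayesian error model.
#' The likelihood of the reads in one barcode family given a true allele is a
#' weighted sum of a base-calling-error term and a PCR-error term;
#' `alpha` weighs the two (at 0.5 the posterior is identical to an unweighted
#' sum), `c_p` is the prior probability that a PCR error occurred somewhere in
#' the amplification (`pcr_cycles * pcr_per_cycle_error` by construction) and
#' scales the base-calling term, `pseudo_count` is the additive constant in
#' the heuristic PCR-error exponent, and `posterior_clamp` bounds how much
#' locus-level evidence a single barcode can contribute
#' (`-log10(posterior_clamp)` index units, 6 by default).
#'
#' @param alpha Weight of the base-calling-error term, in `[0, 1]`.
#' @param c_p PCR-error prior. Defaults to `pcr_cycles * pcr_per_cycle_error`.
#' @param pcr_cycles Number of PCR cycles assumed in the error prior.
#' @param pcr_per_cycle_error Per-base polymerase error probability per cycle.
#' @param pseudo_count Additive constant in the PCR-error exponent.
#' @param posterior_clamp Floor applied to `1 - posterior` before taking
#'   `-log10`; keeps per-barcode evidence finite.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params()
#' p$c_p  # 3e-05
#' @export
model_params <- function(alpha = 0.5,
                         c_p = pcr_cycles * pcr_per_cycle_error,
                         pcr_cycles = 30L,
                         pcr_per_cycle_error = 1e-6,
                         pseudo_count = 0.5,
                         posterior_clamp = 1e-6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(c_p), c_p > 0, c_p < 1,
            pcr_cycles >= 1, pcr_per_cycle_error >= 0, pcr_per_cycle_error < 1,
            pseudo_count > 0, posterior_clamp > 0, posterior_clamp < 1)
  structure(list(alpha = alpha, c_p = c_p, pcr_cycles = as.integer(pcr_cycles),
                 pcr_per_cycle_error = pcr_per_cycle_error,
                 pseudo_count = pseudo_count,
                 posterior_clamp = posterior_clamp),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Per-barcode model parameters\n")
  cat(sprintf("  alpha (base-call vs PCR weight): %g\n", x$alpha))
  cat(sprintf("  c_p (PCR error prior):           %g  (%d cycles x %g)\n",
              x$c_p, x$pcr_cycles, x$pcr_per_cycle_error))
  cat(sprintf("  pseudo count:                    %g\n", x$pseudo_count))
  cat(sprintf("  posterior clamp:                 %g  (max %0.3g index units/barcode)\n",
              x$posterior_clamp, -log10(x$posterior_clamp)))
  invisible(x)
}

#' Read-level and candidate-level filter configuration
#'
#' Thresholds for the pre-processing (read-level) and post-processing
#' (candidate-level) artifact filters. Post-filters annotate candidate calls
#' (VCF FILTER column) rather than delete them, so sweeps over thresholds can
#' be done after the fact.
#'
#' @param min_mapq Minimum mapping quality for a read to enter a pileup.
#' @param min_baseq Minimum Phred base quality; lower observations are
#'   dropped individually, the read stays usable elsewhere.
#' @param require_proper_pair Drop reads not flagged as properly paired.
#' @param strong_barcode_min_count Minimum number of barcodes each carrying at
#'   least `strong_barcode_min_evidence` index units for the candidate allele.
#' @param strong_barcode_min_evidence Per-barcode evidence floor (index units,
#'   i.e. `-log10(1 - posterior)`) for a barcode to count as "strong".
#' @param strand_bias_p_floor Two-sided Fisher exact p-value below which,
#'   together with the ratio condition, a candidate fails the strand-bias
#'   filter.
#' @param strand_bias_min_ratio Fold imbalance (with +0.5 continuity
#'   correction) the alt barcode counts must exceed, in a direction the
#'   reference counts do not, for the strand-bias filter to fail.
#' @param homopolymer_max_run Single-base run length at/adjacent to the
#'   variant that triggers the `Homopolymer` label.
#' @param low_complexity_window Half-width (bases) of the reference window
#'   used by the sequence-context filters.
#' @param low_complexity_entropy Floor (bits) on the dinucleotide Shannon
#'   entropy of the window; lower triggers `LowComplexity`.
#' @param repeat_min_coverage Fraction of the window that must be covered by a
#'   tandem repeat of period 2-6 to trigger `Repeat`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_mapq = 17L,
                          min_baseq = 20L,
                          require_proper_pair = TRUE,
                          strong_barcode_min_count = 2L,
                          strong_barcode_min_evidence = 2.0,
                          strand_bias_p_floor = 1e-5,
                          strand_bias_min_ratio = 5,
                          homopolymer_max_run = 8L,
                          low_complexity_window = 50L,
                          low_complexity_entropy = 1.0,
                          repeat_min_coverage = 0.8) {
  vals <- list(min_mapq = as.integer(min_mapq),
               min_baseq = as.integer(min_baseq),
               require_proper_pair = isTRUE(require_proper_pair),
               strong_barcode_min_count = as.integer(strong_barcode_min_count),
               strong_barcode_min_evidence = strong_barcode_min_evidence,
               strand_bias_p_floor = strand_bias_p_floor,
               strand_bias_min_ratio = strand_bias_min_ratio,
               homopolymer_max_run = as.integer(homopolymer_max_run),
               low_complexity_window = as.integer(low_complexity_window),
               low_complexity_entropy = low_complexity_entropy,
               repeat_min_coverage = repeat_min_coverage)
  num <- vals[!vapply(vals, is.logical, logical(1))]
  stopifnot(all(vapply(num, function(v) is.finite(v) && v > 0, logical(1))))
  structure(vals, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Filter configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
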