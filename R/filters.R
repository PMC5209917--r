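#' Strong-barcode filter
#'
#' Rejects candidate mutations lacking enough barcodes with good read
#' evidence: passes iff at least `strong_barcode_min_count` barcodes each
#' contribute at least `strong_barcode_min_evidence` index units
#' (`-log10(1 - posterior)`) for the candidate allele.
#'
#' @param weights Numeric vector of per-barcode evidence weights for the
#'   candidate allele.
#' @param config [filter_config()].
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
strong_barcode_filter <- function(weights, config = filter_config()) {
  sum(weights >= config$strong_barcode_min_evidence) >= config$strong_barcode_min_count
}

#' Strand-bias filter
#'
#' Variants arising from first-cycle polymerase errors or DNA damage tend to
#' be supported on one strand only. The filter runs a two-sided Fisher exact
#' test on the 2x2 table of barcode counts (ref/alt x forward/reverse) and
#' fails the candidate iff the p-value falls below `strand_bias_p_floor` AND
#' the alt forward:reverse ratio (+0.5 continuity correction) exceeds
#' `strand_bias_min_ratio` in a direction the reference counts do not.
#'
#' @param alt_fwd,alt_rev Alt-supporting barcode counts by strand.
#' @param ref_fwd,ref_rev Reference barcode counts by strand.
#' @param config [filter_config()].
#' @return `TRUE` (pass) or `FALSE` (fail), with the Fisher p-value attached
#'   as attribute `p_value`.
#' @export
strand_bias_filter <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                               config = filter_config()) {
  tab <- matrix(c(ref_fwd, ref_rev, alt_fwd, alt_rev), nrow = 2, byrow = TRUE)
  if (all(tab == 0)) return(structure(TRUE, p_value = 1))
  p <- fisher.test(tab)$p.value
  r <- config$strand_bias_min_ratio
  alt_ratio <- (alt_fwd + 0.5) / (alt_rev + 0.5)
  ref_ratio <- (ref_fwd + 0.5) / (ref_rev + 0.5)
  skewed <- (alt_ratio > r & ref_ratio <= r) |
    (alt_ratio < 1 / r & ref_ratio >= 1 / r)
  structure(!(p < config$strand_bias_p_floor && skewed), p_value = p)
}

# maximal single-base run lengths covering each position of a sequence
.run_lengths_at <- function(chars) {
  r <- rle(chars)
  rep(r$lengths, r$lengths)
}

# Shannon entropy (bits) of overlapping dinucleotide frequencies
dinucleotide_entropy <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  if (length(chars) < 2L) return(0)
  di <- paste0(chars[-length(chars)], chars[-1L])
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

# fraction of the window covered by a tandem repeat of period 2..6
# (exhaustive scan: positions i where seq[i] == seq[i + p] extend a tract;
# tracts shorter than two repeat units, and single-base tracts -- those are
# homopolymers, flagged separately -- are ignored)
tandem_repeat_coverage <- function(seq, periods = 2:6) {
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  if (L < 4L) return(0)
  covered <- logical(L)
  for (p in periods) {
    if (L < 2L * p) next
    match <- chars[seq_len(L - p)] == chars[(p + 1L):L]
    r <- rle(match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= p)) {
      tract <- starts[k]:(ends[k] + p)
      if (length(unique(chars[tract])) > 1L) covered[tract] <- TRUE
    }
  }
  mean(covered)
}

#' Sequence-context filters: homopolymer, low complexity, tandem repeat
#'
#' Flags candidates in reference contexts where alignment and PCR artifacts
#' concentrate: single-base runs, low-entropy sequence, and short-period
#' tandem repeats (microsatellites).
#'
#' @param window Reference sequence around the variant (a character string;
#'   at a contig edge pass whatever is available).
#' @param variant_offset 1-based position of the variant base within
#'   `window`.
#' @param config [filter_config()].
#' @return Character vector of failed labels, possibly empty: subset of
#'   `"Homopolymer"`, `"LowComplexity"`, `"Repeat"`.
#' @export
region_context_filters <- function(window, variant_offset, config = filter_config()) {
  window <- toupper(window)
  chars <- strsplit(window, "")[[1L]]
  labels <- character()
  runs <- .run_lengths_at(chars)
  near <- max(1L, variant_offset - 1L):min(length(chars), variant_offset + 1L)
  if (any(runs[near] >= config$homopolymer_max_run)) {
    labels <- c(labels, "Homopolymer")
  }
  if (dinucleotide_entropy(window) < config$low_complexity_entropy) {
    labels <- c(labels, "LowComplexity")
  }
  if (tandem_repeat_coverage(window) >= config$repeat_min_coverage) {
    labels <- c(labels, "Repeat")
  }
  sort(labels)
}

#' Apply post-processing filters to a locus call
#'
#' Runs the strong-barcode, strand-bias and sequence-context filters on
#' every candidate allele of a locus call and annotates, never deletes:
#' `FILTER` is `"PASS"` when all pass, otherwise the sorted list of failed
#' labels.
#'
#' @param call A `locus_call` (from [call_locus()]).
#' @param window Optional reference window for the context filters (character
#'   string) with `variant_offset` locating the call within it; `NULL` skips
#'   the context filters.
#' @param variant_offset 1-based offset of the variant in `window`.
#' @param config [filter_config()].
#' @return The call with `filters` set: a named list (per candidate allele)
#'   of failed labels, and `filter_string` per candidate.
#' @export
apply_filters <- function(call, window = NULL, variant_offset = NULL,
                          config = filter_config()) {
  stopifnot(inherits(call, "locus_call"))
  ctx <- if (!is.null(window)) {
    region_context_filters(window, variant_offset, config)
  } else character()
  res <- lapply(call$candidate_alleles, function(a) {
    fails <- ctx
    w <- call$barcode_evidence[[a]]
    if (!strong_barcode_filter(w, config)) fails <- c(fails, "StrongBarcode")
    sc <- call$strand_counts
    if (!is.null(sc)) {
      sb <- strand_bias_filter(sc[[a]]["fwd"], sc[[a]]["rev"],
                               sc[["ref_fwd"]], sc[["ref_rev"]], config)
      if (!sb) fails <- c(fails, "StrandBias")
    }
    sort(unique(fails))
  })
  names(res) <- call$candidate_alleles
  call$filters <- res
  call$filter_string <- vapply(res, function(f) {
    if (!length(f)) "PASS" else paste(f, collapse = ";")
  }, character(1))
  call
}
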