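allele_rank <- function(allele) {
  r <- match(allele, NUCLEOTIDES)
  r[is.na(r)] <- 5L
  r
}

# per-family consensus allele (plurality; ties broken A<C<G<T<indels) and
# majority strand, used for VMT/VMF and the strand-bias table
.family_consensus <- function(obs) {
  cons <- obs[, .(n_y = .N), by = .(locus, barcode, allele)]
  cons[, rk := allele_rank(allele)]
  setorder(cons, locus, barcode, -n_y, rk, allele)
  cons <- cons[, .(consensus = allele[1L]), by = .(locus, barcode)]
  strands <- obs[, .(fwd = sum(strand == "+"), n = .N), by = .(locus, barcode)]
  strands[, fam_strand := ifelse(fwd * 2L >= n, "+", "-")]
  cons[strands[, .(locus, barcode, fam_strand)], on = c("locus", "barcode")]
}

#' Call one locus
#'
#' Computes the per-allele prediction index over all barcode families at the
#' locus and nominates every non-reference allele whose index reaches the
#' threshold as a candidate variant.
#'
#' @param pileup A [locus_pileup()].
#' @param threshold Positive prediction-index cutoff (see
#'   [recommend_cutoff()]).
#' @param params [model_params()].
#' @return An object of class `locus_call` carrying the allele space, the
#'   per-allele prediction indices, per-barcode evidence weights, barcode
#'   consensus counts and strand counts, and `candidate_alleles`.
#' @export
call_locus <- function(pileup, threshold, params = model_params()) {
  stopifnot(inherits(pileup, "locus_pileup"), threshold > 0)
  obs <- copy(pileup$obs)
  if (!nrow(obs)) {
    return(structure(list(contig = pileup$contig, pos = pileup$pos,
                          ref = pileup$ref, allele_space = NULL,
                          prediction_index = numeric(),
                          barcode_evidence = list(), n_barcodes = 0L,
                          candidate_alleles = character(),
                          strand_counts = NULL, vmt = integer(),
                          filters = list(), filter_string = character(),
                          no_coverage = TRUE, threshold = threshold),
                     class = "locus_call"))
  }
  obs[, locus := 1L]
  space <- allele_space(pileup$ref, obs$allele)
  tab <- family_posterior_table(obs[, .(locus, barcode, allele, phred_q)],
                                data.table(locus = 1L, allele = space$alleles),
                                params)
  idx <- tab[, .(index = sum(weight)), by = allele]
  index <- setNames(idx$index, idx$allele)[space$alleles]
  evid <- split(tab$weight, tab$allele)[space$alleles]
  names(evid) <- space$alleles
  cand <- setdiff(space$alleles, space$reference)
  cand <- cand[index[cand] >= threshold]

  cons <- .family_consensus(obs)
  vmt <- table(factor(cons$consensus, levels = space$alleles))
  strand_counts <- lapply(space$alleles, function(a) {
    c(fwd = sum(cons$consensus == a & cons$fam_strand == "+"),
      rev = sum(cons$consensus == a & cons$fam_strand == "-"))
  })
  names(strand_counts) <- space$alleles
  strand_counts$ref_fwd <- strand_counts[[space$reference]][["fwd"]]
  strand_counts$ref_rev <- strand_counts[[space$reference]][["rev"]]

  structure(list(contig = pileup$contig, pos = pileup$pos, ref = pileup$ref,
                 allele_space = space, prediction_index = index,
                 barcode_evidence = evid, n_barcodes = pileup$barcode_depth,
                 candidate_alleles = cand, strand_counts = strand_counts,
                 vmt = setNames(as.integer(vmt), names(vmt)),
                 read_depth = pileup$read_depth, rpb = pileup$rpb,
                 filters = list(), filter_string = character(),
                 no_coverage = FALSE, threshold = threshold),
            class = "locus_call")
}

#' @export
print.locus_call <- function(x, ...) {
  if (x$no_coverage) {
    cat(sprintf("Locus call %s:%s -- no coverage\n", x$contig, x$pos))
    return(invisible(x))
  }
  cat(sprintf("Locus call %s:%d ref %s, N = %d barcodes\n",
              x$contig, x$pos, x$ref, x$n_barcodes))
  cat("  prediction index:",
      paste(sprintf("%s=%.3g", names(x$prediction_index), x$prediction_index),
            collapse = " "), "\n")
  cat("  candidates:", if (length(x$candidate_alleles))
    paste(x$candidate_alleles, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Call variants over a pileup table
#'
#' The batch engine behind the `call` command: evaluates the per-barcode
#' model at every locus of the table, nominates candidates against the
#' threshold, and applies the post-processing filters. Candidates are
#' annotated, never deleted.
#'
#' @param obs Pileup observation table (multiple loci).
#' @param threshold Prediction-index cutoff, or `"auto"` to derive it from
#'   the observed mean barcode depth via [recommend_cutoff()].
#' @param params [model_params()].
#' @param config [filter_config()].
#' @param reference Optional named character vector of contig sequences used
#'   by the sequence-context filters.
#' @param fpr_per_mb Tolerated false-positive rate for `threshold = "auto"`.
#' @return A `data.table` with one row per candidate allele: `contig`,
#'   `pos`, `ref`, `alt` (VCF-style), `qual` (prediction index), `umt`
#'   (barcode depth), `vmt` (alt barcode count), `vmf` (alt barcode
#'   fraction), `rpb`, strand counts and `filter`. The threshold used is
#'   attached as attribute `threshold`.
#' @export
call_pileups <- function(obs, threshold = "auto", params = model_params(),
                         config = filter_config(), reference = NULL,
                         fpr_per_mb = 20) {
  obs <- as.data.table(obs)
  obs <- obs[allele != AMBIGUOUS_ALLELE]
  if (identical(threshold, "auto")) {
    threshold <- recommend_cutoff(fpr_per_mb, mean_barcode_depth(obs))
  }
  stopifnot(is.numeric(threshold), threshold > 0)
  empty <- data.table(contig = character(), pos = integer(), ref = character(),
                      alt = character(), allele = character(), qual = numeric(),
                      umt = integer(), vmt = integer(), vmf = numeric(),
                      rpb = numeric(), alt_fwd = integer(), alt_rev = integer(),
                      ref_fwd = integer(), ref_rev = integer(),
                      filter = character())
  if (!nrow(obs)) return(structure(empty, threshold = threshold))

  loci <- unique(obs[, .(contig, pos, ref)])
  setorder(loci, contig, pos)
  loci[, locus := .I]
  obs <- obs[loci, on = c("contig", "pos", "ref")]

  theta <- rbindlist(lapply(seq_len(nrow(loci)), function(i) {
    sp <- allele_space(loci$ref[i], obs[locus == i, allele])
    data.table(locus = i, allele = sp$alleles)
  }))
  tab <- family_posterior_table(obs[, .(locus, barcode, allele, phred_q)],
                                theta, params)
  tau <- config$strong_barcode_min_evidence
  idx <- tab[, .(qual = sum(weight), strong_n = sum(weight >= tau)),
             by = .(locus, allele)]
  depth <- obs[, .(umt = length(unique(barcode)), reads = .N), by = locus]
  depth[, rpb := reads / umt]
  idx <- idx[loci, on = "locus"][depth, on = "locus"]
  cand <- idx[allele != ref & qual >= threshold]
  if (!nrow(cand)) return(structure(empty, threshold = threshold))

  cons <- .family_consensus(obs)
  vm <- cons[, .(vmt = .N,
                 fwd = sum(fam_strand == "+"), rev = sum(fam_strand == "-")),
             by = .(locus, consensus)]
  cand <- vm[, .(locus, allele = consensus, vmt, alt_fwd = fwd, alt_rev = rev)][
    cand, on = c("locus", "allele")]
  for (col in c("vmt", "alt_fwd", "alt_rev")) cand[is.na(get(col)), (col) := 0L]
  refc <- vm[loci, on = c(locus = "locus", consensus = "ref")]
  refc <- refc[, .(locus, ref_fwd = fwd, ref_rev = rev)]
  for (col in c("ref_fwd", "ref_rev")) refc[is.na(get(col)), (col) := 0L]
  cand <- refc[cand, on = "locus"]
  cand[, vmf := vmt / umt]

  cand[, filter := vapply(seq_len(.N), function(i) {
    fails <- character()
    if (cand$strong_n[i] < config$strong_barcode_min_count) {
      fails <- c(fails, "StrongBarcode")
    }
    if (!strand_bias_filter(cand$alt_fwd[i], cand$alt_rev[i],
                            cand$ref_fwd[i], cand$ref_rev[i], config)) {
      fails <- c(fails, "StrandBias")
    }
    if (!is.null(reference) && cand$contig[i] %in% names(reference)) {
      seq <- reference[[cand$contig[i]]]
      w <- config$low_complexity_window
      lo <- max(1L, cand$pos[i] - w)
      hi <- min(nchar(seq), cand$pos[i] + w)
      fails <- c(fails, region_context_filters(substr(seq, lo, hi),
                                               cand$pos[i] - lo + 1L, config))
    }
    if (!length(fails)) "PASS" else paste(sort(unique(fails)), collapse = ";")
  }, character(1))]

  cand[, alt := allele]
  out <- cand[, .(contig, pos, ref, alt, allele, qual, umt, vmt, vmf, rpb,
                  alt_fwd, alt_rev, ref_fwd, ref_rev, filter)]
  setorder(out, contig, pos, alt)
  structure(out, threshold = threshold)
}

#' Mean barcode depth of a pileup table
#'
#' Number of distinct barcode families per covered locus, averaged over
#' loci; the `x` of the cutoff-recommendation equations.
#'
#' @param obs Pileup observation table.
#' @return Mean barcode depth (numeric scalar).
#' @export
mean_barcode_depth <- function(obs) {
  obs <- as.data.table(obs)
  if (!nrow(obs)) return(0)
  mean(obs[, .(n = length(unique(barcode))), by = .(contig, pos)]$n)
}
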