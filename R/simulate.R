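#' Simulation configuration
#'
#' Parameters of the synthetic barcoded-amplicon error process. Molecule
#' counts per locus are Poisson with mean `mean_barcode_depth`; each
#' molecule carries the truth alt allele with probability equal to the
#' truth allele fraction; a first-cycle polymerase error (probability
#' `first_cycle_error_rate` per base) replaces the molecule's allele
#' entirely, making it indistinguishable from a real variant by barcode
#' consensus; each molecule yields `1 + Poisson(rpb_mean - 1)` read pairs
#' (or a constant count); each read pair independently suffers a
#' later-cycle PCR error (probability `pcr_cycles *
#' later_cycle_error_rate`) and a base-calling error (probability
#' `10^(-phred_q/10)`), each drawn uniformly over the three other bases;
#' strands are Bernoulli(`strand_prob`).
#'
#' @param contig Contig name of the synthetic region.
#' @param region_length Length of the synthetic region (bases).
#' @param mean_barcode_depth Mean number of molecules (barcode families)
#'   per locus, `D`.
#' @param rpb_mean Mean read pairs per barcode.
#' @param rpb_dist `"poisson"` (shifted: `1 + Poisson(rpb_mean - 1)`) or
#'   `"constant"`.
#' @param first_cycle_error_rate Per-base probability of a first-cycle
#'   polymerase error (molecule-level, uncorrectable by consensus).
#' @param pcr_cycles,later_cycle_error_rate Later-cycle PCR error model:
#'   per read pair, error probability `pcr_cycles * later_cycle_error_rate`.
#' @param phred_q Constant Phred quality of simulated base calls.
#' @param strand_prob Probability a read pair is on the forward strand.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(contig = "sim1", region_length = 2000L,
                       mean_barcode_depth = 1000, rpb_mean = 8.5,
                       rpb_dist = c("poisson", "constant"),
                       first_cycle_error_rate = 1e-6,
                       pcr_cycles = 30L, later_cycle_error_rate = 1e-6,
                       phred_q = 30L, strand_prob = 0.5) {
  rpb_dist <- match.arg(rpb_dist)
  stopifnot(region_length >= 1, mean_barcode_depth > 0, rpb_mean >= 1,
            first_cycle_error_rate >= 0, first_cycle_error_rate <= 1,
            later_cycle_error_rate >= 0, later_cycle_error_rate <= 1,
            phred_q >= 0, strand_prob >= 0, strand_prob <= 1)
  structure(list(contig = contig, region_length = as.integer(region_length),
                 mean_barcode_depth = mean_barcode_depth, rpb_mean = rpb_mean,
                 rpb_dist = rpb_dist,
                 first_cycle_error_rate = first_cycle_error_rate,
                 pcr_cycles = as.integer(pcr_cycles),
                 later_cycle_error_rate = later_cycle_error_rate,
                 phred_q = as.integer(phred_q), strand_prob = strand_prob),
            class = "sim_config")
}

#' Simulate a random reference sequence
#'
#' @param config [sim_config()].
#' @param seed Integer seed.
#' @return A character string of length `config$region_length`.
#' @export
simulate_reference <- function(config, seed = 1L) {
  set.seed(seed)
  paste(sample(NUCLEOTIDES, config$region_length, replace = TRUE),
        collapse = "")
}

.draw_rpb <- function(n, config) {
  if (config$rpb_dist == "constant") {
    rep(as.integer(round(config$rpb_mean)), n)
  } else {
    1L + rpois(n, config$rpb_mean - 1)
  }
}

# unique barcode strings: base-4 encoding of distinct random integers
.make_barcodes <- function(n, width = 12L) {
  ids <- sample.int(4^width, n) - 1
  cols <- lapply(rev(seq_len(width) - 1L), function(k) {
    NUCLEOTIDES[(ids %/% 4^k) %% 4 + 1]
  })
  do.call(paste0, cols)
}

#' Simulate a truth set of low-fraction variants
#'
#' Places SNVs and short (1-10 bp) indels uniformly over the region at the
#' configured allele fractions, with a minimum spacing. Deterministic given
#' the seed.
#'
#' @param config [sim_config()].
#' @param reference Reference sequence string (from [simulate_reference()]).
#' @param n_snv,n_indel Numbers of SNVs and indels to place.
#' @param fractions Allele fraction(s), recycled over variants.
#' @param min_spacing Minimum distance between variant positions.
#' @param seed Integer seed.
#' @return A `data.table` (the truth set): `contig`, `pos`, `ref`, `allele`
#'   (pileup-style: base, `+SEQ` or `-SEQ`), `af`.
#' @export
simulate_truth <- function(config, reference, n_snv, n_indel = 0L,
                           fractions = 0.01, min_spacing = 50L, seed = 1L) {
  set.seed(seed)
  n <- n_snv + n_indel
  if (n == 0L) {
    return(data.table(contig = character(), pos = integer(), ref = character(),
                      allele = character(), af = numeric()))
  }
  L <- nchar(reference)
  # leave room for deletions at the right edge
  avail <- seq(2L, L - 12L)
  slots <- floor((length(avail) - 1L) / min_spacing) + 1L
  if (slots < n) {
    stop(sprintf("region of %d bases cannot hold %d variants at spacing %d",
                 L, n, min_spacing))
  }
  pos <- sort(sample(avail[seq(1L, length(avail), by = min_spacing)], n))
  ref <- strsplit(reference, "")[[1L]]
  is_indel <- c(rep(FALSE, n_snv), rep(TRUE, n_indel))[sample.int(n)]
  allele <- character(n)
  for (i in seq_len(n)) {
    if (!is_indel[i]) {
      allele[i] <- sample(setdiff(NUCLEOTIDES, ref[pos[i]]), 1L)
    } else if (runif(1) < 0.5) {
      len <- sample.int(10L, 1L)
      allele[i] <- paste0("+", paste(sample(NUCLEOTIDES, len, replace = TRUE),
                                     collapse = ""))
    } else {
      len <- sample.int(10L, 1L)
      allele[i] <- paste0("-", paste(ref[(pos[i] + 1L):(pos[i] + len)],
                                     collapse = ""))
    }
  }
  data.table(contig = config$contig, pos = as.integer(pos),
             ref = ref[pos], allele = allele,
             af = rep_len(fractions, n))
}

#' Simulate barcode-resolved pileups
#'
#' Runs the molecule/read error process of [sim_config()] at the given
#' positions and returns a pileup observation table ready for
#' [call_pileups()] or [write_pileup_table()]. Substitution errors apply to
#' single-base alleles; reads from indel-carrying molecules keep their
#' indel allele.
#'
#' @param truth Truth set from [simulate_truth()] (may be empty).
#' @param config [sim_config()].
#' @param reference Reference sequence string.
#' @param positions Loci to simulate; defaults to the truth positions, or
#'   the whole region when the truth is empty.
#' @param seed Integer seed.
#' @return Pileup observation table (`data.table`).
#' @export
simulate_pileups <- function(truth, config, reference,
                             positions = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(positions)) {
    positions <- if (nrow(truth)) truth$pos else seq_len(config$region_length)
  }
  positions <- sort(unique(as.integer(positions)))
  refchars <- strsplit(reference, "")[[1L]]
  af <- setNames(rep(0, length(positions)), positions)
  alt <- setNames(rep(NA_character_, length(positions)), positions)
  if (nrow(truth)) {
    hit <- as.character(truth$pos)
    af[hit[hit %in% names(af)]] <- truth$af[truth$pos %in% positions]
    alt[hit[hit %in% names(alt)]] <- truth$allele[truth$pos %in% positions]
  }

  n_mol <- rpois(length(positions), config$mean_barcode_depth)
  mol <- data.table(pos = rep(positions, n_mol))
  if (!nrow(mol)) return(.empty_obs(config))
  mol[, ref := refchars[pos]]
  mol[, allele := ref]
  mol[, f := af[as.character(pos)]]
  mol[, is_alt := runif(.N) < f]
  mol[is_alt == TRUE, allele := alt[as.character(pos)]]
  # first-cycle polymerase error: the whole molecule flips to another base
  fc <- runif(nrow(mol)) < config$first_cycle_error_rate
  if (any(fc)) {
    flip <- which(fc & !is_indel_allele(mol$allele))
    mol$allele[flip] <- .substitute_base(mol$allele[flip])
  }
  mol[, barcode := .make_barcodes(.N)]
  mol[, n_reads := .draw_rpb(.N, config)]

  reads <- mol[rep(seq_len(nrow(mol)), mol$n_reads),
               .(pos, ref, barcode, allele)]
  reads[, pair_id := as.character(seq_len(.N)), by = .(pos, barcode)]
  p_pcr <- config$pcr_cycles * config$later_cycle_error_rate
  e_bc <- phred_to_error(config$phred_q)
  subst <- (runif(nrow(reads)) < p_pcr) | (runif(nrow(reads)) < e_bc)
  flip <- which(subst & !is_indel_allele(reads$allele))
  if (length(flip)) reads$allele[flip] <- .substitute_base(reads$allele[flip])
  reads[, strand := ifelse(runif(.N) < config$strand_prob, "+", "-")]
  reads[, `:=`(contig = config$contig, phred_q = config$phred_q)]
  out <- reads[, .(contig, pos, ref, barcode, allele, phred_q, strand, pair_id)]
  setorder(out, pos, barcode, pair_id)
  out[]
}

.empty_obs <- function(config) {
  data.table(contig = character(), pos = integer(), ref = character(),
             barcode = character(), allele = character(), phred_q = integer(),
             strand = character(), pair_id = character())
}

# uniform substitution to one of the three other bases
.substitute_base <- function(base) {
  k <- sample.int(3L, length(base), replace = TRUE)
  vapply(seq_along(base), function(i) setdiff(NUCLEOTIDES, base[i])[k[i]],
         character(1))
}

#' Downsample barcode depth
#'
#' Bernoulli thinning of whole barcode families: each (locus, barcode)
#' family is kept independently with the given probability; families are
#' never partially removed.
#'
#' @param obs Pileup observation table.
#' @param fraction Keep probability, in `(0, 1]`.
#' @param seed Integer seed.
#' @return Thinned observation table.
#' @export
downsample_barcodes <- function(obs, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  obs <- as.data.table(obs)
  if (fraction == 1 || !nrow(obs)) return(copy(obs))
  set.seed(seed)
  fams <- unique(obs[, .(contig, pos, barcode)])
  fams[, keep := runif(.N) < fraction]
  out <- obs[fams[keep == TRUE, .(contig, pos, barcode)],
             on = c("contig", "pos", "barcode")]
  out[]
}

#' Downsample read pairs per barcode
#'
#' Subsamples read pairs within each family towards a target mean rpb:
#' every family keeps one randomly chosen read pair, and each remaining
#' pair survives with probability `(target - 1) / (mean - 1)`, so the
#' expected mean rpb equals the target while no family drops to zero.
#'
#' @param obs Pileup observation table.
#' @param target_rpb Target mean read pairs per barcode, `>= 1` and at most
#'   the current mean.
#' @param seed Integer seed.
#' @return Thinned observation table.
#' @export
downsample_rpb <- function(obs, target_rpb, seed = 1L) {
  obs <- as.data.table(obs)
  if (!nrow(obs)) return(copy(obs))
  fam_sizes <- obs[, .N, by = .(contig, pos, barcode)]
  cur <- mean(fam_sizes$N)
  if (target_rpb > cur) {
    stop(sprintf("target rpb %.2f exceeds current mean %.2f", target_rpb, cur))
  }
  stopifnot(target_rpb >= 1)
  if (cur == 1) return(copy(obs))
  p <- (target_rpb - 1) / (cur - 1)
  set.seed(seed)
  out <- copy(obs)
  out[, u := runif(.N)]
  out[, guaranteed := u == max(u), by = .(contig, pos, barcode)]
  out <- out[guaranteed == TRUE | runif(.N) < p]
  out[, c("u", "guaranteed") := NULL]
  out[]
}

#' Compare calls against a truth set
#'
#' Matches candidate calls to truth variants by (contig, position, allele)
#' over a threshold sweep and reports sensitivity, false positives per
#' megabase and positive predictive value.
#'
#' @param calls Candidate table from [call_pileups()] (columns `contig`,
#'   `pos`, `allele`, `qual`, `filter`).
#' @param truth Truth set from [simulate_truth()].
#' @param target_size Size in bases of the interrogated region (> 0).
#' @param thresholds Numeric vector of prediction-index thresholds to sweep.
#' @param pass_only Count only `FILTER == "PASS"` calls (default `TRUE`).
#' @return A `data.table` with one row per threshold: `threshold`, `tp`,
#'   `fp`, `fn`, `sensitivity`, `fp_per_mb`, `ppv`.
#' @export
evaluate_calls <- function(calls, truth, target_size,
                           thresholds = attr(calls, "threshold"),
                           pass_only = TRUE) {
  if (is.null(target_size) || target_size <= 0) stop("target size must be positive")
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  key <- c("contig", "pos", "allele")
  rbindlist(lapply(thresholds, function(t) {
    kept <- calls[qual >= t]
    if (pass_only && nrow(kept)) kept <- kept[filter == "PASS"]
    kept <- unique(kept[, key, with = FALSE])
    tp <- if (nrow(truth)) nrow(kept[truth[, key, with = FALSE], on = key,
                                     nomatch = NULL]) else 0L
    fp <- nrow(kept) - tp
    fn <- nrow(truth) - tp
    data.table(threshold = t, tp = tp, fp = fp, fn = fn,
               sensitivity = if (nrow(truth)) tp / nrow(truth) else NA_real_,
               fp_per_mb = fp * 1e6 / target_size,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }))
}
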