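# Per-family evidence weights for the canonical compositions the background
# scan needs, computed through the regular posterior engine and cached by
# family size. Symmetry over the four bases lets "A" stand for the
# reference and "C" for the substituted allele; the "_other" kinds score a
# non-reference allele ("G") that the family does not actually contain --
# a family with one error read lends almost the same weight to every
# non-reference allele, because the PCR-error term is governed by the
# dominant reference count either way.
.scan_weight <- function(n, kind = c("clean", "one_alt", "one_alt_other",
                                     "all_alt", "all_alt_other"),
                         phred_q, params) {
  kind <- match.arg(kind)
  alleles <- switch(kind,
                    clean = rep("A", n),
                    one_alt = ,
                    one_alt_other = c(rep("A", n - 1L), "C"),
                    all_alt = ,
                    all_alt_other = rep("C", n))
  scored <- if (endsWith(kind, "other")) "G" else "C"
  obs <- data.table(locus = 1L, barcode = "BC",
                    allele = alleles, phred_q = phred_q)
  theta <- data.table(locus = 1L, allele = NUCLEOTIDES)
  tab <- family_posterior_table(obs, theta, params)
  tab[allele == scored, weight]
}

.scan_weight_table <- function(nmax, kind, phred_q, params) {
  vapply(seq_len(nmax), .scan_weight, numeric(1),
         kind = kind, phred_q = phred_q, params = params)
}

#' Large-scale false-positive scan over wild-type loci
#'
#' Measures the caller's false-positive rate over many variant-free loci at
#' full barcode depth without materialising every read: per locus it draws
#' the molecule count, the first-cycle error molecules and the
#' PCR/base-calling error reads from the same laws as [simulate_pileups()],
#' evaluates only the families that contain non-reference evidence through
#' the regular posterior engine (first-cycle families at their simulated
#' size; error reads inside families of size-biased rpb), and adds the
#' expected evidence contribution of the all-reference families
#' (about 1e-5 index units each). A locus is a false positive when any
#' non-reference allele's prediction index reaches the threshold. Two error
#' reads landing in the same family are treated as separate families
#' (the collision probability is small and the combined family's weight is
#' of the same tiny order).
#'
#' @param n_loci Number of wild-type loci to scan.
#' @param config [sim_config()].
#' @param threshold Prediction-index cutoff.
#' @param params [model_params()].
#' @param seed Integer seed.
#' @param chunk_size Loci per vectorised chunk.
#' @param return_indices Also return the per-locus maximum non-reference
#'   index (only sensible for modest `n_loci`).
#' @return List of class `background_scan`: `n_loci`, `threshold`, `fp`,
#'   `fp_per_mb`, and optionally `max_index`.
#' @export
scan_background <- function(n_loci, config, threshold,
                            params = model_params(), seed = 1L,
                            chunk_size = 100000L, return_indices = FALSE) {
  stopifnot(n_loci > 0, threshold > 0)
  set.seed(seed)
  D <- config$mean_barcode_depth
  lambda <- config$rpb_mean - 1
  p_pcr <- config$pcr_cycles * config$later_cycle_error_rate
  e_bc <- phred_to_error(config$phred_q)
  p_err <- 1 - (1 - p_pcr) * (1 - e_bc)

  if (config$rpb_dist == "constant") {
    nmax <- as.integer(round(config$rpb_mean))
    rpb_pmf <- c(rep(0, nmax - 1L), 1)
  } else {
    nmax <- as.integer(stats::qpois(1 - 1e-12, lambda)) + 1L
    rpb_pmf <- stats::dpois(seq_len(nmax) - 1L, lambda)
    rpb_pmf <- rpb_pmf / sum(rpb_pmf)
  }
  sb_pmf <- seq_len(nmax) * rpb_pmf        # size-biased: an error read lands
  sb_pmf <- sb_pmf / sum(sb_pmf)           # in a family w.p. proportional to size

  w_clean <- .scan_weight_table(nmax, "clean", config$phred_q, params)
  w_one <- .scan_weight_table(nmax, "one_alt", config$phred_q, params)
  w_one_o <- .scan_weight_table(nmax, "one_alt_other", config$phred_q, params)
  w_full <- .scan_weight_table(nmax, "all_alt", config$phred_q, params)
  w_full_o <- .scan_weight_table(nmax, "all_alt_other", config$phred_q, params)
  e_wclean <- sum(rpb_pmf * w_clean)

  fp <- 0L
  max_idx <- if (return_indices) numeric(n_loci) else NULL
  sum_idx <- if (return_indices) numeric(n_loci) else NULL
  done <- 0L
  while (done < n_loci) {
    m <- min(chunk_size, n_loci - done)
    N <- rpois(m, D)
    n_reads <- if (config$rpb_dist == "constant") N * nmax else
      N + rpois(m, N * lambda)
    fc <- rbinom(m, N, config$first_cycle_error_rate)
    err <- rbinom(m, n_reads, p_err)
    bg <- N * e_wclean
    idx <- matrix(rep(bg, 3L), nrow = m)  # per-locus index of the 3 alt alleles
    ev_locus <- c(rep(seq_len(m), fc), rep(seq_len(m), err))
    if (length(ev_locus)) {
      n_fc <- sum(fc)
      ev_allele <- sample.int(3L, length(ev_locus), replace = TRUE)
      sizes <- c(sample.int(nmax, n_fc, replace = TRUE, prob = rpb_pmf),
                 sample.int(nmax, sum(err), replace = TRUE, prob = sb_pmf))
      is_fc <- seq_along(ev_locus) <= n_fc
      # weight for the substituted allele itself, and for the two
      # non-reference alleles the family does not contain
      w_self <- ifelse(is_fc, w_full[sizes], w_one[sizes])
      w_other <- ifelse(is_fc, w_full_o[sizes], w_one_o[sizes])
      ev <- data.table(locus = ev_locus, al = ev_allele,
                       w_delta = w_self - w_other, w_other = w_other)
      shared <- ev[, .(w = sum(w_other)), by = locus]
      idx[shared$locus, ] <- idx[shared$locus, ] + shared$w
      agg <- ev[, .(w = sum(w_delta)), by = .(locus, al)]
      idx[cbind(agg$locus, agg$al)] <- idx[cbind(agg$locus, agg$al)] + agg$w
    }
    top <- pmax(idx[, 1L], idx[, 2L], idx[, 3L])
    fp <- fp + sum(top >= threshold)
    if (return_indices) {
      max_idx[done + seq_len(m)] <- top
      sum_idx[done + seq_len(m)] <- idx[, 1L] + idx[, 2L] + idx[, 3L]
    }
    done <- done + m
  }
  structure(list(n_loci = n_loci, threshold = threshold, fp = fp,
                 fp_per_mb = fp * 1e6 / n_loci,
                 max_index = max_idx, sum_index = sum_idx),
            class = "background_scan")
}

#' @export
print.background_scan <- function(x, ...) {
  cat(sprintf("Background scan: %d wild-type loci at threshold %.3g -> %d FP (%.2f FP/Mb)\n",
              x$n_loci, x$threshold, x$fp, x$fp_per_mb))
  invisible(x)
}
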