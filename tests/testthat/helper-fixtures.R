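library(data.table)

# naive direct-product evaluation of the per-barcode likelihood, kept free of
# log-space tricks so it can serve as an independent oracle for small families
naive_likelihood <- function(alleles, phred_q, x, theta,
                             alpha = 0.5, c_p = 3e-5, pseudo = 0.5) {
  e <- 10^(-phred_q / 10)
  t1 <- c_p * prod(ifelse(alleles == x, 1 - e, e))
  s <- sum(pseudo + tabulate(factor(alleles, levels = theta), length(theta)))
  n_y <- tabulate(factor(alleles, levels = theta), length(theta))
  names(n_y) <- theta
  t2 <- prod(1 - e) *
    min(10^(-6 * (pseudo + n_y[setdiff(theta, x)]) / s))
  alpha * t1 + (1 - alpha) * t2
}

naive_posterior <- function(alleles, phred_q, theta, alpha = 0.5, c_p = 3e-5) {
  L <- vapply(theta, function(x) naive_likelihood(alleles, phred_q, x, theta,
                                                  alpha, c_p), numeric(1))
  L / sum(L)
}

# random barcode family over ACGT at mixed qualities
random_family <- function(n, seed) {
  set.seed(seed)
  list(alleles = sample(c("A", "C", "G", "T"), n, replace = TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)),
       phred_q = sample(c(20L, 25L, 30L, 37L), n, replace = TRUE))
}

# observation table for one locus built from per-barcode allele vectors
make_obs <- function(fam_alleles, phred_q = 30L, ref = "T", pos = 100L,
                     contig = "chr1", strand = NULL) {
  rows <- lapply(seq_along(fam_alleles), function(i) {
    a <- fam_alleles[[i]]
    data.table(contig = contig, pos = pos, ref = ref,
               barcode = sprintf("BC%04d", i), allele = a,
               phred_q = phred_q,
               strand = if (is.null(strand)) "+" else strand[[i]],
               pair_id = as.character(seq_along(a)))
  })
  rbindlist(rows)
}

# minimal SAM + FASTA + BED fixture written programmatically
write_sam_fixture <- function(dir, reads, ref_seq, contig = "ctg1") {
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", contig), ref_seq), fasta)
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, nchar(ref_seq)))
  writeLines(c(hdr, reads), sam)
  bed <- file.path(dir, "targets.bed")
  writeLines(sprintf("%s\t0\t%d", contig, nchar(ref_seq)), bed)
  list(sam = sam, fasta = fasta, bed = bed, contig = contig)
}

sam_read <- function(qname, pos, seq, contig = "ctg1", flag = 0L, mapq = 60L,
                     cigar = NULL, qual_char = "I", barcode = "AAAACCCC") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  paste(qname, flag, contig, pos, mapq, cigar, "*", 0, 0, seq,
        strrep(qual_char, nchar(seq)), paste0("MI:Z:", barcode),
        sep = "\t")
}
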