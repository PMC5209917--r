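# pileup-style allele ("G", "+AC", "-T") -> VCF REF/ALT at the anchor base
.to_vcf_alleles <- function(ref_base, allele) {
  ref <- ref_base
  alt <- allele
  ins <- startsWith(allele, "+")
  del <- startsWith(allele, "-")
  alt[ins] <- paste0(ref_base[ins], substring(allele[ins], 2L))
  ref[del] <- paste0(ref_base[del], substring(allele[del], 2L))
  alt[del] <- ref_base[del]
  list(ref = ref, alt = alt)
}

# VCF REF/ALT -> pileup-style allele
.from_vcf_alleles <- function(ref, alt) {
  out <- alt
  ins <- nchar(ref) == 1L & nchar(alt) > 1L & substr(alt, 1L, 1L) == ref
  del <- nchar(alt) == 1L & nchar(ref) > 1L & substr(ref, 1L, 1L) == alt
  out[ins] <- paste0("+", substring(alt[ins], 2L))
  out[del] <- paste0("-", substring(ref[del], 2L))
  out
}

#' Write candidate calls as VCF 4.2
#'
#' One record per candidate allele, in genomic order. `QUAL` carries the
#' prediction index of the allele; `INFO` carries the barcode depth (`UMT`),
#' alt barcode count (`VMT`), alt barcode fraction (`VMF`) and mean read
#' pairs per barcode (`RPB`); `FILTER` lists failed post-filters or `PASS`.
#'
#' @param calls Candidate table from [call_pileups()].
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @param contigs Optional named vector of contig lengths for the header.
#' @param date Include a `fileDate` header line (disable for byte-stable
#'   output).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE", contigs = NULL,
                      date = FALSE) {
  calls <- as.data.table(calls)
  if (nrow(calls) &&
      !identical(order(calls$contig, calls$pos), seq_len(nrow(calls)))) {
    stop("calls must be in genomic order")
  }
  hdr <- c("##fileformat=VCFv4.2",
           if (date) sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")),
           sprintf("##source=umicall-%s",
                   as.character(utils::packageVersion("umicall"))),
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=UMT,Number=1,Type=Integer,Description=\"Barcode depth (unique molecules) at the locus\">",
           "##INFO=<ID=VMT,Number=1,Type=Integer,Description=\"Barcodes whose consensus is the alt allele\">",
           "##INFO=<ID=VMF,Number=1,Type=Float,Description=\"Alt barcode fraction VMT/UMT\">",
           "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"Mean read pairs per barcode\">",
           "##FILTER=<ID=StrongBarcode,Description=\"Too few barcodes with strong read evidence\">",
           "##FILTER=<ID=StrandBias,Description=\"Alt barcodes imbalanced between strands\">",
           "##FILTER=<ID=Homopolymer,Description=\"Variant in or adjacent to a long single-base run\">",
           "##FILTER=<ID=LowComplexity,Description=\"Low dinucleotide entropy context\">",
           "##FILTER=<ID=Repeat,Description=\"Short-period tandem repeat context\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  lines <- hdr
  if (nrow(calls)) {
    va <- .to_vcf_alleles(calls$ref, calls$allele)
    info <- sprintf("UMT=%d;VMT=%d;VMF=%.6g;RPB=%.4g",
                    calls$umt, calls$vmt, calls$vmf, calls$rpb)
    lines <- c(lines,
               sprintf("%s\t%d\t.\t%s\t%s\t%.4f\t%s\t%s\tGT\t0/1",
                       calls$contig, calls$pos, va$ref, va$alt, calls$qual,
                       calls$filter, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated truth set as VCF 4.2
#'
#' @param truth Truth set from [simulate_truth()].
#' @param path Output path.
#' @param contigs Optional named contig lengths.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path, contigs = NULL) {
  truth <- as.data.table(truth)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Simulated allele fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (nrow(truth)) {
    setorder(truth, contig, pos)
    va <- .to_vcf_alleles(truth$ref, truth$allele)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                              truth$contig, truth$pos, va$ref, va$alt,
                              truth$af))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a call/truth table
#'
#' Thin wrapper over `VariantAnnotation::readVcf` that normalises records
#' back to the package's anchored allele representation, for
#' [evaluate_calls()].
#'
#' @param path VCF path.
#' @return `data.table` with `contig`, `pos`, `ref`, `allele`, `qual`,
#'   `filter`.
#' @export
read_calls_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- as.character(unlist(VariantAnnotation::alt(v)))
  ref <- as.character(VariantAnnotation::ref(v))
  dt <- data.table(contig = as.character(GenomicRanges::seqnames(rr)),
                   pos = GenomicRanges::start(rr),
                   ref_vcf = ref, alt_vcf = alt,
                   qual = as.numeric(rr$QUAL),
                   filter = as.character(rr$FILTER))
  dt[, ref := substr(ref_vcf, 1L, 1L)]
  dt[, allele := .from_vcf_alleles(ref_vcf, alt_vcf)]
  dt[, .(contig, pos, ref, allele, qual, filter)]
}
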