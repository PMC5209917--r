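#' Barcode source configuration
#'
#' Where to find the molecular barcode on each alignment record: a BAM tag
#' (`"MI"` with `"BX"` fallback by default) or a delimited suffix of the
#' read name.
#'
#' @param mode `"tag"` or `"read_name"`.
#' @param tags Tag names to try, in order.
#' @param delimiter Read-name delimiter; the barcode is the final field.
#' @return An object of class `barcode_config`.
#' @export
barcode_config <- function(mode = c("tag", "read_name"),
                           tags = c("MI", "BX"), delimiter = ":") {
  structure(list(mode = match.arg(mode), tags = tags, delimiter = delimiter),
            class = "barcode_config")
}

#' Extract molecular barcodes from alignment records
#'
#' @param qname Read names.
#' @param tags Named list of tag vectors (as returned by [Rsamtools::scanBam()]).
#' @param config [barcode_config()].
#' @return Uppercase barcode per record; `NA` where no barcode is present
#'   (such records are excluded from pileups and counted).
#' @export
extract_barcode <- function(qname, tags = list(), config = barcode_config()) {
  n <- length(qname)
  bc <- rep(NA_character_, n)
  if (config$mode == "tag") {
    for (tg in config$tags) {
      v <- tags[[tg]]
      if (is.null(v)) next
      fill <- is.na(bc) & !is.na(v) & nzchar(v)
      bc[fill] <- v[fill]
    }
  } else {
    parts <- strsplit(qname, config$delimiter, fixed = TRUE)
    last <- vapply(parts, function(p) if (length(p) > 1L) p[length(p)] else NA_character_,
                   character(1))
    bc <- last
  }
  toupper(bc)
}

#' Read-level pre-processing filter
#'
#' Screens alignment records before family formation: unmapped, secondary,
#' supplementary and QC-fail records are rejected, as are records below the
#' mapping-quality floor and (optionally) non-proper pairs.
#'
#' @param flag Integer SAM flag vector.
#' @param mapq Mapping qualities.
#' @param config [filter_config()].
#' @return Character vector: `"accept"` or the rejection reason.
#' @export
prefilter_read <- function(flag, mapq, config = filter_config()) {
  out <- rep("accept", length(flag))
  out[bitwAnd(flag, 0x4) != 0L] <- "unmapped"
  out[out == "accept" & bitwAnd(flag, 0x100) != 0L] <- "secondary"
  out[out == "accept" & bitwAnd(flag, 0x800) != 0L] <- "supplementary"
  out[out == "accept" & bitwAnd(flag, 0x200) != 0L] <- "qcfail"
  if (config$require_proper_pair) {
    paired <- bitwAnd(flag, 0x1) != 0L
    out[out == "accept" & paired & bitwAnd(flag, 0x2) == 0L] <- "not_proper_pair"
  }
  out[out == "accept" & (is.na(mapq) | mapq < config$min_mapq)] <- "low_mapq"
  out
}

# expand aligned reads into one row per (read, reference position) using the
# CIGAR; insertion/deletion alleles are anchored at the preceding base and
# replace the anchor-base observation of the same read
.expand_alignments <- function(qname, flag, contig, pos, cigar, seq, qual,
                               barcode, refseq_by_contig) {
  n <- length(qname)
  qual_int <- as(Biostrings::PhredQuality(qual), "IntegerList")
  qual_flat <- unlist(qual_int)
  seq_flat <- unlist(strsplit(as.character(seq), ""))
  off <- cumsum(c(0L, S4Vectors::width(seq)[-n]))

  mref <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos, ops = "M")
  mqry <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "M")
  w <- unlist(lapply(S4Vectors::width(mref), sum))
  read_idx <- rep(seq_len(n), w)
  ref_pos <- unlist(lapply(seq_len(n), function(i) {
    r <- mref[[i]]; unlist(Map(seq.int, IRanges::start(r), IRanges::end(r)))
  }))
  qry_pos <- unlist(lapply(seq_len(n), function(i) {
    r <- mqry[[i]]; unlist(Map(seq.int, IRanges::start(r), IRanges::end(r)))
  }))
  base_obs <- data.table(read = read_idx, pos = ref_pos,
                         allele = seq_flat[off[read_idx] + qry_pos],
                         phred_q = qual_flat[off[read_idx] + qry_pos])

  # insertions: query sequence inserted after the reference base at start-1
  iref <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos, ops = "I")
  iqry <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "I")
  ins_n <- lengths(iref)
  ins <- NULL
  if (sum(ins_n)) {
    ridx <- rep(seq_len(n), ins_n)
    anchors <- unlist(lapply(iref, IRanges::start)) - 1L
    qs <- unlist(lapply(iqry, IRanges::start))
    qe <- unlist(lapply(iqry, IRanges::end))
    ins_seq <- substr(as.character(seq)[ridx], qs, qe)
    ins <- data.table(read = ridx, pos = anchors,
                      allele = paste0("+", toupper(ins_seq)),
                      phred_q = qual_flat[off[ridx] + qs])
  }
  # deletions: reference bases missing from the read, anchored one base left
  dref <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, pos = pos, ops = "D")
  del_n <- lengths(dref)
  del <- NULL
  if (sum(del_n)) {
    ridx <- rep(seq_len(n), del_n)
    ds <- unlist(lapply(dref, IRanges::start))
    de <- unlist(lapply(dref, IRanges::end))
    del_seq <- substr(refseq_by_contig[contig[ridx]], ds, de)
    anchors <- ds - 1L
    # quality of the last aligned base before the deletion
    del <- data.table(read = ridx, pos = anchors,
                      allele = paste0("-", toupper(del_seq)),
                      phred_q = NA_integer_)
  }
  indels <- rbindlist(list(ins, del), use.names = TRUE)
  if (nrow(indels)) {
    aq <- base_obs[indels[, .(read, pos)], on = c("read", "pos"), x.phred_q]
    indels[, phred_q := data.table::fifelse(is.na(phred_q), aq, phred_q)]
    indels[is.na(phred_q), phred_q := 30L]
    base_obs <- base_obs[!indels[, .(read, pos)], on = c("read", "pos")]
    base_obs <- rbind(base_obs, indels)
  }
  base_obs[, `:=`(contig = contig[read],
                  barcode = barcode[read],
                  strand = ifelse(bitwAnd(flag[read], 0x10) != 0L, "-", "+"),
                  pair_id = qname[read])]
  base_obs
}

#' Build barcode-resolved pileups from aligned reads
#'
#' Collects reads over the target intervals, applies the read-level
#' pre-filters, extracts and (optionally) clusters barcodes per target
#' region, consolidates overlapping mates into single observations (mates
#' that agree keep the higher quality; mates that disagree are dropped) and
#' returns the pileup observation table.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM (a `.sam` file is
#'   converted on the fly).
#' @param bed Path to a BED file of target intervals (0-based half-open).
#' @param fasta Path to the reference FASTA.
#' @param config [filter_config()].
#' @param barcode [barcode_config()].
#' @param cluster Apply [cluster_barcodes()] per target region.
#' @param max_edit_distance Barcode clustering distance.
#' @return Pileup observation table restricted to target bases, in genomic
#'   order; attribute `n_no_barcode` counts excluded barcode-less reads.
#' @export
build_pileups <- function(bam, bed, fasta, config = filter_config(),
                          barcode = barcode_config(), cluster = TRUE,
                          max_edit_distance = 1L) {
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(bam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  targets <- rtracklayer::import(bed, format = "BED")
  if (!length(targets)) return(.empty_obs(NULL))
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  missing_contig <- setdiff(unique(as.character(GenomicRanges::seqnames(targets))),
                            names(hdr))
  if (length(missing_contig)) {
    stop(sprintf("target contig %s absent from alignment file",
                 missing_contig[1L]))
  }
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*", "", names(ref))
  refseq <- setNames(as.character(ref), names(ref))

  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::reduce(targets),
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = if (barcode$mode == "tag") barcode$tags else character())
  chunks <- Rsamtools::scanBam(bam, param = param)
  recs <- list(
    qname = unlist(lapply(chunks, `[[`, "qname")),
    flag = unlist(lapply(chunks, `[[`, "flag")),
    contig = as.character(unlist(lapply(chunks, `[[`, "rname"))),
    pos = unlist(lapply(chunks, `[[`, "pos")),
    mapq = unlist(lapply(chunks, `[[`, "mapq")),
    cigar = unlist(lapply(chunks, `[[`, "cigar")),
    seq = do.call(c, unname(lapply(chunks, `[[`, "seq"))),
    qual = do.call(c, unname(lapply(chunks, `[[`, "qual"))))
  tags <- list()
  if (barcode$mode == "tag") {
    for (tg in barcode$tags) {
      tags[[tg]] <- unlist(lapply(chunks, function(ch) {
        v <- ch$tag[[tg]]
        if (is.null(v)) rep(NA_character_, length(ch$qname)) else v
      }))
    }
  }
  # a read pair overlapping two target windows is returned once per window
  dup <- duplicated(paste(recs$qname, recs$flag, recs$pos))
  keep0 <- !dup
  verdict <- prefilter_read(recs$flag, recs$mapq, config)
  bc <- extract_barcode(recs$qname, tags, barcode)
  n_no_barcode <- sum(keep0 & verdict == "accept" & is.na(bc))
  keep <- which(keep0 & verdict == "accept" & !is.na(bc) & !is.na(recs$pos))
  if (!length(keep)) {
    return(structure(.empty_obs(NULL), n_no_barcode = n_no_barcode))
  }

  obs <- .expand_alignments(recs$qname[keep], recs$flag[keep],
                            recs$contig[keep], recs$pos[keep],
                            recs$cigar[keep], recs$seq[keep], recs$qual[keep],
                            bc[keep], refseq)
  obs <- obs[phred_q >= config$min_baseq | is_indel_allele(allele)]
  obs <- obs[allele != AMBIGUOUS_ALLELE]

  # restrict to target bases, tagging each with its target region
  gr <- GenomicRanges::GRanges(obs$contig, IRanges::IRanges(obs$pos, obs$pos))
  hit <- GenomicRanges::findOverlaps(gr, targets, select = "first")
  obs[, region := hit]
  obs <- obs[!is.na(region)]
  if (!nrow(obs)) return(structure(.empty_obs(NULL), n_no_barcode = n_no_barcode))

  # mate consolidation: one vote per read pair per locus
  obs[, distinct := length(unique(allele)), by = .(contig, pos, barcode, pair_id)]
  obs <- obs[distinct == 1L]
  setorder(obs, contig, pos, barcode, pair_id, -phred_q)
  obs <- obs[!duplicated(obs[, .(contig, pos, barcode, pair_id)])]

  if (cluster && nrow(obs)) {
    parts <- split(obs, by = "region", sorted = TRUE)
    obs <- rbindlist(lapply(parts, function(d) {
      counts <- d[, .(n = length(unique(pair_id))), by = barcode]
      cl <- cluster_barcodes(setNames(counts$n, counts$barcode),
                             max_edit_distance)
      map <- unlist(lapply(cl, function(x) {
        setNames(rep(x$representative, length(x$members)), names(x$members))
      }))
      d[, barcode := map[barcode]]
      d
    }))
  }
  obs[, ref := toupper(substr(refseq[contig], pos, pos))]
  out <- obs[, .(contig, pos, ref, barcode, allele, phred_q, strand, pair_id)]
  setorder(out, contig, pos, barcode, pair_id)
  structure(out[], n_no_barcode = n_no_barcode)
}
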