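PILEUP_COLUMNS <- c("contig", "pos", "ref", "barcode", "allele", "phred_q",
                    "strand", "pair_id")

#' Locus pileup: all barcode families covering one position
#'
#' @param obs A data frame with one row per read(-pair) observation at a
#'   single position; columns `contig`, `pos`, `ref`, `barcode`, `allele`,
#'   `phred_q`, `strand`, `pair_id`.
#' @return An object of class `locus_pileup` with fields `contig`, `pos`,
#'   `ref`, `obs`, `barcode_depth` (number of families, N), `read_depth`
#'   (total read pairs) and `rpb` (read pairs per barcode).
#' @export
locus_pileup <- function(obs) {
  obs <- as.data.table(obs)
  stopifnot(all(PILEUP_COLUMNS %in% names(obs)))
  if (nrow(obs)) {
    stopifnot(length(unique(obs$pos)) == 1L, length(unique(obs$contig)) == 1L)
  }
  obs <- obs[allele != AMBIGUOUS_ALLELE]
  bd <- if (nrow(obs)) length(unique(obs$barcode)) else 0L
  structure(list(contig = if (nrow(obs)) obs$contig[1L] else NA_character_,
                 pos = if (nrow(obs)) obs$pos[1L] else NA_integer_,
                 ref = if (nrow(obs)) obs$ref[1L] else NA_character_,
                 obs = obs,
                 barcode_depth = bd,
                 read_depth = nrow(obs),
                 rpb = if (bd > 0L) nrow(obs) / bd else NA_real_),
            class = "locus_pileup")
}

#' @export
print.locus_pileup <- function(x, ...) {
  cat(sprintf("Locus pileup %s:%d ref %s -- %d barcodes, %d read pairs (rpb %.2f)\n",
              x$contig, x$pos, x$ref, x$barcode_depth, x$read_depth, x$rpb))
  invisible(x)
}

#' Split a locus pileup into barcode families
#'
#' @param pileup A [locus_pileup()].
#' @return Named list of [barcode_family()] objects.
#' @export
pileup_families <- function(pileup) {
  stopifnot(inherits(pileup, "locus_pileup"))
  sp <- split(pileup$obs, by = "barcode")
  lapply(sp, function(d) barcode_family(d$barcode[1L], d$allele, d$phred_q,
                                        d$strand, d$pair_id))
}

#' Read a barcode-resolved pileup table
#'
#' The plain-text exchange/fixture format: a tab-separated file with header
#' columns `contig`, `pos` (1-based), `ref`, `barcode`, `allele`, `phred_q`,
#' `strand`, `pair_id`. Rows must be grouped by contig and non-decreasing in
#' position within a contig.
#'
#' @param path File path.
#' @return A `data.table` of observations (the pileup table).
#' @export
read_pileup_table <- function(path) {
  tbl <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("contig", "ref", "barcode",
                                                           "allele", "strand", "pair_id")))
  if (!all(PILEUP_COLUMNS %in% names(tbl))) {
    stop(sprintf("pileup table %s lacks required columns: %s", path,
                 paste(setdiff(PILEUP_COLUMNS, names(tbl)), collapse = ", ")))
  }
  tbl <- tbl[, PILEUP_COLUMNS, with = FALSE]
  bad <- which(!is.finite(tbl$pos) | tbl$pos < 1 | !is.finite(tbl$phred_q) |
                 tbl$phred_q < 0 | !nzchar(tbl$allele) | !tbl$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("malformed pileup line %d in %s", bad[1L] + 1L, path))
  }
  ooo <- tbl[, any(diff(pos) < 0), by = contig][V1 == TRUE]
  if (nrow(ooo)) {
    stop(sprintf("pileup table %s: positions out of order on contig %s",
                 path, ooo$contig[1L]))
  }
  tbl[, pos := as.integer(pos)]
  tbl[, phred_q := as.integer(phred_q)]
  tbl[]
}

#' Write a barcode-resolved pileup table
#'
#' @param obs Pileup observation table (as returned by [read_pileup_table()]
#'   or [simulate_pileups()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pileup_table <- function(obs, path) {
  obs <- as.data.table(obs)
  stopifnot(all(PILEUP_COLUMNS %in% names(obs)))
  data.table::fwrite(obs[, PILEUP_COLUMNS, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Split a pileup table into locus pileups
#'
#' @param obs Pileup observation table.
#' @return List of [locus_pileup()] objects in genomic order.
#' @export
as_locus_pileups <- function(obs) {
  obs <- as.data.table(obs)
  if (!nrow(obs)) return(list())
  sp <- split(obs, by = c("contig", "pos"), sorted = TRUE)
  unname(lapply(sp, locus_pileup))
}
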