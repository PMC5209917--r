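#' @importFrom data.table data.table := .N .SD .I setorder as.data.table copy rbindlist
#' @importFrom stats pbinom rbinom rpois runif setNames fisher.test
#' @importFrom utils adist head tail
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")
AMBIGUOUS_ALLELE <- "N"

# Indel alleles use pileup-style strings anchored at the locus:
#   "+SEQ" = insertion of SEQ immediately after the locus base
#   "-SEQ" = deletion of SEQ immediately after the locus base
# They are converted to VCF REF/ALT representation only when writing output.
is_indel_allele <- function(allele) startsWith(allele, "+") | startsWith(allele, "-")

#' Allele space at a locus
#'
#' The set of alleles considered by the per-barcode model at one position:
#' always all four nucleotides, plus every distinct indel allele observed in
#' the reads, plus the reference allele. Each allele receives an equal prior
#' probability `1 / |theta|`.
#'
#' @param reference Reference allele at the locus (a single base).
#' @param observed Character vector of observed alleles (bases and/or indel
#'   alleles such as `"+AC"`, `"-T"`); ambiguous-base sentinels are ignored.
#' @return An object of class `allele_space` with elements `alleles`,
#'   `reference` and `prior`.
#' @examples
#' allele_space("T", c("A", "A", "+AC"))
#' @export
allele_space <- function(reference, observed = character()) {
  stopifnot(is.character(reference), length(reference) == 1L, nzchar(reference))
  reference <- toupper(reference)
  observed <- setdiff(unique(toupper(observed)), AMBIGUOUS_ALLELE)
  indels <- sort(observed[is_indel_allele(observed)])
  alleles <- unique(c(NUCLEOTIDES, indels, reference))
  # deterministic order: A < C < G < T < indels (by string), reference included
  alleles <- c(NUCLEOTIDES[NUCLEOTIDES %in% alleles],
               sort(setdiff(alleles, NUCLEOTIDES)))
  structure(list(alleles = alleles, reference = reference,
                 prior = 1 / length(alleles)),
            class = "allele_space")
}

#' @export
print.allele_space <- function(x, ...) {
  cat(sprintf("Allele space: {%s}, reference %s, uniform prior %.4g\n",
              paste(x$alleles, collapse = ", "), x$reference, x$prior))
  invisible(x)
}
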