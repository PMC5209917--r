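#' Cluster barcodes by edit distance (directional rule)
#'
#' Sequencing or PCR errors in the barcode itself split one molecule's reads
#' over several near-identical barcodes. Within an amplicon, barcodes within
#' a small Levenshtein distance of a much better-supported barcode are folded
#' into it: barcode `a` absorbs barcode `b` when `dist(a, b) <=
#' max_edit_distance` and `count(a) >= 2 * count(b) - 1` (the directional
#' rule). Absorption proceeds transitively outward from the highest-count
#' seed; total read count is conserved.
#'
#' @param counts Named integer vector: read count per barcode.
#' @param max_edit_distance Maximum Levenshtein distance to merge (default 1).
#' @param count_ratio Directional threshold: absorb `b` into `a` when
#'   `count(a) >= count_ratio * count(b) - 1` (default 2).
#' @return List of clusters; each has `representative`, `members` (named
#'   count vector) and `reads` (total read count).
#' @examples
#' cluster_barcodes(c(AAAA = 100L, AAAT = 2L))
#' @export
cluster_barcodes <- function(counts, max_edit_distance = 1L, count_ratio = 2) {
  if (!length(counts)) stop("no barcodes to cluster")
  stopifnot(!is.null(names(counts)), all(counts > 0))
  bc <- names(counts)
  # deterministic: by decreasing count, ties lexicographic
  ord <- order(-counts, bc)
  bc <- bc[ord]; cnt <- as.integer(counts[ord])
  n <- length(bc)
  d <- adist(bc)  # Levenshtein
  assigned <- integer(n)  # 0 = unassigned, else cluster seed index
  clusters <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    assigned[i] <- i
    frontier <- i
    while (length(frontier)) {
      nxt <- integer()
      for (j in frontier) {
        cand <- which(assigned == 0L & d[j, ] <= max_edit_distance &
                        cnt[j] >= count_ratio * cnt - 1)
        if (length(cand)) {
          assigned[cand] <- i
          nxt <- c(nxt, cand)
        }
      }
      frontier <- nxt
    }
    members <- which(assigned == i)
    clusters[[length(clusters) + 1L]] <-
      list(representative = bc[i],
           members = setNames(cnt[members], bc[members]),
           reads = sum(cnt[members]))
  }
  clusters
}

#' Relabel barcodes in a pileup table by their cluster representative
#'
#' Clustering is applied per target region (identified here by contig),
#' since identical barcodes on different amplicons are distinct molecules.
#'
#' @param obs Pileup observation table.
#' @param max_edit_distance Passed to [cluster_barcodes()].
#' @return The table with `barcode` replaced by cluster representatives.
#' @export
apply_barcode_clusters <- function(obs, max_edit_distance = 1L) {
  obs <- as.data.table(obs)
  if (!nrow(obs)) return(obs)
  out <- lapply(split(obs, by = "contig", sorted = TRUE), function(d) {
    counts <- d[, .N, by = barcode]
    cl <- cluster_barcodes(setNames(counts$N, counts$barcode), max_edit_distance)
    map <- unlist(lapply(cl, function(x) setNames(rep(x$representative,
                                                      length(x$members)),
                                                  names(x$members))))
    d[, barcode := map[barcode]]
    d
  })
  data.table::rbindlist(out)
}
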