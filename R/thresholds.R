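CUTOFF_EQUATIONS <- data.frame(
  fpr_per_mb = c(20, 50, 100),
  intercept  = c(14, 15, 13),
  slope      = c(0.012, 0.0092, 0.0088)
)

#' Recommended prediction-index cutoff
#'
#' Empirical linear rule mapping barcode depth to the prediction-index
#' cutoff that keeps the false-positive rate at the tolerated level:
#' `ceiling(a + b * depth)` with `(a, b)` = (14, 0.012), (15, 0.0092) and
#' (13, 0.0088) for 20, 50 and 100 false positives per megabase. No
#' interpolation is offered for other rates.
#'
#' @param fpr_per_mb Tolerated false positives per megabase: 20, 50 or 100.
#' @param barcode_depth Barcode depth (mean number of molecular-barcode
#'   families per base); positive, may be fractional.
#' @return Integer cutoff(s).
#' @examples
#' recommend_cutoff(20, 1000)  # 26
#' @export
recommend_cutoff <- function(fpr_per_mb, barcode_depth) {
  i <- match(fpr_per_mb, CUTOFF_EQUATIONS$fpr_per_mb)
  if (any(is.na(i))) {
    stop(sprintf("unsupported FPR %s; supported values: %s",
                 paste(fpr_per_mb[is.na(i)], collapse = ", "),
                 paste(CUTOFF_EQUATIONS$fpr_per_mb, collapse = ", ")))
  }
  if (any(barcode_depth <= 0)) stop("barcode depth must be positive")
  as.integer(ceiling(CUTOFF_EQUATIONS$intercept[i] +
                       CUTOFF_EQUATIONS$slope[i] * barcode_depth))
}

#' Minimum number of alt-supporting barcodes needed to reach a cutoff
#'
#' With a typical good barcode contributing `i_bar` index units (around 3.5),
#' a variant needs `ceiling(cutoff / i_bar)` supporting barcodes to clear
#' the cutoff.
#'
#' @param cutoff Prediction-index cutoff (> 0).
#' @param i_bar Average per-barcode index of a barcode with good read
#'   evidence (> 0).
#' @return Positive integer.
#' @examples
#' min_alt_barcodes(26, 3.5)  # 8
#' @export
min_alt_barcodes <- function(cutoff, i_bar = 3.5) {
  stopifnot(all(cutoff > 0), all(i_bar > 0))
  as.integer(ceiling(cutoff / i_bar))
}

#' Locus-specific detection limit
#'
#' The smallest allele fraction `f*` detectable at a locus with the stated
#' confidence: the number of alt-supporting barcodes is binomial in the
#' barcode depth, and detection requires at least `k =
#' ceiling(cutoff / i_bar)` of them. By default (`convention =
#' "narrative"`) the cutoff is taken from the run-average barcode depth `D`
#' (a deeper run demands a stricter cutoff) while sampling uses the locus
#' depth `d` (a deeper locus has more power); `convention = "literal"`
#' swaps the two, i.e. cutoff from `d` and sampling from `Bin(D, f)`.
#' Solved by bisection to absolute tolerance `1e-5` with an exact binomial
#' tail check at the solution.
#'
#' @param d Locus barcode depth (> 0).
#' @param D Run-average barcode depth (> 0).
#' @param fpr_per_mb Tolerated false-positive rate (20, 50 or 100).
#' @param i_bar Average index of a good barcode (default 3.5).
#' @param confidence Required detection probability (default 0.95).
#' @param convention `"narrative"` (default) or `"literal"`, see above.
#' @return `f*` in `(0, 1]`. When even `f = 1` cannot supply `k` barcodes
#'   (`k > d`), returns `1.0` with attribute `undetectable = TRUE`.
#' @examples
#' detection_limit(1000, 1000)  # about 0.0132
#' @export
detection_limit <- function(d, D, fpr_per_mb = 20, i_bar = 3.5,
                            confidence = 0.95, convention = c("narrative", "literal")) {
  convention <- match.arg(convention)
  stopifnot(d > 0, D > 0, i_bar > 0, confidence > 0, confidence < 1)
  cutoff_depth <- if (convention == "narrative") D else d
  n_trials <- if (convention == "narrative") d else D
  k <- min_alt_barcodes(recommend_cutoff(fpr_per_mb, cutoff_depth), i_bar)
  if (k > n_trials) {
    return(structure(1.0, undetectable = TRUE))
  }
  tail_ok <- function(f) pbinom(k - 1, n_trials, f, lower.tail = FALSE) >= confidence
  if (!tail_ok(1)) return(structure(1.0, undetectable = TRUE))  # k = n, conf > p^n
  lo <- 0; hi <- 1
  while (hi - lo > 1e-5) {
    mid <- (lo + hi) / 2
    if (tail_ok(mid)) hi <- mid else lo <- mid
  }
  stopifnot(tail_ok(hi))  # exact tail verification at the solution
  hi
}

#' Detection-limit profile over a region
#'
#' Element-wise [detection_limit()] over a per-base barcode-depth track,
#' memoised over distinct depths. Bases with zero depth have no defined
#' limit (`NA`).
#'
#' @param depths Integer vector of per-base barcode depths.
#' @param pos 1-based positions, parallel to `depths` (default consecutive).
#' @param contig Contig name.
#' @param D Run-average barcode depth; default the mean of the nonzero
#'   depths.
#' @param ... Passed to [detection_limit()].
#' @return A `data.table` (class `detection_limit_profile`) with columns
#'   `contig`, `pos`, `depth`, `f_star`.
#' @export
detection_limit_track <- function(depths, pos = seq_along(depths),
                                  contig = "region", D = NULL, ...) {
  stopifnot(length(depths) == length(pos))
  if (!length(depths)) {
    return(structure(data.table(contig = character(), pos = integer(),
                                depth = integer(), f_star = numeric()),
                     class = c("detection_limit_profile", "data.table", "data.frame")))
  }
  if (is.null(D)) D <- mean(depths[depths > 0])
  uniq <- unique(depths[depths > 0])
  fmap <- setNames(vapply(uniq, function(d) as.numeric(detection_limit(d, D, ...)),
                          numeric(1)), uniq)
  f <- rep(NA_real_, length(depths))
  nz <- depths > 0
  f[nz] <- fmap[as.character(depths[nz])]
  structure(data.table(contig = contig, pos = as.integer(pos),
                       depth = as.integer(depths), f_star = f),
            class = c("detection_limit_profile", "data.table", "data.frame"))
}

#' Write a per-base value track as bedGraph
#'
#' Emits 0-based half-open intervals, merging adjacent bases with equal
#' values; bases with `NA` value are omitted.
#'
#' @param profile A `data.table` with columns `contig`, `pos` (1-based) and
#'   the value column.
#' @param path Output file path.
#' @param value Name of the value column (default `"f_star"`).
#' @param track_name Optional bedGraph track name line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, value = "f_star", track_name = NULL) {
  profile <- as.data.table(profile)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  }
  prof <- profile[!is.na(get(value))]
  if (nrow(prof)) {
    setorder(prof, contig, pos)
    # runs of consecutive positions with identical value
    prof[, run := cumsum(c(1L, (diff(pos) != 1L) |
                             (get(value)[-1L] != get(value)[-.N]) |
                             (contig[-1L] != contig[-.N]))), ]
    runs <- prof[, .(contig = contig[1L], start0 = pos[1L] - 1L,
                     end = pos[.N], val = get(value)[1L]), by = run]
    writeLines(sprintf("%s\t%d\t%d\t%g", runs$contig, runs$start0,
                       runs$end, runs$val), con)
  }
  invisible(path)
}
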