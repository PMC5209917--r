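#' Convert a Phred quality score to an error probability
#'
#' @param q Integer Phred score(s), `>= 0`.
#' @return `10^(-q/10)`, the probability the base call is wrong.
#' @examples
#' phred_to_error(30)  # 0.001
#' @export
phred_to_error <- function(q) {
  if (any(!is.finite(q)) || any(q < 0)) stop("Phred quality must be finite and >= 0")
  10^(-q / 10)
}

#' Construct a barcode family
#'
#' All read(-pair) observations at one locus that share one molecular
#' barcode; the independent evidence unit of the model. Ambiguous-base
#' observations (`N`) are dropped at construction.
#'
#' @param barcode Barcode string (A/C/G/T).
#' @param alleles Character vector of observed alleles, one per read pair.
#' @param phred_q Integer vector of Phred qualities, parallel to `alleles`.
#' @param strand Optional strand vector (`"+"`/`"-"`), recycled if length 1.
#' @param pair_id Optional read-pair identifiers.
#' @return An object of class `barcode_family`.
#' @export
barcode_family <- function(barcode, alleles, phred_q, strand = "+", pair_id = NULL) {
  stopifnot(length(alleles) == length(phred_q))
  alleles <- toupper(alleles)
  keep <- alleles != AMBIGUOUS_ALLELE
  alleles <- alleles[keep]
  phred_q <- phred_q[keep]
  if (length(strand) == 1L) strand <- rep(strand, length(alleles)) else strand <- strand[keep]
  if (is.null(pair_id)) pair_id <- as.character(seq_along(alleles)) else pair_id <- pair_id[keep]
  if (any(phred_q < 0)) stop("Phred quality must be >= 0")
  obs <- data.table(allele = alleles, phred_q = as.integer(phred_q),
                    strand = strand, pair_id = pair_id)
  counts <- table(factor(alleles, levels = unique(alleles)))
  structure(list(barcode = barcode, observations = obs,
                 allele_counts = setNames(as.integer(counts), names(counts))),
            class = "barcode_family")
}

log10e <- log(10)

# log-sum-exp of two vectors, -Inf-safe
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

# Vectorised per-barcode posterior engine. `obs` holds one row per read
# observation with columns locus (integer id), barcode, allele, phred_q.
# `theta` holds the allele space per locus (columns locus, allele).
# Returns one row per (locus, barcode, theta allele) with the log-likelihood,
# posterior and the evidence weight -log10(1 - posterior).
family_posterior_table <- function(obs, theta, params = model_params()) {
  obs <- as.data.table(obs)
  if (!nrow(obs)) {
    return(data.table(locus = integer(), barcode = character(),
                      allele = character(), n = integer(),
                      posterior = numeric(), weight = numeric()))
  }
  obs <- obs[allele != AMBIGUOUS_ALLELE]
  theta <- as.data.table(theta)
  e <- phred_to_error(obs$phred_q)
  obs[, `:=`(ln_e = -phred_q / 10 * log10e, ln_1me = log1p(-e))]

  fam <- obs[, .(tot_lne = sum(ln_e), tot_ln1me = sum(ln_1me), n = .N),
             by = .(locus, barcode)]
  by_allele <- obs[, .(s_lne = sum(ln_e), s_ln1me = sum(ln_1me), n_y = .N),
                   by = .(locus, barcode, allele)]
  # top-two observed allele counts per family, for min_{Y != x} of the
  # PCR-error exponent (the min is attained at the largest n_Y, ties broken
  # by allele order -- the value is identical either way)
  setorder(by_allele, locus, barcode, -n_y, allele)
  top <- by_allele[, .(top_allele = allele[1L], top_n = n_y[1L],
                       second_n = if (.N > 1L) n_y[2L] else 0L),
                   by = .(locus, barcode)]
  fam <- top[fam, on = c("locus", "barcode")]

  th_size <- theta[, .(k_theta = .N), by = locus]
  grid <- fam[theta, on = "locus", allow.cartesian = TRUE]
  grid <- th_size[grid, on = "locus"]
  grid <- by_allele[, .(locus, barcode, allele, s_lne, s_ln1me, n_y)][
    grid, on = c("locus", "barcode", "allele")]
  for (col in c("s_lne", "s_ln1me")) grid[is.na(get(col)), (col) := 0]
  grid[is.na(n_y), n_y := 0L]
  grid[, max_n_not_x := ifelse(allele == top_allele, second_n, top_n)]

  ps <- params$pseudo_count
  grid[, s_total := ps * k_theta + n]
  t1 <- if (params$alpha > 0) {
    log(params$alpha) + log(params$c_p) +
      (grid$tot_lne - grid$s_lne) + grid$s_ln1me
  } else rep(-Inf, nrow(grid))
  t2 <- if (params$alpha < 1) {
    log1p(-params$alpha) + grid$tot_ln1me +
      log10e * (-6 * (ps + grid$max_n_not_x) / grid$s_total)
  } else rep(-Inf, nrow(grid))
  grid[, ll := lse2(t1, t2)]

  # posterior with a uniform prior: normalise within each family; 1 - p is
  # accumulated from the complementary alleles so that small complements
  # survive floating point
  grid[, m := max(ll), by = .(locus, barcode)]
  grid[, ex := ifelse(is.finite(ll), exp(ll - m), 0)]
  grid[, sum_ex := sum(ex), by = .(locus, barcode)]
  grid[sum_ex == 0, ex := 1]  # fully degenerate family: uniform posterior
  grid[sum_ex == 0, sum_ex := as.double(k_theta)]
  grid[, posterior := ex / sum_ex]
  grid[, one_minus := pmax((sum_ex - ex) / sum_ex, 0)]
  grid[, weight := -log10(pmax(one_minus, params$posterior_clamp))]
  out <- grid[, .(locus, barcode, allele, n, ll, posterior, weight)]
  setorder(out, locus, barcode, allele)
  out[]
}

.family_obs_table <- function(family) {
  stopifnot(inherits(family, "barcode_family"))
  if (!nrow(family$observations)) stop("barcode family has no usable observations")
  data.table(locus = 1L, barcode = family$barcode,
             allele = family$observations$allele,
             phred_q = family$observations$phred_q)
}

.theta_table <- function(space) data.table(locus = 1L, allele = space$alleles)

#' Likelihood of a barcode family given a true allele
#'
#' Heuristic likelihood of all reads in one barcode family given that the
#' originating molecule carried allele `x`: a weighted sum of a base-calling
#' error term (each non-`x` read explained by its Phred error probability,
#' scaled by the PCR-error prior `c_p`) and a PCR-error term (no base-calling
#' errors, with the non-`x` alleles explained by a heuristic PCR-error
#' probability `10^(-6 (0.5 + n_Y) / sum_Z (0.5 + n_Z))` minimised over the
#' competing alleles `Y != x`).
#'
#' @param family A [barcode_family()].
#' @param x Candidate true allele, must lie in the allele space.
#' @param space An [allele_space()].
#' @param params [model_params()].
#' @return The likelihood, in `(0, 1]` (up to floating point).
#' @export
likelihood_family_given_allele <- function(family, x, space, params = model_params()) {
  if (!x %in% space$alleles) stop(sprintf("allele '%s' not in the allele space", x))
  obs <- .family_obs_table(family)
  tab <- family_posterior_table(obs, .theta_table(space), params)
  exp(tab[allele == x, ll])
}

#' Posterior allele probabilities for one barcode family
#'
#' Applies Bayes' rule with a uniform prior over the allele space to the
#' per-allele family likelihoods. Computed in log space; never returns `NaN`
#' and always sums to 1 over the space.
#'
#' @inheritParams likelihood_family_given_allele
#' @return Named numeric vector of posteriors over `space$alleles`.
#' @export
posterior_family <- function(family, space, params = model_params()) {
  obs <- .family_obs_table(family)
  tab <- family_posterior_table(obs, .theta_table(space), params)
  setNames(tab$posterior, tab$allele)[space$alleles]
}

#' Evidence weight of one barcode for one allele
#'
#' The contribution of a single barcode family to the locus-level prediction
#' index: `-log10(1 - posterior)`, with `1 - posterior` floored at
#' `params$posterior_clamp` so one molecule contributes at most
#' `-log10(clamp)` (6 by default) index units.
#'
#' @param posterior Posterior probability in `[0, 1]`.
#' @param params [model_params()].
#' @return Nonnegative finite weight.
#' @examples
#' barcode_evidence(0.9)  # 1
#' @export
barcode_evidence <- function(posterior, params = model_params()) {
  stopifnot(all(posterior >= 0 & posterior <= 1))
  -log10(pmax(1 - posterior, params$posterior_clamp))
}

#' Locus-level prediction index of an allele
#'
#' Sum over the (mutually independent) barcode families covering the locus of
#' the per-barcode evidence weight for `allele`. The index is the `-log10` of
#' the probability that no molecule carries the allele, so it grows additively
#' with supporting barcodes.
#'
#' @param families List of [barcode_family()] objects with distinct barcodes.
#' @param allele Allele to score.
#' @param space [allele_space()].
#' @param params [model_params()].
#' @return Nonnegative real; `0` for an empty family list.
#' @export
prediction_index <- function(families, allele, space, params = model_params()) {
  if (!length(families)) return(0)
  sum(vapply(families, function(f) {
    barcode_evidence(posterior_family(f, space, params)[[allele]], params)
  }, numeric(1)))
}
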