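test_that("phred conversion follows the 10^(-q/10) law and rejects bad input", {
  expect_equal(phred_to_error(30), 0.001)
  expect_equal(phred_to_error(10), 0.1)
  expect_equal(phred_to_error(0), 1.0)
  expect_error(phred_to_error(-1), ">= 0")
})

test_that("single-read likelihoods match hand evaluation of both terms", {
  sp <- allele_space("T")
  one_a_q10 <- barcode_family("b1", "A", 10L)
  expect_equal(
    likelihood_family_given_allele(one_a_q10, "A", sp, model_params(alpha = 1)),
    3e-5 * 0.9, tolerance = 1e-12)
  one_a_q20 <- barcode_family("b1", "A", 20L)
  expect_equal(
    likelihood_family_given_allele(one_a_q20, "T", sp, model_params(alpha = 0)),
    (1 - 0.01) * 10^(-6 * 1.5 / 3), tolerance = 1e-12)
})

test_that("likelihood favours the allele the reads support", {
  sp <- allele_space("T")
  for (q in c(15L, 25L, 35L)) {
    fam <- barcode_family("b", rep("A", 6L), rep(q, 6L))
    expect_gt(likelihood_family_given_allele(fam, "A", sp),
              likelihood_family_given_allele(fam, "T", sp))
  }
})

test_that("invalid inputs to the likelihood raise errors", {
  sp <- allele_space("T")
  fam <- barcode_family("b", "A", 30L)
  expect_error(likelihood_family_given_allele(fam, "+AC", sp), "not in")
  empty <- barcode_family("b", character(), integer())
  expect_error(likelihood_family_given_allele(empty, "A", sp), "no usable")
})

test_that("posteriors normalise, are symmetric under tied evidence, and are confident under unanimous evidence", {
  sp <- allele_space("T")
  for (seed in 1:25) {
    f <- random_family(sample(1:10, 1), seed)
    fam <- barcode_family("b", f$alleles, f$phred_q)
    p <- posterior_family(fam, sp)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_false(any(is.nan(p)))
  }
  tied <- barcode_family("b", c("A", "A", "T", "T"), rep(30L, 4))
  p <- posterior_family(tied, sp)
  expect_equal(p[["A"]], p[["T"]], tolerance = 1e-12)
  pure <- barcode_family("b", rep("A", 8), rep(30L, 8))
  expect_gt(posterior_family(pure, sp)[["A"]], 0.99)
})

test_that("log-space posteriors agree with the naive direct-product oracle", {
  sp <- allele_space("T")
  for (seed in 1:40) {
    f <- random_family(sample(1:10, 1), seed + 100)
    fam <- barcode_family("b", f$alleles, f$phred_q)
    got <- posterior_family(fam, sp)
    want <- naive_posterior(f$alleles, f$phred_q, sp$alleles)
    expect_equal(unname(got), unname(want[sp$alleles]), tolerance = 1e-9)
  }
})

test_that("alpha = 0.5 posteriors equal those of the unweighted term sum", {
  sp <- allele_space("T")
  for (seed in 1:10) {
    f <- random_family(8L, seed + 300)
    fam <- barcode_family("b", f$alleles, f$phred_q)
    p_half <- posterior_family(fam, sp, model_params(alpha = 0.5))
    # direct sum of the two error terms, via the alpha = 1 / alpha = 0 limits
    lik_sum <- vapply(sp$alleles, function(x) {
      likelihood_family_given_allele(fam, x, sp, model_params(alpha = 1)) +
        likelihood_family_given_allele(fam, x, sp, model_params(alpha = 0))
    }, numeric(1))
    expect_equal(unname(p_half), unname(lik_sum / sum(lik_sum)),
                 tolerance = 1e-12)
  }
})

test_that("barcode evidence is the clamped -log10 complement of the posterior", {
  expect_equal(barcode_evidence(0.9), 1.0)
  expect_equal(barcode_evidence(0), 0.0)
  expect_equal(barcode_evidence(1), 6.0)
  expect_equal(barcode_evidence(1, model_params(posterior_clamp = 1e-4)), 4.0)
  expect_error(barcode_evidence(1.5))
})

test_that("the prediction index is additive over barcodes and zero when empty", {
  sp <- allele_space("T")
  fam <- barcode_family("b", rep("A", 8), rep(30L, 8))
  p <- posterior_family(fam, sp)[["A"]]
  w <- barcode_evidence(p)
  expect_equal(prediction_index(list(fam, fam, fam), "A", sp), 3 * w)
  expect_equal(prediction_index(list(), "A", sp), 0)
  f2 <- barcode_family("c", c("A", "T", "T"), rep(30L, 3))
  expect_equal(prediction_index(list(fam, f2), "A", sp),
               prediction_index(list(fam), "A", sp) +
                 prediction_index(list(f2), "A", sp),
               tolerance = 1e-12)
})

test_that("raising alt-read quality never lowers the alt posterior", {
  sp <- allele_space("T")
  qs <- c(10L, 15L, 20L, 25L, 30L, 35L, 40L)
  for (n_alt in c(1L, 3L, 5L)) {
    post <- vapply(qs, function(q) {
      fam <- barcode_family("b", c(rep("A", n_alt), rep("T", 8 - n_alt)),
                            c(rep(q, n_alt), rep(30L, 8 - n_alt)))
      posterior_family(fam, sp)[["A"]]
    }, numeric(1))
    expect_true(all(diff(post) >= -1e-12))
  }
})

test_that("ambiguous-base observations are excluded from the family", {
  fam <- barcode_family("b", c("A", "N", "A"), c(30L, 30L, 30L))
  expect_equal(nrow(fam$observations), 2L)
  sp <- allele_space("T")
  clean <- barcode_family("b", c("A", "A"), c(30L, 30L))
  expect_equal(posterior_family(fam, sp), posterior_family(clean, sp))
})

test_that("calling a locus nominates non-reference alleles above the threshold", {
  obs <- make_obs(c(replicate(10, rep("A", 8), simplify = FALSE),
                    replicate(5, rep("T", 8), simplify = FALSE)))
  pl <- locus_pileup(obs)
  call <- call_locus(pl, threshold = 14)
  expect_s3_class(call, "locus_call")
  expect_equal(call$candidate_alleles, "A")
  expect_equal(call$n_barcodes, 15L)
  expect_gt(call$prediction_index[["A"]], 14)
  # all-reference pileup yields no candidates
  wt <- locus_pileup(make_obs(replicate(10, rep("T", 8), simplify = FALSE)))
  expect_length(call_locus(wt, 14)$candidate_alleles, 0L)
  # zero-barcode locus is flagged
  none <- locus_pileup(make_obs(list("T"))[0L])
  expect_true(call_locus(none, 14)$no_coverage)
})

test_that("indel alleles enter the allele space and can be called", {
  fams <- c(replicate(10, rep("+AC", 6), simplify = FALSE),
            replicate(20, rep("T", 6), simplify = FALSE))
  pl <- locus_pileup(make_obs(fams))
  call <- call_locus(pl, threshold = 14)
  expect_true("+AC" %in% call$allele_space$alleles)
  expect_equal(call$candidate_alleles, "+AC")
})
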