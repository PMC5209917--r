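test_that("truth simulation is deterministic, spaced and sized as requested", {
  cfg <- sim_config(region_length = 10000L)
  ref <- simulate_reference(cfg, seed = 3)
  expect_equal(nchar(ref), 10000L)
  expect_identical(ref, simulate_reference(cfg, seed = 3))

  t1 <- simulate_truth(cfg, ref, n_snv = 100, min_spacing = 50, seed = 4)
  expect_equal(nrow(t1), 100L)
  expect_true(all(diff(t1$pos) >= 50))
  expect_identical(t1, simulate_truth(cfg, ref, n_snv = 100,
                                      min_spacing = 50, seed = 4))
  expect_equal(nrow(simulate_truth(cfg, ref, n_snv = 0, seed = 4)), 0L)
  expect_error(simulate_truth(cfg, ref, n_snv = 500, min_spacing = 50,
                              seed = 4), "cannot hold")
  # SNV alt never equals the reference base
  expect_true(all(t1$allele != t1$ref))
})

test_that("indel truth alleles are anchored insertions or deletions of 1-10 bp", {
  cfg <- sim_config(region_length = 20000L)
  ref <- simulate_reference(cfg, seed = 5)
  tr <- simulate_truth(cfg, ref, n_snv = 0, n_indel = 40, seed = 6)
  expect_true(all(grepl("^[+-][ACGT]{1,10}$", tr$allele)))
  refchars <- strsplit(ref, "")[[1L]]
  dels <- tr[startsWith(allele, "-")]
  for (i in seq_len(nrow(dels))) {
    seq <- substring(dels$allele[i], 2L)
    expect_equal(seq, paste(refchars[dels$pos[i] + seq_len(nchar(seq))],
                            collapse = ""))
  }
})

test_that("error-free simulation recovers the allele fraction and stays clean", {
  cfg <- sim_config(region_length = 500L, mean_barcode_depth = 800,
                    rpb_mean = 4, first_cycle_error_rate = 0,
                    later_cycle_error_rate = 0, phred_q = 93L)
  ref <- simulate_reference(cfg, seed = 7)
  truth <- simulate_truth(cfg, ref, n_snv = 4, fractions = 0.5,
                          min_spacing = 60, seed = 8)
  obs <- simulate_pileups(truth, cfg, ref, seed = 9)
  # alt barcode fraction approximately 0.5 within 3 sigma
  for (i in seq_len(nrow(truth))) {
    fam <- obs[pos == truth$pos[i], .(alt = all(allele == truth$allele[i])),
               by = barcode]
    n <- nrow(fam)
    expect_lt(abs(mean(fam$alt) - 0.5), 3 * sqrt(0.25 / n))
  }
  # f = 0 with zero error rates: no non-reference observation anywhere
  wt <- simulate_pileups(truth[0L], cfg, ref,
                         positions = truth$pos + 1L, seed = 10)
  expect_true(all(wt$allele == wt$ref))
})

test_that("pileup simulation is deterministic under a fixed seed", {
  cfg <- sim_config(region_length = 300L, mean_barcode_depth = 200)
  ref <- simulate_reference(cfg, seed = 11)
  truth <- simulate_truth(cfg, ref, n_snv = 2, fractions = 0.05,
                          min_spacing = 60, seed = 12)
  o1 <- simulate_pileups(truth, cfg, ref, seed = 13)
  o2 <- simulate_pileups(truth, cfg, ref, seed = 13)
  expect_identical(o1, o2)
  o3 <- simulate_pileups(truth, cfg, ref, seed = 14)
  expect_false(identical(o1, o3))
})

test_that("rpb distribution has the configured mean and a floor of one", {
  cfg <- sim_config(region_length = 50L, mean_barcode_depth = 400,
                    rpb_mean = 8.5)
  ref <- simulate_reference(cfg, seed = 15)
  obs <- simulate_pileups(simulate_truth(cfg, ref, 0), cfg, ref,
                          positions = 1:50, seed = 16)
  sizes <- obs[, .N, by = .(pos, barcode)]$N
  expect_gte(min(sizes), 1L)
  expect_lt(abs(mean(sizes) - 8.5), 0.1)
})

test_that("barcode downsampling thins whole families binomially", {
  cfg <- sim_config(region_length = 20L, mean_barcode_depth = 500)
  ref <- simulate_reference(cfg, seed = 17)
  obs <- simulate_pileups(simulate_truth(cfg, ref, 0), cfg, ref,
                          positions = 1:20, seed = 18)
  expect_identical(downsample_barcodes(obs, 1, seed = 19), obs)
  half <- downsample_barcodes(obs, 0.5, seed = 19)
  n0 <- nrow(unique(obs[, .(pos, barcode)]))
  n1 <- nrow(unique(half[, .(pos, barcode)]))
  expect_lt(abs(n1 - 0.5 * n0), 3 * sqrt(n0 * 0.25))
  # families survive intact
  s0 <- obs[, .N, by = .(pos, barcode)]
  s1 <- half[, .N, by = .(pos, barcode)]
  merged <- s1[s0, on = c("pos", "barcode"), nomatch = NULL]
  expect_true(all(merged$N == merged$i.N))
  expect_identical(downsample_barcodes(obs, 0.5, seed = 19), half)
})

test_that("rpb downsampling hits the target mean with a floor of one read", {
  cfg <- sim_config(region_length = 30L, mean_barcode_depth = 400,
                    rpb_mean = 8.5)
  ref <- simulate_reference(cfg, seed = 20)
  obs <- simulate_pileups(simulate_truth(cfg, ref, 0), cfg, ref,
                          positions = 1:30, seed = 21)
  for (target in c(4, 1.5, 1.1)) {
    ds <- downsample_rpb(obs, target, seed = 22)
    sizes <- ds[, .N, by = .(pos, barcode)]
    expect_gte(min(sizes$N), 1L)
    expect_lt(abs(mean(sizes$N) - target) / target, 0.05)
    # no family lost entirely
    expect_equal(nrow(sizes), nrow(unique(obs[, .(pos, barcode)])))
  }
  expect_error(downsample_rpb(obs, 20), "exceeds")
  near_one <- downsample_rpb(obs, 1.1, seed = 23)
  sizes <- near_one[, .N, by = .(pos, barcode)]$N
  expect_gt(mean(sizes == 1L), 0.85)
})

test_that("call evaluation counts TP/FP/FN and converts to per-megabase rates", {
  truth <- data.table(contig = "sim1", pos = c(100L, 200L),
                      ref = c("A", "C"), allele = c("T", "G"),
                      af = c(0.01, 0.01))
  calls <- data.table(contig = "sim1", pos = c(100L, 300L),
                      ref = c("A", "G"), allele = c("T", "A"),
                      qual = c(30, 20), filter = c("PASS", "PASS"))
  m <- evaluate_calls(calls, truth, target_size = 1e6, thresholds = c(14, 25))
  expect_equal(m$tp, c(1L, 1L))
  expect_equal(m$fp, c(1L, 0L))
  expect_equal(m$fn, c(1L, 1L))
  expect_equal(m$sensitivity, c(0.5, 0.5))
  expect_equal(m$fp_per_mb, c(1, 0))
  expect_equal(m$ppv, c(0.5, 1))
  # calls identical to truth: perfect metrics
  perfect <- data.table(contig = "sim1", pos = truth$pos, ref = truth$ref,
                        allele = truth$allele, qual = 99, filter = "PASS")
  mp <- evaluate_calls(perfect, truth, 1e6, thresholds = 14)
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$fp_per_mb, 0)
  # empty calls
  me <- evaluate_calls(perfect[0L], truth, 1e6, thresholds = 14)
  expect_equal(me$sensitivity, 0)
  expect_equal(me$fp_per_mb, 0)
  expect_error(evaluate_calls(calls, truth, 0), "positive")
})

test_that("the background scan agrees with the full pipeline at small scale", {
  # constant rpb keeps the per-locus index distribution light-tailed (no
  # singleton families), so the mean total non-reference index is a sharp
  # statistic; first-cycle events are too rare at this scale for a stable
  # mean and their weight path is exercised through the same engine
  cfg <- sim_config(region_length = 2000L, mean_barcode_depth = 60,
                    rpb_mean = 6, rpb_dist = "constant", phred_q = 30L,
                    first_cycle_error_rate = 0)
  ref <- simulate_reference(cfg, seed = 30)
  obs <- simulate_pileups(simulate_truth(cfg, ref, 0), cfg, ref,
                          positions = 1:2000, seed = 31)
  # full pipeline: per-locus total non-reference index
  calls <- call_pileups(obs, threshold = 1e-12)
  full_sum <- calls[, .(s = sum(qual)), by = pos]$s
  sc <- scan_background(2000, cfg, threshold = 1e9, seed = 32,
                        return_indices = TRUE)
  expect_lt(abs(mean(sc$sum_index) - mean(full_sum)) / mean(full_sum), 0.1)
  expect_equal(length(sc$max_index), 2000L)
  expect_true(all(sc$max_index <= sc$sum_index + 1e-12))
})

test_that("pileup table round trips through the simulator output", {
  cfg <- sim_config(region_length = 100L, mean_barcode_depth = 30)
  ref <- simulate_reference(cfg, seed = 40)
  truth <- simulate_truth(cfg, ref, 1, fractions = 0.3, seed = 41)
  obs <- simulate_pileups(truth, cfg, ref, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup_table(obs, path)
  expect_equal(as.data.frame(read_pileup_table(path)), as.data.frame(obs))
})
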