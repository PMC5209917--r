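test_that("barcodes are extracted from tags or read-name suffixes", {
  cfg_tag <- barcode_config()
  expect_equal(extract_barcode("r1", list(MI = "ttttaaaa"), cfg_tag),
               "TTTTAAAA")
  # BX fallback when MI is absent
  expect_equal(extract_barcode("r1", list(MI = NA_character_, BX = "acgt"),
                               cfg_tag), "ACGT")
  expect_true(is.na(extract_barcode("r1", list(), cfg_tag)))

  cfg_name <- barcode_config(mode = "read_name", delimiter = ":")
  expect_equal(extract_barcode("R1:ACGTACGT", config = cfg_name), "ACGTACGT")
  expect_true(is.na(extract_barcode("R1", config = cfg_name)))
})

ref60 <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")  # ACGTACGT...

test_that("pileups from a SAM fixture have the expected family structure", {
  dir <- withr::local_tempdir()
  # 2 barcodes x 3 reads over positions 11..20 (all matching the reference)
  seg <- substr(ref60, 11, 20)
  reads <- c(
    vapply(1:3, function(i) sam_read(sprintf("a%d", i), 11L, seg,
                                     barcode = "AAAACCCC"), character(1)),
    vapply(1:3, function(i) sam_read(sprintf("b%d", i), 11L, seg,
                                     barcode = "GGGGTTTT"), character(1)))
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  pl <- locus_pileup(obs[pos == 15L])
  expect_equal(pl$barcode_depth, 2L)
  expect_equal(pl$read_depth, 6L)
  expect_equal(pl$rpb, 3.0)
  expect_equal(pl$ref, substr(ref60, 15, 15))
  expect_true(all(obs$allele == obs$ref))  # perfect reads
})

test_that("reads below the mapping-quality floor are absent from families", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  reads <- c(sam_read("a1", 11L, seg, barcode = "AAAACCCC"),
             sam_read("a2", 11L, seg, barcode = "AAAACCCC", mapq = 5L))
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  expect_equal(unique(obs$pair_id), "a1")
})

test_that("low base qualities drop observations but keep the read", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  # base 5 has quality '#' (Q2), the rest 'I' (Q40)
  qualmix <- sam_read("a1", 11L, seg, barcode = "AAAACCCC")
  qualmix <- sub(strrep("I", 10), paste0("IIII#IIIII"), qualmix)
  fx <- write_sam_fixture(dir, qualmix, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  expect_false(15L %in% obs$pos)
  expect_true(all(c(11:14, 16:20) %in% obs$pos))
})

test_that("insertions and deletions are anchored at the preceding base", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  with_ins <- paste0(substr(seg, 1, 5), "TT", substr(seg, 6, 10))
  reads <- c(sam_read("i1", 11L, with_ins, cigar = "5M2I5M",
                      barcode = "AAAACCCC"),
             sam_read("d1", 11L, paste0(substr(seg, 1, 5), substr(seg, 8, 10)),
                      cigar = "5M2D3M", barcode = "GGGGTTTT"))
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  ins <- obs[barcode == "AAAACCCC" & pos == 15L]
  expect_equal(ins$allele, "+TT")
  del <- obs[barcode == "GGGGTTTT" & pos == 15L]
  expect_equal(del$allele, paste0("-", substr(ref60, 16, 17)))
  # deleted positions carry no base observation from that read
  expect_false(any(obs$barcode == "GGGGTTTT" & obs$pos %in% 16:17))
})

test_that("disagreeing mates are discarded and agreeing mates keep one vote", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  mut <- paste0(substr(seg, 1, 4), "A", substr(seg, 6, 10))  # pos 15 -> A
  reads <- c(sam_read("p1", 11L, seg, barcode = "AAAACCCC"),
             sam_read("p1", 11L, seg, barcode = "AAAACCCC", flag = 16L),
             sam_read("p2", 11L, seg, barcode = "AAAACCCC"),
             sam_read("p2", 11L, mut, barcode = "AAAACCCC", flag = 16L))
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  at15 <- obs[pos == 15L]
  expect_equal(nrow(at15), 1L)       # p2 dropped (disagreement), p1 one vote
  expect_equal(at15$pair_id, "p1")
})

test_that("barcode-less reads are excluded and counted", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  no_bc <- paste(c("n1", 0L, "ctg1", 11L, 60L, "10M", "*", 0, 0, seg,
                   strrep("I", 10)), collapse = "\t")
  reads <- c(sam_read("a1", 11L, seg, barcode = "AAAACCCC"), no_bc)
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  expect_equal(attr(obs, "n_no_barcode"), 1L)
  expect_equal(unique(obs$pair_id), "a1")
})

test_that("a contig missing from the alignment header is a hard error", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  fx <- write_sam_fixture(dir, sam_read("a1", 11L, seg), ref60)
  bad_bed <- file.path(dir, "bad.bed")
  writeLines("other_ctg\t0\t60", bad_bed)
  expect_error(build_pileups(fx$sam, bad_bed, fx$fasta), "other_ctg")
})

test_that("an empty BED yields an empty stream", {
  dir <- withr::local_tempdir()
  fx <- write_sam_fixture(dir, sam_read("a1", 11L, substr(ref60, 11, 20)),
                          ref60)
  empty_bed <- file.path(dir, "empty.bed")
  file.create(empty_bed)
  obs <- build_pileups(fx$sam, empty_bed, fx$fasta)
  expect_equal(nrow(obs), 0L)
})

test_that("near-miss barcodes in a region are folded into the dominant one", {
  dir <- withr::local_tempdir()
  seg <- substr(ref60, 11, 20)
  reads <- c(vapply(1:10, function(i) sam_read(sprintf("a%d", i), 11L, seg,
                                               barcode = "AAAACCCC"),
                    character(1)),
             sam_read("e1", 11L, seg, barcode = "AAAACCCG"))
  fx <- write_sam_fixture(dir, reads, ref60)
  obs <- build_pileups(fx$sam, fx$bed, fx$fasta)
  expect_equal(unique(obs$barcode), "AAAACCCC")
  obs_raw <- build_pileups(fx$sam, fx$bed, fx$fasta, cluster = FALSE)
  expect_setequal(unique(obs_raw$barcode), c("AAAACCCC", "AAAACCCG"))
})
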