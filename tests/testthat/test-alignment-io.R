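# Alignment loading, filtering, and (V,S,L) pileup construction.

test_that("alignment filters drop supplementary/secondary/unmapped and low MAPQ", {
  aln <- dplyr::bind_rows(
    aln_rec(10, "10M", strrep("A", 10), flag = 2048L, mapq = 60L, id = "supp"),
    aln_rec(10, "10M", strrep("A", 10), flag = 256L, mapq = 60L, id = "sec"),
    aln_rec(10, "10M", strrep("A", 10), flag = 4L, mapq = 60L, id = "unmapped"),
    aln_rec(10, "10M", strrep("A", 10), flag = 8L, mapq = 60L, id = "mate"),
    aln_rec(10, "10M", strrep("A", 10), flag = 0L, mapq = 9L, id = "lowq"),
    aln_rec(10, "10M", strrep("A", 10), flag = 0L, mapq = 10L, id = "boundary"),
    aln_rec(10, "10M", strrep("A", 10), flag = 99L, mapq = 60L, id = "good")
  )
  kept <- filter_alignments(aln, mapq_min = 10)
  expect_setequal(kept$read_id, c("boundary", "good"))
})

test_that("BAM round trip preserves records and honours block fetch", {
  ref <- tiny_ref(2000)
  aln <- dplyr::bind_rows(
    aln_rec(100, "50M", substring(ref, 101, 150), flag = 99L, id = "a"),
    aln_rec(900, "50M", substring(ref, 901, 950), flag = 99L, id = "b"),
    aln_rec(1500, "50M", substring(ref, 1501, 1550), flag = 99L, id = "c")
  )
  bam <- file.path(withr::local_tempdir(), "t.bam")
  write_bam(aln, ref, bam)
  all_recs <- read_alignments(bam)
  expect_equal(all_recs$read_id, c("a", "b", "c"))
  expect_equal(all_recs$start, c(100L, 900L, 1500L))
  expect_equal(all_recs$seq, aln$seq)
  blk <- read_alignments(bam, list(chrom = "chr1", start = 800, end = 1000))
  expect_equal(blk$read_id, "b")
  expect_warning(
    none <- read_alignments(bam, list(chrom = "chrX", start = 0, end = 10)),
    "not in BAM"
  )
  expect_equal(nrow(none), 0L)
  expect_error(read_alignments(file.path(tempdir(), "nope.bam")), "not found")
})

test_that("pileup counts bases, insertions and deletions per the CIGAR walk", {
  ref <- setNames(paste0("AAAAA", "C", "AAAAA"), "chr1") # pos 6 is C
  aln <- dplyr::bind_rows(
    lapply(1:8, function(i) aln_rec(0, "11M", "AAAAACAAAAA", id = paste0("c", i))),
    lapply(1:2, function(i) aln_rec(0, "11M", "AAAAATAAAAA", id = paste0("t", i)))
  )
  pl <- build_pileup(aln, list(chrom = "chr1", start = 0, end = 11), ref)
  at6 <- pl[pl$pos == 6, ]
  expect_equal(at6$C, 8L)
  expect_equal(at6$T, 2L)
  expect_equal(at6$total, 10L)
  expect_equal(at6$S, 2L * 40L) # two Q40 mismatches

  # two reads inserting AC after pos 6 land in V["I"] and L["I"]
  aln2 <- dplyr::bind_rows(
    aln_rec(0, "6M2I5M", "AAAAACACAAAAA", id = "i1"),
    aln_rec(0, "6M2I5M", "AAAAACACAAAAA", id = "i2"),
    aln_rec(0, "11M", "AAAAACAAAAA", id = "m1")
  )
  pl2 <- build_pileup(aln2, list(chrom = "chr1", start = 0, end = 11), ref)
  at6 <- pl2[pl2$pos == 6, ]
  expect_equal(at6$I, 2L)
  expect_equal(at6$ins_seqs[[1]], c("AC", "AC"))
  # indel reads count toward I instead of the anchor base
  expect_equal(at6$C, 1L)
  expect_equal(at6$total, 3L)

  # a deletion anchors at the base before, records the deleted sequence,
  # and deleted positions keep their spanning depth
  aln3 <- aln_rec(0, "6M3D2M", "AAAAACAA", id = "d1")
  pl3 <- build_pileup(aln3, list(chrom = "chr1", start = 0, end = 11), ref)
  expect_equal(pl3$D[pl3$pos == 6], 1L)
  expect_equal(pl3$del_seqs[[which(pl3$pos == 6)]], "AAA")
  expect_equal(pl3$depth[pl3$pos == 8], 1L)
  expect_equal(pl3$total[pl3$pos == 8], 0L)
})

test_that("reads matching the reference everywhere give S = 0", {
  ref <- tiny_ref(500)
  aln <- tile_reads(ref[[1]], read_len = 80, step = 7)
  pl <- build_pileup(aln, list(chrom = "chr1", start = 0, end = 500), ref)
  expect_true(all(pl$S == 0))
  # and every observation is the reference base
  ref_count <- diag(as.matrix(pl[, pl$ref_base])[, seq_len(nrow(pl))])
  expect_equal(unname(ref_count), pl$total)
})

test_that("malformed CIGAR/sequence records are skipped with a warning", {
  ref <- tiny_ref(100)
  aln <- dplyr::bind_rows(
    aln_rec(0, "20M", substring(ref, 1, 10), id = "bad"), # length mismatch
    aln_rec(0, "10M", substring(ref, 1, 10), id = "good")
  )
  expect_warning(
    pl <- build_pileup(aln, list(chrom = "chr1", start = 0, end = 100), ref),
    "skipped"
  )
  expect_equal(max(pl$depth), 1L)
})

test_that("adjacent block pileups concatenate to the merged block pileup", {
  ref <- tiny_ref(600, seed = 9)
  withr::with_seed(11, {
    starts <- sample(0:500, 60, replace = TRUE)
  })
  aln <- dplyr::bind_rows(lapply(seq_along(starts), function(i) {
    s <- starts[i]
    aln_rec(s, "80M", substring(ref, s + 1, s + 80), id = paste0("r", i))
  }))
  whole <- build_pileup(aln, list(chrom = "chr1", start = 0, end = 600), ref)
  left <- build_pileup(aln, list(chrom = "chr1", start = 0, end = 300), ref)
  right <- build_pileup(aln, list(chrom = "chr1", start = 300, end = 600), ref)
  both <- dplyr::bind_rows(left, right)
  expect_equal(both$pos, whole$pos)
  expect_equal(both$total, whole$total)
  expect_equal(both$depth, whole$depth)
  expect_equal(as.matrix(both[, c("A", "C", "G", "T", "N", "I", "D")]),
               as.matrix(whole[, c("A", "C", "G", "T", "N", "I", "D")]))
})
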