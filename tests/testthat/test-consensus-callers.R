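# POA consensus, de Bruijn assembly, realignment and region genotyping.

seg_tbl <- function(seqs, qual_char = "I") {
  tibble::tibble(
    read_id = paste0("s", seq_along(seqs)), seq = seqs,
    qual = strrep(qual_char, nchar(seqs)),
    overlap = 1, spans = TRUE
  )
}

test_that("LC sites merge by distance and regions get flanks and clamping", {
  chrom_lengths <- c(chr1 = 10000L)
  sites <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = 100L, del_seqs = list(NULL)),
    tibble::tibble(chrom = "chr1", pos = 105L, del_seqs = list(NULL)),
    tibble::tibble(chrom = "chr1", pos = 150L, del_seqs = list(NULL))
  )
  reg <- merge_lc_sites(sites, t_lc = 10, flank_f = 25, chrom_lengths)
  expect_equal(nrow(reg), 2L) # 100+105 merged (gap 5 < 10), 150 alone
  expect_equal(reg$start[1], 100L - 1L - 25L)
  expect_equal(reg$end[1], 105L + 25L)
  expect_equal(reg$member_pos[[1]], c(100L, 105L))

  low <- merge_lc_sites(
    tibble::tibble(chrom = "chr1", pos = 3L, del_seqs = list(NULL)),
    chrom_lengths = chrom_lengths
  )
  expect_equal(low$start, 0L) # clamped at the chromosome start
})

test_that("segment extraction clips to the region and applies the overlap rule", {
  ref <- tiny_ref(400)
  region <- list(chrom = "chr1", start = 100L, end = 200L)
  aln <- dplyr::bind_rows(
    aln_rec(80, "150M", substring(ref, 81, 230), id = "spanning"),
    aln_rec(160, "150M", substring(ref, 161, 310), id = "cover40"),
    aln_rec(150, "150M", substring(ref, 151, 300), id = "cover50")
  )
  segs <- extract_segments(aln, region, min_overlap = 0.5)
  expect_setequal(segs$read_id, c("spanning", "cover50"))
  sp <- segs[segs$read_id == "spanning", ]
  expect_equal(nchar(sp$seq), 100L)
  expect_equal(sp$seq, substring(ref[[1]], 101, 200))
  expect_true(sp$spans)
  expect_equal(segs$overlap[segs$read_id == "cover50"], 0.5)
})

test_that("POA consensus reproduces one or two generating haplotypes", {
  withr::with_seed(606, {
    a <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  })
  # identical segments: the consensus is the segment
  one <- poa_consensus(seg_tbl(rep(a, 10)))
  expect_equal(one$sequence, a)
  expect_equal(one$support, 10L)

  # balanced mix of two haplotypes differing by an insertion: both recovered
  b <- paste0(substring(a, 1, 40), "TTCGA", substring(a, 41, 80))
  two <- poa_consensus(seg_tbl(c(rep(a, 5), rep(b, 5))))
  expect_setequal(two$sequence, c(a, b))
  expect_equal(sort(two$support), c(5L, 5L))

  # two segments differing by one base: every consensus is one of the inputs
  c2 <- a
  substr(c2, 11, 11) <- setdiff(c("A", "C", "G", "T"), substring(a, 11, 11))[1]
  few <- poa_consensus(seg_tbl(c(a, c2)), min_support = 1)
  expect_true(all(few$sequence %in% c(a, c2)))
})

test_that("POA recovers both haplotypes for anti-phased heterozygous SNVs", {
  withr::with_seed(607, {
    base <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  })
  h1 <- base
  substr(h1, 20, 20) <- "A"; substr(h1, 60, 60) <- "C"
  h2 <- base
  substr(h2, 20, 20) <- "G"; substr(h2, 60, 60) <- "T"
  res <- poa_consensus(seg_tbl(c(rep(h1, 8), rep(h2, 8))))
  expect_setequal(res$sequence, c(h1, h2))
})

test_that("de Bruijn graphs report cycles and unbranched paths faithfully", {
  # a tandem repeat with 6 bp unit forces a cycle at k = 11
  rep_seq <- strrep("ACGTAC", 10)
  g <- build_debruijn(rep_seq, k = 11)
  expect_true(g$cyclic)

  # error-free tiled reads from a non-repetitive window: one unbranched path
  ref <- tiny_ref(300, seed = 70)
  reads <- tile_reads(ref[[1]], read_len = 100, step = 4)$seq
  g2 <- build_debruijn(reads, k = 41, min_cov = 1)
  expect_false(g2$cyclic)
  expect_equal(nrow(g2$contigs), 1L)
  expect_equal(g2$contigs$sequence, ref[[1]])

  # two haplotypes differing by one SNV: one bubble, two parallel paths
  alt <- ref[[1]]
  substr(alt, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                   substring(alt, 150, 150))[1]
  g3 <- build_debruijn(c(reads, tile_reads(alt, read_len = 100, step = 4)$seq),
                       k = 41, min_cov = 1)
  expect_false(g3$cyclic)
  expect_setequal(g3$contigs$sequence, c(ref[[1]], alt))
})

test_that("window assembly reconstructs donor haplotypes exactly", {
  # reads tile a 500 bp donor; the 300 bp window sits in the middle so its
  # edges have full read support (as in the pipeline)
  donor <- tiny_ref(500, seed = 71)[[1]]
  window <- substring(donor, 101, 400)
  reads <- tile_reads(donor, read_len = 100, step = 2)$seq # ~50x
  h <- assemble_window(reads, window_len = 300)
  expect_equal(nrow(h), 1L)
  expect_true(grepl(window, h$sequence, fixed = TRUE))

  # heterozygous 10 bp deletion: one contig with and one without it
  del_hap <- paste0(substring(donor, 1, 240), substring(donor, 251, 500))
  del_window <- substring(del_hap, 101, 390)
  mix <- c(tile_reads(donor, 100, 2)$seq, tile_reads(del_hap, 100, 2)$seq)
  h2 <- assemble_window(mix, window_len = 300)
  expect_equal(nrow(h2), 2L)
  expect_true(any(grepl(window, h2$sequence, fixed = TRUE)))
  expect_true(any(grepl(del_window, h2$sequence, fixed = TRUE)))

  # a 100 bp unit duplicated in tandem stays cyclic for every k <= 75
  dup <- paste0(substring(donor, 1, 150), strrep(substring(donor, 151, 250), 3),
                substring(donor, 251, 400))
  h3 <- assemble_window(tile_reads(dup, 100, 2)$seq, window_len = 300)
  expect_equal(nrow(h3), 0L)
  expect_equal(attr(h3, "reason"), "cyclic_at_all_k")
})

test_that("realignment emits variants only where haplotype and reference differ", {
  scoring <- align_scoring()
  ref_seg <- tiny_ref(120, seed = 72)[[1]]
  none <- realign_and_call(tibble::tibble(sequence = ref_seg, support = 10L),
                           ref_seg, 1000L, "chr1", scoring)
  expect_equal(nrow(none), 0L)

  snv_hap <- ref_seg
  substr(snv_hap, 61, 61) <- setdiff(c("A", "C", "G", "T"),
                                     substring(ref_seg, 61, 61))[1]
  v <- realign_and_call(tibble::tibble(sequence = snv_hap, support = 10L),
                        ref_seg, 1000L, "chr1", scoring)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 1061L)
  expect_equal(v$kind, "SNV")
  expect_equal(v$alt, substring(snv_hap, 61, 61))
})

test_that("indels are left-normalised to the shift oracle's canonical form", {
  # "ACGTTTTACG" minus one T: canonical anchor is the G before the T run
  chrom_seq <- paste0(strrep("C", 50), "ACGTTTTACG", strrep("A", 50))
  scoring <- align_scoring()
  hap <- paste0(strrep("C", 50), "ACGTTTACG", strrep("A", 50))
  v <- realign_and_call(tibble::tibble(sequence = hap, support = 5L),
                        chrom_seq, 0L, "chr1", scoring, chrom_seq = chrom_seq)
  expect_equal(nrow(v), 1L)
  oracle <- shift_oracle(pos = 56, ref = "TT", alt = "T", chrom_seq)
  expect_equal(v$pos, oracle$pos)
  expect_equal(v$ref, oracle$ref)
  expect_equal(v$alt, oracle$alt)

  # random homopolymer/indel cases agree with the iterative-shift oracle
  withr::with_seed(808, {
    for (i in 1:25) {
      cs <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
      p <- sample(50:150, 1)
      len <- sample(1:6, 1)
      if (runif(1) < 0.5) {
        raw <- list(pos = p, ref = substring(cs, p, p + len),
                    alt = substring(cs, p, p))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        raw <- list(pos = p, ref = substring(cs, p, p),
                    alt = paste0(substring(cs, p, p), ins))
      }
      got <- left_normalize(
        tibble::tibble(chrom = "chr1", pos = raw$pos, ref = raw$ref,
                       alt = raw$alt),
        chrom_seq = cs
      )
      want <- shift_oracle(raw$pos, raw$ref, raw$alt, cs)
      expect_equal(got$pos, want$pos)
      expect_equal(got$ref, want$ref)
      expect_equal(got$alt, want$alt)
    }
  })
})

test_that("region genotyping resolves hom, het, and quality-free inputs", {
  ref <- tiny_ref(400, seed = 73)
  chrom_seq <- ref[[1]]
  p <- 200L
  alt_base <- setdiff(c("A", "C", "G", "T"), substring(chrom_seq, p, p))[1]
  alt_seq <- chrom_seq
  substr(alt_seq, p, p) <- alt_base
  variants <- tibble::tibble(chrom = "chr1", pos = p,
                             ref = substring(chrom_seq, p, p),
                             alt = alt_base, kind = "SNV")
  hom_aln <- tile_reads(alt_seq, read_len = 120, step = 6)
  het_aln <- dplyr::bind_rows(tile_reads(alt_seq, 120, 12),
                              tile_reads(chrom_seq, 120, 12))
  het_aln$read_id <- paste0(het_aln$read_id, seq_len(nrow(het_aln)))

  hom <- genotype_region(variants, hom_aln, ref)
  expect_equal(hom$genotype, "1/1")
  expect_equal(hom$ad_ref, 0L)

  het <- genotype_region(variants, het_aln, ref)
  expect_equal(het$genotype, "0/1")
  expect_gt(het$ad_ref, 0L)
  expect_gt(het$ad_alt, 0L)

  # without quality strings the binomial count model takes over
  noq <- het_aln
  noq$qual <- ""
  binom <- genotype_region(variants, noq, ref)
  expect_equal(binom$genotype, "0/1")
  direct <- binomial_likelihoods(binom$ad_ref, binom$ad_alt)
  expect_equal(binom$qual, direct$qual)
})
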