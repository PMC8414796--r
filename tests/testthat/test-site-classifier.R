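# Three-way HC / LC / TRC triage.

cand_site <- function(pos, freq, multi = FALSE, top_alt = "T", chrom = "chr1",
                      ins = NULL, del = NULL) {
  n_alt <- round(40 * freq)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref_base = "A",
    ref_count = 40L - n_alt, total = 40L, depth = 40L, S = 1200L,
    bq_ave = 30, is_multiallele = multi,
    alt_allele = list(top_alt), alt_count = list(n_alt),
    alt_freq = list(freq), top_alt = top_alt, top_count = n_alt,
    top_freq = freq, ins_seqs = list(ins), del_seqs = list(del)
  )
}

test_that("BED annotations are unioned and merged per chromosome", {
  dir <- withr::local_tempdir()
  b1 <- file.path(dir, "a.bed")
  b2 <- file.path(dir, "b.bed")
  writeLines(c("chr1\t10\t20", "chr2\t5\t9"), b1)
  writeLines("chr1\t15\t30", b2)
  ann <- load_annotation(c(b1, b2))
  d <- as.data.frame(ann)
  expect_equal(nrow(d), 2L)
  expect_equal(d$start[d$seqnames == "chr1"], 11) # 1-based merged [10,30)
  expect_equal(d$end[d$seqnames == "chr1"], 30)

  empty <- file.path(dir, "empty.bed")
  writeLines(character(0), empty)
  expect_equal(length(load_annotation(empty)), 0L)

  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t1\t2", "chr1\tnot-a-number\t5"), bad)
  expect_error(load_annotation(bad), "malformed BED line 2")
})

test_that("HC requires majority frequency, isolation, single allele", {
  sites <- dplyr::bind_rows(
    cand_site(1000, 0.6),            # isolated, > 0.5: HC
    cand_site(2000, 0.8),            # has neighbour 40 bp away: LC
    cand_site(2040, 0.9),            # the neighbour: LC
    cand_site(3000, 0.5),            # exactly 0.5 is not a majority: LC
    cand_site(4000, 0.45),           # minority: LC
    cand_site(5000, 0.7, multi = TRUE) # multi-allele: LC
  )
  cl <- classify_sites(sites, annotation = NULL, flank = 100)
  expect_equal(cl$category,
               c("HC", "LC", "LC", "LC", "LC", "LC"))
})

test_that("sites inside annotated repeats are TRC regardless of frequency", {
  sites <- dplyr::bind_rows(
    cand_site(150, 0.9),
    cand_site(155, 0.9), # neighbours inside the repeat: still TRC
    cand_site(900, 0.9)
  )
  ann <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  cl <- classify_sites(sites, ann)
  expect_equal(cl$category, c("TRC", "TRC", "HC"))
})

test_that("divergent indel support demotes an otherwise-HC indel to LC", {
  consistent <- cand_site(1000, 0.6, top_alt = "I",
                          ins = c("AC", "AC", "AC", "AC", "AC", "AG"))
  divergent <- cand_site(5000, 0.6, top_alt = "I",
                         ins = c("AC", "AG", "A", "ACG", "AC", "AG"))
  cl <- classify_sites(dplyr::bind_rows(consistent, divergent))
  expect_equal(cl$category, c("HC", "LC"))
})

test_that("classification partitions candidates and proximity is symmetric", {
  withr::with_seed(202, {
    pos <- sort(sample(1:50000, 120))
  })
  sites <- dplyr::bind_rows(lapply(pos, function(p) {
    cand_site(p, freq = sample(c(0.4, 0.6, 0.9), 1))
  }))
  ann <- tibble::tibble(chrom = "chr1", start = 20000L, end = 25000L)
  cl <- classify_sites(sites, ann)
  expect_equal(nrow(cl), length(pos))
  expect_true(all(cl$category %in% c("HC", "LC", "TRC")))
  # symmetry: if A is within flank of B then both carry has_neighbor
  d <- outer(cl$pos, cl$pos, function(a, b) abs(a - b))
  diag(d) <- Inf
  expect_equal(cl$has_neighbor, apply(d <= 100, 1, any))
  # unsorted input is rejected
  expect_error(classify_sites(cl[rev(seq_len(nrow(cl))), ]), "sorted")
})

test_that("with no annotation and isolated majority sites, all are HC", {
  sites <- dplyr::bind_rows(lapply(seq(1000, 9000, by = 1000), function(p) {
    cand_site(p, 0.85)
  }))
  cl <- classify_sites(sites)
  expect_true(all(cl$category == "HC"))
})
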