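# Task splitting, integration/dedup, VCF output, and pipeline invariants.

test_that("task splitting covers every chromosome without spanning", {
  ridx <- tibble::tibble(chrom = c("chr1", "chr2"),
                         length = c(45000000L, 3000000L))
  blocks <- split_tasks(ridx, block_size = 2e7)
  b1 <- blocks[blocks$chrom == "chr1", ]
  expect_equal(nrow(b1), 3L)
  expect_equal(b1$end - b1$start, c(2e7, 2e7, 5e6))
  expect_equal(b1$start[1], 0L)
  b2 <- blocks[blocks$chrom == "chr2", ]
  expect_equal(nrow(b2), 1L) # shorter than one block
  expect_equal(b2$end, 3000000L)
  # exhaustive, non-overlapping cover
  expect_true(all(b1$start[-1] == b1$end[-3]))
})

test_that("integration dedups by quality with HC preference and tags LowQual", {
  ridx <- tibble::tibble(chrom = "chr1", length = 1000L)
  base <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 100L, 200L, 300L, 300L, 400L),
    ref = "A", alt = "T", kind = "SNV", genotype = "0/1",
    qual = c(50, 40, 60, 33, 33, 10),
    dp = 40L, ad_ref = 20L, ad_alt = 20L,
    source = c("HC", "LC", "HC", "LC", "HC", "HC")
  )
  out <- integrate_calls(base, ridx, lowqual = 15)
  expect_equal(nrow(out), 4L)
  expect_equal(out$qual[out$pos == 100], 50) # higher quality wins
  expect_equal(out$source[out$pos == 300], "HC") # tie prefers HC
  expect_equal(out$filter, c("PASS", "PASS", "PASS", "LowQual"))
  # repeated integration is idempotent and deterministic
  expect_identical(integrate_calls(out, ridx), integrate_calls(out, ridx))
})

test_that("VCF output is well-formed and round-trips through a standard parser", {
  dir <- withr::local_tempdir()
  ridx <- tibble::tibble(chrom = "chr1", length = 5000L)

  empty <- integrate_calls(shortcall:::empty_calls(), ridx)
  p0 <- file.path(dir, "empty.vcf")
  write_vcf(empty, ridx, "S1", p0)
  v0 <- VariantAnnotation::readVcf(p0)
  expect_equal(nrow(v0), 0L)

  calls <- tibble::tibble(
    chrom = "chr1", pos = c(150L, 900L), ref = c("A", "C"),
    alt = c("G", "CTT"), kind = c("SNV", "INS"),
    genotype = c("0/1", "1/1"), qual = c(57.2, 60),
    dp = c(38L, 41L), ad_ref = c(19L, 0L), ad_alt = c(19L, 41L),
    source = c("HC", "LC")
  )
  out <- integrate_calls(calls, ridx)
  p1 <- file.path(dir, "calls.vcf")
  write_vcf(out, ridx, "S1", p1)
  v1 <- VariantAnnotation::readVcf(p1)
  expect_equal(nrow(v1), 2L)
  expect_equal(as.vector(BiocGenerics::start(v1)), c(150L, 900L))
  expect_equal(as.character(VariantAnnotation::ref(v1)), c("A", "C"))
  gt <- VariantAnnotation::geno(v1)$GT
  expect_equal(unname(gt[, "S1"]), c("0/1", "1/1"))
  # insertion is padded per VCF: REF is the anchor base
  alt1 <- as.character(unlist(VariantAnnotation::alt(v1)))
  expect_equal(alt1, c("G", "CTT"))
})

sim_small <- function() {
  simulate_dataset(length = 60000, seed = 33, n_repeats = 1,
                   coverage_per_hap = 15)
}

test_that("block with no reads yields no calls; one hom SNV yields one 1/1 call", {
  ref <- tiny_ref(4000, seed = 80)
  cfg <- shortcall_config(block_size = 4000)
  none <- run_block(list(chrom = "chr1", start = 0L, end = 4000L),
                    list(alignments = empty_aln <- shortcall:::empty_alignments(),
                         ref = ref), cfg)
  expect_equal(nrow(none), 0L)

  alt_seq <- ref[[1]]
  substr(alt_seq, 2000, 2000) <- setdiff(c("A", "C", "G", "T"),
                                         substring(ref, 2000, 2000))[1]
  aln <- tile_reads(alt_seq, read_len = 100, step = 5) # ~20x hom alt
  calls <- run_block(list(chrom = "chr1", start = 0L, end = 4000L),
                     list(alignments = aln, ref = ref), cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 2000L)
  expect_equal(calls$genotype, "1/1")
  expect_equal(calls$source, "HC")
})

test_that("final calls are invariant to block size and worker count", {
  sim <- sim_small()
  run <- function(block_size, workers = 1) {
    call_variants(ref = sim$ref, alignments = sim$alignments,
                  annotation = sim$repeats,
                  config = shortcall_config(block_size = block_size),
                  workers = workers)
  }
  whole <- run(60000)
  split10 <- run(10000)
  expect_equal(tidy(split10), tidy(whole))
  par2 <- run(10000, workers = 2)
  expect_equal(tidy(par2), tidy(whole))
  # no duplicate records in the final set
  key <- paste(whole$chrom, whole$pos, whole$ref, whole$alt)
  expect_equal(anyDuplicated(key), 0L)
})
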