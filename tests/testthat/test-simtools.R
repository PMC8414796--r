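# Diploid simulator, exact read placement, and the evaluator.

test_that("simulation is deterministic and respects its stated rates", {
  a <- simulate_dataset(length = 50000, seed = 12, n_repeats = 1,
                        coverage_per_hap = 5)
  b <- simulate_dataset(length = 50000, seed = 12, n_repeats = 1,
                        coverage_per_hap = 5)
  expect_identical(a$ref, b$ref)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads$seq, b$reads$seq)
  expect_identical(a$alignments, b$alignments)

  big <- spike_variants(tiny_ref(300000, seed = 5), seed = 2)
  n_snv <- sum(big$truth$type == "SNV")
  n_indel <- sum(big$truth$type != "SNV")
  expect_gt(n_snv, 300000 / 900 * 0.7) # Poisson-ish around the density
  expect_lt(n_snv, 300000 / 900 * 1.3)
  expect_gt(n_indel, 300000 / 5800 * 0.4)
  expect_true(all(nchar(big$truth$ref) <= 50 & nchar(big$truth$alt) <= 50))
  expect_true(all(big$truth$genotype %in% c("0|1", "1|0", "1|1")))
})

test_that("error-free reads are exact substrings of their source haplotype", {
  sim <- simulate_dataset(length = 20000, seed = 3, base_error_rate = 0,
                          coverage_per_hap = 4, n_repeats = 0)
  haps <- list(sim$spike$hap1, sim$spike$hap2)
  ok <- vapply(seq_len(nrow(sim$reads)), function(i) {
    r <- sim$reads[i, ]
    substring(haps[[r$hap]], r$hap_start,
              r$hap_start + nchar(r$seq) - 1L) == r$seq
  }, logical(1))
  expect_true(all(ok))
  # read count tracks coverage * length / read length
  expect_equal(nrow(sim$reads), 2 * round(4 * 20000 / (2 * 150)) * 2)
})

test_that("placed alignments carry exact CIGARs for the variants they span", {
  sim <- simulate_dataset(length = 30000, seed = 21, base_error_rate = 0,
                          n_repeats = 0)
  aln <- sim$alignments
  # reads spanning no indel are pure matches
  expect_true(any(aln$cigar == "150M"))
  dels <- sim$truth[sim$truth$type == "DEL", ]
  if (nrow(dels) > 0) {
    d <- dels[1, ]
    dl <- nchar(d$ref) - 1L
    covering <- aln[aln$start + 20 < d$pos & aln$start + 130 > d$pos &
                      grepl("D", aln$cigar), ]
    expect_gt(nrow(covering), 0)
    expect_true(all(grepl(paste0(dl, "D"), covering$cigar)))
  }
  # CIGAR query lengths always equal the sequence length
  qlen <- vapply(aln$cigar, function(cg) {
    m <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(m[m[, 3] %in% c("M", "I", "S", "=", "X"), 2]))
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(qlen, nchar(aln$seq))
})

test_that("pileup of placed error-free reads recovers spiked alleles exactly", {
  sim <- simulate_dataset(length = 30000, seed = 44, base_error_rate = 0,
                          n_repeats = 0)
  pl <- build_pileup(filter_alignments(sim$alignments),
                     list(chrom = "chr1", start = 0, end = 30000), sim$ref)
  hom_snv <- sim$truth[sim$truth$type == "SNV" & sim$truth$genotype == "1|1", ]
  for (i in seq_len(min(5, nrow(hom_snv)))) {
    row <- pl[pl$pos == hom_snv$pos[i], ]
    expect_equal(row[[hom_snv$alt[i]]], row$total)
    expect_gt(row$total, 0)
  }
  # away from variants, every base matches the reference (no candidates)
  near <- unlist(lapply(sim$truth$pos, function(p) (p - 55):(p + 55)))
  clean <- pl[!pl$pos %in% near & pl$total >= 4, ]
  cands <- detect_candidates(clean)
  expect_equal(nrow(cands), 0L)
})

test_that("reads contained in planted repeats receive low mapping quality", {
  sim <- simulate_dataset(length = 20000, seed = 9, n_repeats = 0)
  repeats <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5400L)
  aln <- place_alignments(sim$reads, sim$spike, repeats = repeats, seed = 9)
  ref_end <- aln$start + shortcall:::cigar_ref_width(aln$cigar)
  inside <- aln$start >= 5000 & ref_end <= 5400
  if (any(inside)) expect_true(all(aln$mapq[inside] <= 10))
  expect_true(all(aln$mapq[!inside] == 60L))
})

test_that("evaluation metrics follow their definitions", {
  truth <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L),
    ref = "A", alt = "T", genotype = "0|1"
  )
  calls <- truth[1:9, ]
  calls$genotype <- "0/1"
  calls <- dplyr::bind_rows(
    calls, tibble::tibble(chrom = "chr1", pos = 999L, ref = "A", alt = "T",
                          genotype = "0/1")
  )
  ev <- evaluate_calls(calls, truth)
  snv <- ev[ev$type == "SNV", ]
  expect_equal(snv$tp, 9L)
  expect_equal(snv$fp, 1L)
  expect_equal(snv$fn, 1L)
  expect_equal(snv$precision, 0.9)
  expect_equal(snv$recall, 0.9)
  expect_equal(snv$f1, 0.9)

  perfect <- evaluate_calls(truth |> dplyr::mutate(genotype = "1|0"), truth)
  expect_true(all(perfect$precision[perfect$type != "INDEL"] == 1))
  expect_true(all(perfect$recall[perfect$type != "INDEL"] == 1))

  none <- evaluate_calls(truth[0, ], truth)
  expect_equal(none$precision[none$type == "SNV"], 0)
  expect_equal(none$recall[none$type == "SNV"], 0)

  # genotype-aware mode punishes genotype errors on both sides
  wrong_gt <- truth
  wrong_gt$genotype <- "1/1"
  aware <- evaluate_calls(wrong_gt, truth)
  expect_equal(aware$tp[aware$type == "SNV"], 0L)
  blind <- evaluate_calls(wrong_gt, truth, genotype_aware = FALSE)
  expect_equal(blind$tp[blind$type == "SNV"], 10L)
})

test_that("the evaluator matches a brute-force all-pairs matcher", {
  withr::with_seed(99, {
    for (rep in 1:8) {
      n_t <- sample(5:40, 1)
      truth <- tibble::tibble(
        chrom = "chr1",
        pos = sort(sample(seq(10, 5000, by = 10), n_t)),
        ref = sample(c("A", "C"), n_t, TRUE),
        alt = sample(c("G", "T"), n_t, TRUE),
        genotype = sample(c("0|1", "1|0", "1|1"), n_t, TRUE)
      )
      keep <- runif(n_t) < 0.8
      calls <- truth[keep, ]
      flip <- runif(nrow(calls)) < 0.2
      calls$genotype[flip] <- ifelse(calls$genotype[flip] == "1|1",
                                     "0/1", "1/1")
      extra_n <- sample(0:5, 1)
      if (extra_n > 0) {
        calls <- dplyr::bind_rows(calls, tibble::tibble(
          chrom = "chr1", pos = sort(sample(5001:6000, extra_n)),
          ref = "A", alt = "T",
          genotype = sample(c("0/1", "1/1"), extra_n, TRUE)
        ))
      }
      got <- evaluate_calls(calls, truth)
      want <- brute_eval(calls, truth)
      all_row <- got[got$type == "ALL", ]
      expect_equal(all_row$tp, want$tp)
      expect_equal(all_row$fp, want$fp)
      expect_equal(all_row$fn, want$fn)
      expect_equal(all_row$precision, want$precision)
      expect_equal(all_row$recall, want$recall)
      expect_equal(all_row$f1, want$f1)
    }
  })
})
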