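#' Simulate a reference chromosome, optionally with planted tandem repeats
#'
#' Generates a random nucleotide sequence with the requested GC content.
#' Short tandem repeats can be planted at well-separated random positions
#' (overwriting the background sequence) and are reported as a BED-style
#' interval table, which drives the TRC calling path when passed to the
#' caller as annotation.
#'
#' @param length Chromosome length in bp (>= 10,000).
#' @param gc GC fraction (default 0.5).
#' @param repeat_spec `NULL` for no repeats, or a list with `n` (number of
#'   repeats), `unit_len` (range of unit lengths, default 2:6) and
#'   `max_total` (maximum repeat tract length in bp, default 60 — short
#'   tandem repeats that local assembly can span).
#' @param seed Random seed.
#' @param chrom Chromosome name.
#' @return List with `ref` (named character vector), `repeats` (tibble
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @export
simulate_reference <- function(length, gc = 0.5, repeat_spec = NULL,
                               seed = 1, chrom = "chr1") {
  stopifnot(length >= 10000)
  withr::with_seed(random_seed_below_2_31(seed, 1), {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq <- paste(sample(names(probs), length, replace = TRUE, prob = probs),
                 collapse = "")
    repeats <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer())
    if (!is.null(repeat_spec) && repeat_spec$n > 0) {
      unit_len <- repeat_spec$unit_len %||% (2:6)
      max_total <- repeat_spec$max_total %||% 60
      n <- repeat_spec$n
      # well-separated placements, away from the chromosome ends
      slots <- seq(2000L, length - 2000L, length.out = n + 2)[2:(n + 1)]
      starts <- as.integer(slots + sample(-500:500, n, replace = TRUE))
      units <- sample(unit_len, n, replace = TRUE)
      copies <- vapply(units, function(u) {
        sample(8:max(8, floor(max_total / u)), 1)
      }, integer(1))
      tracts <- vapply(seq_len(n), function(i) {
        unit <- paste(sample(c("A", "C", "G", "T"), units[i], replace = TRUE),
                      collapse = "")
        strrep(unit, copies[i])
      }, character(1))
      for (i in seq_len(n)) {
        substr(seq, starts[i] + 1L, starts[i] + nchar(tracts[i])) <- tracts[i]
      }
      repeats <- tibble::tibble(chrom = chrom, start = starts,
                                end = starts + nchar(tracts))
    }
  })
  list(ref = setNames(seq, chrom), repeats = repeats)
}

#' Spike variants into a reference to create two donor haplotypes
#'
#' Draws SNV and indel positions at the given per-base rates (at least 2 bp
#' apart after accounting for reference spans), assigns phased genotypes
#' (`1|1` homozygous with probability `1 - het_fraction`, otherwise `1|0` or
#' `0|1` equally), and applies the variants to produce the two in-silico
#' donor haplotypes. Indel lengths are geometric, capped at 49 bp.
#'
#' @param ref Reference (single chromosome; named character vector or the
#'   `ref` element of [simulate_reference()]).
#' @param snv_rate,indel_rate Per-base variant rates (defaults 1/900 and
#'   1/5800, matching a human chromosome scaled down).
#' @param het_fraction Fraction of heterozygous variants (default 2/3).
#' @param seed Random seed.
#' @return List with `chrom`, `hap1`, `hap2` (character sequences), `truth`
#'   (sorted, left-normalised tibble `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `type`), and `maps` (per-haplotype indel coordinate maps
#'   used by [place_alignments()]).
#' @export
spike_variants <- function(ref, snv_rate = 1 / 900, indel_rate = 1 / 5800,
                           het_fraction = 2 / 3, seed = 1) {
  ref <- as_reference(ref)
  stopifnot(length(ref) == 1)
  chrom <- names(ref)
  chrom_seq <- ref[[1]]
  L <- nchar(chrom_seq)
  withr::with_seed(random_seed_below_2_31(seed, 2), {
    n_snv <- rbinom(1, L, snv_rate)
    n_indel <- rbinom(1, L, indel_rate)
    n <- n_snv + n_indel
    pos <- sort(sample(100:(L - 100), n))
    is_snv <- sample(rep(c(TRUE, FALSE), c(n_snv, n_indel)))
    ins_len <- pmin(rgeom(n, 0.35) + 1L, 49L)
    is_ins <- runif(n) < 0.5
    ref_allele <- alt_allele <- character(n)
    type <- character(n)
    for (i in seq_len(n)) {
      b <- substring(chrom_seq, pos[i], pos[i])
      if (is_snv[i]) {
        ref_allele[i] <- b
        alt_allele[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        type[i] <- "SNV"
      } else if (is_ins[i]) {
        ref_allele[i] <- b
        alt_allele[i] <- paste0(b, paste(
          sample(c("A", "C", "G", "T"), ins_len[i], replace = TRUE),
          collapse = ""))
        type[i] <- "INS"
      } else {
        dl <- min(ins_len[i], L - pos[i] - 100L)
        ref_allele[i] <- substring(chrom_seq, pos[i], pos[i] + dl)
        alt_allele[i] <- b
        type[i] <- "DEL"
      }
    }
    # enforce >= 2 bp between a variant's reference span and the next one
    keep <- logical(n)
    prev_end <- -10L
    for (i in seq_len(n)) {
      if (pos[i] > prev_end + 2L) {
        keep[i] <- TRUE
        prev_end <- pos[i] + nchar(ref_allele[i]) - 1L
      }
    }
    hom <- runif(n) >= het_fraction
    hap1_has <- ifelse(hom, TRUE, runif(n) < 0.5)
    genotype <- ifelse(hom, "1|1", ifelse(hap1_has, "1|0", "0|1"))
  })
  vars <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref_allele, alt = alt_allele,
    genotype = genotype, type = type
  )[keep, ]

  apply_hap <- function(carries) {
    v <- vars[carries, ]
    if (nrow(v) == 0) {
      return(list(seq = chrom_seq, map = empty_indel_map()))
    }
    at <- IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L)
    seq <- as.character(Biostrings::replaceAt(
      Biostrings::DNAString(chrom_seq), at, Biostrings::DNAStringSet(v$alt)
    ))
    ind <- v[nchar(v$ref) != nchar(v$alt), ]
    map <- if (nrow(ind) == 0) empty_indel_map() else {
      delta <- nchar(ind$alt) - nchar(ind$ref)
      off_after <- cumsum(delta)
      off_before <- off_after - delta
      tibble::tibble(
        pos = ind$pos, ref_len = nchar(ind$ref), alt_len = nchar(ind$alt),
        vhap = ind$pos + off_before,
        alt_end = ind$pos + off_before + nchar(ind$alt) - 1L,
        off_before = off_before, off_after = off_after
      )
    }
    list(seq = seq, map = map)
  }
  carries1 <- vars$genotype %in% c("1|0", "1|1")
  carries2 <- vars$genotype %in% c("0|1", "1|1")
  h1 <- apply_hap(carries1)
  h2 <- apply_hap(carries2)

  truth <- left_normalize(vars, chrom_seq = chrom_seq)
  truth <- truth[order(truth$pos), ]
  truth <- dplyr::distinct(truth, .data$chrom, .data$pos, .data$ref,
                           .data$alt, .keep_all = TRUE)
  list(chrom = chrom, hap1 = h1$seq, hap2 = h2$seq,
       truth = truth, maps = list(h1$map, h2$map))
}

empty_indel_map <- function() {
  tibble::tibble(pos = integer(), ref_len = integer(), alt_len = integer(),
                 vhap = integer(), alt_end = integer(),
                 off_before = integer(), off_after = integer())
}

#' Simulate paired-end reads from the two donor haplotypes
#'
#' Samples fragments uniformly from each haplotype at `coverage_per_hap`
#' (the merged set is the diploid coverage), with Gaussian insert sizes,
#' and reads both fragment ends. Substitution errors are injected at
#' `base_error_rate`; base qualities are constant and Phred-consistent with
#' that rate (Q30 when the rate is 0).
#'
#' @param spike Result of [spike_variants()].
#' @param coverage_per_hap Coverage per haplotype (default 20, i.e. 40x
#'   diploid).
#' @param read_len Read length (150 or 250).
#' @param insert_mean,insert_sd Fragment size distribution (defaults 500
#'   and 50).
#' @param base_error_rate Per-base substitution error rate (default 0.002).
#' @param seed Random seed.
#' @return Tibble of reads: `read_id`, `hap`, `mate`, `hap_start` (1-based
#'   on the haplotype), `seq`, `qual`.
#' @export
simulate_reads <- function(spike, coverage_per_hap = 20, read_len = 150,
                           insert_mean = 500, insert_sd = 50,
                           base_error_rate = 0.002, seed = 1) {
  qchar <- if (base_error_rate > 0) {
    max(2L, as.integer(round(-10 * log10(base_error_rate))))
  } else 30L
  qual <- strrep(intToUtf8(qchar + 33L), read_len)
  out <- vector("list", 2)
  withr::with_seed(random_seed_below_2_31(seed, 3), {
    for (h in 1:2) {
      hap <- if (h == 1) spike$hap1 else spike$hap2
      L <- nchar(hap)
      if (insert_mean > L) stop("fragment size exceeds haplotype length")
      nfrag <- round(coverage_per_hap * L / (2 * read_len))
      fl <- pmin(pmax(as.integer(round(rnorm(nfrag, insert_mean, insert_sd))),
                      read_len), L)
      start <- as.integer(floor(runif(nfrag) * (L - fl + 1))) + 1L
      r1 <- substring(hap, start, start + read_len - 1L)
      s2 <- start + fl - read_len
      r2 <- substring(hap, s2, s2 + read_len - 1L)
      rd <- tibble::tibble(
        read_id = rep(sprintf("h%d_f%07d", h, seq_len(nfrag)), 2),
        hap = h,
        mate = rep(1:2, each = nfrag),
        hap_start = c(start, s2),
        seq = c(r1, r2),
        qual = qual
      )
      if (base_error_rate > 0) {
        nerr <- rbinom(nrow(rd), read_len, base_error_rate)
        idx <- which(nerr > 0)
        for (i in idx) {
          p <- sample.int(read_len, nerr[i])
          s <- rd$seq[i]
          for (pp in p) {
            old <- substring(s, pp, pp)
            substr(s, pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          }
          rd$seq[i] <- s
        }
      }
      out[[h]] <- rd
    }
  })
  dplyr::bind_rows(out)
}

#' Place simulated reads at their true reference positions
#'
#' Computes each read's reference start and exact CIGAR from its true
#' haplotype coordinates and the indels it spans (reads that start or end
#' inside an inserted sequence are soft-clipped there, as an aligner
#' would). This bypasses an external aligner so that the whole pipeline is
#' hermetic and the pileup has a known ground truth. Reads whose aligned
#' span falls entirely inside a planted repeat interval receive a low
#' mapping quality (0-10), emulating ambiguous mapping in repeats.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param spike Result of [spike_variants()].
#' @param repeats Optional repeat interval tibble from
#'   [simulate_reference()].
#' @param seed Seed for the repeat-MAPQ draw.
#' @return Alignment tibble (see [read_alignments()]) sorted by position,
#'   with extra truth columns `hap` and `hap_start`.
#' @export
place_alignments <- function(reads, spike, repeats = NULL, seed = 1) {
  chrom <- spike$chrom
  parts <- vector("list", 2)
  for (h in 1:2) {
    mp <- spike$maps[[h]]
    rd <- reads[reads$hap == h, ]
    if (nrow(rd) == 0) next
    rl <- nchar(rd$seq)
    h1 <- rd$hap_start
    h2 <- h1 + rl - 1L
    if (nrow(mp) == 0) {
      starts <- h1
      cigars <- paste0(rl, "M")
    } else {
      i0 <- findInterval(h1, mp$vhap)
      iend <- findInterval(h2, mp$vhap)
      # does variant i0 (anchor at/left of read start) still intrude?
      intrude <- i0 > 0 & (
        (mp$ref_len[pmax(i0, 1)] > 1 & mp$vhap[pmax(i0, 1)] == h1 & h2 > h1) |
          (mp$alt_len[pmax(i0, 1)] > 1 & mp$alt_end[pmax(i0, 1)] >= h1)
      )
      simple <- iend == i0 & !intrude
      off <- ifelse(i0 == 0, 0L, mp$off_after[pmax(i0, 1)])
      starts <- integer(nrow(rd))
      cigars <- character(nrow(rd))
      starts[simple] <- h1[simple] - off[simple]
      cigars[simple] <- paste0(rl[simple], "M")
      for (r in which(!simple)) {
        pc <- place_complex(h1[r], h2[r], mp, i0[r])
        starts[r] <- pc$start
        cigars[r] <- pc$cigar
      }
    }
    parts[[h]] <- tibble::tibble(
      read_id = rd$read_id, chrom = chrom, start = starts - 1L,
      mapq = 60L, flag = ifelse(rd$mate == 1, 99L, 147L),
      cigar = cigars, seq = rd$seq, qual = rd$qual,
      hap = h, hap_start = rd$hap_start
    )
  }
  aln <- dplyr::bind_rows(parts)
  if (!is.null(repeats) && nrow(repeats) > 0 && nrow(aln) > 0) {
    ref_end <- aln$start + cigar_ref_width(aln$cigar)
    contained <- rep(FALSE, nrow(aln))
    for (i in seq_len(nrow(repeats))) {
      contained <- contained |
        (aln$start >= repeats$start[i] & ref_end <= repeats$end[i])
    }
    if (any(contained)) {
      withr::with_seed(random_seed_below_2_31(seed, 4), {
        aln$mapq[contained] <- sample(0:10, sum(contained), replace = TRUE)
      })
    }
  }
  dplyr::arrange(aln, .data$start)
}

# exact CIGAR for a read crossing indels; h1/h2 are 1-based haplotype
# coordinates, mp the per-haplotype indel map, i0 = findInterval(h1, vhap)
place_complex <- function(h1, h2, mp, i0) {
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0) return()
    k <- length(ops)
    if (k > 0 && ops[k] == op) {
      lens[k] <<- lens[k] + len
    } else {
      ops[k + 1] <<- op
      lens[k + 1] <<- len
    }
  }
  cur_hap <- h1
  jstart <- i0 + 1L
  if (i0 > 0 && mp$alt_len[i0] > 1 && h1 > mp$vhap[i0] && h1 <= mp$alt_end[i0]) {
    # read starts inside an inserted sequence: soft-clip the inserted bases
    lead <- mp$alt_end[i0] - h1 + 1L
    push("S", lead)
    cur_hap <- mp$alt_end[i0] + 1L
    ref_start <- mp$pos[i0] + mp$ref_len[i0]
  } else if (i0 > 0 && mp$vhap[i0] == h1) {
    ref_start <- h1 - mp$off_before[i0]
    jstart <- i0 # the anchor is the first base; its event is still ahead
  } else if (i0 > 0) {
    ref_start <- h1 - mp$off_after[i0]
  } else {
    ref_start <- h1
  }
  j <- jstart
  while (j <= nrow(mp) && mp$vhap[j] <= h2) {
    push("M", mp$vhap[j] - cur_hap + 1L)
    cur_hap <- mp$vhap[j] + 1L
    if (mp$alt_len[j] > 1) { # insertion
      n_in <- min(mp$alt_end[j], h2) - mp$vhap[j]
      if (n_in > 0) {
        if (mp$alt_end[j] <= h2) push("I", n_in) else push("S", n_in)
        cur_hap <- cur_hap + n_in
      }
    } else if (mp$ref_len[j] > 1 && cur_hap <= h2 + 1L && mp$vhap[j] < h2) {
      push("D", mp$ref_len[j] - 1L) # read extends past the anchor
    }
    j <- j + 1L
  }
  push("M", h2 - cur_hap + 1L)
  list(start = ref_start,
       cigar = paste0(lens, ops, collapse = ""))
}

#' Write alignments as SAM and convert to an indexed BAM
#'
#' @param alignments Alignment tibble.
#' @param ref Reference (for the header contig lines).
#' @param bam_path Output BAM path (a `.sam` sibling is written first).
#' @return The BAM path, invisibly.
#' @export
write_bam <- function(alignments, ref, bam_path) {
  ref <- as_reference(ref)
  ridx <- ref_index(ref)
  sam_path <- sub("\\.bam$", ".sam", bam_path)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ridx$chrom, ridx$length)
  )
  aln <- dplyr::arrange(alignments, match(.data$chrom, ridx$chrom), .data$start)
  qual <- ifelse(aln$qual == "", "*", aln$qual)
  lines <- paste(aln$read_id, aln$flag, aln$chrom, aln$start + 1L, aln$mapq,
                 aln$cigar, "*", 0L, 0L, aln$seq, qual, sep = "\t")
  writeLines(c(header, lines), sam_path)
  tmp <- Rsamtools::asBam(sam_path, sub("\\.bam$", "", bam_path),
                          overwrite = TRUE, indexDestination = TRUE)
  invisible(tmp)
}

#' Simulate a complete diploid sequencing data set
#'
#' Convenience wrapper reproducing the simulation design end to end:
#' reference (with planted short tandem repeats), spiked diploid variants,
#' two per-haplotype read sets merged to the diploid coverage, and exactly
#' placed alignments.
#'
#' @param length Genome length (default 1e6).
#' @param read_len Read length (default 150).
#' @param coverage_per_hap Per-haplotype coverage (default 20).
#' @param snv_rate,indel_rate Variant densities (defaults 1/900, 1/5800).
#' @param base_error_rate Sequencing error rate (default 0.002).
#' @param n_repeats Planted tandem repeats (default 20 per Mb).
#' @param insert_mean,insert_sd Fragment size model (500, 50).
#' @param seed Master seed; all stages derive their seeds from it.
#' @return List with `ref`, `repeats`, `spike`, `truth`, `reads`,
#'   `alignments`.
#' @export
simulate_dataset <- function(length = 1e6, read_len = 150,
                             coverage_per_hap = 20, snv_rate = 1 / 900,
                             indel_rate = 1 / 5800, base_error_rate = 0.002,
                             n_repeats = round(20 * length / 1e6),
                             insert_mean = 500, insert_sd = 50, seed = 1) {
  sim <- simulate_reference(length,
                            repeat_spec = if (n_repeats > 0) list(n = n_repeats),
                            seed = seed)
  spike <- spike_variants(sim$ref, snv_rate = snv_rate,
                          indel_rate = indel_rate, seed = seed)
  reads <- simulate_reads(spike, coverage_per_hap = coverage_per_hap,
                          read_len = read_len, insert_mean = insert_mean,
                          insert_sd = insert_sd,
                          base_error_rate = base_error_rate, seed = seed)
  aln <- place_alignments(reads, spike, repeats = sim$repeats, seed = seed)
  list(ref = sim$ref, repeats = sim$repeats, spike = spike,
       truth = spike$truth, reads = reads, alignments = aln)
}
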