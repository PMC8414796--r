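#' Caller configuration
#'
#' Bundles every tunable of the pipeline with its default.
#'
#' @param mapq_min Minimum mapping quality (default 10).
#' @param snv_min_af,indel_min_af Candidate detection thresholds on `P_alt`.
#' @param min_bq Minimum mean alternative base quality (default 20).
#' @param min_depth Minimum observations at a candidate site (default 4).
#' @param flank HC proximity window in bp (default 100).
#' @param t_lc,flank_f LC merge distance and region extension (10 and 25 bp).
#' @param min_overlap Minimum segment/region overlap fraction (default 0.5).
#' @param window_len TRC reassembly window length (default 300).
#' @param k_min,k_max,k_step De Bruijn k-mer schedule (41, 75, 5).
#' @param max_haplotypes Haplotypes per window (default 2).
#' @param eps,prior,qual_cap Genotype model parameters (see [model_params()]).
#' @param match,mismatch,gap_open,gap_extend Realignment scoring
#'   (see [align_scoring()]).
#' @param lowqual Phred threshold below which calls are tagged LowQual
#'   (default 15; calls are kept, not dropped).
#' @param block_size Task block size in bp (default 20,000,000).
#' @param margin Context margin around each block used for detection and
#'   classification so that results are block-size invariant (default 500).
#' @param context Flank for genotyping haplotypes (default 50).
#' @return A named list.
#' @export
shortcall_config <- function(mapq_min = 10, snv_min_af = 0.2,
                             indel_min_af = 0.125, min_bq = 20, min_depth = 4,
                             flank = 100, t_lc = 10, flank_f = 25,
                             min_overlap = 0.5, window_len = 300,
                             k_min = 41, k_max = 75, k_step = 5,
                             max_haplotypes = 2, eps = 0.03, prior = 1 / 3,
                             qual_cap = 60, match = 2, mismatch = -6,
                             gap_open = 6, gap_extend = 1, lowqual = 15,
                             block_size = 2e7, margin = 500, context = 50) {
  as.list(environment())
}

#' Split the reference into non-overlapping task blocks
#'
#' @param ref_index Tibble with `chrom` and `length` columns (see
#'   [call_variants()]), or a reference accepted by `as_reference`.
#' @param block_size Block size in bp (default 20,000,000).
#' @return Tibble of blocks `chrom`, `start`, `end` (0-based half-open)
#'   covering every chromosome exactly; the last block of a chromosome may
#'   be short. Blocks never span chromosomes.
#' @export
split_tasks <- function(ref_index, block_size = 2e7) {
  stopifnot(block_size > 0)
  if (!is.data.frame(ref_index)) ref_index <- ref_index(ref_index)
  purrr::pmap_dfr(ref_index, function(chrom, length, ...) {
    starts <- seq(0L, length - 1L, by = as.integer(block_size))
    tibble::tibble(chrom = chrom, start = as.integer(starts),
                   end = as.integer(pmin(starts + block_size, length)))
  })
}

empty_calls <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), kind = character(), genotype = character(),
    qual = double(), dp = integer(), ad_ref = integer(),
    ad_alt = integer(), source = character()
  )
}

# Binomial-model calls for high-confidence sites (also the fallback model
# for LC sites with too few segments). The alternative allele is the top
# pileup allele; for indels, the majority supporting sequence.
call_binomial_sites <- function(sites, ref, params, source = "HC") {
  if (nrow(sites) == 0) return(empty_calls())
  ref <- as_reference(ref)
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (s$ref_count + s$top_count <= 0) next
    if (s$top_alt %in% c("A", "C", "G", "T")) {
      ref_allele <- s$ref_base
      alt_allele <- s$top_alt
      kind <- "SNV"
    } else if (s$top_alt == "I") {
      seqs <- s$ins_seqs[[1]]
      if (length(seqs) == 0) next
      ins <- names(which.max(table(seqs)))
      ref_allele <- s$ref_base
      alt_allele <- paste0(s$ref_base, ins)
      kind <- "INS"
    } else {
      seqs <- s$del_seqs[[1]]
      if (length(seqs) == 0) next
      del <- names(which.max(table(seqs)))
      ref_allele <- paste0(s$ref_base, del)
      alt_allele <- s$ref_base
      kind <- "DEL"
    }
    gt <- binomial_likelihoods(s$ref_count, s$top_count, params)
    if (!gt$genotype %in% c("0/1", "1/1")) next
    rows[[i]] <- tibble::tibble(
      chrom = s$chrom, pos = s$pos, ref = ref_allele, alt = alt_allele,
      kind = kind, genotype = gt$genotype, qual = gt$qual, dp = s$total,
      ad_ref = s$ref_count, ad_alt = s$top_count, source = source
    )
  }
  dplyr::bind_rows(rows)
}

# LC path: POA consensus over clipped segments, realignment, Bayesian
# genotyping. Falls back to the binomial model (< 2 segments) or local
# assembly (POA failure).
call_lc_region <- function(region, member_sites, alignments, ref, params,
                           scoring, config) {
  segs <- extract_segments(alignments, region, config$min_overlap)
  if (nrow(segs) < 2) {
    return(call_binomial_sites(member_sites, ref, params, source = "LC"))
  }
  haps <- poa_consensus(segs, max_consensus = config$max_haplotypes)
  if (nrow(haps) == 0) {
    reads <- region_reads(alignments, region)
    haps <- assemble_window(reads$seq, region$end - region$start,
                            k_min = config$k_min, k_max = config$k_max,
                            k_step = config$k_step,
                            max_haplotypes = config$max_haplotypes)
  }
  if (nrow(haps) == 0) return(empty_calls())
  chrom_seq <- ref_chrom(ref, region$chrom)
  ref_segment <- substring(chrom_seq, region$start + 1L, region$end)
  vars <- realign_and_call(haps, ref_segment, region$start, region$chrom,
                           scoring, chrom_seq = chrom_seq)
  if (nrow(vars) == 0) return(empty_calls())
  out <- genotype_region(vars, alignments, ref, params, scoring,
                         context = config$context,
                         min_overlap = config$min_overlap)
  if (nrow(out) == 0) return(empty_calls())
  dplyr::mutate(dplyr::select(out, -"hap_support"), source = "LC")
}

# TRC path: de Bruijn local assembly over the window, realignment of the
# contigs, Bayesian genotyping. Unassembleable windows emit no calls.
call_trc_window <- function(window, alignments, ref, params, scoring, config) {
  reads <- region_reads(alignments, window)
  if (nrow(reads) < 2) return(empty_calls())
  haps <- assemble_window(reads$seq, window$end - window$start,
                          k_min = config$k_min, k_max = config$k_max,
                          k_step = config$k_step,
                          max_haplotypes = config$max_haplotypes)
  contigs <- attr(haps, "all_contigs")
  if (nrow(haps) == 0) return(empty_calls())
  chrom_seq <- ref_chrom(ref, window$chrom)
  pad <- 150L
  seg0 <- max(0L, window$start - pad)
  seg1 <- min(nchar(chrom_seq), window$end + pad)
  ref_segment <- substring(chrom_seq, seg0 + 1L, seg1)
  vars <- realign_and_call(
    tibble::tibble(sequence = contigs$sequence, support = contigs$score),
    ref_segment, seg0, window$chrom, scoring, chrom_seq = chrom_seq
  )
  vars <- dplyr::filter(vars, .data$pos > window$start, .data$pos <= window$end)
  if (nrow(vars) == 0) return(empty_calls())
  out <- genotype_region(vars, alignments, ref, params, scoring,
                         context = config$context,
                         min_overlap = config$min_overlap)
  if (nrow(out) == 0) return(empty_calls())
  dplyr::mutate(dplyr::select(out, -"hap_support"), source = "TRC")
}

region_reads <- function(alignments, region) {
  aln <- alignments[alignments$chrom == region$chrom, ]
  if (!"end" %in% names(aln)) aln$end <- aln$start + cigar_ref_width(aln$cigar)
  aln[aln$start < region$end & aln$end > region$start, ]
}

#' Run the per-block calling pipeline
#'
#' Executes pileup, candidate detection, three-way classification and the
#' category-specific callers over one block. Detection and classification
#' use a margin around the block so that classification context (proximity,
#' merged regions) does not depend on block boundaries; only calls anchored
#' inside the block proper are emitted. Blocks share no mutable state and
#' can run concurrently.
#'
#' @param block Block row (`chrom`, `start`, `end`).
#' @param inputs List with either `alignments` (tibble) or `bam` (path),
#'   plus `ref` (named sequences) and optional `annotation`.
#' @param config [shortcall_config()].
#' @return Call tibble (possibly empty) for the block.
#' @export
run_block <- function(block, inputs, config = shortcall_config()) {
  block <- as_block(block)
  ref <- as_reference(inputs$ref)
  chrom_seq <- ref_chrom(ref, block$chrom)
  chrom_lengths <- setNames(nchar(ref), names(ref))
  exp_block <- list(
    chrom = block$chrom,
    start = max(0L, as.integer(block$start - config$margin)),
    end = min(nchar(chrom_seq), as.integer(block$end + config$margin))
  )
  if (!is.null(inputs$alignments)) {
    aln <- inputs$alignments
    if (!"end" %in% names(aln)) aln$end <- aln$start + cigar_ref_width(aln$cigar)
    aln <- aln[aln$chrom == block$chrom & aln$start < exp_block$end &
                 aln$end > exp_block$start, ]
    aln <- filter_alignments(aln, config$mapq_min)
  } else {
    aln <- read_alignments(inputs$bam, exp_block, config$mapq_min)
    if (nrow(aln) > 0) aln$end <- aln$start + cigar_ref_width(aln$cigar)
  }
  if (nrow(aln) == 0) return(empty_calls())

  params <- model_params(config$eps, config$prior, config$qual_cap)
  scoring <- align_scoring(config$match, config$mismatch, config$gap_open,
                           config$gap_extend)

  pl <- build_pileup(aln, exp_block, ref)
  cands <- detect_candidates(pl, snv_min_af = config$snv_min_af,
                             indel_min_af = config$indel_min_af,
                             min_bq = config$min_bq,
                             min_depth = config$min_depth)
  if (nrow(cands) == 0) return(empty_calls())
  sites <- classify_sites(cands, inputs$annotation, flank = config$flank)

  hc_calls <- call_binomial_sites(
    dplyr::filter(sites, .data$category == "HC"), ref, params, source = "HC"
  )

  lc_sites <- dplyr::filter(sites, .data$category == "LC")
  lc_regions <- merge_lc_sites(lc_sites, config$t_lc, config$flank_f,
                               chrom_lengths)
  lc_calls <- purrr::map_dfr(seq_len(nrow(lc_regions)), function(i) {
    region <- as.list(lc_regions[i, c("chrom", "start", "end")])
    members <- dplyr::filter(lc_sites,
                             .data$pos %in% lc_regions$member_pos[[i]])
    call_lc_region(region, members, aln, ref, params, scoring, config)
  })

  trc_sites <- dplyr::filter(sites, .data$category == "TRC")
  trc_windows <- make_trc_windows(trc_sites, config$window_len, chrom_lengths)
  trc_calls <- purrr::map_dfr(seq_len(nrow(trc_windows)), function(i) {
    window <- as.list(trc_windows[i, c("chrom", "start", "end")])
    call_trc_window(window, aln, ref, params, scoring, config)
  })

  calls <- dplyr::bind_rows(hc_calls, lc_calls, trc_calls)
  if (nrow(calls) == 0) return(empty_calls())
  calls <- left_normalize(calls, chrom_seq = chrom_seq)
  dplyr::filter(calls, .data$pos > block$start, .data$pos <= block$end)
}

#' Integrate per-block calls into the final deduplicated call set
#'
#' Sorts calls by reference order and position, collapses duplicate
#' (chrom, pos, ref, alt) records keeping the one with the higher quality
#' (ties prefer the HC-sourced record, then the first seen), and tags calls
#' below the LowQual threshold (they are kept, not dropped).
#'
#' @param calls Call tibble (concatenated block results).
#' @param ref_index Reference index tibble (`chrom`, `length`).
#' @param lowqual Phred threshold for the LowQual filter tag.
#' @return Ordered, deduplicated call tibble with a `filter` column.
#' @export
integrate_calls <- function(calls, ref_index, lowqual = 15) {
  if (nrow(calls) == 0) {
    calls$filter <- character(0)
    return(calls)
  }
  chrom_rank <- match(calls$chrom, ref_index$chrom)
  calls |>
    dplyr::mutate(.rank = chrom_rank, .hc = .data$source != "HC",
                  .seen = dplyr::row_number()) |>
    dplyr::arrange(.data$.rank, .data$pos, .data$ref, .data$alt,
                   dplyr::desc(.data$qual), .data$.hc, .data$.seen) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .keep_all = TRUE) |>
    dplyr::select(-".rank", -".hc", -".seen") |>
    dplyr::mutate(filter = ifelse(.data$qual < lowqual, "LowQual", "PASS"))
}

#' Call SNVs and indels from short-read alignments
#'
#' The main entry point: splits the genome into blocks, runs the per-block
#' pipeline (pileup, candidate detection, HC/LC/TRC triage, category
#' specific calling and genotyping), and integrates the results into one
#' deduplicated call set.
#'
#' @param ref Reference genome: named character vector, `DNAStringSet`, or
#'   FASTA path.
#' @param bam Path to an indexed coordinate-sorted BAM, or
#' @param alignments an in-memory alignment tibble (e.g. from
#'   [place_alignments()]).
#' @param annotation Optional tandem-repeat/LCR annotation (BED path(s),
#'   `GRanges`, or 0-based tibble).
#' @param config [shortcall_config()].
#' @param workers Number of parallel workers for block execution (forked;
#'   results are deterministic regardless of worker count).
#' @param sample_name Sample name for VCF output.
#' @param out_vcf Optional path: write the calls as VCF 4.2.
#' @return A `shortcall_calls` tibble: `chrom`, `pos`, `ref`, `alt`, `kind`,
#'   `genotype`, `qual`, `dp`, `ad_ref`, `ad_alt`, `source`, `filter`.
#' @export
call_variants <- function(ref, bam = NULL, alignments = NULL,
                          annotation = NULL, config = shortcall_config(),
                          workers = 1, sample_name = "SAMPLE",
                          out_vcf = NULL) {
  if (is.null(bam) && is.null(alignments)) {
    stop("supply either `bam` or `alignments`", call. = FALSE)
  }
  ref <- as_reference(ref)
  ridx <- ref_index(ref)
  ann <- as_annotation(annotation)
  blocks <- split_tasks(ridx, config$block_size)
  if (!is.null(alignments) && !"end" %in% names(alignments)) {
    alignments$end <- alignments$start + cigar_ref_width(alignments$cigar)
  }
  inputs <- list(alignments = alignments, bam = bam, ref = ref,
                 annotation = ann)
  runner <- function(i) {
    run_block(blocks[i, ], inputs, config)
  }
  idx <- seq_len(nrow(blocks))
  if (workers > 1) {
    res <- parallel::mclapply(idx, runner, mc.cores = workers)
    failed <- vapply(res, inherits, logical(1), "try-error")
    if (any(failed)) stop("block execution failed: ", res[[which(failed)[1]]])
  } else {
    res <- lapply(idx, runner)
  }
  calls <- integrate_calls(dplyr::bind_rows(res), ridx, config$lowqual)
  calls <- tibble::new_tibble(calls, class = "shortcall_calls")
  attr(calls, "ref_index") <- ridx
  attr(calls, "sample_name") <- sample_name
  attr(calls, "config") <- config
  if (!is.null(out_vcf)) write_vcf(calls, ridx, sample_name, out_vcf)
  calls
}

#' Write calls as a VCF 4.2 file
#'
#' @param calls Call tibble from [call_variants()] / [integrate_calls()]
#'   (sorted, deduplicated).
#' @param ref_index Reference index (`chrom`, `length`) for the contig
#'   header lines.
#' @param sample_name Name of the single sample column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref_index, sample_name, path) {
  if (missing(ref_index) && !is.null(attr(calls, "ref_index"))) {
    ref_index <- attr(calls, "ref_index")
  }
  if (missing(sample_name)) {
    sample_name <- attr(calls, "sample_name") %||% "SAMPLE"
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=shortcall",
    sprintf("##contig=<ID=%s,length=%d>", ref_index$chrom, ref_index$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at the site\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele read fraction\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling path (HC/LC/TRC)\">",
    "##FILTER=<ID=LowQual,Description=\"Genotype quality below threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele-supporting read counts\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  lines <- character(0)
  if (nrow(calls) > 0) {
    af <- ifelse(calls$ad_ref + calls$ad_alt > 0,
                 round(calls$ad_alt / (calls$ad_ref + calls$ad_alt), 4), 0)
    lines <- paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt,
      formatC(calls$qual, format = "f", digits = 2),
      calls$filter %||% "PASS",
      sprintf("DP=%d;AF=%s;SRC=%s", calls$dp, af, calls$source),
      "GT:DP:AD:GQ",
      sprintf("%s:%d:%d,%d:%d", calls$genotype, calls$dp, calls$ad_ref,
              calls$ad_alt, round(calls$qual)),
      sep = "\t"
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}
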