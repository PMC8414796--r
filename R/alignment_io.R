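#' Read and filter alignments from a coordinate-sorted BAM file
#'
#' Loads the alignment records overlapping a genomic block and applies the
#' standard caller filters: unmapped reads (flag 4), reads with an unmapped
#' mate (flag 8), secondary alignments (flag 256), supplementary alignments
#' (flag 2048), and records with mapping quality below `mapq_min` are all
#' excluded.
#'
#' @param bam_path Path to an indexed, coordinate-sorted BAM file.
#' @param block A one-row tibble or list with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. a row of [split_tasks()]. `NULL` loads the
#'   whole file.
#' @param mapq_min Minimum mapping quality to keep (default 10; records with
#'   MAPQ strictly below are dropped).
#' @return A tibble of alignment records with columns `read_id`, `chrom`,
#'   `start` (0-based), `mapq`, `flag`, `cigar`, `seq`, `qual` (empty string
#'   when base qualities are absent), ordered by coordinate.
#' @export
read_alignments <- function(bam_path, block = NULL, mapq_min = 10) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path, call. = FALSE)
  }
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for: ", bam_path, call. = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
  )
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  if (!is.null(block)) {
    block <- as_block(block)
    hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
    if (!block$chrom %in% names(hdr)) {
      warning("chromosome '", block$chrom, "' not in BAM header; returning no records")
      return(empty_alignments())
    }
    which <- GenomicRanges::GRanges(
      block$chrom, IRanges::IRanges(block$start + 1, block$end)
    )
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, which = which,
                                     mapqFilter = mapq_min)
  } else {
    param <- Rsamtools::ScanBamParam(flag = flags, what = what,
                                     mapqFilter = mapq_min)
  }
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  qual <- as.character(res$qual)
  qual[qual == "*" | is.na(qual)] <- ""
  tibble::tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    mapq = res$mapq,
    flag = res$flag,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = qual
  ) |>
    dplyr::arrange(.data$start)
}

empty_alignments <- function() {
  tibble::tibble(
    read_id = character(), chrom = character(), start = integer(),
    mapq = integer(), flag = integer(), cigar = character(),
    seq = character(), qual = character()
  )
}

#' Apply the standard alignment filters to an in-memory alignment tibble
#'
#' The same filters [read_alignments()] applies when reading from BAM, for
#' pipelines that carry alignments as tibbles (e.g. from
#' [place_alignments()]).
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param mapq_min Minimum mapping quality to keep.
#' @return The filtered tibble.
#' @export
filter_alignments <- function(alignments, mapq_min = 10) {
  drop_bits <- bitwOr(bitwOr(4L, 8L), bitwOr(256L, 2048L))
  dplyr::filter(
    alignments,
    bitwAnd(.data$flag, drop_bits) == 0L,
    .data$mapq >= mapq_min
  )
}

#' Build per-position pileup summaries over a block
#'
#' Walks the CIGAR of every record and accumulates, for each reference
#' position of the block, the (V, S, L) summary: `V` is the per-allele count
#' over labels A/C/G/T/N/I/D, `S` is the summed base quality of alternative
#' base observations, and `L` collects the inserted and deleted sequences.
#' A read showing an insertion or deletion anchored at a position contributes
#' to the `I`/`D` count there instead of the anchor's base count, so `T`
#' (the sum of V) reflects one observation per read. Indels are anchored at
#' the last reference base before the event. Soft-clipped bases contribute
#' nothing. Records whose CIGAR does not match the sequence length are
#' skipped with a warning.
#'
#' @param alignments Alignment tibble (already filtered).
#' @param block Block (`chrom`, `start`, `end`, 0-based half-open).
#' @param ref Reference: named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param depth_cap Maximum implied coverage before the block's reads are
#'   uniformly downsampled (memory guard; deterministic).
#' @return A tibble with one row per covered position: `chrom`, `pos`
#'   (1-based), `ref_base`, allele counts `A`,`C`,`G`,`T`,`N`,`I`,`D`, `S`,
#'   `total` (the sum of V), `depth`, and list-columns `ins_seqs`, `del_seqs`.
#' @export
build_pileup <- function(alignments, block, ref, depth_cap = 1000) {
  block <- as_block(block)
  ref <- as_reference(ref)
  chrom_seq <- ref_chrom(ref, block$chrom)
  aln <- dplyr::filter(alignments, .data$chrom == block$chrom)
  len <- block$end - block$start
  if (nrow(aln) > 0) {
    implied_cov <- sum(nchar(aln$seq)) / len
    if (implied_cov > depth_cap) {
      keep_n <- ceiling(nrow(aln) * depth_cap / implied_cov)
      withr::with_seed(7191L, {
        keep <- sort(sample.int(nrow(aln), keep_n))
      })
      aln <- aln[keep, ]
    }
  }
  pl <- cpp_pileup(aln$seq, aln$qual, aln$start, aln$cigar,
                   chrom_seq, block$start, block$end)
  if (pl$skipped > 0) {
    warning(pl$skipped, " record(s) with CIGAR/sequence length mismatch skipped")
  }
  counts <- pl$counts
  colnames(counts) <- c("A", "C", "G", "T", "N", "I", "D")
  pos <- (block$start + 1L):block$end
  keep <- pl$depth > 0 | rowSums(counts) > 0
  out <- tibble::as_tibble(as.data.frame(counts[keep, , drop = FALSE]))
  out$chrom <- rep(block$chrom, nrow(out))
  out$pos <- pos[keep]
  out$ref_base <- if (nrow(out) > 0) {
    substring(chrom_seq, out$pos, out$pos)
  } else character(0)
  out$S <- pl$S[keep]
  out$total <- as.integer(rowSums(counts[keep, , drop = FALSE]))
  out$depth <- pl$depth[keep]
  out$ins_seqs <- seq_list_column(pl$ins_pos, pl$ins_seq, out$pos)
  out$del_seqs <- seq_list_column(pl$del_pos, pl$del_seq, out$pos)
  attr(out, "qual_missing") <- pl$no_qual > 0 && pl$no_qual >= nrow(aln)
  dplyr::select(
    out, "chrom", "pos", "ref_base",
    "A", "C", "G", "T", "N", "I", "D", "S", "total", "depth",
    "ins_seqs", "del_seqs"
  )
}

# group indel event sequences (0-based anchors) into a list-column aligned
# with the 1-based positions `pos`
seq_list_column <- function(ev_pos, ev_seq, pos) {
  out <- vector("list", length(pos))
  if (length(ev_pos) == 0) return(out)
  grp <- split(toupper(ev_seq), ev_pos + 1L)
  idx <- match(as.integer(names(grp)), pos)
  ok <- !is.na(idx)
  out[idx[ok]] <- grp[ok]
  out
}
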