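#' Genotype realigned variants from read evidence
#'
#' For each candidate variant, builds the local reference and alternative
#' allele haplotypes over a context window, aligns every overlapping read
#' segment against both, and genotypes the site. With base qualities
#' available, the per-read haploid likelihood is
#' \eqn{\Pr(R_j|H) = 10^{-\sum Q_e/10}} over the mismatch qualities (an indel
#' in the read-vs-haplotype alignment contributes the quality of its first
#' affected base), reads are combined per genotype with
#' \eqn{\Pr(R|G) = \prod_j (\Pr(R_j|H_1) + \Pr(R_j|H_2))/2}, and posteriors
#' follow Bayes rule with equal genotype priors. Without base qualities the
#' binomial count model is used on the allele-supporting read counts.
#'
#' @param variants Tibble `chrom`, `pos`, `ref`, `alt`, `kind` (e.g. from
#'   [realign_and_call()]).
#' @param alignments Alignment tibble covering the region.
#' @param ref Reference sequences.
#' @param params [model_params()].
#' @param scoring [align_scoring()].
#' @param context Flank (bp) around the variant used for the allele
#'   haplotypes (default 50).
#' @param min_overlap Minimum fraction of the context window a segment must
#'   cover (default 0.5).
#' @param max_segments Cap on segments used per variant (deepest first).
#' @return The variants tibble with `genotype`, `qual`, `dp`, `ad_ref`,
#'   `ad_alt` added; variants genotyped `0/0` or unresolvable are dropped.
#' @export
genotype_region <- function(variants, alignments, ref, params = model_params(),
                            scoring = align_scoring(), context = 50,
                            min_overlap = 0.5, max_segments = 60) {
  ref <- as_reference(ref)
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, genotype = character(0), qual = double(0),
                         dp = integer(0), ad_ref = integer(0),
                         ad_alt = integer(0)))
  }
  if (!"end" %in% names(alignments)) {
    alignments$end <- alignments$start + cigar_ref_width(alignments$cigar)
  }
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    chrom_seq <- ref_chrom(ref, v$chrom)
    rl <- nchar(v$ref)
    ctx0 <- max(0L, v$pos - 1L - as.integer(context))
    ctx1 <- min(nchar(chrom_seq), v$pos - 1L + rl + as.integer(context))
    aln <- alignments[alignments$chrom == v$chrom &
                        alignments$start < ctx1 & alignments$end > ctx0, ]
    if (nrow(aln) == 0) next
    cl <- cpp_clip_reads(aln$seq, aln$qual, aln$start, aln$cigar, ctx0, ctx1)
    segs <- tibble::tibble(seq = as.character(cl$seq),
                           qual = as.character(cl$qual),
                           overlap = cl$overlap)
    segs <- segs[segs$overlap >= min_overlap & nchar(segs$seq) > 0, ]
    if (nrow(segs) == 0) next
    segs <- segs[order(-segs$overlap, segs$seq), ]
    segs <- utils::head(segs, max_segments)

    ref_hap <- substring(chrom_seq, ctx0 + 1L, ctx1)
    off <- v$pos - ctx0
    alt_hap <- paste0(substring(ref_hap, 1, off - 1L), v$alt,
                      substring(ref_hap, off + rl, nchar(ref_hap)))
    has_qual <- all(nchar(segs$qual) == nchar(segs$seq)) && all(nchar(segs$qual) > 0)

    if (has_qual) {
      s_ref <- mismatch_qual_sums(segs, ref_hap, scoring)
      s_alt <- mismatch_qual_sums(segs, alt_hap, scoring)
      l00 <- -sum(s_ref) / 10
      l11 <- -sum(s_alt) / 10
      l01 <- sum(log10((10^(-s_ref / 10) + 10^(-s_alt / 10)) / 2))
      gt <- posterior_genotypes_log10(l00, l01, l11,
                                      qual_cap = params$qual_cap)
      ad_ref <- sum(s_ref < s_alt)
      ad_alt <- sum(s_alt < s_ref)
    } else {
      sc <- cpp_fit_scores(segs$seq, c(ref_hap, alt_hap),
                           match = scoring$match, mismatch = scoring$mismatch,
                           gap = -4)
      ad_ref <- sum(sc[, 1] > sc[, 2])
      ad_alt <- sum(sc[, 2] > sc[, 1])
      if (ad_ref + ad_alt == 0) next
      gt <- binomial_likelihoods(ad_ref, ad_alt, params)
    }
    rows[[i]] <- dplyr::mutate(v, genotype = gt$genotype, qual = gt$qual,
                               dp = nrow(segs), ad_ref = as.integer(ad_ref),
                               ad_alt = as.integer(ad_alt))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(dplyr::mutate(variants[0, ], genotype = character(0),
                         qual = double(0), dp = integer(0),
                         ad_ref = integer(0), ad_alt = integer(0)))
  }
  dplyr::filter(out, .data$genotype %in% c("0/1", "1/1"))
}

# Per-segment mismatch-quality sums against one haplotype: the Phred
# qualities of mismatching bases plus, for each indel event in the
# alignment, the quality of its first affected read base.
mismatch_qual_sums <- function(segs, hap, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(segs$seq), subject = hap,
    type = "global-local", substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  n <- nrow(segs)
  qs <- numeric(n)
  mt <- Biostrings::mismatchTable(pa)
  if (nrow(mt) > 0) {
    q <- utf8ToInt(paste0(substring(segs$qual[mt$PatternId], mt$PatternStart,
                                    mt$PatternStart), collapse = "")) - 33L
    add <- tapply(q, mt$PatternId, sum)
    idx <- as.integer(names(add))
    qs[idx] <- qs[idx] + as.numeric(add)
  }
  for (slot in list(Biostrings::insertion(pa), Biostrings::deletion(pa))) {
    st <- IRanges::start(slot)
    lens <- lengths(st)
    if (sum(lens) == 0) next
    pat_id <- rep(seq_len(n), lens)
    ppos <- unlist(st, use.names = FALSE)
    ppos <- pmin(pmax(ppos, 1L), nchar(segs$seq[pat_id]))
    q <- utf8ToInt(paste0(substring(segs$qual[pat_id], ppos, ppos),
                          collapse = "")) - 33L
    add <- tapply(q, pat_id, sum)
    idx <- as.integer(names(add))
    qs[idx] <- qs[idx] + as.numeric(add)
  }
  qs
}
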