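#' Pairwise-alignment scoring parameters
#'
#' Affine-gap scoring used for consensus/contig realignment and read-vs-allele
#' likelihood alignment. The default penalises a mismatch more than a gap
#' opening so that a genuine short deletion is not re-written as a run of
#' mismatches.
#'
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Positive gap-opening/extension costs (Biostrings
#'   convention).
#' @return A list of scoring parameters with the substitution matrix attached.
#' @export
align_scoring <- function(match = 2, mismatch = -6, gap_open = 6, gap_extend = 1) {
  list(
    match = match, mismatch = mismatch,
    gap_open = gap_open, gap_extend = gap_extend,
    submat = Biostrings::nucleotideSubstitutionMatrix(match, mismatch,
                                                      baseOnly = FALSE)
  )
}

#' Merge low-confidence sites into calling regions
#'
#' Consecutive LC sites on a chromosome are merged when their distance is
#' shorter than `t_lc` bp; each merged run becomes a calling region extended
#' by `flank_f` bp on both sides (plus the longest member deletion, so that a
#' deletion's reference span stays inside the region), clamped to the
#' chromosome.
#'
#' @param sites Classified site tibble (rows with category "LC"), sorted by
#'   position.
#' @param t_lc Merge distance in bp (default 10).
#' @param flank_f Flank extension in bp (default 25).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A tibble of regions: `chrom`, `start`, `end` (0-based half-open),
#'   `kind = "LC"`, and a list-column `member_pos` of member site positions.
#' @export
merge_lc_sites <- function(sites, t_lc = 10, flank_f = 25, chrom_lengths) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), kind = character(),
                          member_pos = list()))
  }
  sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      grp <- cumsum(c(1L, as.integer(diff(d$pos) >= t_lc)))
      max_del <- vapply(d$del_seqs, function(s) {
        if (length(s) == 0) 0L else max(nchar(s))
      }, integer(1))
      len <- chrom_lengths[[key$chrom]]
      dplyr::tibble(
        start = as.integer(pmax(0L, tapply(d$pos, grp, min) - 1L - flank_f)),
        end = as.integer(pmin(len, tapply(d$pos + max_del, grp, max) + flank_f)),
        kind = "LC",
        member_pos = unname(split(d$pos, grp))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "kind", "member_pos")
}

#' Pack tandem-repeat sites into reassembly windows
#'
#' Consecutive TRC sites are greedily grouped so that one window spans at
#' most `window_len` bp between its first and last member, then each window
#' is padded symmetrically to `window_len` bp.
#'
#' @param sites Classified site tibble (rows with category "TRC"), sorted.
#' @param window_len Target window length (default 300).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Region tibble like [merge_lc_sites()] with `kind = "TRC"`.
#' @export
make_trc_windows <- function(sites, window_len = 300, chrom_lengths) {
  if (nrow(sites) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), kind = character(),
                          member_pos = list()))
  }
  sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      grp <- integer(nrow(d))
      g <- 1L
      anchor <- d$pos[1]
      for (i in seq_len(nrow(d))) {
        if (d$pos[i] - anchor > window_len - 50L) {
          g <- g + 1L
          anchor <- d$pos[i]
        }
        grp[i] <- g
      }
      len <- chrom_lengths[[key$chrom]]
      lo <- tapply(d$pos, grp, min)
      hi <- tapply(d$pos, grp, max)
      pad <- pmax(0, ceiling((window_len - (hi - lo + 1)) / 2))
      dplyr::tibble(
        start = as.integer(pmax(0L, lo - 1L - pad)),
        end = as.integer(pmin(len, hi + pad)),
        kind = "TRC",
        member_pos = unname(split(d$pos, grp))
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "kind", "member_pos")
}

#' Extract read segments over a calling region
#'
#' Clips every overlapping alignment to the region's reference coordinates
#' (so all segments share homogeneous breakpoints) and discards segments
#' whose aligned span covers less than `min_overlap` of the region.
#'
#' @param alignments Alignment tibble.
#' @param region List/one-row tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_overlap Minimum covered fraction of the region (default 0.5;
#'   a read covering exactly half is retained).
#' @return Tibble `read_id`, `seq`, `qual`, `overlap`, `spans`.
#' @export
extract_segments <- function(alignments, region, min_overlap = 0.5) {
  region <- as_block(region)
  aln <- dplyr::filter(alignments, .data$chrom == region$chrom)
  if (nrow(aln) > 0) {
    ref_end <- if ("end" %in% names(aln)) aln$end else
      aln$start + cigar_ref_width(aln$cigar)
    aln <- aln[aln$start < region$end & ref_end > region$start, ]
  }
  if (nrow(aln) == 0) {
    return(tibble::tibble(read_id = character(), seq = character(),
                          qual = character(), overlap = double(),
                          spans = logical()))
  }
  cl <- cpp_clip_reads(aln$seq, aln$qual, aln$start, aln$cigar,
                       region$start, region$end)
  out <- tibble::tibble(
    read_id = aln$read_id, seq = as.character(cl$seq),
    qual = as.character(cl$qual), overlap = cl$overlap, spans = cl$spans
  )
  dplyr::filter(out, .data$overlap >= min_overlap, nchar(.data$seq) > 0)
}

#' Partial-order alignment consensus of read segments
#'
#' Aligns the segments into a partial-order graph and extracts up to
#' `max_consensus` consensus haplotypes for a diploid sample. The heaviest
#' path by read-supported edge weight gives the primary consensus; segments
#' are then aligned back to it and the strongest recurrent difference
#' (a mismatch or indel signature shared by at least `min_support` segments
#' and 20% of the pile) splits the segments into carrier and non-carrier
#' clusters, each of which is re-consensused — recovering both haplotypes of
#' a heterozygous region regardless of phase. Each segment is assigned to
#' its best-fitting consensus to obtain read support; a consensus supported
#' by fewer than `min_support` segments is dropped (the top consensus is
#' always kept).
#'
#' @param segments Segment tibble from [extract_segments()] (needs >= 2
#'   rows; with fewer, callers fall back to the binomial pileup model).
#' @param max_consensus Maximum number of consensus sequences (default 2).
#' @param min_support Minimum supporting segments per consensus (default 3).
#' @param max_graph_reads Segments used per consensus graph (deepest regions
#'   are capped for speed; support is still computed from all segments).
#' @return Tibble `sequence`, `support`, `source = "POA"`, ordered by
#'   decreasing support.
#' @export
poa_consensus <- function(segments, max_consensus = 2, min_support = 3,
                          max_graph_reads = 40) {
  if (nrow(segments) < 2) {
    return(tibble::tibble(sequence = character(), support = integer(),
                          source = character()))
  }
  consensus_of <- function(seqs) {
    if (length(seqs) == 0) return(character(0))
    ord <- order(-nchar(seqs), seqs)
    cpp_poa_consensus(utils::head(seqs[ord], max_graph_reads))$cons[1]
  }
  spanners_first <- order(-segments$spans, -nchar(segments$seq), segments$seq)
  c1 <- consensus_of(segments$seq[spanners_first])
  cons <- c1
  if (max_consensus >= 2) {
    carriers <- discriminating_carriers(segments, c1, min_support)
    if (!is.null(carriers) && sum(!carriers) >= 2) {
      ca <- consensus_of(segments$seq[!carriers])
      cb <- consensus_of(segments$seq[carriers])
      cons <- unique(c(ca, cb))
    }
  }
  cons <- utils::head(cons, max_consensus)
  scores <- cpp_fit_scores(segments$seq, cons)
  best <- max.col(scores, ties.method = "first")
  support <- vapply(seq_along(cons), function(i) sum(best == i), integer(1))
  keep <- support >= min_support
  keep[which.max(support)] <- TRUE
  out <- tibble::tibble(sequence = cons[keep], support = support[keep],
                        source = "POA")
  dplyr::arrange(out, dplyr::desc(.data$support), .data$sequence)
}

# Align segments to the primary consensus and look for the strongest
# recurrent difference: a mismatch (same consensus position, same base) or
# an indel (same consensus anchor, same length) carried by >= min_support
# segments and >= 20% of them. Returns a logical carrier vector, or NULL
# when no such signature exists (homozygous pile; lone errors never recur).
discriminating_carriers <- function(segments, c1, min_support) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(2, -4, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(segments$seq), subject = c1,
    type = "global-local", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 2
  )
  n <- nrow(segments)
  keys <- list()
  mt <- Biostrings::mismatchTable(pa)
  if (nrow(mt) > 0) {
    keys[[1]] <- tibble::tibble(
      id = mt$PatternId,
      key = paste0("X:", mt$SubjectStart, ":", mt$SubjectEnd, ":",
                   as.character(mt$PatternSubstring))
    )
  }
  ins_l <- IRanges::start(Biostrings::insertion(pa))
  ins_w <- IRanges::width(Biostrings::insertion(pa))
  del_l <- IRanges::start(Biostrings::deletion(pa))
  del_w <- IRanges::width(Biostrings::deletion(pa))
  sstart <- Biostrings::start(Biostrings::subject(pa))
  ev <- which(lengths(ins_l) + lengths(del_l) > 0)
  for (j in ev) {
    # project pattern-space event anchors onto consensus coordinates
    ia <- ins_l[[j]]; iw <- ins_w[[j]]
    da <- del_l[[j]]; dw <- del_w[[j]]
    proj <- function(p) {
      ins_before <- sum(pmax(0, pmin(p - 1, ia + iw - 1) - ia + 1))
      del_before <- sum(dw[da < p])
      sstart[j] - 1 + (p - 1) - ins_before + del_before
    }
    k <- character(0)
    if (length(ia) > 0) {
      k <- c(k, vapply(seq_along(ia), function(e) {
        paste0("I:", proj(ia[e]), ":", iw[e])
      }, character(1)))
    }
    if (length(da) > 0) {
      k <- c(k, vapply(seq_along(da), function(e) {
        paste0("D:", proj(da[e]) + 1, ":", dw[e])
      }, character(1)))
    }
    keys[[length(keys) + 1]] <- tibble::tibble(id = j, key = k)
  }
  if (length(keys) == 0) return(NULL)
  tab <- dplyr::distinct(dplyr::bind_rows(keys))
  counts <- sort(table(tab$key), decreasing = TRUE)
  top <- counts[1]
  if (top < max(min_support, ceiling(0.2 * n))) return(NULL)
  seq_len(n) %in% tab$id[tab$key == names(top)]
}

#' Build a de Bruijn graph from reads and extract contigs
#'
#' Nodes are k-mers, edges are (k+1)-mers with coverage equal to their
#' multiplicity in the reads; k-mers containing non-ACGT characters are
#' dropped. Contigs are maximal paths found by depth-first search that takes
#' the highest-coverage edge first (ties broken towards the
#' lexicographically smaller k-mer); on cyclic graphs paths are truncated at
#' the first repeated node. A contig's score is the minimum edge coverage
#' along its path.
#'
#' @param reads Character vector of read sequences.
#' @param k Odd k-mer size (>= 11).
#' @param min_cov Minimum edge coverage kept in the graph (default 1).
#' @param max_paths Cap on enumerated paths.
#' @return List with `cyclic`, `n_nodes`, `n_edges`, and a `contigs` tibble
#'   (`sequence`, `score`).
#' @export
build_debruijn <- function(reads, k, min_cov = 1, max_paths = 32) {
  stopifnot(k >= 11)
  g <- cpp_debruijn(reads, as.integer(k), as.integer(min_cov),
                    as.integer(max_paths))
  list(
    cyclic = g$cyclic, n_nodes = g$n_nodes, n_edges = g$n_edges,
    contigs = tibble::tibble(sequence = as.character(g$contigs),
                             score = as.integer(g$scores))
  )
}

#' Assemble a reassembly window into haplotype contigs
#'
#' Iterates the k-mer size from `k_min` upwards by `k_step` while the de
#' Bruijn graph is cyclic; truncated contigs from a cyclic iteration are fed
#' to the next round as pseudoreads (each contributing edge weight 1). The
#' first acyclic graph yields the contigs; those spanning at least
#' `min_window_frac` of the window are ranked by score (minimum edge
#' coverage), then length, and the top `max_haplotypes` are returned. If
#' every k is cyclic or no contig spans the window, the window is
#' unassembleable and an empty tibble is returned with an attribute
#' `reason`.
#'
#' @param reads Character vector of full read sequences overlapping the
#'   window.
#' @param window_len Window length in bp (windows are roughly 300 bp).
#' @param k_min,k_max,k_step k-mer iteration schedule (defaults 41, 75, 5).
#' @param max_haplotypes Haplotypes to return (default 2).
#' @param min_cov Minimum edge coverage (default 3; also the minimum read
#'   support of an emitted haplotype).
#' @param min_window_frac Minimum fraction of the window a contig must span.
#' @return Tibble `sequence`, `support`, `source = "assembly"`. The full
#'   ranked contig set is attached as attribute `all_contigs`.
#' @export
assemble_window <- function(reads, window_len, k_min = 41, k_max = 75,
                            k_step = 5, max_haplotypes = 2, min_cov = 3,
                            min_window_frac = 0.5) {
  empty <- tibble::tibble(sequence = character(), support = integer(),
                          source = character())
  pseudo <- character(0)
  contigs <- NULL
  for (k in seq(k_min, k_max, by = k_step)) {
    g <- build_debruijn(c(reads, pseudo), k, min_cov = min_cov)
    if (!g$cyclic) {
      contigs <- g$contigs
      break
    }
    pseudo <- g$contigs$sequence
  }
  if (is.null(contigs)) {
    attr(empty, "reason") <- "cyclic_at_all_k"
    return(empty)
  }
  contigs <- contigs[nchar(contigs$sequence) >= min_window_frac * window_len, ]
  if (nrow(contigs) == 0) {
    attr(empty, "reason") <- "no_spanning_contig"
    return(empty)
  }
  contigs <- contigs[order(-contigs$score, -nchar(contigs$sequence),
                           contigs$sequence), ]
  out <- tibble::tibble(
    sequence = utils::head(contigs$sequence, max_haplotypes),
    support = utils::head(contigs$score, max_haplotypes),
    source = "assembly"
  )
  attr(out, "all_contigs") <- utils::head(contigs, 8)
  out
}

#' Realign haplotypes to the local reference and extract variants
#'
#' Globally aligns each consensus/contig against the reference segment
#' (affine gaps, haplotype fully aligned, free segment ends), walks the
#' alignment, and emits SNVs at mismatch columns and insertions/deletions at
#' gap runs. Indels are reported VCF-style (anchored at the reference base
#' before the event) and left-normalised. A haplotype whose alignment score
#' falls below `score_floor` times the maximum attainable score is rejected
#' as a misassembly.
#'
#' @param haplotypes Tibble `sequence`, `support` (from [poa_consensus()] or
#'   [assemble_window()]).
#' @param ref_segment Reference sequence of the region.
#' @param seg_start0 0-based genomic start of `ref_segment`.
#' @param chrom Chromosome name.
#' @param scoring [align_scoring()].
#' @param chrom_seq Full chromosome sequence (for left-normalisation across
#'   the segment edge; falls back to the segment when absent).
#' @param score_floor Fraction of the maximum attainable score below which a
#'   haplotype is rejected (default 0.25).
#' @return Tibble `chrom`, `pos` (1-based), `ref`, `alt`, `kind`
#'   (SNV/INS/DEL), `hap_support`; identical variants found in several
#'   haplotypes are collapsed with summed support.
#' @export
realign_and_call <- function(haplotypes, ref_segment, seg_start0, chrom,
                             scoring = align_scoring(), chrom_seq = NULL,
                             score_floor = 0.25) {
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          kind = character(), hap_support = integer())
  if (nrow(haplotypes) == 0 || nchar(ref_segment) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(haplotypes))) {
    hap <- haplotypes$sequence[i]
    if (nchar(hap) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = hap, subject = ref_segment, type = "global-local",
      substitutionMatrix = scoring$submat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
    )
    if (Biostrings::score(aln) < score_floor * scoring$match * nchar(hap)) next
    v <- walk_alignment(aln, seg_start0, chrom)
    if (nrow(v) == 0) next
    v$hap_support <- haplotypes$support[i]
    out[[length(out) + 1]] <- v
  }
  if (length(out) == 0) return(empty)
  vars <- dplyr::bind_rows(out)
  vars <- left_normalize(vars, chrom_seq = chrom_seq, ref_segment = ref_segment,
                         seg_start0 = seg_start0)
  vars |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$kind) |>
    dplyr::summarise(hap_support = sum(.data$hap_support), .groups = "drop") |>
    dplyr::arrange(.data$pos)
}

# walk a pairwise alignment, emitting raw (unnormalised) variants
walk_alignment <- function(aln, seg_start0, chrom) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  subj_off <- Biostrings::start(Biostrings::subject(aln)) - 1L # consumed before
  pos <- integer(0); refs <- character(0); alts <- character(0); kind <- character(0)
  ref_i <- subj_off
  k <- 1L
  n <- length(p)
  while (k <= n) {
    if (p[k] != "-" && s[k] != "-") {
      ref_i <- ref_i + 1L
      if (toupper(p[k]) != toupper(s[k])) {
        pos <- c(pos, seg_start0 + ref_i)
        refs <- c(refs, toupper(s[k])); alts <- c(alts, toupper(p[k]))
        kind <- c(kind, "SNV")
      }
      k <- k + 1L
    } else if (s[k] == "-") { # insertion in haplotype
      j <- k
      while (j <= n && s[j] == "-") j <- j + 1L
      ins <- paste(toupper(p[k:(j - 1L)]), collapse = "")
      if (ref_i >= 1L) { # needs an anchor base
        anchor <- toupper(s[which(s[seq_len(k - 1L)] != "-")][ref_i - subj_off])
        pos <- c(pos, seg_start0 + ref_i)
        refs <- c(refs, anchor); alts <- c(alts, paste0(anchor, ins))
        kind <- c(kind, "INS")
      }
      k <- j
    } else { # deletion in haplotype
      j <- k
      while (j <= n && p[j] == "-") j <- j + 1L
      del <- paste(toupper(s[k:(j - 1L)]), collapse = "")
      if (ref_i >= 1L) {
        anchor <- toupper(s[which(s[seq_len(k - 1L)] != "-")][ref_i - subj_off])
        pos <- c(pos, seg_start0 + ref_i)
        refs <- c(refs, paste0(anchor, del)); alts <- c(alts, anchor)
        kind <- c(kind, "DEL")
      }
      ref_i <- ref_i + (j - k)
      k <- j
    }
  }
  tibble::tibble(chrom = chrom, pos = pos, ref = refs, alt = alts, kind = kind)
}

#' Left-normalise variants against the reference
#'
#' Shifts indels to their leftmost equivalent position and trims shared
#' allele bases, producing the canonical VCF representation. SNVs are
#' unchanged.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` (and any other
#'   columns, preserved).
#' @param ref Reference (named sequences); alternatively supply `chrom_seq`
#'   (single chromosome sequence) or a `ref_segment` + `seg_start0` pair.
#' @param chrom_seq,ref_segment,seg_start0 See above.
#' @return The tibble with normalised `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(variants, ref = NULL, chrom_seq = NULL,
                           ref_segment = NULL, seg_start0 = 0) {
  if (nrow(variants) == 0) return(variants)
  get_base <- function(chrom, p) {
    if (!is.null(chrom_seq)) return(substring(chrom_seq, p, p))
    if (!is.null(ref)) return(substring(ref_chrom(ref, chrom), p, p))
    # fall back to the segment; positions left of it stop the shift
    sp <- p - seg_start0
    if (sp < 1) return("")
    substring(ref_segment, sp, sp)
  }
  if (!is.null(ref)) ref <- as_reference(ref)
  for (i in seq_len(nrow(variants))) {
    r <- variants$ref[i]; a <- variants$alt[i]; p <- variants$pos[i]
    if (nchar(r) == 1 && nchar(a) == 1) next
    repeat {
      rl <- nchar(r); al <- nchar(a)
      if (rl == 0 || al == 0 ||
          substring(r, rl, rl) != substring(a, al, al)) break
      if (rl == 1 || al == 1) {
        # shifting left: prepend the previous reference base, drop the last
        b <- get_base(variants$chrom[i], p - 1L)
        if (b == "" || p <= 1L) break
        r <- paste0(b, substring(r, 1, rl - 1L))
        a <- paste0(b, substring(a, 1, al - 1L))
        p <- p - 1L
      } else {
        r <- substring(r, 1, rl - 1L)
        a <- substring(a, 1, al - 1L)
      }
    }
    while (nchar(r) >= 2 && nchar(a) >= 2 &&
           substring(r, 1, 1) == substring(a, 1, 1)) {
      r <- substring(r, 2); a <- substring(a, 2)
      p <- p + 1L
    }
    variants$ref[i] <- r; variants$alt[i] <- a; variants$pos[i] <- p
  }
  variants
}
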