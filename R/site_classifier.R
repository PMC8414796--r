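#' Load tandem-repeat / low-complexity annotations from BED files
#'
#' Reads one or more BED files (chrom, start, end; 0-based half-open),
#' takes their union, and merges overlapping intervals per chromosome.
#'
#' @param bed_paths Character vector of BED file paths.
#' @return A `GRanges` with merged intervals (empty when no paths given).
#' @export
load_annotation <- function(bed_paths) {
  if (length(bed_paths) == 0) return(GenomicRanges::GRanges())
  parts <- lapply(bed_paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    if (length(lines) == 0) return(GenomicRanges::GRanges())
    fields <- strsplit(lines, "\t")
    bad <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(bad) > 0) {
      stop("malformed BED line ", bad[1], " in ", p, call. = FALSE)
    }
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
    if (anyNA(start) || anyNA(end)) {
      stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ", p,
           call. = FALSE)
    }
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  })
  GenomicRanges::reduce(do.call(c, parts))
}

# annotation argument -> GRanges (accepts GRanges, a 0-based half-open
# tibble with chrom/start/end, bed path(s), or NULL)
as_annotation <- function(annotation) {
  if (is.null(annotation)) return(GenomicRanges::GRanges())
  if (methods::is(annotation, "GRanges")) return(GenomicRanges::reduce(annotation))
  if (is.character(annotation)) return(load_annotation(annotation))
  if (is.data.frame(annotation)) {
    if (nrow(annotation) == 0) return(GenomicRanges::GRanges())
    return(GenomicRanges::reduce(GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(annotation$start + 1L, annotation$end)
    )))
  }
  stop("unsupported annotation type", call. = FALSE)
}

#' Classify candidate sites into HC, LC and TRC categories
#'
#' Applies the three-way triage. A site inside an annotated tandem-repeat or
#' low-complexity region is a TRC regardless of its other properties. A site
#' outside those regions is a high-confidence candidate (HC) when its top
#' allele frequency is strictly above 0.5, it is not multi-allelic, no other
#' candidate lies within `flank` bp on the same chromosome, and — for indel
#' alleles — the supporting inserted/deleted sequences are not divergent
#' (a single sequence accounts for more than `1 - divergence_max` of the
#' allele's supporting reads). Everything else is a low-confidence candidate
#' (LC); in particular a site with frequency above 0.5 still becomes LC when
#' another candidate sits within the flank window.
#'
#' @param candidates Candidate tibble from [detect_candidates()], sorted by
#'   position within each chromosome.
#' @param annotation Repeat/LCR annotation: `GRanges`, BED path(s), a 0-based
#'   `chrom`/`start`/`end` tibble, or `NULL` for none.
#' @param flank Proximity window in bp (default 100).
#' @param divergence_max An indel allele is "divergent" when no single
#'   supporting sequence exceeds this fraction of its supporting reads
#'   (default 0.5).
#' @return The input tibble with added columns `category` (factor HC/LC/TRC),
#'   `in_repeat`, `has_neighbor`, `indel_divergent`.
#' @export
classify_sites <- function(candidates, annotation = NULL, flank = 100,
                           divergence_max = 0.5) {
  if (nrow(candidates) == 0) {
    candidates$category <- character(0)
    return(candidates)
  }
  chrom_f <- factor(candidates$chrom, levels = unique(candidates$chrom))
  contiguous <- length(rle(as.integer(chrom_f))$lengths) == nlevels(chrom_f)
  if (!contiguous ||
      any(vapply(split(candidates$pos, chrom_f), is.unsorted, logical(1)))) {
    stop("candidate sites must be sorted by position", call. = FALSE)
  }
  ann <- as_annotation(annotation)
  sites_gr <- GenomicRanges::GRanges(
    candidates$chrom, IRanges::IRanges(candidates$pos, candidates$pos)
  )
  in_repeat <- IRanges::overlapsAny(sites_gr, ann)

  has_neighbor <- unlist(lapply(
    split(candidates$pos, chrom_f),
    function(p) {
      if (length(p) == 1) return(FALSE)
      gap_prev <- c(Inf, diff(p))
      gap_next <- c(diff(p), Inf)
      gap_prev <= flank | gap_next <= flank
    }
  ), use.names = FALSE)

  indel_divergent <- mapply(function(top, ins, del) {
    if (!top %in% c("I", "D")) return(FALSE)
    seqs <- if (top == "I") ins else del
    if (length(seqs) == 0) return(TRUE)
    max(table(seqs)) / length(seqs) <= divergence_max
  }, candidates$top_alt, candidates$ins_seqs, candidates$del_seqs,
  USE.NAMES = FALSE)

  hc <- !in_repeat & candidates$top_freq > 0.5 & !candidates$is_multiallele &
    !has_neighbor & !indel_divergent
  category <- dplyr::case_when(in_repeat ~ "TRC", hc ~ "HC", TRUE ~ "LC")
  dplyr::mutate(
    candidates,
    in_repeat = in_repeat,
    has_neighbor = has_neighbor,
    indel_divergent = indel_divergent,
    category = category
  )
}
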