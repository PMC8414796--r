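#' Alternative allele frequencies at pileup positions
#'
#' Computes, for every non-reference allele label with a positive count, the
#' frequency `P_alt = c_alt / T`, where `T` is the total number of
#' observations at the position (the sum of the V counts).
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @return A long tibble with columns `chrom`, `pos`, `allele`, `count`,
#'   `freq`; positions with `T = 0` or no alternative observations yield no
#'   rows.
#' @export
allele_frequencies <- function(pileup) {
  labels <- c("A", "C", "G", "T", "N", "I", "D")
  m <- as.matrix(pileup[, labels])
  T <- as.integer(rowSums(m))
  ref_col <- match(pileup$ref_base, labels)
  ref_col[is.na(ref_col)] <- 5L # non-ACGT reference treated as N
  idx <- cbind(seq_len(nrow(m)), ref_col)
  alt <- m
  alt[idx] <- 0L
  hits <- which(alt > 0 & T > 0, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          allele = character(), count = integer(),
                          freq = double()))
  }
  tibble::tibble(
    chrom = pileup$chrom[hits[, 1]],
    pos = pileup$pos[hits[, 1]],
    allele = labels[hits[, 2]],
    count = alt[hits],
    freq = alt[hits] / T[hits[, 1]]
  ) |>
    dplyr::arrange(.data$pos, .data$allele)
}

#' Detect candidate variant sites from pileup summaries
#'
#' A position becomes a candidate site when at least one alternative allele
#' has frequency `P_alt = c_alt/T` strictly above the detection threshold
#' (`snv_min_af` for base alleles, `indel_min_af` for I/D). All alleles
#' exceeding their threshold are recorded; more than one makes the site
#' multi-allelic. Sites are then screened by the mean alternative base
#' quality `BQ_ave = S/N` (`N` = number of alternative base observations,
#' i.e. mismatches plus insertions; deletions carry no base) and dropped
#' when `BQ_ave < min_bq`. `N` base calls never count as alternative
#' alleles.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param snv_min_af,indel_min_af Detection thresholds on `P_alt` for base
#'   and indel alleles (defaults 0.2 and 0.125).
#' @param min_bq Minimum `BQ_ave` (default 20). Set `NULL` to skip the
#'   filter, e.g. when the input has no base qualities.
#' @param min_depth Minimum total observations `T` to consider a site.
#' @return A tibble with one row per candidate site: `chrom`, `pos`,
#'   `ref_base`, `T`, `depth`, `S`, `bq_ave`, `is_multiallele`, list-columns
#'   `alt_allele`, `alt_count`, `alt_freq` (ordered by decreasing count),
#'   `top_alt`, `top_count`, `top_freq`, and the supporting indel sequences
#'   `ins_seqs` / `del_seqs`.
#' @export
detect_candidates <- function(pileup, snv_min_af = 0.2, indel_min_af = 0.125,
                              min_bq = 20, min_depth = 4) {
  stopifnot(snv_min_af > 0, snv_min_af < 1, indel_min_af > 0, indel_min_af < 1)
  if (isTRUE(attr(pileup, "qual_missing"))) min_bq <- NULL
  labels <- c("A", "C", "G", "T", "N", "I", "D")
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref_base = character(),
    ref_count = integer(),
    total = integer(), depth = integer(), S = integer(), bq_ave = double(),
    is_multiallele = logical(), alt_allele = list(), alt_count = list(),
    alt_freq = list(), top_alt = character(), top_count = integer(),
    top_freq = double(), ins_seqs = list(), del_seqs = list()
  )
  if (nrow(pileup) == 0) return(empty)
  m <- as.matrix(pileup[, labels])
  T <- as.integer(rowSums(m))
  ref_col <- match(pileup$ref_base, labels)
  ref_col[is.na(ref_col)] <- 5L
  alt <- m
  alt[cbind(seq_len(nrow(m)), ref_col)] <- 0L
  alt[, "N"] <- 0L
  thr <- matrix(rep(c(rep(snv_min_af, 5), rep(indel_min_af, 2)),
                    each = nrow(m)), nrow = nrow(m))
  pass <- alt > 0 & T >= min_depth & (alt / pmax(T, 1L)) > thr
  site_rows <- which(rowSums(pass) > 0)
  if (length(site_rows) == 0) return(empty)

  sub <- pileup[site_rows, ]
  alt_sub <- alt[site_rows, , drop = FALSE]
  pass_sub <- pass[site_rows, , drop = FALSE]
  T_sub <- T[site_rows]
  # N: alternative base observations (mismatching bases + insertions)
  n_alt <- as.integer(
    T_sub - m[site_rows, , drop = FALSE][cbind(seq_along(site_rows), ref_col[site_rows])] -
      m[site_rows, "D"] - m[site_rows, "N"] * (ref_col[site_rows] != 5L)
  )
  bq_ave <- ifelse(n_alt > 0, sub$S / pmax(n_alt, 1L), NA_real_)

  picks <- lapply(seq_along(site_rows), function(i) {
    k <- which(pass_sub[i, ])
    k <- k[order(-alt_sub[i, k], labels[k])]
    list(allele = labels[k], count = as.integer(alt_sub[i, k]),
         freq = alt_sub[i, k] / T_sub[i])
  })
  out <- tibble::tibble(
    chrom = sub$chrom,
    pos = sub$pos,
    ref_base = sub$ref_base,
    ref_count = as.integer(
      m[site_rows, , drop = FALSE][cbind(seq_along(site_rows), ref_col[site_rows])]
    ),
    total = T_sub,
    depth = sub$depth,
    S = sub$S,
    bq_ave = bq_ave,
    is_multiallele = vapply(picks, function(p) length(p$allele) > 1L, logical(1)),
    alt_allele = lapply(picks, `[[`, "allele"),
    alt_count = lapply(picks, `[[`, "count"),
    alt_freq = lapply(picks, `[[`, "freq"),
    top_alt = vapply(picks, function(p) p$allele[1], character(1)),
    top_count = vapply(picks, function(p) p$count[1], integer(1)),
    top_freq = vapply(picks, function(p) p$freq[1], double(1)),
    ins_seqs = sub$ins_seqs,
    del_seqs = sub$del_seqs
  )
  if (!is.null(min_bq)) {
    out <- dplyr::filter(out, is.na(.data$bq_ave) | .data$bq_ave >= min_bq)
  }
  out
}
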