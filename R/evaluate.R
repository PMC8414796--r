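#' Evaluate a callset against a truth set
#'
#' Left-normalises both sides, then matches records exactly on
#' (chrom, pos, ref, alt). In genotype-aware mode (default) a matched record
#' whose unphased genotype disagrees counts as both a false positive and a
#' false negative, mirroring genotype-aware benchmarking tools. Precision,
#' recall and F1 (harmonic mean) are reported per variant type (SNV, INDEL)
#' and overall; an empty denominator yields 0 by convention.
#'
#' @param calls Call tibble (`chrom`, `pos`, `ref`, `alt`, `genotype`;
#'   a `filter` column, when present, restricts evaluation to PASS calls
#'   unless `pass_only = FALSE`).
#' @param truth Truth tibble (`chrom`, `pos`, `ref`, `alt`, `genotype`,
#'   phased or unphased).
#' @param ref Reference sequences for normalisation (optional but
#'   recommended when either side is not yet normalised).
#' @param genotype_aware Require matching genotypes (default TRUE).
#' @param pass_only Evaluate PASS calls only (default TRUE).
#' @return A `shortcall_eval` tibble: `type`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_calls <- function(calls, truth, ref = NULL, genotype_aware = TRUE,
                           pass_only = TRUE) {
  if (pass_only && "filter" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$filter == "PASS")
  }
  norm <- function(d) {
    d <- tibble::as_tibble(d)[, intersect(
      c("chrom", "pos", "ref", "alt", "genotype"), names(d)
    )]
    if (!"genotype" %in% names(d)) d$genotype <- "./."
    if (!is.null(ref)) d <- left_normalize(d, ref = ref)
    d$genotype <- unphase(d$genotype)
    d$vtype <- ifelse(nchar(d$ref) == 1 & nchar(d$alt) == 1, "SNV", "INDEL")
    d$key <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    dplyr::distinct(d, .data$key, .keep_all = TRUE)
  }
  c_n <- norm(calls)
  t_n <- norm(truth)
  m <- match(c_n$key, t_n$key)
  matched <- !is.na(m)
  gt_ok <- matched & (!genotype_aware | c_n$genotype == t_n$genotype[m])

  per_type <- function(ty) {
    in_c <- if (ty == "ALL") rep(TRUE, nrow(c_n)) else c_n$vtype == ty
    in_t <- if (ty == "ALL") rep(TRUE, nrow(t_n)) else t_n$vtype == ty
    tp <- sum(in_c & gt_ok)
    fp <- sum(in_c & !gt_ok)
    truth_hit <- rep(FALSE, nrow(t_n))
    truth_hit[m[gt_ok & !is.na(m)]] <- TRUE
    fn <- sum(in_t & !truth_hit)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(type = ty, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1)
  }
  out <- dplyr::bind_rows(lapply(c("SNV", "INDEL", "ALL"), per_type))
  tibble::new_tibble(out, class = "shortcall_eval")
}

# "1|0"/"0|1" -> "0/1"; leaves unphased genotypes alone
unphase <- function(gt) {
  parts <- strsplit(gsub("\\|", "/", gt), "/")
  vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
}
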