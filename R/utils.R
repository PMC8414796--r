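# Internal helpers shared across modules.

# log10-sum-exp, numerically stable
log10_sum <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

# Normalise a reference argument to a named character vector of chromosome
# sequences. Accepts a named character vector, a Biostrings::DNAStringSet, or
# a path to a FASTA file.
as_reference <- function(ref) {
  if (is.character(ref) && length(ref) == 1 && file.exists(ref) &&
      !grepl("^[ACGTNacgtn]+$", ref)) {
    ref <- Biostrings::readDNAStringSet(ref)
  }
  if (methods::is(ref, "DNAStringSet")) {
    out <- as.character(ref)
    names(out) <- sub("\\s.*$", "", names(ref))
    return(out)
  }
  if (is.character(ref)) {
    if (is.null(names(ref)) || any(names(ref) == "")) {
      stop("reference sequences must be named by chromosome", call. = FALSE)
    }
    return(toupper(ref))
  }
  stop("unsupported reference type", call. = FALSE)
}

ref_chrom <- function(ref, chrom) {
  if (!chrom %in% names(ref)) stop("chromosome '", chrom, "' not in reference", call. = FALSE)
  ref[[chrom]]
}

# tibble of chromosome names and lengths
ref_index <- function(ref) {
  ref <- as_reference(ref)
  tibble::tibble(chrom = names(ref), length = nchar(unname(ref)))
}

# Normalise a block argument (one-row tibble or list with chrom/start/end,
# 0-based half-open) to a plain list.
as_block <- function(block) {
  if (is.data.frame(block)) {
    stopifnot(nrow(block) == 1)
    block <- as.list(block)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(block)))
  if (block$start < 0 || block$end <= block$start) {
    stop("invalid block: need 0 <= start < end", call. = FALSE)
  }
  block
}

phred_char <- function(q) intToUtf8(pmin(q, 93) + 33, multiple = FALSE)

qual_ints <- function(qual_string) {
  if (is.na(qual_string) || qual_string == "" || qual_string == "*") return(integer(0))
  utf8ToInt(qual_string) - 33L
}

# reference span of a CIGAR (M/D/N/=/X), vectorised
cigar_ref_width <- function(cigar) {
  cpp_cigar_ref_width(cigar)
}

random_seed_below_2_31 <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
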