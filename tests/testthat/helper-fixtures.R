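# Shared fixtures: in-code alignment builders, tiny references, and
# independent oracles used across the suite.

# one alignment record; base qualities default to Q40 ("I")
aln_rec <- function(start, cigar, seq, qual = strrep("I", nchar(seq)),
                    chrom = "chr1", mapq = 60L, flag = 0L,
                    id = paste0("r", start, "_", cigar)) {
  tibble::tibble(read_id = id, chrom = chrom, start = as.integer(start),
                 mapq = as.integer(mapq), flag = as.integer(flag),
                 cigar = cigar, seq = unname(seq), qual = unname(qual))
}

# deterministic random reference as a named vector
tiny_ref <- function(len, seed = 42, chrom = "chr1") {
  withr::with_seed(seed, {
    setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), chrom)
  })
}

# error-free reads tiled over a sequence every `step` bp
tile_reads <- function(seq, read_len = 100, step = 5, start0 = 0,
                       chrom = "chr1") {
  starts <- seq(1, nchar(seq) - read_len + 1, by = step)
  dplyr::bind_rows(lapply(starts, function(s) {
    aln_rec(start0 + s - 1, paste0(read_len, "M"),
            substring(seq, s, s + read_len - 1),
            id = paste0("t", s))
  }))
}

# a minimal one-row pileup for candidate tests
pileup_row <- function(pos, ref_base, counts, S = 0L, ins = NULL, del = NULL,
                       chrom = "chr1") {
  base <- list(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L, I = 0L, D = 0L)
  base[names(counts)] <- lapply(counts, as.integer)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref_base = ref_base,
    A = base$A, C = base$C, G = base$G, T = base$T, N = base$N,
    I = base$I, D = base$D, S = as.integer(S),
    total = sum(unlist(base)),
    depth = sum(unlist(base)[1:5]),
    ins_seqs = list(ins), del_seqs = list(del)
  )
}

# brute-force all-pairs callset/truth matcher: the independent oracle for
# the evaluator (per-record loops, no joins)
brute_eval <- function(calls, truth, genotype_aware = TRUE) {
  unph <- function(g) {
    p <- sort(strsplit(gsub("\\|", "/", g), "/")[[1]])
    paste(p, collapse = "/")
  }
  ckey <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  tp <- 0L; fp <- 0L
  hit <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(calls))) {
    j <- which(tkey == ckey[i])
    if (length(j) == 1 &&
        (!genotype_aware || unph(calls$genotype[i]) == unph(truth$genotype[j]))) {
      tp <- tp + 1L
      hit[j] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  fn <- sum(!hit)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}

# iterative left-shift oracle for pure indel normalisation: shift the event
# one base left while the flanking base allows it, then pad
shift_oracle <- function(pos, ref, alt, chrom_seq) {
  event <- if (nchar(ref) > nchar(alt)) substring(ref, 2) else substring(alt, 2)
  is_del <- nchar(ref) > nchar(alt)
  repeat {
    prev <- substring(chrom_seq, pos, pos) # current anchor base
    last <- substring(event, nchar(event), nchar(event))
    if (pos <= 1 || last != prev) break
    event <- paste0(prev, substring(event, 1, nchar(event) - 1))
    pos <- pos - 1
  }
  anchor <- substring(chrom_seq, pos, pos)
  if (is_del) list(pos = pos, ref = paste0(anchor, event), alt = anchor)
  else list(pos = pos, ref = anchor, alt = paste0(anchor, event))
}
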