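---
title: "Triaged short-read variant calling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triaged short-read variant calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortcall)
```

## The problem and the approach

Germline SNVs and short indels (< 50 bp) leave characteristic divergences
between aligned short reads and the reference: mismatched bases and
insertion/deletion operations in the CIGAR strings. Most such sites are
easy — deep, clean pileups where a direct count-based model suffices — while
a minority carry complex signatures: clustered variants, ambiguous indel
representations, or repeat-induced misalignment. shortcall exploits this
asymmetry. It summarises the pileup at every position, recognises candidate
sites, and triages them three ways:

* **HC** (high-confidence): a single alternative allele with frequency
  strictly above 0.5, no other candidate within 100 bp, outside annotated
  repeat/low-complexity regions, and (for indels) concordant supporting
  sequences. These are called directly with a binomial genotype model.
* **LC** (low-confidence): everything else outside annotated repeats —
  minority-frequency alleles, multi-allelic sites, clustered candidates,
  divergent indel support. Nearby LC sites are merged, overlapping read
  segments are clipped to the region and collapsed into one or two consensus
  haplotypes by partial-order alignment (POA), and variants are read off a
  realignment of the consensus against the local reference.
* **TRC** (tandem-repeat / low-complexity): any candidate inside the
  annotation, regardless of its other properties. Alignment evidence there
  is unreliable, so ~300 bp windows are locally re-assembled with a de
  Bruijn graph and the resulting contigs are realigned like LC consensuses.

Calls from all three paths are integrated, deduplicated by quality, and
written as VCF 4.2.

## Pileup summary and candidate recognition

For every reference position the pileup summary holds the allele-count map
`V` over labels `A,C,G,T,N,I,D`, the accumulated alternative base quality
`S`, and the inserted/deleted sequences `L`. A read whose CIGAR shows an
indel anchored at the position contributes to `I`/`D` *instead of* the
anchor's base count, so the total `T = sum(V)` counts one observation per
read and allele frequencies are comparable across SNVs and indels. Indels
are anchored at the last reference base before the event (VCF convention);
deleted positions contribute spanning depth but no base observation, and
soft-clipped bases contribute nothing.

A site is a candidate when some alternative allele has
`P_alt = c_alt / T` strictly above a detection threshold. The threshold
defaults differ by allele class — 0.2 for base alleles and 0.125 for
indels — conservative pileup-caller conventions chosen so that the 0.5
majority rule, not the detection threshold, governs triage (the method's
description leaves the numeric value open, so it is exposed as
`--snv-min-af` / `--indel-min-af`). Sites with mean alternative base
quality `BQ_ave = S/N < 20` are discarded; `N` counts mismatching bases
plus insertions (a deletion has no base to contribute), `N` base calls are
never alternative alleles, and the filter is skipped when the input has no
base qualities. A minimum of 4 observations is required — genotyping below
that depth is uninformative.

## Genotype models

**Binomial (HC).** With `sr_ref` and `sr_alt` reads supporting the two
alleles, a misassignment probability ε (default 0.03) and a heterozygous
prior of 1/3 (equal priors over the three diploid genotypes):

$$L(0/0) = \tfrac{1-prior}{2}\,(1-\varepsilon)^{sr_{ref}}\varepsilon^{sr_{alt}},\quad
  L(0/1) = prior\,(1/2)^{sr_{ref}+sr_{alt}},\quad
  L(1/1) = \tfrac{1-prior}{2}\,(1-\varepsilon)^{sr_{alt}}\varepsilon^{sr_{ref}}$$

evaluated in log space (linear- and log-space evaluation agree to 1e-9
relative error through depth 60 — part of the test suite). Posteriors are
the normalised joint terms.

**Bayesian read-likelihood (LC/TRC).** For each discovered variant the
local reference and alternative haplotypes are built over a ±50 bp context;
every overlapping read segment is aligned to both with affine gaps. The
haploid likelihood is $\Pr(R|H) = 10^{-\sum_e Q_e/10}$ over the Phred
qualities of the alignment's mismatches, with each indel event contributing
the quality of its first affected read base (the method prescribes
"mismatches and nearby indels" without a formula; this is our
operationalisation). Reads combine per genotype as
$\Pr(R|G) = \prod_j \left(\tfrac{1}{2}\Pr(R_j|H_1) + \tfrac{1}{2}\Pr(R_j|H_2)\right)$
and posteriors follow Bayes rule with equal priors. When base qualities
are absent the binomial count model substitutes.

**Quality and ties.** The reported QUAL/GQ is
`-10·log10(1 - max posterior)` capped at 60 — the source method never
defines a quality, so this is our documented choice, as is the
deterministic tie-break (0/1, then 0/0, then 1/1: the variant-aware
conservative call). Calls below Phred 15 are tagged `LowQual` but kept.

## POA consensus and the two-haplotype split

Segments clipped to an LC region (homogeneous breakpoints; segments
covering less than half the region are discarded, exactly half is kept)
are threaded one by one into a partial-order graph; read-vs-graph
alignment is "fitting" (read global, graph ends free), so partial segments
reinforce only their span. The primary consensus is the heaviest path by
accumulated edge weight.

A diploid region needs up to two consensuses. Re-running the heaviest path
after down-weighting the first path proved fragile (with many weight-1
error branches the alternate path can wander), so the implementation
clusters instead: all segments are aligned back to the primary consensus,
and the strongest *recurrent* difference — the same mismatch base at the
same consensus position, or an indel of the same length at the same
anchor, carried by at least 3 segments and 20% of the pile — splits the
segments into carriers and non-carriers. Each cluster is re-consensused.
This recovers both haplotypes regardless of the phase of nearby
heterozygous variants, while lone sequencing errors (which never recur at
the same place) produce no split. Consensus support is the number of
segments fitting each consensus best; a consensus below 3 supporting
segments is dropped.

## De Bruijn local assembly

TRC windows (~300 bp; consecutive TRC sites are packed greedily and padded
symmetrically) are assembled from all overlapping reads. Nodes are k-mers
and edges (k+1)-mers with their read multiplicity as coverage; edges below
coverage 3 are pruned, which removes sequencing-error tips at 40x. The
k-mer length starts at 41 and grows by 5 up to 75 while the graph remains
cyclic; truncated contigs from a cyclic round are re-injected as
pseudoreads (weight 1) for the next round. Contigs are extracted by
depth-first search taking the highest-coverage edge first
(lexicographically smaller k-mer on ties — determinism where the method's
description leaves the order open), scored by their minimum edge coverage.
The top two contigs become the window haplotypes; because ranked ties
among bubble combinations can hide an allele, variant extraction inspects
the full ranked contig set (up to 8) and leaves the read-based genotyper
to reject unsupported alleles — a genotype of 0/0 drops the variant.
Windows that stay cyclic through k = 75, or yield no contig spanning half
the window, are reported unassembleable and emit no calls: short tandem
repeats longer than the largest k cannot be resolved by this method (its
known recall limitation on repeat-rich indels).

## Realignment and normalisation

Consensus/contig sequences are aligned to the local reference with affine
gaps (match +2, mismatch −6, gap-open 6, gap-extend 1 — a mismatch costs
more than opening a gap, so a genuine short deletion is not re-written as
a run of mismatches). Mismatch columns yield SNVs and gap runs yield
padded indels, which are left-normalised against the chromosome; a
haplotype scoring below 25% of its maximum attainable score is rejected
as misassembly. Normalisation is property-tested against an independent
iterative-shift oracle.

## Orchestration

The reference is split into fixed-size blocks (default 20 Mb). Each block
runs the whole per-block pipeline independently — the parallelism contract
is "no shared mutable state, deterministic merge", satisfied by both the
serial and the forked executor. Detection and classification use a 500 bp
margin around the block so proximity windows, LC merges, and TRC windows
do not depend on where block boundaries fall; only calls anchored inside
the block proper are emitted, and integration collapses any residual
duplicate (chrom, pos, ref, alt) records keeping the higher quality (ties
prefer the HC record, then first seen). Final calls are block-size and
worker-count invariant — asserted in the test suite. As a memory guard,
blocks implying more than 1000x coverage are uniformly downsampled with a
fixed seed (a read-level simplification of a per-position cap; it only
engages on pathological pileups).

## The synthetic world

The simulator reproduces the evaluation design the method was published
with, scaled to desk size:

* a 1 Mb random reference (GC 0.5) with 20 planted short tandem repeats
  (unit 2–6 bp, tract ≤ 60 bp — STR-scale, resolvable at k ≤ 75; longer
  tracts would only exercise the documented unassembleable path);
* SNVs at ~1/900 bp and indels at ~1/5800 bp — the densities implied by
  269,554 SNVs and 42,136 indels on a ~243 Mb human chromosome — with 2/3
  heterozygous (a typical human het:hom ratio; the source does not state
  one), phases assigned uniformly, indel lengths geometric capped at 49 bp,
  and at least 2 bp between reference spans;
* two 20x paired-end read sets (one per haplotype) merged to 40x, read
  length 150 or 250, insert 500 ± 50 bp, substitution errors at 0.2%;
  base qualities are constant and Phred-consistent with the error rate
  (Q27 at 0.2%; Q30 when error-free) — the stated "Q30 baseline" and the
  stated 0.2% error rate cannot both hold, and consistency with the error
  rate is what the likelihood model assumes;
* reads are placed at their *true* coordinates with exact CIGARs (reads
  starting or ending inside an insertion are soft-clipped, as an aligner
  would do), so the pileup has a known ground truth without an external
  aligner. Mapping ambiguity is emulated by assigning MAPQ 0–10 to reads
  fully contained in a planted repeat, exercising the MAPQ filter.

What a green end-to-end test establishes, therefore, is that the caller
recovers exactly placed, uniformly covered variants at the published
operating point. It does not establish robustness to real aligner errors,
coverage biases, PCR duplicates, or machine-specific error profiles — the
published real-data benchmarks (GIAB samples, whole-genome alignments) and
all runtime comparisons are out of scope for this desk-scale build.

The evaluator matches calls to truth exactly on (chrom, pos, ref, alt)
after left-normalising both sides, genotype-aware by default (a matched
record with the wrong genotype counts as FP *and* FN), and reports
precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1 per
variant type, with 0 for empty denominators. It is property-tested against
a brute-force all-pairs matcher.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(length = 1e5, seed = 7)
calls <- call_variants(ref = sim$ref, alignments = sim$alignments,
                       annotation = sim$repeats)
glance(calls)
evaluate_calls(calls, sim$truth, ref = sim$ref)
autoplot(calls)
```

## Known limitations

* Repeats whose period times copy number exceeds the largest k-mer (75)
  are unassembleable by design; variants inside them are missed, mirroring
  the method's published indel-recall ceiling.
* The POA two-haplotype split keys on the single strongest recurrent
  difference; three or more genuine local haplotypes (e.g. somatic
  subclones) are out of scope.
* Multi-allelic sites are genotyped against the strongest alternative
  allele per record; allele pairs at one site emerge as separate records
  rather than one multi-allelic row.
* The caller assumes a diploid individual throughout.
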