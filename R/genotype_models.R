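#' Genotype model parameters
#'
#' @param eps Probability that a read is assigned to the wrong allele
#'   (default 0.03).
#' @param prior Prior probability of the heterozygous genotype (default 1/3,
#'   which makes the three genotype priors equal).
#' @param qual_cap Cap on the Phred-scaled genotype quality (default 60).
#' @return A list of validated parameters.
#' @export
model_params <- function(eps = 0.03, prior = 1 / 3, qual_cap = 60) {
  stopifnot(eps > 0, eps < 0.5, prior > 0, prior < 1, qual_cap > 0)
  list(eps = eps, prior = prior, qual_cap = qual_cap)
}

#' Binomial genotype likelihoods from allele-supporting read counts
#'
#' For a diploid site with `sr_ref` reads supporting the reference allele and
#' `sr_alt` the alternative allele, computes
#' \deqn{L(0/0) = \frac{1-prior}{2}(1-\epsilon)^{sr_{ref}}\epsilon^{sr_{alt}}}
#' \deqn{L(0/1) = prior \cdot (1/2)^{sr_{ref}+sr_{alt}}}
#' \deqn{L(1/1) = \frac{1-prior}{2}(1-\epsilon)^{sr_{alt}}\epsilon^{sr_{ref}}}
#' in log space, normalises them into posteriors, and reports the
#' maximum-posterior genotype with a Phred-scaled quality
#' `-10 log10(1 - max posterior)` capped at `params$qual_cap`. Exact posterior
#' ties prefer 0/1, then 0/0, then 1/1.
#'
#' @param sr_ref,sr_alt Integer vectors of supporting read counts
#'   (recycled; each pair must have a positive total).
#' @param params [model_params()].
#' @return A tibble with columns `L00`, `L01`, `L11` (linear-scale, may
#'   underflow at extreme depth), `p00`, `p01`, `p11`, `genotype`, `qual`.
#' @export
binomial_likelihoods <- function(sr_ref, sr_alt, params = model_params()) {
  n <- max(length(sr_ref), length(sr_alt))
  sr_ref <- rep_len(sr_ref, n)
  sr_alt <- rep_len(sr_alt, n)
  if (any(sr_ref + sr_alt <= 0)) stop("sr_ref + sr_alt must be > 0", call. = FALSE)
  xlog <- function(k, p) ifelse(k == 0, 0, k * log10(p)) # 0 * log(0) := 0
  hom_coef <- log10((1 - params$prior) / 2)
  l00 <- hom_coef + xlog(sr_ref, 1 - params$eps) + xlog(sr_alt, params$eps)
  l01 <- log10(params$prior) + (sr_ref + sr_alt) * log10(0.5)
  l11 <- hom_coef + xlog(sr_alt, 1 - params$eps) + xlog(sr_ref, params$eps)
  post <- posterior_from_log10(cbind(l00, l01, l11))
  tibble::tibble(
    L00 = 10^l00, L01 = 10^l01, L11 = 10^l11,
    p00 = post$p[, 1], p01 = post$p[, 2], p11 = post$p[, 3],
    genotype = post$genotype, qual = pmin(post$qual, params$qual_cap)
  )
}

# shared posterior machinery: rows of log10 joint likelihoods for
# (0/0, 0/1, 1/1); ties prefer 0/1, then 0/0, then 1/1
posterior_from_log10 <- function(l) {
  denom <- apply(l, 1, log10_sum)
  p <- 10^(l - denom)
  p <- p / rowSums(p)
  pref <- c(2L, 1L, 3L) # column preference order: 0/1, 0/0, 1/1
  pick <- apply(p, 1, function(r) pref[which.max(r[pref])])
  maxp <- p[cbind(seq_len(nrow(p)), pick)]
  qual <- ifelse(maxp >= 1, Inf, -10 * log10(1 - maxp))
  list(
    p = p,
    genotype = c("0/0", "0/1", "1/1")[pick],
    qual = qual
  )
}

#' Haploid read likelihood from mismatch base qualities
#'
#' Given the Phred base qualities of the `e` errors (mismatches, and the
#' first affected base of each indel) observed when a read is aligned to a
#' haplotype, the haploid likelihood is \eqn{\Pr(R|H) = 10^{-\sum_e Q_e/10}}.
#' An empty vector (no errors) gives 1.
#'
#' @param mismatch_quals Integer vector of Phred qualities (>= 0).
#' @return A list with `value`, `error_count`, `quality_sum`.
#' @export
haploid_likelihood <- function(mismatch_quals) {
  stopifnot(all(mismatch_quals >= 0))
  qs <- sum(mismatch_quals)
  list(value = 10^(-qs / 10), error_count = length(mismatch_quals),
       quality_sum = qs)
}

#' Diploid read-set likelihood for a genotype
#'
#' Combines per-read haploid likelihoods against the genotype's two
#' haplotypes: \eqn{\Pr(R|G) = \prod_j (\Pr(R_j|H_1)/2 + \Pr(R_j|H_2)/2)}.
#' For 0/0 both haplotypes carry the reference allele, for 1/1 both carry
#' the alternative, for 0/1 one each.
#'
#' @param p_h1,p_h2 Numeric vectors in (0, 1]: per-read likelihoods against
#'   haplotypes 1 and 2.
#' @return The product, a single likelihood.
#' @export
diploid_read_likelihood <- function(p_h1, p_h2) {
  stopifnot(length(p_h1) == length(p_h2))
  prod((p_h1 + p_h2) / 2)
}

#' Posterior genotype probabilities from likelihoods
#'
#' Bayes rule over the three diploid genotypes:
#' \eqn{\Pr(G|R) = \Pr(G)\Pr(R|G) / \sum_i \Pr(G_i)\Pr(R|G_i)}. The call is
#' the maximum-posterior genotype with quality `-10 log10(1 - max posterior)`
#' capped at `qual_cap`. All-zero likelihoods produce a no-call (`./.`) with
#' quality 0.
#'
#' @param l00,l01,l11 Non-negative likelihoods (vectors, recycled).
#' @param priors Genotype prior probabilities (length 3, default equal).
#' @param qual_cap Cap on the reported quality.
#' @return Tibble with `p00`, `p01`, `p11`, `genotype`, `qual`.
#' @export
posterior_genotypes <- function(l00, l01, l11, priors = rep(1 / 3, 3),
                                qual_cap = 60) {
  stopifnot(length(priors) == 3, all(priors > 0))
  n <- max(length(l00), length(l01), length(l11))
  l <- cbind(rep_len(l00, n), rep_len(l01, n), rep_len(l11, n))
  joint <- sweep(l, 2, priors, `*`)
  nocall <- rowSums(joint) == 0
  joint[nocall, ] <- 1 # placeholder, overwritten below
  post <- posterior_from_log10(log10(joint))
  out <- tibble::tibble(
    p00 = post$p[, 1], p01 = post$p[, 2], p11 = post$p[, 3],
    genotype = post$genotype, qual = pmin(post$qual, qual_cap)
  )
  if (any(nocall)) {
    out$p00[nocall] <- out$p01[nocall] <- out$p11[nocall] <- NA_real_
    out$genotype[nocall] <- "./."
    out$qual[nocall] <- 0
  }
  out
}

# Posterior genotypes from log10 likelihoods (internal; avoids underflow for
# deep pileups). Returns the same shape as posterior_genotypes().
posterior_genotypes_log10 <- function(l00, l01, l11, priors = rep(1 / 3, 3),
                                      qual_cap = 60) {
  n <- max(length(l00), length(l01), length(l11))
  l <- cbind(rep_len(l00, n), rep_len(l01, n), rep_len(l11, n))
  joint <- sweep(l, 2, log10(priors), `+`)
  post <- posterior_from_log10(joint)
  tibble::tibble(
    p00 = post$p[, 1], p01 = post$p[, 2], p11 = post$p[, 3],
    genotype = post$genotype, qual = pmin(post$qual, qual_cap)
  )
}
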