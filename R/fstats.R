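#' Group allele frequencies
#'
#' Alternative-allele frequency per SNP over the non-missing members of a
#' sample group. Diploid samples contribute two allele observations,
#' pseudo-haploid samples one (their 0/2 coding is a single sampled
#' allele). SNPs with no data in the group are `NA`.
#'
#' @param G a [geno_matrix()].
#' @param group sample ids (or indices) forming the group.
#' @return list of class `allele_freq` with `freq` (per-SNP frequency) and
#'   `size` (per-SNP number of allele observations).
#' @export
allele_frequencies <- function(G, group) {
  stopifnot(inherits(G, "geno_matrix"), length(group) >= 1)
  Gs <- subset_geno(G, samples = group)
  chrom <- ifelse(Gs$ploidy == "pseudo_haploid", 1, 2)  # alleles per sample
  cnt <- Gs$counts
  alt <- cnt * (chrom / 2)               # pseudo-haploid 0/2 -> 0/1 alleles
  present <- !is.na(cnt)
  size <- colSums(present * chrom)
  total_alt <- colSums(alt, na.rm = TRUE)
  freq <- ifelse(size > 0, total_alt / size, NA_real_)
  structure(list(freq = freq, size = size), class = "allele_freq")
}

as_freq <- function(x) {
  if (inherits(x, "allele_freq")) x else
    structure(list(freq = as.numeric(x),
                   size = rep.int(NA_real_, length(x))),
              class = "allele_freq")
}

#' Weighted delete-one block jackknife
#'
#' Given per-block values of a statistic and positive block weights
#' (typically SNP counts), returns the weighted overall estimate and the
#' delete-one-block jackknife standard error: with total weight `W`,
#' delete-one estimates `theta_(-j)` and their mean `theta_bar`,
#' `var = sum_j ((W - w_j) / W) (theta_(-j) - theta_bar)^2`, which reduces
#' to the textbook `((g - 1) / g) sum (theta_(-j) - theta_bar)^2` for
#' equal weights.
#'
#' @param block_values per-block statistic values (>= 2 blocks).
#' @param block_weights positive block weights.
#' @return list with `estimate`, `stderr`, `loo` (delete-one estimates).
#' @export
block_jackknife <- function(block_values, block_weights) {
  g <- length(block_values)
  if (g < 2) stop("block jackknife needs at least 2 blocks")
  if (length(block_weights) != g || any(block_weights <= 0)) {
    stop("block_weights must be positive and match block_values")
  }
  w <- block_weights
  W <- sum(w)
  tot <- sum(w * block_values)
  est <- tot / W
  loo <- (tot - w * block_values) / (W - w)
  centre <- mean(loo)
  stderr <- sqrt(sum(((W - w) / W) * (loo - centre)^2))
  list(estimate = est, stderr = stderr, loo = loo)
}

jackknife_result <- function(bj, n_blocks, block_values, block_weights,
                             n_snps) {
  z <- if (bj$stderr > 0) bj$estimate / bj$stderr else NA_real_
  structure(list(estimate = bj$estimate, stderr = bj$stderr, z = z,
                 n_blocks = n_blocks, n_snps = n_snps,
                 block_values = block_values, block_weights = block_weights),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("estimate %.6g  stderr %.3g  z %.2f  (%d SNPs, %d blocks)\n",
              x$estimate, x$stderr, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

#' F4 statistic with block-jackknife z-score
#'
#' The F4 statistic of four groups is the mean over usable SNPs of
#' `(a - b)(c - d)` where `a..d` are the group allele frequencies. SNPs
#' missing in any group are excluded (complete-case); the standard error
#' comes from a weighted delete-one jackknife over contiguous blocks of
#' `block_size` usable SNPs, and `|z| > 3` is the conventional
#' significance threshold.
#'
#' @param a,b,c,d per-SNP frequencies (`allele_freq` objects or plain
#'   vectors) on a shared panel.
#' @param block_size SNPs per jackknife block.
#' @return a `jackknife_result` (estimate, stderr, z, per-block values).
#' @export
f4 <- function(a, b, c, d, block_size = 100L) {
  fa <- as_freq(a); fb <- as_freq(b); fc <- as_freq(c); fd <- as_freq(d)
  m <- length(fa$freq)
  stopifnot(length(fb$freq) == m, length(fc$freq) == m, length(fd$freq) == m)
  use <- !(is.na(fa$freq) | is.na(fb$freq) | is.na(fc$freq) | is.na(fd$freq))
  prod <- (fa$freq[use] - fb$freq[use]) * (fc$freq[use] - fd$freq[use])
  n_use <- length(prod)
  block <- (seq_len(n_use) - 1L) %/% block_size + 1L
  if (max(block, 0L) < 2) stop("fewer than 2 jackknife blocks with data")
  bv <- as.numeric(tapply(prod, block, mean))
  bw <- as.numeric(tapply(prod, block, length))
  bj <- block_jackknife(bv, bw)
  jackknife_result(bj, length(bv), bv, bw, n_use)
}

#' ABBA-BABA (D) statistic for four haploid genomes
#'
#' Sites are polarized by the outgroup allele (the "A" state). Among
#' biallelic site patterns across (`h1`, `h2`, `h3`, outgroup), ABBA sites
#' have `h1` matching the outgroup and `h2`, `h3` carrying the derived
#' allele; BABA sites swap `h1` and `h2`. `D = (nABBA - nBABA) /
#' (nABBA + nBABA)`, with the z-score from a delete-one jackknife over
#' uniform windows of `window` informative-bearing SNPs.
#'
#' @param h1,h2,h3,outgroup haploid 0/1 genotype vectors on one panel
#'   (`NA` = missing).
#' @param window SNPs per jackknife window (windows are laid over the
#'   usable SNPs in panel order).
#' @return a `jackknife_result` for D, plus `n_abba`/`n_baba` fields.
#' @export
abba_baba <- function(h1, h2, h3, outgroup, window = 100L) {
  m <- length(h1)
  stopifnot(length(h2) == m, length(h3) == m, length(outgroup) == m)
  use <- !(is.na(h1) | is.na(h2) | is.na(h3) | is.na(outgroup))
  d1 <- h1[use] != outgroup[use]
  d2 <- h2[use] != outgroup[use]
  d3 <- h3[use] != outgroup[use]
  abba <- !d1 & d2 & d3
  baba <- d1 & !d2 & d3
  if (sum(abba) + sum(baba) == 0) {
    stop("no ABBA or BABA sites: D statistic undefined")
  }
  block <- (seq_len(sum(use)) - 1L) %/% window + 1L
  na <- tapply(abba, block, sum)
  nb <- tapply(baba, block, sum)
  keep <- (na + nb) > 0
  na <- as.numeric(na[keep]); nb <- as.numeric(nb[keep])
  if (length(na) < 2) stop("fewer than 2 informative jackknife windows")
  ## weighted mean of per-window D with weights nABBA+nBABA equals the
  ## global D, so the generic jackknife applies directly
  bv <- (na - nb) / (na + nb)
  bw <- na + nb
  bj <- block_jackknife(bv, bw)
  res <- jackknife_result(bj, length(bv), bv, bw, sum(use))
  res$n_abba <- sum(na); res$n_baba <- sum(nb)
  res
}

#' Hudson Fst (ratio of averages)
#'
#' Per-SNP numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`
#' (the sample-size-corrected squared frequency difference) and
#' denominator `p1(1-p2) + p2(1-p1)`, combined as the ratio of sums over
#' usable SNPs. SNPs need at least two allele observations per group.
#'
#' @param freq1,freq2 `allele_freq` objects from [allele_frequencies()].
#' @return Fst estimate (a single value).
#' @export
hudson_fst <- function(freq1, freq2) {
  stopifnot(inherits(freq1, "allele_freq"), inherits(freq2, "allele_freq"))
  p1 <- freq1$freq; p2 <- freq2$freq
  n1 <- freq1$size; n2 <- freq2$size
  use <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  if (!any(use)) stop("no usable SNPs for Fst")
  p1 <- p1[use]; p2 <- p2[use]; n1 <- n1[use]; n2 <- n2[use]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Average pairwise Hudson Fst over several groups
#'
#' @param freqs list of `allele_freq` objects (>= 2).
#' @return mean of all pairwise [hudson_fst()] values.
#' @export
hudson_fst_multi <- function(freqs) {
  stopifnot(is.list(freqs), length(freqs) >= 2)
  pairs <- utils::combn(length(freqs), 2)
  mean(apply(pairs, 2, function(ij) {
    hudson_fst(freqs[[ij[1]]], freqs[[ij[2]]])
  }))
}
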