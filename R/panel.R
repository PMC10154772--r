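#' SNP panel objects
#'
#' A SNP panel is a data frame with one row per site and columns `snp_id`,
#' `chrom` (integer label), `pos` (1-based physical position, strictly
#' increasing within a chromosome), `ref`, `alt` (distinct bases) and
#' `class` (`"transition"` for \{C,T\}/\{A,G\} allele pairs, otherwise
#' `"transversion"`). Capture panels used in ancient-DNA work (e.g. the
#' 1240K set) are dominated by transitions, which is what makes post-mortem
#' deamination able to masquerade as genuine variation.
#'
#' @param x data frame with the columns above (`class` is recomputed if
#'   absent).
#' @return `x` validated, with class `snp_panel` prepended.
#' @export
snp_panel <- function(x) {
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(x$ref %in% BASES) || !all(x$alt %in% BASES)) {
    stop("ref/alt alleles must be one of A, C, G, T")
  }
  if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
  if (is.null(x$class)) {
    x$class <- ifelse(is_transition_pair(x$ref, x$alt),
                      "transition", "transversion")
  } else {
    ok <- (x$class == "transition") == is_transition_pair(x$ref, x$alt)
    if (!all(ok)) stop("`class` inconsistent with allele pair")
  }
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within a chromosome")
    }
  }
  class(x) <- unique(c("snp_panel", class(x)))
  x
}

#' Simulate a transition-rich SNP panel
#'
#' Each site is independently classed as a transition with probability
#' `transition_fraction`; allele pairs are drawn uniformly within the class
#' and ref/alt orientation is random. The default `transition_fraction` of
#' 0.8 makes transversions roughly five times rarer than all SNPs, the
#' regime of ancient-DNA capture panels.
#'
#' @param n_snps number of sites (>= 1).
#' @param transition_fraction probability a site is a transition, in \[0, 1\].
#' @param n_chrom number of chromosome labels to spread sites over.
#' @param seed optional integer seed for reproducibility.
#' @return a [snp_panel()] data frame.
#' @examples
#' p <- simulate_panel(1000, seed = 1)
#' table(p$class)
#' @export
simulate_panel <- function(n_snps, transition_fraction = 0.8, n_chrom = 1L,
                           seed = NULL) {
  stopifnot(n_snps >= 1, n_chrom >= 1)
  check_prob(transition_fraction, "transition_fraction")
  set_seed_if(seed)
  n_snps <- as.integer(n_snps)

  is_ts <- runif(n_snps) < transition_fraction
  ts_pairs <- rbind(c("C", "T"), c("A", "G"))
  tv_pairs <- rbind(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))
  a1 <- a2 <- character(n_snps)
  if (any(is_ts)) {
    k <- sample.int(2L, sum(is_ts), replace = TRUE)
    a1[is_ts] <- ts_pairs[k, 1L]
    a2[is_ts] <- ts_pairs[k, 2L]
  }
  if (any(!is_ts)) {
    k <- sample.int(4L, sum(!is_ts), replace = TRUE)
    a1[!is_ts] <- tv_pairs[k, 1L]
    a2[!is_ts] <- tv_pairs[k, 2L]
  }
  flip <- runif(n_snps) < 0.5
  ref <- ifelse(flip, a2, a1)
  alt <- ifelse(flip, a1, a2)

  chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- integer(n_snps)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample.int(2000L, length(idx), replace = TRUE))
  }

  snp_panel(data.frame(
    snp_id = sprintf("snp_%d_%d", chrom, pos),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    class = ifelse(is_ts, "transition", "transversion"),
    stringsAsFactors = FALSE
  ))
}
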