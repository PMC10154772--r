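#' Trim terminal bases from an observation set
#'
#' UDG-half libraries retain deamination damage at the terminal ~2 bp, so
#' observations within `n_bp` of either fragment end are discarded before
#' calling (the fragment-level analogue of trimming read ends).
#'
#' @param obs observation data frame.
#' @param n_bp number of bases to trim from each end (>= 0).
#' @return the observation data frame with terminal observations removed.
#' @export
trim_terminal <- function(obs, n_bp = 2L) {
  validate_obs(obs)
  stopifnot(n_bp >= 0)
  obs[pmin(obs$dist5, obs$dist3) > n_bp, , drop = FALSE]
}

#' Pseudo-haploid genotype calling
#'
#' Per SNP and sample, observations below the base-quality threshold and
#' observations whose base matches neither panel allele (e.g. damage-created
#' third alleles at transversion SNPs) are discarded; one of the survivors
#' is then chosen uniformly at random and its allele reported. Sites with
#' no surviving observation are missing.
#'
#' @param obs observation data frame.
#' @param panel the [snp_panel()] the `snp_index` column refers to.
#' @param samples sample ids to call (default: all present in `obs`).
#' @param min_bq minimum phred base quality (default 30).
#' @param seed optional integer seed for the random draw.
#' @return a `haploid_calls` object: list with `allele`, a SNPs x samples
#'   integer matrix (0 = ref, 1 = alt, NA = missing), plus `panel` and
#'   `samples`.
#' @export
call_pseudohaploid <- function(obs, panel, samples = NULL, min_bq = 30L,
                               seed = NULL) {
  validate_obs(obs)
  stopifnot(inherits(panel, "snp_panel"))
  set_seed_if(seed)
  samples <- samples %||% sort(unique(obs$sample_id))

  keep <- obs$bq >= min_bq
  obs <- obs[keep, , drop = FALSE]
  is_ref <- obs$base == panel$ref[obs$snp_index]
  is_alt <- obs$base == panel$alt[obs$snp_index]
  obs <- obs[is_ref | is_alt, , drop = FALSE]
  allele_obs <- as.integer(obs$base == panel$alt[obs$snp_index])

  m <- nrow(panel)
  allele <- matrix(NA_integer_, m, length(samples),
                   dimnames = list(panel$snp_id, samples))
  if (nrow(obs)) {
    ## canonical (input-order-independent) sort, then a random
    ## permutation; first record per (snp, sample) is a uniform draw
    ord <- order(obs$snp_index, match(obs$sample_id, samples),
                 obs$base, obs$bq, obs$fraglen, obs$dist5)
    obs <- obs[ord, , drop = FALSE]; allele_obs <- allele_obs[ord]
    perm <- sample.int(nrow(obs))
    obs <- obs[perm, , drop = FALSE]; allele_obs <- allele_obs[perm]
    si <- match(obs$sample_id, samples)
    ok <- !is.na(si)
    first <- !duplicated(cbind(obs$snp_index[ok], si[ok]))
    allele[cbind(obs$snp_index[ok][first], si[ok][first])] <-
      allele_obs[ok][first]
  }
  structure(list(allele = allele, panel = panel, samples = samples),
            class = "haploid_calls")
}

#' Pseudo-diploid coding of haploid calls
#'
#' Recodes the single sampled allele as a homozygote (ref -> 0, alt -> 2,
#' missing preserved), the standard representation of pseudo-haploid
#' ancient samples on diploid panels.
#'
#' @param calls a `haploid_calls` object from [call_pseudohaploid()].
#' @param groups optional per-sample group labels.
#' @return a [geno_matrix()] with ploidy flag `pseudo_haploid`.
#' @export
to_pseudodiploid <- function(calls, groups = NULL) {
  stopifnot(inherits(calls, "haploid_calls"))
  geno_matrix(t(calls$allele * 2L), calls$panel, ploidy = "pseudo_haploid",
              samples = calls$samples, groups = groups)
}

#' Mask transition SNPs
#'
#' Restricts a genotype matrix to transversion-class SNPs. Deamination can
#' only mimic transitions ({C,T} and {A,G} pairs), so the transversion
#' subset is immune to damage-driven allele flips; the cost is a roughly
#' five-fold loss of sites on transition-rich panels.
#'
#' @param G a [geno_matrix()].
#' @return the `geno_matrix` restricted to transversion SNPs.
#' @export
mask_transitions <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  keep <- G$panel$class == "transversion"
  if (!any(keep)) stop("no transversion SNPs remain after masking")
  subset_geno(G, snps = keep)
}

#' Sliding-window LD pruning
#'
#' Within windows of `window` SNPs (advanced by `step`, per chromosome),
#' the later SNP of any pair whose squared Pearson correlation of genotype
#' counts exceeds `r2_max` is removed (greedy keep-first; pairwise-complete
#' on missing data). Mirrors PLINK `--indep-pairwise`.
#'
#' @param G a [geno_matrix()].
#' @param window window size in SNPs.
#' @param step window increment in SNPs (must be <= `window`).
#' @param r2_max squared-correlation threshold above which the later SNP is
#'   dropped.
#' @return integer vector of retained SNP indices (increasing).
#' @export
ld_prune <- function(G, window = 50L, step = 5L, r2_max = 0.2) {
  stopifnot(inherits(G, "geno_matrix"))
  if (window < step) stop("window must be >= step")
  m <- ncol(G$counts)
  keep <- rep(TRUE, m)
  for (ch in unique(G$panel$chrom)) {
    idx <- which(G$panel$chrom == ch)
    if (length(idx) < 2) next
    start <- 1L
    repeat {
      stop_at <- min(start + window - 1L, length(idx))
      win <- idx[start:stop_at]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(
          cor(G$counts[, win, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in (a + 1L):length(win)) {
            if (keep[win[b]] && isTRUE(r2[a, b] > r2_max)) {
              keep[win[b]] <- FALSE
            }
          }
        }
      }
      if (stop_at >= length(idx)) break
      start <- start + step
    }
  }
  which(keep)
}
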