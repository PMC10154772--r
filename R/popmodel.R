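#' Simulate population allele frequencies under Balding-Nichols drift
#'
#' Ancestral frequencies are drawn uniformly on `anc_range`; population `k`
#' then draws its frequency at every SNP from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `p` the ancestral
#' frequency and `F = fst_per_pop[k]`, the Balding-Nichols model. This
#' yields `E[f] = p` and `Var(f) = F p (1 - p)`.
#'
#' @param panel a [snp_panel()].
#' @param n_pops number of populations K.
#' @param fst_per_pop drift parameter per population, each in (0, 1);
#'   recycled to length `n_pops`.
#' @param anc_range range of the uniform ancestral-frequency draw.
#' @param seed optional integer seed.
#' @return a `population_model` list with elements `panel`, `n_pops`,
#'   `ancestral` (length-M vector), `fst` and `freqs` (K x M matrix).
#' @export
simulate_frequencies <- function(panel, n_pops, fst_per_pop,
                                 anc_range = c(0.05, 0.95), seed = NULL) {
  stopifnot(inherits(panel, "snp_panel"), n_pops >= 1)
  fst_per_pop <- rep_len(fst_per_pop, n_pops)
  check_prob(fst_per_pop, "fst_per_pop", open = TRUE)
  set_seed_if(seed)

  m <- nrow(panel)
  p <- runif(m, anc_range[1], anc_range[2])
  freqs <- matrix(NA_real_, n_pops, m)
  for (k in seq_len(n_pops)) {
    f <- fst_per_pop[k]
    freqs[k, ] <- rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  structure(list(panel = panel, n_pops = as.integer(n_pops),
                 ancestral = p, fst = fst_per_pop, freqs = freqs),
            class = "population_model")
}

#' Genotype matrix container
#'
#' Holds an individuals x SNPs matrix of alternative-allele counts
#' (`0/1/2`, `NA` = missing) tied to a SNP panel. Each sample carries a
#' ploidy flag: `"diploid"` (true genotypes) or `"pseudo_haploid"`
#' (one random allele coded as a homozygote, so counts are only 0/2/NA).
#'
#' @param counts integer matrix, samples in rows, SNPs in columns.
#' @param panel the [snp_panel()] the columns refer to.
#' @param ploidy per-sample flag, `"diploid"` or `"pseudo_haploid"`;
#'   recycled.
#' @param samples sample identifiers (default from rownames).
#' @param groups optional per-sample population labels (used by
#'   EIGENSTRAT output and group statistics).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(counts, panel, ploidy = "diploid",
                        samples = rownames(counts), groups = NULL) {
  stopifnot(is.matrix(counts), inherits(panel, "snp_panel"))
  if (ncol(counts) != nrow(panel)) {
    stop("counts has ", ncol(counts), " SNP columns but panel has ",
         nrow(panel), " rows")
  }
  if (is.null(samples)) samples <- sprintf("sample_%d", seq_len(nrow(counts)))
  ploidy <- rep_len(ploidy, nrow(counts))
  if (!all(ploidy %in% c("diploid", "pseudo_haploid"))) {
    stop("ploidy must be 'diploid' or 'pseudo_haploid'")
  }
  bad <- !counts %in% c(0L, 1L, 2L) & !is.na(counts)
  if (any(bad)) stop("counts must be 0, 1, 2 or NA")
  ph <- ploidy == "pseudo_haploid"
  if (any(ph) && any(counts[ph, , drop = FALSE] == 1L, na.rm = TRUE)) {
    stop("pseudo-haploid samples may only carry counts 0, 2 or NA")
  }
  groups <- rep_len(groups %||% "POP", nrow(counts))
  rownames(counts) <- samples
  structure(list(counts = counts, panel = panel, ploidy = ploidy,
                 samples = samples, groups = groups),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs (%d pseudo-haploid, %.1f%% missing)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$ploidy == "pseudo_haploid"),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by sample and/or SNP
#'
#' @param G a [geno_matrix()].
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP indices (or logical mask) to keep (default all).
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  si <- if (is.null(samples)) seq_along(G$samples) else {
    if (is.character(samples)) match(samples, G$samples) else samples
  }
  if (anyNA(si)) stop("unknown sample id")
  ji <- seq_len(ncol(G$counts))
  if (!is.null(snps)) ji <- if (is.logical(snps)) which(snps) else as.integer(snps)
  pan <- G$panel[ji, , drop = FALSE]
  class(pan) <- class(G$panel)
  geno_matrix(G$counts[si, ji, drop = FALSE], pan,
              ploidy = G$ploidy[si], samples = G$samples[si],
              groups = G$groups[si])
}

#' Combine genotype matrices sharing one panel
#'
#' @param ... `geno_matrix` objects on identical panels.
#' @return a `geno_matrix` stacking all samples.
#' @export
rbind_geno <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1, all(vapply(gs, inherits, TRUE, "geno_matrix")))
  pan <- gs[[1]]$panel
  for (g in gs[-1]) {
    if (!identical(g$panel$snp_id, pan$snp_id)) stop("panels differ")
  }
  geno_matrix(do.call(rbind, lapply(gs, `[[`, "counts")), pan,
              ploidy = unlist(lapply(gs, `[[`, "ploidy")),
              samples = unlist(lapply(gs, `[[`, "samples")),
              groups = unlist(lapply(gs, `[[`, "groups")))
}

#' Simulate admixed diploid genotypes
#'
#' Genotype of individual `i` at SNP `j` is `Binomial(2, p_ij)` with
#' `p_ij = sum_k Q[i,k] * F[k,j]`: the two allele draws mix the K ancestral
#' populations with the individual's ancestry proportions.
#'
#' @param model a `population_model` from [simulate_frequencies()].
#' @param Q individuals x K matrix of ancestry proportions; every row must
#'   sum to 1 (tolerance 1e-8).
#' @param samples optional sample ids.
#' @param groups optional per-sample group labels.
#' @param seed optional integer seed.
#' @return a [geno_matrix()] of diploid genotypes with no missingness.
#' @export
simulate_genotypes <- function(model, Q, samples = NULL, groups = NULL,
                               seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  Q <- as.matrix(Q)
  if (ncol(Q) != model$n_pops) stop("Q must have K = ", model$n_pops, " columns")
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop("each row of Q must be a point on the simplex (sum 1, tol 1e-8)")
  }
  set_seed_if(seed)
  P <- Q %*% model$freqs
  n <- nrow(Q); m <- ncol(P)
  counts <- matrix(rbinom(n * m, 2L, P), n, m)
  geno_matrix(counts, model$panel, ploidy = "diploid",
              samples = samples %||% sprintf("ind_%d", seq_len(n)),
              groups = groups)
}
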