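# Fixtures are built in code: tiny hand panels and observation sets used
# across test files.

tiny_panel <- function(ref, alt, chrom = 1L) {
  n <- length(ref)
  snp_panel(data.frame(
    snp_id = sprintf("s%d", seq_len(n)),
    chrom = chrom, pos = seq_len(n) * 100L,
    ref = ref, alt = alt, stringsAsFactors = FALSE))
}

# one observation per row, with consistent dist5/dist3 on a given fragment
make_obs <- function(snp_index, base, bq = 37L, fraglen = 61L, dist5 = 30L,
                     sample_id = "s1") {
  n <- max(length(snp_index), length(base), length(dist5))
  data.frame(
    snp_index = rep_len(snp_index, n),
    sample_id = rep_len(sample_id, n),
    base = rep_len(base, n),
    bq = rep_len(bq, n),
    fraglen = rep_len(fraglen, n),
    dist5 = rep_len(dist5, n),
    dist3 = rep_len(fraglen, n) + 1L - rep_len(dist5, n),
    stringsAsFactors = FALSE)
}

geno_from_counts <- function(counts, panel = NULL, ploidy = "diploid") {
  counts <- as.matrix(counts)
  if (is.null(panel)) {
    panel <- tiny_panel(rep("A", ncol(counts)), rep("C", ncol(counts)))
  }
  geno_matrix(counts, panel, ploidy = ploidy,
              samples = sprintf("i%d", seq_len(nrow(counts))))
}

# two-source-population world used by several recovery tests
sim_world <- function(seed, n_snps = 2000, fst = c(0.1, 0.15), n_per_pop = 30,
                      transition_fraction = 0.8) {
  panel <- simulate_panel(n_snps, transition_fraction, seed = seed)
  model <- simulate_frequencies(panel, length(fst), fst, seed = seed + 1L)
  Q <- diag(length(fst))[rep(seq_along(fst), each = n_per_pop), ]
  G <- simulate_genotypes(model, Q, seed = seed + 2L,
                          groups = rep(sprintf("pop%d", seq_along(fst)),
                                       each = n_per_pop))
  list(panel = panel, model = model, Q = Q, G = G)
}
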