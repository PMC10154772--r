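test_that("terminal trimming removes end-proximal observations", {
  obs <- make_obs(1L, "C", fraglen = 61L,
                  dist5 = c(1L, 2L, 3L, 30L, 59L, 60L, 61L))
  expect_identical(trim_terminal(obs, 0L), obs)
  tr <- trim_terminal(obs, 2L)
  expect_identical(tr$dist5, c(3L, 30L, 59L))   # dist3 = 60, 61 trimmed too

  # uniform positions on 65-bp fragments: ~61/65 survive
  n <- 2e4
  set.seed(1)
  d5 <- sample.int(65L, n, replace = TRUE)
  obs2 <- make_obs(1L, "C", fraglen = 65L, dist5 = d5)
  frac <- nrow(trim_terminal(obs2, 2L)) / n
  expect_lt(abs(frac - 61 / 65), 3 * sqrt((61 / 65) * (4 / 65) / n))
})

test_that("pseudo-haploid calling filters on quality and panel alleles", {
  pan <- tiny_panel(c("A", "C"), c("C", "T"))
  # single low-quality observation -> missing
  calls <- call_pseudohaploid(make_obs(1L, "C", bq = 29L), pan, seed = 1)
  expect_true(is.na(calls$allele[1, 1]))
  # bq exactly at threshold is kept
  calls <- call_pseudohaploid(make_obs(1L, "C", bq = 30L), pan, seed = 1)
  expect_identical(calls$allele[1, 1], 1L)
  # off-panel (damage-created) base -> dropped -> missing
  calls <- call_pseudohaploid(make_obs(2L, "G"), pan, seed = 1)
  expect_true(is.na(calls$allele[2, 1]))
  # all-alt pileup -> alt call
  calls <- call_pseudohaploid(make_obs(rep(2L, 5), "T"), pan, seed = 1)
  expect_identical(calls$allele[2, 1], 1L)
})

test_that("the surviving base is drawn uniformly", {
  n_sites <- 1e4
  pan <- tiny_panel(rep("A", n_sites), rep("C", n_sites))
  obs <- rbind(make_obs(seq_len(n_sites), "A"),
               make_obs(seq_len(n_sites), "C"))
  calls <- call_pseudohaploid(obs, pan, seed = 9)
  frac_alt <- mean(calls$allele[, 1])
  expect_lt(abs(frac_alt - 0.5), 3 * sqrt(0.25 / n_sites))

  # calling is invariant to input row order under the same seed
  shuf <- obs[sample.int(nrow(obs)), ]
  calls2 <- call_pseudohaploid(shuf, pan, seed = 9)
  expect_identical(calls$allele, calls2$allele)
})

test_that("pseudo-diploid coding maps ref/alt/missing to 0/2/NA", {
  pan <- tiny_panel(c("A", "C", "G"), c("C", "T", "T"))
  obs <- rbind(make_obs(1L, "A"), make_obs(2L, "T"))
  G <- to_pseudodiploid(call_pseudohaploid(obs, pan, seed = 1))
  expect_identical(as.vector(G$counts), c(0L, 2L, NA))
  expect_true(all(G$ploidy == "pseudo_haploid"))
})

test_that("transition masking keeps exactly the transversion SNPs", {
  pan <- tiny_panel(c("C", "A", "A", "G", "C", "A", "G", "C", "T", "G"),
                    c("T", "G", "C", "T", "T", "G", "A", "T", "C", "A"))
  expect_identical(pan$class, c("transition", "transition", "transversion",
                                "transversion", "transition", "transition",
                                "transition", "transition", "transition",
                                "transition"))
  G <- geno_from_counts(matrix(0L, 2, 10), pan)
  masked <- mask_transitions(G)
  expect_identical(ncol(masked$counts), 2L)       # 8 transitions removed
  expect_identical(masked$panel$snp_id, c("s3", "s4"))
  expect_identical(nrow(masked$counts), 2L)

  # idempotent; identity on an all-transversion panel
  expect_identical(mask_transitions(masked)$panel, masked$panel)
  tv_only <- subset_geno(G, snps = pan$class == "transversion")
  expect_identical(mask_transitions(tv_only)$counts, tv_only$counts)

  ts_only <- subset_geno(G, snps = pan$class == "transition")
  expect_error(mask_transitions(ts_only), "no transversion")
})

test_that("LD pruning drops correlated columns and keeps independent ones", {
  set.seed(5)
  n <- 200
  x <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  x[, 10] <- x[, 9]                      # identical pair inside one window
  G <- geno_from_counts(x)
  kept <- ld_prune(G, window = 50, step = 5, r2_max = 0.2)
  expect_false(10L %in% kept)
  expect_true(9L %in% kept)

  # retained indices are an increasing subset; r2_max = 1 removes nothing
  expect_true(all(diff(kept) > 0))
  expect_identical(ld_prune(G, r2_max = 1), seq_len(60L))

  # mutually independent SNPs (single homogeneous population) survive
  pan <- simulate_panel(2000, seed = 41)
  mod <- simulate_frequencies(pan, 1, 0.1, seed = 42)
  Gi <- simulate_genotypes(mod, matrix(1, 400, 1), seed = 43)
  kept2 <- ld_prune(Gi)
  expect_gt(length(kept2) / 2000, 0.99)

  expect_error(ld_prune(G, window = 3, step = 5), "window")
})

test_that("EIGENSTRAT round-trips losslessly, including missing data", {
  set.seed(6)
  pan <- simulate_panel(150, seed = 7, n_chrom = 3)
  counts <- matrix(sample(c(0L, 1L, 2L, NA), 8 * 150, replace = TRUE), 8, 150)
  counts[7:8, ] <- counts[7:8, ] - (counts[7:8, ] == 1L)  # make 0/2 rows
  G <- geno_matrix(counts, pan,
                   ploidy = c(rep("diploid", 6), rep("pseudo_haploid", 2)),
                   samples = sprintf("smp%d", 1:8),
                   groups = rep(c("g1", "g2"), 4))
  pre <- tempfile()
  write_eigenstrat(G, pre)
  G2 <- read_eigenstrat(pre)
  expect_equal(unname(G2$counts), unname(G$counts))
  expect_identical(G2$samples, G$samples)
  expect_identical(G2$ploidy, G$ploidy)
  expect_identical(G2$groups, G$groups)
  expect_identical(G2$panel$snp_id, pan$snp_id)
  expect_identical(G2$panel$class, pan$class)

  # sample-count mismatch between .geno and .ind is a format error
  ind <- readLines(paste0(pre, ".ind"))
  writeLines(ind[1:7], paste0(pre, ".ind"))
  expect_error(read_eigenstrat(pre), "sample count")
})
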