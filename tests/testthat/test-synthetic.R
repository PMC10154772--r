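test_that("simulate_panel controls the transition/transversion mix", {
  p <- simulate_panel(10000, transition_fraction = 0.8, seed = 42)
  n_tv <- sum(p$class == "transversion")
  # binomial 3-SE band around 2000 transversions (~5x fewer than all SNPs)
  expect_lt(abs(n_tv - 2000), 3 * sqrt(10000 * 0.8 * 0.2))

  p0 <- simulate_panel(500, transition_fraction = 0, seed = 1)
  expect_true(all(p0$class == "transversion"))
  p1 <- simulate_panel(500, transition_fraction = 1, seed = 1)
  expect_true(all(p1$class == "transition"))

  big <- simulate_panel(1e5, transition_fraction = 0.8, seed = 7)
  expect_lt(abs(mean(big$class == "transition") - 0.8),
            3 * sqrt(0.8 * 0.2 / 1e5))

  expect_error(simulate_panel(100, transition_fraction = 1.5), "0, 1")
})

test_that("panel invariants hold and are validated", {
  p <- simulate_panel(5000, seed = 3, n_chrom = 4)
  expect_true(all(p$ref != p$alt))
  expect_identical(p$class == "transition",
                   paste(pmin(p$ref, p$alt), pmax(p$ref, p$alt)) %in%
                     c("C T", "A G"))
  for (ch in unique(p$chrom)) {
    expect_true(all(diff(p$pos[p$chrom == ch]) > 0))
  }
  bad <- data.frame(snp_id = "x", chrom = 1, pos = 1, ref = "A", alt = "A")
  expect_error(snp_panel(bad), "differ")
})

test_that("Balding-Nichols frequencies have the stated moments", {
  panel <- simulate_panel(1000, seed = 5)
  # near-zero drift: population frequency collapses onto the ancestral one
  m0 <- simulate_frequencies(panel, 1, 1e-6, seed = 6)
  expect_true(all(abs(m0$freqs[1, ] - m0$ancestral) < 1e-2))

  # Beta mean = p and variance = F p (1 - p), checked by Monte Carlo at a
  # pinned ancestral frequency
  big_panel <- simulate_panel(1e5, seed = 7)
  m <- simulate_frequencies(big_panel, 2, c(0.1, 0.5),
                            anc_range = c(0.5, 0.5), seed = 8)
  expect_lt(abs(mean(m$freqs[1, ]) - 0.5),
            3 * sqrt(0.1 * 0.25 / 1e5))
  expect_lt(abs(var(m$freqs[2, ]) - 0.125), 0.1 * 0.125)

  expect_error(simulate_frequencies(panel, 2, c(0.1, 1)), "\\(0, 1\\)")
  expect_error(simulate_frequencies(panel, 1, 0), "\\(0, 1\\)")
})

test_that("genotypes are Binomial(2, QF)", {
  panel <- simulate_panel(10, seed = 1)
  model <- simulate_frequencies(panel, 1, 0.2, seed = 2)
  # degenerate p = 0 -> all genotypes 0
  model$freqs[1, ] <- 0
  G <- simulate_genotypes(model, matrix(1, 50, 1), seed = 3)
  expect_true(all(G$counts == 0))

  # mean genotype 2f at a single SNP over many individuals
  p1 <- tiny_panel("A", "C")
  m1 <- simulate_frequencies(p1, 2, c(0.1, 0.1), seed = 4)
  m1$freqs <- matrix(c(0.3, 0.9), 2, 1)
  G1 <- simulate_genotypes(m1, cbind(rep(1, 1e5), 0), seed = 5)
  se <- sqrt(2 * 0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(G1$counts) - 0.6), 3 * se)

  # heterozygote mass of Bin(2, 1/2) is 1/2
  p2 <- simulate_panel(1e4, seed = 6)
  m2 <- simulate_frequencies(p2, 1, 0.1, seed = 7)
  m2$freqs[] <- 0.5
  G2 <- simulate_genotypes(m2, matrix(1, 1, 1), seed = 8)
  expect_lt(abs(mean(G2$counts == 1) - 0.5), 3 * sqrt(0.25 / 1e4))

  expect_error(simulate_genotypes(m1, matrix(c(0.5, 0.4), 1, 2)), "simplex")
})

test_that("observation simulator matches its stated distributions", {
  w <- sim_world(10, n_snps = 1e5, n_per_pop = 1)
  G1 <- subset_geno(w$G, samples = 1)
  obs <- simulate_observations(G1, coverage = 0.08, seed = 11)
  expect_lt(abs(nrow(obs) - 8000), 3 * sqrt(8000))
  expect_true(all(obs$dist5 + obs$dist3 == obs$fraglen + 1L))
  expect_true(all(obs$dist5 >= 1 & obs$dist3 >= 1))
  expect_true(all(obs$fraglen >= 35))

  obs2 <- simulate_observations(G1, coverage = 1, fragment_length_mean = 65,
                                seed = 12)
  expect_lt(abs(mean(obs2$fraglen) - 65), 0.02 * 65)

  # homozygous-alternative genotypes emit only the alternative allele
  hom <- which(G1$counts[1, ] == 2L)
  sub <- obs2[obs2$snp_index %in% hom, ]
  expect_true(all(sub$base == w$panel$alt[sub$snp_index]))

  # bit-reproducible under a fixed seed
  expect_identical(obs2, simulate_observations(
    G1, coverage = 1, fragment_length_mean = 65, seed = 12))
})

test_that("damage follows the geometric end-decay model", {
  pan <- tiny_panel("C", "T")
  n <- 1e5
  # all-C observations pinned at a given 5' distance
  rate_at <- function(dist5, dm, seed) {
    obs <- make_obs(1L, "C", fraglen = 61L, dist5 = dist5)
    obs <- obs[rep(1, n), ]
    mean(apply_damage(obs, dm, seed = seed)$base == "T")
  }
  dm <- damage_model(d_max5 = 0.3, decay = 0.7)
  expect_lt(abs(rate_at(1L, dm, 21) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(rate_at(4L, dm, 22) - 0.1029),
            3 * sqrt(0.1029 * (1 - 0.1029) / n))

  # UDG-half: zero flips beyond 2 bp from both ends
  dmu <- damage_model(d_max5 = 0.3, decay = 0.7, udg_half = TRUE)
  expect_identical(rate_at(10L, dmu, 23), 0)
  pr <- damage_rates(make_obs(1L, "C", fraglen = 61L, dist5 = 10L), dmu)
  expect_identical(pr$p_ct, 0)

  # closed-form rates
  pr2 <- damage_rates(make_obs(1L, "C", dist5 = c(1L, 4L), fraglen = 61L), dm)
  expect_equal(pr2$p_ct, c(0.3, 0.3 * 0.7^3))
})

test_that("damage only touches C (and G in double-strand mode)", {
  obs <- make_obs(1L, c("A", "T"), dist5 = 1L, fraglen = 61L)
  dm <- damage_model(d_max5 = 1, d_max3 = 1, decay = 0.99)
  expect_identical(apply_damage(obs, dm, seed = 1)$base, c("A", "T"))

  # single-strand: C->T from both ends, never G->A
  obs_g <- make_obs(1L, "G", dist5 = 1L, fraglen = 61L)[rep(1, 1000), ]
  dm_ss <- damage_model(d_max5 = 0.5, d_max3 = 0.5, decay = 0.7,
                        mode = "single_strand")
  expect_true(all(apply_damage(obs_g, dm_ss, seed = 2)$base == "G"))
  obs_c3 <- make_obs(1L, "C", dist5 = 61L, fraglen = 61L)[rep(1, 2000), ]
  expect_gt(mean(apply_damage(obs_c3, dm_ss, seed = 3)$base == "T"), 0.3)
  # ...but in double-strand mode the 3' end only deaminates G
  expect_true(all(apply_damage(obs_c3, damage_model(0.5, 0.5, 0.7),
                               seed = 4)$base == "C"))
})

test_that("flips at transversion SNPs leave the allele pair", {
  w <- sim_world(30, n_snps = 5000, n_per_pop = 2)
  obs <- simulate_observations(subset_geno(w$G, samples = 1),
                               coverage = 2, seed = 31)
  dob <- apply_damage(obs, damage_model(), seed = 32)
  tv <- which(w$panel$class == "transversion")
  chg <- which(obs$base != dob$base & obs$snp_index %in% tv)
  expect_gt(length(chg), 0)
  in_pair <- dob$base[chg] == w$panel$ref[dob$snp_index[chg]] |
    dob$base[chg] == w$panel$alt[dob$snp_index[chg]]
  expect_false(any(in_pair))

  # out-of-pair observation mass matches the expected flip mass
  pr <- damage_rates(obs, damage_model())
  src_c <- obs$base == "C" & obs$snp_index %in% tv &
    w$panel$ref[obs$snp_index] != "T" & w$panel$alt[obs$snp_index] != "T"
  src_g <- obs$base == "G" & obs$snp_index %in% tv &
    w$panel$ref[obs$snp_index] != "A" & w$panel$alt[obs$snp_index] != "A"
  expected <- sum(pr$p_ct[src_c]) + sum(pr$p_ga[src_g])
  out_pair <- sum(dob$base != w$panel$ref[dob$snp_index] &
                    dob$base != w$panel$alt[dob$snp_index])
  expect_lt(abs(out_pair - expected), 4 * sqrt(expected))
})
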