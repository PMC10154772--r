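# paleodamage

Ancient-DNA library preparation leaves chemical fingerprints in the data.
Post-mortem deamination converts cytosine to uracil, read as thymine, so
untreated ("non-UDG") libraries accumulate C→T misincorporations at 5′
fragment ends and complementary G→A at 3′ ends. Because these artefacts
mimic *transition* SNPs ({C,T}, {A,G}) and standard capture panels are
~80% transitions, they can leak into every downstream population-genetic
statistic. `paleodamage` is an R package for quantifying that leak and its
standard mitigation — transversion-only analysis — on fully synthetic,
fully seeded data.

It is aimed at paleogenomics methodologists and anyone who needs a tested,
self-contained implementation of the ancient-DNA analysis stack:

* **Synthetic data**: transition-rich SNP panels; Balding–Nichols
  population frequencies `f ~ Beta(p(1−F)/F, (1−p)(1−F)/F)`; admixed
  genotypes `n_ij ~ Bin(2, Σ_k q_ik f_kj)`; fragment-level sequencing
  observations; a geometric end-decay damage model
  `P(flip at distance p) = d_max · λ^(p−1)` with double-strand,
  single-strand and UDG-half (terminal 2 bp only) modes.
* **Genotypes**: pseudo-haploid calling (random high-quality base,
  phred ≥ 30), terminal trimming, transition masking, PLINK-style LD
  pruning (50/5/0.2), EIGENSTRAT `.geno/.snp/.ind` I/O.
* **Admixture**: maximum-likelihood Q/F estimation under the binomial
  model by multi-start EM (compiled core, monotone log-likelihood),
  cross-validation error, label-switching alignment.
* **F-statistics**: F4 = mean (a−b)(c−d) and ABBA-BABA D with weighted
  block-jackknife standard errors (|z| > 3 convention), Hudson Fst.
* **PCA**: ±1/0 genotype encoding, reference PCA, and least-squares
  projection of high-missingness samples without imputation.
* **Pipeline**: `run_experiment()` compares undamaged, damaged and
  UDG-half libraries of the same individuals on all SNPs vs
  transversions only, end to end.

## Worked example

```r
library(paleodamage)

panel <- simulate_panel(4000, transition_fraction = 0.8, seed = 1)
table(panel$class)
#>   transition transversion
#>         3169          831

model   <- simulate_frequencies(panel, 2, c(0.10, 0.15), seed = 2)
moderns <- simulate_genotypes(model, diag(2)[rep(1:2, each = 25), ], seed = 3,
                              groups = rep(c("pop1", "pop2"), each = 25))
target  <- simulate_genotypes(model, matrix(c(0.5, 0.5), 1),
                              samples = "ancient1", seed = 4)

obs <- simulate_observations(target, coverage = 1,
                             fragment_length_mean = 70, seed = 5)
nrow(obs)                                   # 4089 observations (~1x depth)
dmg <- apply_damage(obs, damage_model(d_max5 = 0.3, d_max3 = 0.3,
                                      decay = 0.7), seed = 6)
sum(dmg$base != obs$base)                   # 37 deamination flips
lib <- to_pseudodiploid(call_pseudohaploid(dmg, panel, min_bq = 30, seed = 7))
lib
#> geno_matrix: 1 samples x 4000 SNPs (1 pseudo-haploid, 40.2% missing)

hudson_fst(allele_frequencies(moderns, 1:25),
           allele_frequencies(moderns, 26:50))
#> [1] 0.1225                                # simulated drift 0.10 + 0.15 / 2
```

The full three-protocol experiment (ten "twin" individuals sequenced as
undamaged, damaged and UDG-half libraries; admixture at K = 3; F4 twin
contrasts; PCA projection; both SNP sets):

```r
cfg <- experiment_config(seed = 42, n_starts = 1L, max_iter = 300L, tol = 1e-4)
report <- run_experiment(cfg)
report
#> distortion_report
#>   [all_snps] 4339 SNPs after filters
#>     admixture divergence vs undamaged:  undamaged=0.0000, damaged=0.0326, udg_half=0.0157
#>     f4 twin contrast (damaged): delta=1.55e-03 combined SE=1.24e-03 z=1.26
#>     PCA twin distance vs undamaged:  undamaged=0.000, damaged=1.413, udg_half=1.644
#>   [transversions] 879 SNPs after filters
#>     admixture divergence vs undamaged:  undamaged=0.0000, damaged=0.0756, udg_half=0.0802
#>     f4 twin contrast (damaged): delta=-1.75e-03 combined SE=1.98e-03 z=-0.88
#>     PCA twin distance vs undamaged:  undamaged=0.000, damaged=1.657, udg_half=1.616
```

Reading it: the damaged libraries' ancestry differs from their undamaged
twins (`divergence 0.033`), and the F4 twin contrast is non-zero but within
noise at this desk scale (z ≈ 1.3) — at default damage rates the
deamination signal is real but an order of magnitude below the
pseudo-haploid sampling noise of a 4–5k-SNP panel; the vignette quantifies
this scaling and shows the full distortion emerging at stronger damage.
`write_report(report, "out/")` emits `report.json` plus Q-matrix, F4 and
PCA score TSVs.

A command-line interface wraps the same functions
(`exec/paleodamage simulate|call|mask|prune|admix|f4|pca|experiment`);
config files are JSON.

## Further reading

`vignettes/protocol-distortion.Rmd` documents the generative model and its
defaults, every estimator and its numerical choices, what the synthetic
world does and does not emulate, and a quantified analysis of which
distortion effects are and are not detectable at desk scale.
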