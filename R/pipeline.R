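#' Configuration for the protocol-comparison experiment
#'
#' Assembles (and defaults) every knob of the synthetic study design: a
#' transition-rich panel, source populations plus an outgroup under
#' Balding-Nichols drift, a set of "twin" target individuals sequenced
#' under several library protocols, and the analysis parameters. Defaults
#' are desk-scale but keep the regimes of real ancient-DNA work: 80%
#' transitions, fragment lengths around 70 bp, terminal C->T/G->A damage
#' 0.3 decaying geometrically (0.7), phred >= 30 calling, PLINK-style
#' 50/5/0.2 pruning, jackknife blocks of 100 SNPs, and K one above the
#' number of source populations so a spurious damage component can emerge.
#'
#' @param ... overrides for any default listed below.
#' @param seed integer master seed; stage seeds are small fixed offsets.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(..., seed = 1L) {
  cfg <- list(
    n_snps = 5000L, transition_fraction = 0.8, n_chrom = 1L,
    n_src_pops = 2L, fst = c(0.10, 0.15), outgroup_fst = 0.30,
    n_per_pop = 25L, n_twins = 10L, twin_admixture = NULL,
    coverage = 1.0, fragment_length_mean = 70,
    damage = list(d_max5 = 0.3, d_max3 = 0.3, decay = 0.7,
                  mode = "double_strand"),
    protocols = c("undamaged", "damaged", "udg_half"),
    trim_bp = 2L, min_bq = 30L,
    K = NULL, n_starts = 2L, tol = 1e-5, max_iter = 500L,
    pseudohaploid_as = "two",
    block_size = 100L, n_components = 2L,
    ld_prune = TRUE, ld_window = 50L, ld_step = 5L, ld_r2 = 0.2,
    prune_order = "after_mask",
    seed = as.integer(seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$K <- cfg$K %||% (cfg$n_src_pops + 1L)
  cfg$twin_admixture <- cfg$twin_admixture %||%
    rep(1 / cfg$n_src_pops, cfg$n_src_pops)
  if (length(cfg$protocols) < 2) stop("need at least two protocols")
  bad <- setdiff(cfg$protocols, c("undamaged", "damaged", "udg_half"))
  if (length(bad)) stop("unknown protocols: ", paste(bad, collapse = ", "))
  structure(cfg, class = "experiment_config")
}

protocol_damage <- function(cfg, protocol) {
  dm <- cfg$damage
  switch(protocol,
         undamaged = NULL,
         damaged = damage_model(dm$d_max5, dm$d_max3, dm$decay, dm$mode,
                                udg_half = FALSE),
         udg_half = damage_model(dm$d_max5, dm$d_max3, dm$decay, dm$mode,
                                 udg_half = TRUE))
}

#' SNP call-set accounting
#'
#' Per-library counts of called (non-missing) SNPs with all pairwise
#' intersections and the full intersection, the Venn-diagram bookkeeping of
#' a multi-protocol comparison.
#'
#' @param masks named list (>= 2) of logical vectors, one per call set,
#'   `TRUE` where the SNP is called.
#' @return list with `counts`, `pairwise` (symmetric intersection-count
#'   matrix) and `all_sets` (size of the full intersection).
#' @export
snp_set_accounting <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 2)
  m <- length(masks[[1]])
  stopifnot(all(vapply(masks, length, 0L) == m))
  nm <- names(masks) %||% sprintf("set%d", seq_along(masks))
  counts <- vapply(masks, sum, 0L)
  pairwise <- matrix(0L, length(masks), length(masks), dimnames = list(nm, nm))
  for (i in seq_along(masks)) {
    for (j in seq_along(masks)) {
      pairwise[i, j] <- sum(masks[[i]] & masks[[j]])
    }
  }
  list(counts = counts, pairwise = pairwise,
       all_sets = sum(Reduce(`&`, masks)))
}

prune_set <- function(G, cfg) {
  if (!isTRUE(cfg$ld_prune)) return(seq_len(ncol(G$counts)))
  ld_prune(G, window = cfg$ld_window, step = cfg$ld_step, r2_max = cfg$ld_r2)
}

#' Run the protocol-comparison experiment
#'
#' The executable study design: simulate panel and populations, sequence
#' each twin individual under every configured protocol, damage and (for
#' UDG-half) trim, call pseudo-haploid genotypes, then analyse the
#' all-SNPs and transversions-only sets side by side with ADMIXTURE-style
#' fitting, F4 twin contrasts, and projection PCA. Every stage is seeded
#' from `config$seed`, so identical configs give identical reports.
#'
#' @param config an [experiment_config()].
#' @return a `distortion_report` list; see the fields in the examples of
#'   the package vignette. Key entries: `admixture$divergence` (per
#'   protocol and SNP set, mean |Q - Q_undamaged| over twins), `f4`
#'   (per-protocol estimates and twin contrasts), `pca$twin_distance`,
#'   `protocol_component_cor`, `snp_counts`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  if (!"undamaged" %in% cfg$protocols) {
    stop("the experiment needs the 'undamaged' protocol as reference")
  }
  s0 <- cfg$seed

  panel <- simulate_panel(cfg$n_snps, cfg$transition_fraction,
                          n_chrom = cfg$n_chrom, seed = s0 + 1L)
  n_all_pops <- cfg$n_src_pops + 1L               # + outgroup
  model <- simulate_frequencies(panel, n_all_pops,
                                c(cfg$fst, cfg$outgroup_fst),
                                seed = s0 + 2L)

  ## modern cohort: diploid members of each source population + outgroup
  Qm <- diag(n_all_pops)[rep(seq_len(n_all_pops), each = cfg$n_per_pop), ]
  moderns <- simulate_genotypes(
    model, Qm,
    samples = sprintf("pop%d_ind%d",
                      rep(seq_len(n_all_pops), each = cfg$n_per_pop),
                      rep(seq_len(cfg$n_per_pop), n_all_pops)),
    groups = rep(c(sprintf("pop%d", seq_len(cfg$n_src_pops)), "outgroup"),
                 each = cfg$n_per_pop),
    seed = s0 + 3L)

  ## twin target individuals: admixed between the source populations
  Qt <- matrix(rep(c(cfg$twin_admixture, 0), cfg$n_twins),
               cfg$n_twins, n_all_pops, byrow = TRUE)
  twins <- simulate_genotypes(model, Qt,
                              samples = sprintf("twin%d", seq_len(cfg$n_twins)),
                              groups = "twin", seed = s0 + 4L)

  ## per-protocol libraries of the same twin genotypes
  libs <- list()
  for (pi in seq_along(cfg$protocols)) {
    prot <- cfg$protocols[pi]
    obs <- simulate_observations(twins, cfg$coverage,
                                 cfg$fragment_length_mean,
                                 seed = s0 + 10L + pi)
    dm <- protocol_damage(cfg, prot)
    if (!is.null(dm)) obs <- apply_damage(obs, dm, seed = s0 + 20L + pi)
    if (prot == "udg_half") obs <- trim_terminal(obs, cfg$trim_bp)
    calls <- call_pseudohaploid(obs, panel, samples = twins$samples,
                                min_bq = cfg$min_bq, seed = s0 + 30L + pi)
    g <- to_pseudodiploid(calls, groups = prot)
    g$samples <- paste0(g$samples, "_", prot)
    rownames(g$counts) <- g$samples
    libs[[prot]] <- g
  }

  combined <- do.call(rbind_geno, c(list(moderns), unname(libs)))
  is_outgroup <- combined$groups == "outgroup"
  lib_ids <- lapply(libs, `[[`, "samples")

  snp_sets <- list(all_snps = seq_len(nrow(panel)),
                   transversions = which(panel$class == "transversion"))

  report <- list(config = cfg, admixture = list(), f4 = list(), pca = list())

  acct_masks_all <- lapply(libs, function(g) colSums(!is.na(g$counts)) > 0)
  report$snp_counts <- list(
    all_snps = snp_set_accounting(acct_masks_all),
    transversions = snp_set_accounting(
      lapply(acct_masks_all, function(mk) mk & panel$class == "transversion")))

  for (set_name in names(snp_sets)) {
    Gset <- subset_geno(combined, snps = snp_sets[[set_name]])
    kept <- prune_set(Gset, cfg)
    Gset <- subset_geno(Gset, snps = kept)

    ## --- admixture on source populations + libraries (outgroup excluded)
    Gadm <- subset_geno(Gset, samples = which(!is_outgroup))
    fit <- fit_admixture(Gadm, cfg$K, n_starts = cfg$n_starts,
                         tol = cfg$tol, max_iter = cfg$max_iter,
                         seed = s0 + 40L,
                         pseudohaploid_as = cfg$pseudohaploid_as)
    Qrow <- function(ids) fit$Q[match(ids, Gadm$samples), , drop = FALSE]
    div <- vapply(cfg$protocols, function(pr) {
      mean(abs(Qrow(lib_ids[[pr]]) - Qrow(lib_ids[["undamaged"]])))
    }, 0)
    report$admixture[[set_name]] <-
      list(fit = fit, divergence_from_undamaged = div)

    ## protocol-vs-component correlation (Fig. 4 analogue): across all
    ## libraries, correlate the damage-associated component (largest
    ## damaged-minus-other mean loading) with the protocol indicator
    ## (1 = no retained damage, i.e. undamaged/UDG-half)
    if ("damaged" %in% cfg$protocols) {
      lib_rows <- match(unlist(lib_ids), Gadm$samples)
      indicator <- as.numeric(!grepl("_damaged$", Gadm$samples[lib_rows]))
      Ql <- fit$Q[lib_rows, , drop = FALSE]
      comp_gap <- colMeans(Ql[indicator == 0, , drop = FALSE]) -
        colMeans(Ql[indicator == 1, , drop = FALSE])
      comp <- which.max(comp_gap)
      report$admixture[[set_name]]$protocol_component_cor <-
        suppressWarnings(cor(indicator, Ql[, comp]))
      report$admixture[[set_name]]$damage_component <- comp
    }

    ## --- F4(W = pop1, Y = protocol libraries; X = pop2, O = outgroup)
    fw <- allele_frequencies(Gset, which(Gset$groups == "pop1"))
    fx <- allele_frequencies(Gset, which(Gset$groups == "pop2"))
    fo <- allele_frequencies(Gset, which(Gset$groups == "outgroup"))
    f4s <- lapply(cfg$protocols, function(pr) {
      fy <- allele_frequencies(Gset, lib_ids[[pr]])
      f4(fw, fy, fx, fo, block_size = cfg$block_size)
    })
    names(f4s) <- cfg$protocols
    contrasts <- lapply(setdiff(cfg$protocols, "undamaged"), function(pr) {
      delta <- f4s[[pr]]$estimate - f4s[["undamaged"]]$estimate
      se <- sqrt(f4s[[pr]]$stderr^2 + f4s[["undamaged"]]$stderr^2)
      list(protocol = pr, delta = delta, combined_se = se,
           z = if (se > 0) delta / se else NA_real_)
    })
    names(contrasts) <- setdiff(cfg$protocols, "undamaged")
    report$f4[[set_name]] <- list(per_protocol = f4s,
                                  twin_contrast = contrasts)

    ## --- projection PCA: reference = modern source populations
    ref_rows <- which(!is_outgroup[match(Gset$samples, combined$samples)] &
                        Gset$groups %in% sprintf("pop%d",
                                                 seq_len(cfg$n_src_pops)))
    Eref <- encode_genotypes(subset_geno(Gset, samples = ref_rows))
    pca <- fit_reference(Eref, n_components = cfg$n_components)
    proj <- lapply(cfg$protocols, function(pr) {
      project_pca(pca, encode_genotypes(
        subset_geno(Gset, samples = lib_ids[[pr]])))
    })
    names(proj) <- cfg$protocols
    tw_dist <- vapply(cfg$protocols, function(pr) {
      mean(sqrt(rowSums((proj[[pr]] - proj[["undamaged"]])^2)))
    }, 0)
    report$pca[[set_name]] <- list(model = pca, projections = proj,
                                   twin_distance_from_undamaged = tw_dist)
    report$n_snps_used <- c(report$n_snps_used,
                            stats::setNames(ncol(Gset$counts), set_name))
  }
  class(report) <- "distortion_report"
  report
}

#' @export
print.distortion_report <- function(x, ...) {
  cat("distortion_report\n")
  for (set in names(x$admixture)) {
    cat(sprintf("  [%s] %d SNPs after filters\n", set, x$n_snps_used[[set]]))
    div <- x$admixture[[set]]$divergence_from_undamaged
    cat("    admixture divergence vs undamaged: ",
        paste(sprintf("%s=%.4f", names(div), div), collapse = ", "), "\n")
    for (nm in names(x$f4[[set]]$twin_contrast)) {
      ct <- x$f4[[set]]$twin_contrast[[nm]]
      cat(sprintf("    f4 twin contrast (%s): delta=%.2e combined SE=%.2e z=%.2f\n",
                  nm, ct$delta, ct$combined_se, ct$z))
    }
    td <- x$pca[[set]]$twin_distance_from_undamaged
    cat("    PCA twin distance vs undamaged: ",
        paste(sprintf("%s=%.3f", names(td), td), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a distortion report to disk
#'
#' Emits `report.json` (summary statistics), `qmatrix_<set>.tsv`,
#' `f4_<set>.tsv` and `pca_scores_<set>.tsv` under `dir`.
#'
#' @param report a `distortion_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "distortion_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = report$config$seed,
                  n_snps_used = as.list(report$n_snps_used))
  for (set in names(report$admixture)) {
    adm <- report$admixture[[set]]
    summary[[set]] <- list(
      admixture_divergence = as.list(adm$divergence_from_undamaged),
      protocol_component_cor = adm$protocol_component_cor,
      f4 = lapply(report$f4[[set]]$per_protocol, function(r) {
        list(estimate = r$estimate, stderr = r$stderr, z = r$z,
             n_snps = r$n_snps, n_blocks = r$n_blocks)
      }),
      f4_twin_contrast = report$f4[[set]]$twin_contrast,
      pca_twin_distance =
        as.list(report$pca[[set]]$twin_distance_from_undamaged),
      snp_counts = list(
        counts = as.list(report$snp_counts[[set]]$counts),
        all_sets = report$snp_counts[[set]]$all_sets))
    fit <- adm$fit
    qm <- data.frame(sample = fit$samples, fit$Q)
    write.table(qm, file.path(dir, sprintf("qmatrix_%s.tsv", set)),
                quote = FALSE, sep = "\t", row.names = FALSE)
    f4tab <- do.call(rbind, lapply(names(report$f4[[set]]$per_protocol),
      function(nm) {
        r <- report$f4[[set]]$per_protocol[[nm]]
        data.frame(protocol = nm, estimate = r$estimate, stderr = r$stderr,
                   z = r$z, n_snps = r$n_snps, n_blocks = r$n_blocks)
      }))
    write.table(f4tab, file.path(dir, sprintf("f4_%s.tsv", set)),
                quote = FALSE, sep = "\t", row.names = FALSE)
    sc <- do.call(rbind, lapply(names(report$pca[[set]]$projections),
      function(nm) {
        p <- report$pca[[set]]$projections[[nm]]
        data.frame(sample = rownames(p), protocol = nm, p)
      }))
    write.table(sc, file.path(dir, sprintf("pca_scores_%s.tsv", set)),
                quote = FALSE, sep = "\t", row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
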