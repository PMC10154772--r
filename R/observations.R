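#' Post-mortem damage model
#'
#' Cytosine deamination converts C to U (read as T), concentrated at
#' fragment ends. On a double-stranded library this is seen as C->T at the
#' 5' end and G->A at the 3' end; single-stranded chemistry shows C->T at
#' both ends. The per-position rate decays geometrically from the terminal
#' maximum: rate at distance `p` from an end is `d_max * decay^(p - 1)`.
#' UDG-half treatment excises internal uracils but leaves the terminal
#' ~2 bp as an authenticity signal, modelled by zeroing the rate wherever
#' `min(dist5, dist3) > 2`.
#'
#' @param d_max5 C->T probability at the 5'-terminal base, in \[0, 1\].
#' @param d_max3 G->A (or 3' C->T for single-strand) terminal probability.
#' @param decay geometric decay factor, in (0, 1).
#' @param mode `"double_strand"` (C->T at 5', G->A at 3') or
#'   `"single_strand"` (C->T at both ends, no G->A).
#' @param udg_half if `TRUE`, damage survives only at the terminal 2 bp.
#' @return a `damage_model` list.
#' @export
damage_model <- function(d_max5 = 0.3, d_max3 = 0.3, decay = 0.7,
                         mode = c("double_strand", "single_strand"),
                         udg_half = FALSE) {
  check_prob(d_max5, "d_max5"); check_prob(d_max3, "d_max3")
  check_prob(decay, "decay", open = TRUE)
  mode <- match.arg(mode)
  structure(list(d_max5 = d_max5, d_max3 = d_max3, decay = decay,
                 mode = mode, udg_half = isTRUE(udg_half)),
            class = "damage_model")
}

validate_obs <- function(obs) {
  need <- c("snp_index", "sample_id", "base", "bq", "fraglen", "dist5", "dist3")
  if (!all(need %in% names(obs))) {
    stop("observation set must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(obs) && any(obs$dist5 + obs$dist3 != obs$fraglen + 1L)) {
    stop("invariant violated: dist5 + dist3 must equal fragment length + 1")
  }
  obs
}

#' Simulate sequencing observations at panel sites
#'
#' Emulates an aligned-read pileup for low-coverage ancient libraries
#' without modelling alignment itself. Per sample and SNP the depth is
#' `Poisson(coverage)`; each observation samples one of the two chromosomes
#' (so the alternative allele with probability genotype/2), a fragment
#' length from a shifted geometric distribution (minimum 35 bp) with the
#' requested mean, a uniform position of the SNP within the fragment, and a
#' two-point base quality (37 with probability 0.9, else 25) so that the
#' phred >= 30 calling filter is exercised.
#'
#' @param G a [geno_matrix()]; observations are generated for all its
#'   samples (subset first with [subset_geno()] for a single target).
#' @param coverage mean depth per site (> 0).
#' @param fragment_length_mean mean fragment length in bp (> 35).
#' @param bq_values,bq_probs base-quality support and mixture weights.
#' @param min_fraglen minimum fragment length.
#' @param seed optional integer seed.
#' @return an observation data frame with columns `snp_index`, `sample_id`,
#'   `base`, `bq`, `fraglen`, `dist5`, `dist3` (1-based end distances;
#'   `dist5 + dist3 = fraglen + 1`).
#' @export
simulate_observations <- function(G, coverage, fragment_length_mean = 70,
                                  bq_values = c(37L, 25L),
                                  bq_probs = c(0.9, 0.1),
                                  min_fraglen = 35L, seed = NULL) {
  stopifnot(inherits(G, "geno_matrix"), coverage > 0,
            fragment_length_mean > min_fraglen)
  set_seed_if(seed)
  m <- ncol(G$counts)
  out <- vector("list", length(G$samples))
  geom_p <- 1 / (fragment_length_mean - min_fraglen + 1)
  for (s in seq_along(G$samples)) {
    depth <- rpois(m, coverage)
    idx <- rep.int(seq_len(m), depth)
    n_obs <- length(idx)
    if (!n_obs) next
    g <- G$counts[s, idx]
    carry_alt <- runif(n_obs) < g / 2      # NA genotype -> NA -> dropped
    keep <- !is.na(carry_alt)
    idx <- idx[keep]; carry_alt <- carry_alt[keep]; n_obs <- length(idx)
    base <- ifelse(carry_alt, G$panel$alt[idx], G$panel$ref[idx])
    fraglen <- min_fraglen + rgeom(n_obs, geom_p)
    dist5 <- 1L + as.integer(floor(runif(n_obs) * fraglen))
    out[[s]] <- data.frame(
      snp_index = idx,
      sample_id = G$samples[s],
      base = base,
      bq = sample(bq_values, n_obs, replace = TRUE, prob = bq_probs),
      fraglen = fraglen,
      dist5 = dist5,
      dist3 = fraglen + 1L - dist5,
      stringsAsFactors = FALSE
    )
  }
  validate_obs(do.call(rbind, c(out, list(make.row.names = FALSE))) %||%
                 empty_obs())
}

empty_obs <- function() {
  data.frame(snp_index = integer(), sample_id = character(),
             base = character(), bq = integer(), fraglen = integer(),
             dist5 = integer(), dist3 = integer(), stringsAsFactors = FALSE)
}

#' Per-observation damage flip probabilities
#'
#' @param obs observation data frame (see [simulate_observations()]).
#' @param dm a [damage_model()].
#' @return list with vectors `p_ct` (C->T) and `p_ga` (G->A), one entry per
#'   observation, already zeroed beyond the terminal 2 bp for UDG-half.
#' @export
damage_rates <- function(obs, dm) {
  stopifnot(inherits(dm, "damage_model"))
  r5 <- dm$d_max5 * dm$decay^(obs$dist5 - 1)
  r3 <- dm$d_max3 * dm$decay^(obs$dist3 - 1)
  if (dm$mode == "double_strand") {
    p_ct <- r5
    p_ga <- r3
  } else {                               # single-strand: C->T at both ends
    p_ct <- pmin(1, r5 + r3)
    p_ga <- rep(0, nrow(obs))
  }
  if (dm$udg_half) {
    internal <- pmin(obs$dist5, obs$dist3) > 2L
    p_ct[internal] <- 0
    p_ga[internal] <- 0
  }
  list(p_ct = p_ct, p_ga = p_ga)
}

#' Apply post-mortem damage to an observation set
#'
#' Flips observed C bases to T and (in double-strand mode) G bases to A
#' with the end-distance dependent probabilities of the damage model. Only
#' the carried base matters: A and T source bases are never altered, and a
#' flip at a transversion SNP can create a base outside the allele pair
#' (later discarded at calling).
#'
#' @param obs observation data frame.
#' @param dm a [damage_model()].
#' @param seed optional integer seed.
#' @return the observation data frame with damaged `base` values.
#' @export
apply_damage <- function(obs, dm, seed = NULL) {
  validate_obs(obs)
  set_seed_if(seed)
  if (!nrow(obs)) return(obs)
  pr <- damage_rates(obs, dm)
  u <- runif(nrow(obs))
  flip_ct <- obs$base == "C" & u < pr$p_ct
  flip_ga <- obs$base == "G" & u < pr$p_ga
  obs$base[flip_ct] <- "T"
  obs$base[flip_ga] <- "A"
  obs
}
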