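#' Numeric encoding of genotypes for PCA
#'
#' Maps homozygous reference to +1, heterozygote to 0, homozygous
#' alternative to -1, preserving missingness. Pseudo-haploid samples
#' therefore take only +/-1 or `NA`. A `literal` variant (+1 hom ref,
#' 0 hom alt, -1 het) is kept behind a flag for comparison; it places the
#' heterozygote outside the homozygote interval and is not recommended for
#' a dosage model.
#'
#' @param G a [geno_matrix()].
#' @param literal use the non-standard heterozygote = -1 mapping.
#' @return samples x SNPs numeric matrix with `NA` for missing entries.
#' @export
encode_genotypes <- function(G, literal = FALSE) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!literal) {
    1 - G$counts
  } else {
    E <- matrix(NA_real_, nrow(G$counts), ncol(G$counts),
                dimnames = dimnames(G$counts))
    E[G$counts == 0L] <- 1
    E[G$counts == 2L] <- 0
    E[G$counts == 1L] <- -1
    E
  }
}

#' Fit a PCA model on reference (complete) samples
#'
#' Centers each SNP by its reference mean (missing entries, which should
#' be rare in the reference, are mean-imputed for fitting only) and
#' computes the leading principal components by singular value
#' decomposition. Optional per-SNP scaling by `sqrt(p(1-p))` is off by
#' default.
#'
#' @param E encoded reference matrix (see [encode_genotypes()]).
#' @param n_components number of components to retain.
#' @param scale logical; scale SNPs by the binomial standard deviation
#'   implied by their mean encoding.
#' @return a `pca_model`: list with `snp_means`, `scales`, `loadings`
#'   (SNPs x components, orthonormal), `explained_variance` (decreasing)
#'   and `reference_scores` (samples x components).
#' @export
fit_reference <- function(E, n_components = 10L, scale = FALSE) {
  E <- as.matrix(E)
  if (n_components > min(dim(E))) {
    stop("n_components exceeds the matrix rank bound min(samples, SNPs)")
  }
  miss_rate <- mean(is.na(E))
  if (miss_rate > 0.05) {
    warning(sprintf("reference missingness %.1f%% exceeds 5%%", 100 * miss_rate))
  }
  mu <- colMeans(E, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- sweep(E, 2, mu)
  X[is.na(X)] <- 0                       # mean imputation, fitting only
  sc <- rep(1, ncol(E))
  if (scale) {
    ## encoded mean m relates to allele frequency p by m = 1 - 2p
    p <- pmin(pmax((1 - mu) / 2, 1e-6), 1 - 1e-6)
    sc <- sqrt(p * (1 - p))
    X <- sweep(X, 2, sc, "/")
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(E)
  structure(list(snp_means = mu, scales = sc, loadings = sv$v,
                 explained_variance = sv$d[seq_len(n_components)]^2 /
                   (nrow(E) - 1),
                 reference_scores = scores),
            class = "pca_model")
}

#' Project samples with missing data onto a fitted PCA
#'
#' For each sample, solves the least-squares problem
#' `min_s || x_obs - mu_obs - L_obs s ||^2` over its non-missing SNPs
#' (normal equations on the restricted loadings). Complete samples recover
#' their fitted scores exactly; high-missingness ancient samples get the
#' best-fitting coordinates without imputation. Rank-deficient restricted
#' loadings fall back to the minimum-norm solution with a warning.
#'
#' @param model a `pca_model` from [fit_reference()].
#' @param E encoded matrix (samples x SNPs) or a single encoded vector on
#'   the model's panel.
#' @return samples x components score matrix.
#' @export
project_pca <- function(model, E) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  E <- as.matrix(E)
  if (ncol(E) != length(model$snp_means)) {
    stop("sample does not share the model's SNP panel")
  }
  k <- ncol(model$loadings)
  out <- matrix(NA_real_, nrow(E), k, dimnames = list(rownames(E), NULL))
  for (i in seq_len(nrow(E))) {
    obs <- which(!is.na(E[i, ]))
    if (!length(obs)) stop("sample ", i, " has no non-missing SNPs")
    L <- model$loadings[obs, , drop = FALSE]
    y <- (E[i, obs] - model$snp_means[obs]) / model$scales[obs]
    M <- crossprod(L)
    s <- tryCatch(solve(M, crossprod(L, y)), error = function(e) NULL)
    if (is.null(s)) {
      warning("rank-deficient restricted loadings for sample ", i,
              "; returning the minimum-norm solution")
      sv <- svd(L)
      pos <- sv$d > sv$d[1] * 1e-12
      s <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    }
    out[i, ] <- s
  }
  out
}
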