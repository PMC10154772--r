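## Maximum-likelihood ancestry estimation under the binomial admixture
## model: n_ij ~ Bin(c_i, p_ij), p_ij = sum_k q_ik f_kj. Q rows live on the
## K-simplex, F in [0,1]. Optimization is EM (monotone ascent); the
## compiled inner loop lives in src/admixture_em.cpp and a one-step pure-R
## reference (em_step_r) is kept for cross-checking.

admix_inputs <- function(G, pseudohaploid_as = c("two", "one")) {
  stopifnot(inherits(G, "geno_matrix"))
  pseudohaploid_as <- match.arg(pseudohaploid_as)
  n <- G$counts * 1.0
  cvec <- rep(2, nrow(n))
  if (pseudohaploid_as == "one") {
    ph <- G$ploidy == "pseudo_haploid"
    n[ph, ] <- n[ph, ] / 2
    cvec[ph] <- 1
  }
  obs <- !is.na(n) * 1.0
  n[is.na(n)] <- 0
  list(n = n, obs = obs, cvec = cvec)
}

check_Q <- function(Q, tol = 1e-6) {
  if (any(Q < -tol) || any(abs(rowSums(Q) - 1) > tol)) {
    stop("each row of Q must lie on the simplex (tolerance ", tol, ")")
  }
  invisible(Q)
}

#' Admixture model log-likelihood
#'
#' Binomial log-likelihood (up to the constant binomial coefficient) of
#' genotype counts under ancestry proportions `Q` and ancestral allele
#' frequencies `F`: the sum over non-missing entries of
#' `n log(p) + (c - n) log(1 - p)` with `p = QF` clamped to
#' `[1e-9, 1 - 1e-9]`. Diploid samples have `c = 2`; pseudo-haploid 0/2
#' coding is treated as `c = 2` by default or as one Bernoulli trial with
#' `pseudohaploid_as = "one"`.
#'
#' @param G a [geno_matrix()].
#' @param Q samples x K ancestry proportions (rows on the simplex).
#' @param F_mat K x SNPs ancestral allele frequencies in \[0, 1\].
#' @param pseudohaploid_as `"two"` (default) or `"one"` trials for
#'   pseudo-haploid samples.
#' @return log-likelihood value (always <= 0).
#' @export
admixture_loglik <- function(G, Q, F_mat, pseudohaploid_as = c("two", "one")) {
  d <- admix_inputs(G, pseudohaploid_as)
  Q <- as.matrix(Q); F_mat <- as.matrix(F_mat)
  check_Q(Q)
  stopifnot(nrow(Q) == nrow(d$n), ncol(Q) == nrow(F_mat),
            ncol(F_mat) == ncol(d$n), all(F_mat >= 0), all(F_mat <= 1))
  eps <- 1e-9
  P <- pmin(pmax(Q %*% F_mat, eps), 1 - eps)
  sum((d$n * log(P) + (d$cvec - d$n) * log1p(-P)) * d$obs)
}

## one pure-R EM step; reference implementation for tests
em_step_r <- function(n, obs, cvec, Q, F_mat, eps = 1e-9) {
  P <- pmin(pmax(Q %*% F_mat, eps), 1 - eps)
  A <- (n / P) * obs
  B <- ((cvec - n) / (1 - P)) * obs
  Qn <- Q * (A %*% t(F_mat) + B %*% t(1 - F_mat))
  Qn <- Qn / pmax(rowSums(obs) * cvec, 1)
  Qn <- Qn / rowSums(Qn)
  Fa <- F_mat * (t(Q) %*% A)
  Fb <- (1 - F_mat) * (t(Q) %*% B)
  Fn <- Fa / (Fa + Fb)
  Fn[!is.finite(Fn)] <- F_mat[!is.finite(Fn)]
  list(Q = Qn, F = Fn)
}

#' Fit the admixture model by multi-start EM
#'
#' Runs `n_starts` EM optimizations from random initializations (Q rows
#' from Dirichlet(1,...,1), F from Uniform(0.05, 0.95)) and keeps the best
#' run: lowest cross-validation error when `cv_folds >= 2` (ties broken by
#' log-likelihood), otherwise highest log-likelihood. Each run iterates
#' until the log-likelihood gain falls below `tol` or `max_iter` is
#' reached; non-convergence is reported via the `converged` flag, not an
#' error.
#'
#' @inheritParams admixture_loglik
#' @param K number of ancestral populations (>= 1).
#' @param n_starts number of random restarts.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap per start.
#' @param cv_folds if >= 2, compute a `cv_error` per start (see
#'   [cv_error()]) and select by it; 0 (default) selects by likelihood.
#' @param seed optional integer seed.
#' @return an `admixture_fit`: list with `Q` (samples x K), `F` (K x SNPs),
#'   `loglik`, `loglik_trace`, `cv_error` (NA unless requested), `n_iter`,
#'   `converged`, `K`, `seed`.
#' @export
fit_admixture <- function(G, K, n_starts = 10L, tol = 1e-6, max_iter = 2000L,
                          cv_folds = 0L, seed = NULL,
                          pseudohaploid_as = c("two", "one")) {
  pseudohaploid_as <- match.arg(pseudohaploid_as)
  d <- admix_inputs(G, pseudohaploid_as)
  stopifnot(K >= 1, nrow(d$n) >= K, ncol(d$n) >= 1, n_starts >= 1)
  set_seed_if(seed)
  N <- nrow(d$n); M <- ncol(d$n)

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    Q0 <- matrix(rgamma(N * K, 1), N, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(runif(K * M, 0.05, 0.95), K, M)
    fit <- admix_em_cpp(d$n, d$obs, d$cvec, Q0, F0,
                        as.integer(max_iter), tol)
    fit$cv <- if (cv_folds >= 2) {
      cv_error(G, K, folds = cv_folds, warm = fit,
               pseudohaploid_as = pseudohaploid_as,
               tol = tol, max_iter = max_iter)
    } else NA_real_
    runs[[s]] <- fit
  }
  ll <- vapply(runs, function(r) max(r$loglik_trace), 0)
  best <- if (cv_folds >= 2) {
    cv <- vapply(runs, `[[`, 0, "cv")
    order(cv, -ll)[1]
  } else which.max(ll)
  r <- runs[[best]]
  if (!r$converged) {
    warning("EM did not reach tolerance ", tol, " within ", max_iter,
            " iterations")
  }
  structure(list(Q = r$Q, F = r$F, loglik = max(r$loglik_trace),
                 loglik_trace = r$loglik_trace, cv_error = r$cv,
                 n_iter = r$n_iter, converged = r$converged,
                 K = as.integer(K), seed = seed,
                 samples = G$samples), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d samples, loglik = %.2f (%s, %d iters)\n",
              x$K, nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Cross-validation error of the admixture model
#'
#' Partitions the non-missing genotype entries into `folds` random folds;
#' each fold is masked in turn, the model refit, and the mean squared
#' deviation between the held-out counts `n` and their fitted binomial
#' means `c * p` recorded. Returns the average over folds. Used to pick
#' the number of clusters and (as in the standard protocol) the best of
#' several random restarts.
#'
#' @inheritParams fit_admixture
#' @param folds number of folds (>= 2).
#' @param warm optional fit (with `Q`/`F`) used as a warm start for the
#'   fold refits; by default each fold refits from one random start.
#' @return mean held-out squared error; 0 with a warning if no entries
#'   could be masked.
#' @export
cv_error <- function(G, K, folds = 5L, seed = NULL, warm = NULL,
                     tol = 1e-5, max_iter = 500L,
                     pseudohaploid_as = c("two", "one")) {
  pseudohaploid_as <- match.arg(pseudohaploid_as)
  stopifnot(folds >= 2)
  d <- admix_inputs(G, pseudohaploid_as)
  set_seed_if(seed)
  N <- nrow(d$n); M <- ncol(d$n)
  present <- which(d$obs > 0)
  if (!length(present)) {
    warning("no non-missing entries to hold out; cv error defined as 0")
    return(0)
  }
  fold_of <- sample(rep_len(seq_len(folds), length(present)))
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    held <- present[fold_of == f]
    obs_f <- d$obs
    obs_f[held] <- 0
    if (is.null(warm)) {
      Q0 <- matrix(rgamma(N * K, 1), N, K); Q0 <- Q0 / rowSums(Q0)
      F0 <- matrix(runif(K * M, 0.05, 0.95), K, M)
    } else {
      Q0 <- warm$Q; F0 <- warm$F
    }
    fit <- admix_em_cpp(d$n, obs_f, d$cvec, Q0, F0,
                        as.integer(max_iter), tol)
    P <- fit$Q %*% fit$F
    pred <- (d$cvec * P)[held]      # c_i recycled down columns
    errs[f] <- mean((d$n[held] - pred)^2)
  }
  mean(errs)
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Resolve label switching between two ancestry matrices
#'
#' Finds the permutation of the columns of `Q_est` maximizing the sum of
#' per-component correlations with `Q_ref` (exhaustive assignment; K is
#' small in practice). Components with zero variance fall back to a
#' negative mean-absolute-difference similarity.
#'
#' @param Q_est,Q_ref samples x K ancestry matrices with matching K.
#' @return integer permutation `perm` such that `Q_est[, perm]` aligns
#'   component-wise with `Q_ref`.
#' @export
align_components <- function(Q_est, Q_ref) {
  Q_est <- as.matrix(Q_est); Q_ref <- as.matrix(Q_ref)
  if (ncol(Q_est) != ncol(Q_ref)) stop("component counts (K) differ")
  k <- ncol(Q_est)
  if (k == 1) return(1L)
  if (k > 8) stop("exhaustive alignment supports K <= 8")
  sim <- suppressWarnings(cor(Q_est, Q_ref))
  fallback <- -vapply(seq_len(k), function(a) {
    vapply(seq_len(k), function(b) mean(abs(Q_est[, a] - Q_ref[, b])), 0)
  }, numeric(k))
  sim[!is.finite(sim)] <- t(fallback)[!is.finite(sim)]
  pp <- perms_of(k)
  scores <- apply(pp, 1, function(pr) sum(sim[cbind(pr, seq_len(k))]))
  as.integer(pp[which.max(scores), ])
}
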