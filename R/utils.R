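#' @useDynLib paleodamage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rbeta rbinom rgamma rgeom rpois runif sd var
#' @importFrom utils read.table write.table
NULL

BASES <- c("A", "C", "G", "T")

## {C,T} and {A,G} pairs are transitions; everything else a transversion
is_transition_pair <- function(a1, a2) {
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "")
  key %in% c("CT", "AG")
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x) ||
      (open && any(x <= 0 | x >= 1)) ||
      (!open && any(x < 0 | x > 1))) {
    stop(sprintf("`%s` must lie in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
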