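#' EIGENSTRAT output
#'
#' Writes `<prefix>.geno` (one row per SNP, one character per sample:
#' 0/1/2 alternative-allele count, 9 = missing), `<prefix>.snp`
#' (id, chromosome, genetic position 0.0, physical position, ref, alt) and
#' `<prefix>.ind` (sample, sex/ploidy code, group). The ploidy flag is
#' preserved in the second `.ind` column (`U` diploid, `H` pseudo-haploid),
#' a package convention, so write/read round-trips are lossless.
#'
#' @param G a [geno_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(G, prefix) {
  stopifnot(inherits(G, "geno_matrix"))
  p <- G$panel
  write.table(
    data.frame(p$snp_id, p$chrom, format(0, nsmall = 1), p$pos, p$ref, p$alt),
    paste0(prefix, ".snp"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(G$samples, ifelse(G$ploidy == "pseudo_haploid", "H", "U"),
               G$groups),
    paste0(prefix, ".ind"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  g <- G$counts                      # samples x SNPs
  g[is.na(g)] <- 9L
  lines <- apply(g, 2L, paste0, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  invisible(prefix)
}

#' EIGENSTRAT input
#'
#' @param prefix path prefix of a `.geno`/`.snp`/`.ind` triple written by
#'   [write_eigenstrat()] (or compatible).
#' @return a [geno_matrix()].
#' @export
read_eigenstrat <- function(prefix) {
  snp <- read.table(paste0(prefix, ".snp"), stringsAsFactors = FALSE)
  if (ncol(snp) < 6) stop("malformed .snp file: expected 6 columns")
  panel <- snp_panel(data.frame(
    snp_id = as.character(snp[[1]]), chrom = snp[[2]], pos = snp[[4]],
    ref = snp[[5]], alt = snp[[6]], stringsAsFactors = FALSE))
  ind <- read.table(paste0(prefix, ".ind"), stringsAsFactors = FALSE)
  lines <- readLines(paste0(prefix, ".geno"))
  if (length(lines) != nrow(panel)) {
    stop(".geno has ", length(lines), " SNP rows but .snp has ", nrow(panel))
  }
  if (nrow(ind) && any(nchar(lines) != nrow(ind))) {
    stop(".geno row width does not match the .ind sample count")
  }
  g <- matrix(as.integer(unlist(strsplit(lines, "", fixed = TRUE),
                                use.names = FALSE)),
              nrow = nrow(ind), ncol = nrow(panel))
  g[g == 9L] <- NA_integer_
  geno_matrix(g, panel,
              ploidy = ifelse(ind[[2]] == "H", "pseudo_haploid", "diploid"),
              samples = as.character(ind[[1]]),
              groups = as.character(ind[[3]]))
}

#' Write an observation set as TSV
#'
#' @param obs observation data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  validate_obs(obs)
  write.table(obs, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an observation set TSV
#'
#' @param path file written by [write_observations()].
#' @return observation data frame.
#' @export
read_observations <- function(path) {
  validate_obs(read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}
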