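# Genotype matrix: samples x biallelic sites, alternate-allele dosage codes.

new_genotype_matrix <- function(codes, sample_ids, sites) {
  p <- colMeans(codes, na.rm = TRUE) / 2
  structure(
    list(codes = codes, sample_ids = sample_ids, sites = sites, p = unname(p)),
    class = "genotype_matrix"
  )
}

#' Build a genotype matrix from a cohort
#'
#' Restricts the cohort to biallelic sites (always), optionally to SNPs,
#' autosomes, and a minor-allele-frequency threshold, and codes each genotype
#' as the number of alternate-allele copies (0/1/2, `NA` for missing). The
#' per-site alternate-allele frequency `p` is recomputed from the non-missing
#' calls; the VCF INFO `AF` field is never used here.
#'
#' @param cohort a `variant_cohort`.
#' @param snps_only keep only SNP sites (default `TRUE`).
#' @param autosomes_only keep only autosomal sites (default `TRUE`).
#' @param maf keep sites with minor-allele frequency strictly greater than
#'   this value (default 0, i.e. no frequency filter beyond polymorphism is
#'   implied; use `maf = 0.05` for relationship-matrix work).
#' @param drop_monomorphic drop sites with `p` of exactly 0 or 1
#'   (default `FALSE`).
#' @return A `genotype_matrix`: list with `codes` (samples x sites integer
#'   matrix), `sample_ids`, `sites` (data.frame `chrom`,`pos`,`ref`,`alt`) and
#'   `p` (alternate-allele frequency per site). Errors if no site survives.
#' @export
build_genotype_matrix <- function(cohort, snps_only = TRUE,
                                  autosomes_only = TRUE, maf = 0,
                                  drop_monomorphic = FALSE) {
  cls <- classify_variants(cohort)
  keep <- cls$allelicity == "biallelic" & cls$type != "mixed"
  if (snps_only) keep <- keep & cls$type == "SNP"
  if (autosomes_only) keep <- keep & is_autosome(cohort$variants$chrom)
  idx <- which(keep)
  if (length(idx) == 0) stop("no biallelic sites retained for genotype matrix")

  codes <- t(cohort$a1[idx, , drop = FALSE] + cohort$a2[idx, , drop = FALSE])
  rownames(codes) <- cohort$samples
  p <- colMeans(codes, na.rm = TRUE) / 2
  ok <- !is.nan(p)                       # all-missing sites are dropped
  if (maf > 0) ok <- ok & (pmin(p, 1 - p) > maf)
  if (drop_monomorphic) ok <- ok & (p > 0) & (p < 1)
  if (!any(ok)) stop("no sites retained after frequency filtering")

  idx <- idx[ok]
  sites <- cohort$variants[idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(sites) <- NULL
  gm <- new_genotype_matrix(codes[, ok, drop = FALSE], cohort$samples, sites)
  attr(gm, "n_input_sites") <- n_sites(cohort)
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites\n",
              nrow(x$codes), ncol(x$codes)))
  cat(sprintf("  alt-allele frequency: min %.4f, median %.4f, max %.4f\n",
              min(x$p), stats::median(x$p), max(x$p)))
  cat(sprintf("  missing genotypes: %d\n", sum(is.na(x$codes))))
  invisible(x)
}

# Swap the focal allele at every site: codes -> 2 - codes, p -> 1 - p.
# Used to verify that estimators are invariant to ref/alt orientation.
#' Filter a genotype matrix by minor allele frequency
#'
#' Keeps sites whose minor-allele frequency (from the recomputed `p`) is
#' strictly greater than `maf`; monomorphic sites never survive a positive
#' threshold.
#'
#' @param gm a `genotype_matrix`.
#' @param maf strict lower bound on minor-allele frequency.
#' @return A `genotype_matrix` restricted to passing sites; errors when no
#'   site passes.
#' @export
filter_maf <- function(gm, maf = 0.05) {
  keep <- pmin(gm$p, 1 - gm$p) > maf
  if (!any(keep)) stop("no sites pass the MAF filter")
  out <- new_genotype_matrix(gm$codes[, keep, drop = FALSE], gm$sample_ids,
                             gm$sites[keep, , drop = FALSE])
  for (a in c("p_true", "f_true")) {
    if (!is.null(attr(gm, a))) {
      attr(out, a) <- if (a == "p_true") attr(gm, a)[keep] else attr(gm, a)
    }
  }
  out
}

#' Flip reference and alternate alleles at every site
#'
#' Returns a genotype matrix with `codes` replaced by `2 - codes` and site
#' frequencies by `1 - p`; useful for checking allele-orientation invariance
#' of downstream estimators.
#'
#' @param gm a `genotype_matrix`.
#' @return A `genotype_matrix` with the focal allele swapped.
#' @export
swap_alleles <- function(gm) {
  sites <- gm$sites
  tmp <- sites$ref
  sites$ref <- sites$alt
  sites$alt <- tmp
  new_genotype_matrix(2L - gm$codes, gm$sample_ids, sites)
}
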