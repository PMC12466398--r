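# Observed/expected heterozygosity and sliding-window nucleotide diversity.

#' Per-site observed and expected heterozygosity
#'
#' For each biallelic site, `ho` is the fraction of heterozygous calls among
#' non-missing genotypes and `he = 2 p (1 - p)` with `p` estimated from the
#' non-missing alleles. With `unbiased = TRUE`, `he` carries the
#' `n/(n-1)` small-sample correction (n = number of non-missing alleles).
#'
#' @param codes integer vector (one site) or matrix (samples x sites) of
#'   alternate-allele dosage codes, or a `genotype_matrix`.
#' @param unbiased apply the small-sample correction to `he` (default
#'   `FALSE`).
#' @return `data.frame` with columns `ho`, `he`, `n_called` (one row per
#'   site). Sites with zero non-missing calls yield `NA` and are reported by
#'   a message.
#' @export
#' @examples
#' site_heterozygosity(c(0, 1, 2))  # ho = 1/3, he = 0.5
site_heterozygosity <- function(codes, unbiased = FALSE) {
  if (inherits(codes, "genotype_matrix")) codes <- codes$codes
  if (is.vector(codes)) codes <- matrix(codes, ncol = 1)
  n_called <- colSums(!is.na(codes))
  n_het <- colSums(codes == 1L, na.rm = TRUE)
  p <- colMeans(codes, na.rm = TRUE) / 2
  ho <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  he <- 2 * p * (1 - p)
  if (unbiased) {
    nall <- 2 * n_called
    he <- he * ifelse(nall > 1, nall / (nall - 1), NA_real_)
  }
  he[n_called == 0] <- NA_real_
  if (any(n_called == 0)) {
    message(sum(n_called == 0), " site(s) with all genotypes missing skipped")
  }
  data.frame(ho = ho, he = unname(he), n_called = n_called)
}

#' Cohort heterozygosity summary
#'
#' Site-level `ho`/`he` plus genome means (averaged across sites) and
#' per-sample observed-heterozygosity fractions for QC.
#'
#' @param gm a `genotype_matrix`.
#' @inheritParams site_heterozygosity
#' @return A `het_summary`: list with `sites` (chrom, pos, ho, he),
#'   `ho_mean`, `he_mean`, and `per_sample` (sample, het_fraction).
#' @export
het_summary <- function(gm, unbiased = FALSE) {
  hh <- site_heterozygosity(gm$codes, unbiased = unbiased)
  per_sample <- data.frame(
    sample = gm$sample_ids,
    het_fraction = rowMeans(gm$codes == 1L, na.rm = TRUE)
  )
  structure(list(
    sites = cbind(gm$sites[, c("chrom", "pos")], hh[, c("ho", "he")]),
    ho_mean = mean(hh$ho, na.rm = TRUE),
    he_mean = mean(hh$he, na.rm = TRUE),
    per_sample = per_sample
  ), class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat(sprintf("het_summary over %d sites: Ho = %.4f, He = %.4f\n",
              nrow(x$sites), x$ho_mean, x$he_mean))
  invisible(x)
}

# per-site pi: average pairwise difference between 2N sequences at one site,
# the unbiased form 2 j (n - j) / (n (n - 1)) with n alleles, j alt copies.
site_pi <- function(codes) {
  n_alleles <- 2 * colSums(!is.na(codes))
  j <- colSums(codes, na.rm = TRUE)
  pi <- ifelse(n_alleles >= 2,
               2 * j * (n_alleles - j) / (n_alleles * (n_alleles - 1)),
               NA_real_)
  list(pi = pi, n_alleles = n_alleles)
}

#' Sliding-window nucleotide diversity
#'
#' Sums per-site diversity contributions
#' `pi_site = 2 j (n - j) / (n (n - 1))` (n = non-missing allele count,
#' j = alternate-allele count) over 1-based half-open windows
#' `[start, start + window)` and divides by the window length, so
#' unobserved positions count as invariant. Sites with fewer than two called
#' alleles are skipped and counted.
#'
#' @param gm a `genotype_matrix` (typically biallelic autosomal sites).
#' @param window window size in bp (default 10000).
#' @param step step size in bp (default `window`, i.e. non-overlapping).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   missing, the last window on each chromosome ends at the furthest site.
#' @return A `data.frame` of class `pi_windows` with columns `chrom`,
#'   `start`, `end` (1-based half-open), `n_sites`, `pi`, `callable_bp`;
#'   attribute `n_skipped` counts sites with n < 2.
#' @export
window_pi <- function(gm, window = 10000, step = window,
                      chrom_lengths = NULL) {
  stopifnot(window >= step, step >= 1)
  sp <- site_pi(gm$codes)
  skipped <- sum(is.na(sp$pi))
  out <- list()
  for (chrom in unique(gm$sites$chrom)) {
    sel <- gm$sites$chrom == chrom
    pos <- gm$sites$pos[sel]
    pis <- sp$pi[sel]
    L <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(pos)
    }
    starts <- seq(1, max(1, L), by = step)
    for (s in starts) {
      e <- min(s + window, L + 1)      # half-open end, clipped at chrom end
      in_w <- pos >= s & pos < e
      width <- e - s
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s, end = e,
        n_sites = sum(in_w & !is.na(pis)),
        pi = sum(pis[in_w], na.rm = TRUE) / width,
        callable_bp = width, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- skipped
  class(res) <- c("pi_windows", "data.frame")
  res
}

#' Write windows as a BED-compatible TSV
#'
#' Converts the 1-based half-open window coordinates to BED's 0-based
#' half-open convention on output.
#'
#' @param windows a `pi_windows` table from [window_pi()].
#' @param path output path.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom, start = windows$start - 1,
                    end = windows$end - 1, n_sites = windows$n_sites,
                    pi = windows$pi)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome diversity report
#'
#' Combines heterozygosity means, the length-weighted genome mean of window
#' diversity, and the projected count of pairwise nucleotide differences
#' over a genome of the given size(s).
#'
#' @param gm a `genotype_matrix`.
#' @param windows optional precomputed [window_pi()] table (computed with
#'   defaults when `NULL`).
#' @param genome_size genome size(s) in bp for the projected
#'   pairwise-difference count (default `c(2.5e9, 2.7e9)`, the horse genome
#'   size range).
#' @inheritParams window_pi
#' @return A `diversity_report`: list with `ho_mean`, `he_mean`, `pi_mean`
#'   (per bp), and `projected_differences` (named by genome size).
#' @export
genome_diversity_report <- function(gm, windows = NULL,
                                    genome_size = c(2.5e9, 2.7e9),
                                    chrom_lengths = NULL) {
  hs <- het_summary(gm)
  if (is.null(windows)) windows <- window_pi(gm, chrom_lengths = chrom_lengths)
  pi_mean <- sum(windows$pi * windows$callable_bp) / sum(windows$callable_bp)
  structure(list(
    ho_mean = hs$ho_mean, he_mean = hs$he_mean, pi_mean = pi_mean,
    projected_differences = stats::setNames(pi_mean * genome_size,
                                            format(genome_size, scientific = TRUE)),
    per_sample = hs$per_sample
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("diversity_report: Ho = %.4f, He = %.4f, pi = %.3g per bp\n",
              x$ho_mean, x$he_mean, x$pi_mean))
  for (nm in names(x$projected_differences)) {
    cat(sprintf("  projected pairwise differences over %s bp: %s\n", nm,
                format(round(x$projected_differences[[nm]]), big.mark = ",")))
  }
  invisible(x)
}
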