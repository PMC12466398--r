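# Genomic relationship matrix and the three genomic inbreeding estimators.
#
# With dosage codes x (alternate-allele copies) and per-site frequency p:
#   GRM   = Z Z' / (2 * sum_i p_i (1 - p_i)),  Z centered as x - 2p
#           (pooled denominator, VanRaden method 1)
#   F_GRM = GRM diagonal - 1
#   F_HOM = (N_OHom - N_EHom) / (N_NonMiss - N_EHom),
#           N_EHom = sum over non-missing sites of (1 - 2 p_i (1 - p_i))
#   F_UNI = (1/n) sum_i (x_i^2 - (1 + 2 p_i) x_i + 2 p_i^2) / (2 p_i (1 - p_i))
# All three are invariant to which allele is counted (ref/alt swap).

#' Build a genomic relationship matrix
#'
#' Centers the dosage codes per site (`x - 2p`) and scales by the pooled
#' denominator `2 * sum(p (1 - p))` (VanRaden method 1). With
#' `scaling = "per_site"` each site is instead standardized by
#' `sqrt(2 p (1 - p))` and the matrix divided by the site count (the GCTA
#' default). Missing genotypes are imputed to `2p` (zero after centering),
#' which keeps the matrix positive semidefinite.
#'
#' @param gm a `genotype_matrix`; every site must be polymorphic
#'   (0 < p < 1) — filter upstream, e.g. `build_genotype_matrix(maf = 0.05)`.
#' @param scaling `"pooled"` (default) or `"per_site"`.
#' @return A `grm` object: list with `matrix` (samples x samples), `n_sites`,
#'   `site_weights_sum` (`sum 2 p (1-p)`) and `scaling`.
#' @export
build_grm <- function(gm, scaling = c("pooled", "per_site")) {
  scaling <- match.arg(scaling)
  p <- gm$p
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic site(s) in genotype matrix; filter before build_grm")
  }
  all_missing <- rowSums(!is.na(gm$codes)) == 0
  if (any(all_missing)) {
    stop("sample(s) with no called genotypes: ",
         paste(gm$sample_ids[all_missing], collapse = ", "))
  }
  Z <- sweep(gm$codes, 2, 2 * p)
  Z[is.na(Z)] <- 0                       # missing -> imputed to 2p
  if (scaling == "pooled") {
    w <- 2 * sum(p * (1 - p))
    G <- tcrossprod(Z) / w
  } else {
    Zs <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    w <- ncol(Z)
    G <- tcrossprod(Zs) / w
  }
  dimnames(G) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(matrix = G, n_sites = ncol(gm$codes),
                 site_weights_sum = 2 * sum(p * (1 - p)), scaling = scaling),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d sites, %s scaling\n",
              nrow(x$matrix), x$n_sites, x$scaling))
  cat(sprintf("  diagonal: min %.4f, mean %.4f, max %.4f\n",
              min(diag(x$matrix)), mean(diag(x$matrix)), max(diag(x$matrix))))
  invisible(x)
}

#' GRM-diagonal inbreeding coefficient
#'
#' `F_GRM = GRM_ii - 1` for each sample.
#'
#' @param grm a `grm` object from [build_grm()].
#' @return Named numeric vector of per-sample coefficients.
#' @export
f_grm <- function(grm) {
  diag(grm$matrix) - 1
}

#' Excess-homozygosity inbreeding coefficient
#'
#' Wright's coefficient from observed vs expected homozygote counts:
#' `F_HOM = (N_OHom - N_EHom) / (N_NonMiss - N_EHom)`, where the expected
#' homozygous count sums `1 - 2 p (1 - p)` over the sample's non-missing
#' sites. A sample whose denominator vanishes gets `NA` with a warning.
#'
#' @param gm a `genotype_matrix` with polymorphic sites.
#' @return Named numeric vector of per-sample coefficients.
#' @export
f_hom <- function(gm) {
  p <- gm$p
  called <- !is.na(gm$codes)
  o_hom <- rowSums((gm$codes == 0L | gm$codes == 2L) & called, na.rm = TRUE)
  e_site <- 1 - 2 * p * (1 - p)
  e_hom <- called %*% e_site
  n_nonmiss <- rowSums(called)
  denom <- n_nonmiss - e_hom
  out <- as.numeric((o_hom - e_hom) / denom)
  bad <- abs(denom) < 1e-12
  if (any(bad)) {
    warning("F_HOM undefined (N_NonMiss == N_EHom) for: ",
            paste(gm$sample_ids[bad], collapse = ", "))
    out[bad] <- NA_real_
  }
  stats::setNames(out, gm$sample_ids)
}

#' Uniting-gametes inbreeding coefficient
#'
#' The correlation between uniting gametes, averaged per site:
#' `F_UNI = (1/n) sum_i (x_i^2 - (1 + 2 p_i) x_i + 2 p_i^2) / (2 p_i (1 - p_i))`
#' over each sample's non-missing sites.
#'
#' @param gm a `genotype_matrix` with polymorphic sites.
#' @return Named numeric vector of per-sample coefficients; `NA` with a
#'   warning for a sample with no called genotypes.
#' @export
f_uni <- function(gm) {
  p <- gm$p
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic site(s) in genotype matrix; filter before f_uni")
  }
  x <- gm$codes
  # (x^2 - (1+2p) x + 2 p^2) / (2 p (1-p)), per site, averaged per sample
  num <- x^2 - sweep(x, 2, 1 + 2 * p, "*") + matrix(2 * p^2, nrow(x), ncol(x),
                                                    byrow = TRUE)
  num[is.na(x)] <- NA
  ratio <- sweep(num, 2, 2 * p * (1 - p), "/")
  n_used <- rowSums(!is.na(ratio))
  out <- rowMeans(ratio, na.rm = TRUE)
  if (any(n_used == 0)) {
    warning("F_UNI undefined (no called genotypes) for: ",
            paste(gm$sample_ids[n_used == 0], collapse = ", "))
    out[n_used == 0] <- NA_real_
  }
  stats::setNames(out, gm$sample_ids)
}

#' Estimate genomic inbreeding by three methods
#'
#' Computes `F_GRM`, `F_HOM` and `F_UNI` for every sample plus the
#' per-method minimum / maximum / mean descriptive table.
#'
#' @param gm a `genotype_matrix` of polymorphic biallelic sites (apply the
#'   MAF filter upstream).
#' @param scaling GRM scaling passed to [build_grm()].
#' @return An `inbreeding_est` object: list with `samples` (data.frame
#'   `sample`, `f_grm`, `f_hom`, `f_uni`, `n_ohom`, `n_nonmiss`) and
#'   `summary` (method, min, max, mean). `as.data.frame()` returns the
#'   per-sample table.
#' @export
inbreeding <- function(gm, scaling = "pooled") {
  g <- build_grm(gm, scaling = scaling)
  fg <- f_grm(g)
  fh <- f_hom(gm)
  fu <- f_uni(gm)
  called <- !is.na(gm$codes)
  samples <- data.frame(
    sample = gm$sample_ids,
    f_grm = unname(fg), f_hom = unname(fh), f_uni = unname(fu),
    n_ohom = rowSums((gm$codes == 0L | gm$codes == 2L) & called, na.rm = TRUE),
    n_nonmiss = rowSums(called),
    stringsAsFactors = FALSE
  )
  summ <- data.frame(
    method = c("F_GRM", "F_HOM", "F_UNI"),
    min = c(min(fg), min(fh, na.rm = TRUE), min(fu, na.rm = TRUE)),
    max = c(max(fg), max(fh, na.rm = TRUE), max(fu, na.rm = TRUE)),
    mean = c(mean(fg), mean(fh, na.rm = TRUE), mean(fu, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, summary = summ, n_sites = ncol(gm$codes)),
            class = "inbreeding_est")
}

#' @export
print.inbreeding_est <- function(x, digits = 3, ...) {
  cat(sprintf("Genomic inbreeding, %d samples x %d sites\n",
              nrow(x$samples), x$n_sites))
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.inbreeding_est <- function(x, ...) x$samples

#' Principal component analysis of a GRM
#'
#' Eigendecomposition of the relationship matrix; component scores are
#' `eigenvector * sqrt(eigenvalue)` and explained variance is each
#' eigenvalue over the eigenvalue total. Signs follow a fixed convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param grm a `grm` object.
#' @param k number of components to return (clamped to the sample count with
#'   a warning).
#' @return A `grm_pca` object: list with `eigenvalues` (all, descending),
#'   `scores` (samples x k), `explained` (percent per component, all
#'   components).
#' @export
pca_from_grm <- function(grm, k = 10) {
  G <- grm$matrix
  n <- nrow(G)
  if (k > n) {
    warning("k clamped from ", k, " to number of samples (", n, ")")
    k <- n
  }
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  for (j in seq_len(n)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(k)], 0)), k, k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  explained <- 100 * vals / sum(vals)
  structure(list(eigenvalues = vals, scores = scores, explained = explained),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- min(5, ncol(x$scores))
  cat("GRM principal components\n")
  for (j in seq_len(k)) {
    cat(sprintf("  PC%d: eigenvalue %.4f (%.2f%%)\n", j,
                x$eigenvalues[j], x$explained[j]))
  }
  invisible(x)
}

#' Write a GRM in GCTA-compatible text layout
#'
#' `<prefix>.grm.txt` holds the lower triangle (i, j, n_sites, value) and
#' `<prefix>.grm.id` the sample ids.
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$matrix)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      rows[[length(rows) + 1]] <- c(i, j, grm$n_sites, grm$matrix[i, j])
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, paste0(prefix, ".grm.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- data.frame(fid = rownames(grm$matrix), iid = rownames(grm$matrix))
  utils::write.table(ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
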