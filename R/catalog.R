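# Mendelian trait-variant catalog: matching, heterozygote counts, MAF,
# segregation report.

#' Read a trait-variant catalog
#'
#' Tab-separated catalog of known Mendelian-trait variants with columns
#' `chrom`, `pos`, `ref`, `alt`, `a1`, `a2`, `variant_type`, `gene`,
#' `phenotype`, `omia_id`. `a1`/`a2` are reported verbatim (catalog allele
#' labels do not always make `a1` the minor allele); the analysis frequency
#' always comes from the genotypes. A catalog excerpt for seven horse
#' coat-color/gait variants ships in
#' `system.file("extdata", "omia_trait_variants.tsv", package = "equifix")`.
#'
#' @param path path to the catalog TSV.
#' @return `data.frame` of catalog variants.
#' @export
read_trait_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  needed <- c("chrom", "pos", "ref", "alt", "variant_type", "gene")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[, c("chrom", "pos", "ref", "alt")])) {
    stop("catalog has duplicate (chrom, pos, ref, alt) entries")
  }
  df
}

#' Left-normalize a variant representation
#'
#' Trims bases shared by `ref` and `alt` (common suffix first, then common
#' prefix, advancing `pos` per trimmed leading base), the standard VCF
#' normalization that reconciles anchor-base VCF records with HGVS-style
#' delins coordinates.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @return List with normalized `pos`, `ref`, `alt` (empty alleles kept as
#'   `""`).
#' @export
#' @examples
#' normalize_variant(21555810, "GC", "GAAAT")  # -> pos 21555811, C > AAAT
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim common suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim common prefix, advancing pos
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Match catalog variants against a cohort
#'
#' Matches on normalized chromosome name and left-normalized position, then
#' checks allele compatibility (normalized ref/alt equality). Unmatched
#' catalog entries are reported as absent; several cohort records at one
#' position are all reported and flagged ambiguous.
#'
#' @param catalog catalog `data.frame` (see [read_trait_catalog()]).
#' @param cohort a `variant_cohort`.
#' @return `data.frame`, one row per catalog entry (plus extra rows for
#'   ambiguous multi-matches), with `matched`, `allele_match`, `ambiguous`,
#'   `site` (cohort row index or `NA`), `n_het`, `n_hom_alt`, `n_missing`,
#'   `n_called`.
#' @export
match_catalog <- function(catalog, cohort) {
  v <- cohort$variants
  v_chrom <- normalize_chrom(v$chrom)
  v_norm <- mapply(function(p, r, a) {
    a1 <- strsplit(a, ",", fixed = TRUE)[[1]][1]
    normalize_variant(p, r, a1)
  }, v$pos, v$ref, v$alt, SIMPLIFY = FALSE)
  v_pos <- vapply(v_norm, `[[`, numeric(1), "pos")
  v_ref <- vapply(v_norm, `[[`, character(1), "ref")
  v_alt <- vapply(v_norm, `[[`, character(1), "alt")

  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    cn <- normalize_variant(catalog$pos[i], catalog$ref[i], catalog$alt[i])
    hits <- which(v_chrom == normalize_chrom(catalog$chrom[i]) &
                    v_pos == cn$pos)
    if (length(hits) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        catalog_row = i, matched = FALSE, allele_match = NA, ambiguous = FALSE,
        site = NA_integer_, n_het = 0L, n_hom_alt = 0L, n_missing = 0L,
        n_called = 0L
      )
      next
    }
    for (h in hits) {
      g1 <- cohort$a1[h, ]; g2 <- cohort$a2[h, ]
      miss <- is.na(g1) | is.na(g2)
      rows[[length(rows) + 1]] <- data.frame(
        catalog_row = i, matched = TRUE,
        allele_match = (v_ref[h] == cn$ref && v_alt[h] == cn$alt),
        ambiguous = length(hits) > 1, site = h,
        n_het = sum(g1 != g2 & !miss),
        n_hom_alt = sum(g1 == g2 & g1 >= 1 & !miss),
        n_missing = sum(miss), n_called = sum(!miss)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$ambiguous)) {
    warning("ambiguous multi-match at ", sum(out$ambiguous), " position(s)")
  }
  out
}

#' Minor allele frequency from genotype counts
#'
#' `maf = min(q, 1 - q)` with `q = (n_het + 2 n_hom_alt) / (2 n_samples)`,
#' the folded non-reference allele frequency among called diploid samples.
#'
#' @param n_het number of heterozygous samples.
#' @param n_hom_alt number of homozygous-alternate samples.
#' @param n_samples number of called (non-missing) samples.
#' @return Minor allele frequency in `[0, 0.5]`. Vectorized; errors when
#'   `n_samples` is zero or carrier counts exceed it.
#' @export
#' @examples
#' maf_from_counts(4, 0, 20)  # 0.100
#' maf_from_counts(3, 0, 20)  # 0.075
maf_from_counts <- function(n_het, n_hom_alt, n_samples) {
  if (any(n_samples == 0)) stop("n_samples must be positive")
  if (any(n_het + n_hom_alt > n_samples)) {
    stop("carrier counts exceed sample count")
  }
  q <- (n_het + 2 * n_hom_alt) / (2 * n_samples)
  pmin(q, 1 - q)
}

#' Segregation report over a trait-variant catalog
#'
#' Genotypes the cohort at every catalog variant and reports carrier counts,
#' minor allele frequency and a status: `segregating` (at least one
#' non-reference allele observed and not fixed), `fixed` (every called
#' sample homozygous alternate), or `absent`. Rows are ordered by chromosome
#' and position; missing genotypes are excluded from allele denominators.
#'
#' @inheritParams match_catalog
#' @return A `segregation_report`: data.frame with catalog columns plus
#'   `matched`, `n_het`, `n_hom_alt`, `n_missing`, `maf`, `status`. The
#'   `segregating` rows are what the study-style table prints.
#' @export
segregation_report <- function(catalog, cohort) {
  m <- match_catalog(catalog, cohort)
  # one row per catalog entry: prefer the allele-matching hit
  pick <- vapply(seq_len(nrow(catalog)), function(i) {
    cand <- which(m$catalog_row == i)
    am <- cand[which(m$allele_match[cand])]
    if (length(am) > 0) am[1] else cand[1]
  }, integer(1))
  m <- m[pick, , drop = FALSE]
  maf <- ifelse(m$n_called > 0,
                maf_from_counts(m$n_het, m$n_hom_alt, pmax(m$n_called, 1)),
                0)
  alt_copies <- m$n_het + 2 * m$n_hom_alt
  fixed <- m$matched & m$n_called > 0 & m$n_hom_alt == m$n_called
  status <- ifelse(!m$matched | alt_copies == 0, "absent",
                   ifelse(fixed, "fixed", "segregating"))
  out <- cbind(catalog, m[, c("matched", "n_het", "n_hom_alt", "n_missing")],
               maf = maf, status = status)
  ord <- order(match(normalize_chrom(out$chrom), c(as.character(1:31), "X")),
               out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("segregation_report", "data.frame")
  out
}

#' @export
print.segregation_report <- function(x, ...) {
  seg <- x[x$status == "segregating", , drop = FALSE]
  cat(sprintf("segregation_report: %d catalog variants, %d segregating\n",
              nrow(x), nrow(seg)))
  if (nrow(seg) > 0) {
    cols <- intersect(c("chrom", "pos", "gene", "variant_type", "maf",
                        "n_het", "phenotype"), names(seg))
    print(as.data.frame(seg)[, cols], row.names = FALSE)
  }
  invisible(x)
}
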