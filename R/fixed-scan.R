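# Breed-specific fixed-variant cascade and prioritized candidate genes (PCGs).
#
# Stage order follows the narrated analysis: fixed alternative allele
# (AF = 1 in the cohort) -> per-sample depth >= 10x -> autosomes ->
# gene-level aggregation of exonic HIGH/MODERATE variants, keeping genes
# with at least 5 qualifying variants.

#' Keep sites fixed for the alternate allele
#'
#' Retains sites where every sample is homozygous for the same alternate
#' allele. By default a missing genotype disqualifies the site (strict
#' reading of "in all samples"); `allow_missing = TRUE` relaxes to "every
#' non-missing call is homozygous alternate, with at least one call".
#'
#' @param cohort a `variant_cohort`.
#' @param allow_missing tolerate missing genotypes (default `FALSE`).
#' @return The surviving sites as a `variant_cohort` (may be empty-site).
#' @export
fixed_alt_filter <- function(cohort, allow_missing = FALSE) {
  if (n_sites(cohort) == 0) return(cohort)
  a1 <- cohort$a1; a2 <- cohort$a2
  hom_alt <- (a1 == a2) & (a1 >= 1L)
  if (allow_missing) {
    keep <- rowSums(!hom_alt, na.rm = TRUE) == 0 &
      rowSums(!is.na(hom_alt)) > 0
  } else {
    hom_alt[is.na(hom_alt)] <- FALSE
    keep <- rowSums(hom_alt) == ncol(a1)
  }
  # all samples must carry the SAME alt allele
  same <- apply(cohort$a1, 1, function(r) length(unique(r[!is.na(r)])) <= 1)
  subset_sites(cohort, which(keep & same))
}

#' Keep sites covered in every sample
#'
#' Retains sites with per-genotype depth `DP >= min_dp` in every sample
#' ("at least" semantics: the boundary is inclusive). Sites with missing DP
#' are dropped conservatively and counted in the `n_missing_dp` attribute.
#'
#' @param cohort a `variant_cohort`.
#' @param min_dp minimum per-sample depth (default 10).
#' @return The surviving sites as a `variant_cohort`.
#' @export
depth_filter <- function(cohort, min_dp = 10) {
  if (n_sites(cohort) == 0) return(cohort)
  dp <- cohort$dp
  ok <- dp >= min_dp
  ok[is.na(ok)] <- FALSE
  keep <- rowSums(ok) == ncol(dp)
  missing_dp <- rowSums(is.na(dp)) > 0
  out <- subset_sites(cohort, which(keep))
  attr(out, "n_missing_dp") <- sum(missing_dp & !keep)
  out
}

#' Select prioritized candidate genes
#'
#' Per gene, counts distinct variants whose annotation for that gene is
#' exonic with impact in `impact_set`; genes reaching `min_variants`
#' qualifying variants are returned, ordered by chromosome and position.
#' A variant annotated to several genes counts once for each.
#'
#' @param cohort a `variant_cohort` that already passed the fixed-allele,
#'   depth and autosome filters.
#' @param gene_models optional `gene_models` object used to attach gene
#'   coordinates; a gene absent from it is still reported (coordinates from
#'   the span of its qualifying variants) with a warning.
#' @param impact_set impact classes that qualify
#'   (default `c("HIGH", "MODERATE")`).
#' @param min_variants minimum qualifying variants per gene (default 5).
#' @param include_utr count UTR consequences as exonic (default `FALSE`).
#' @return `data.frame` with columns `gene_id`, `gene_symbol`,
#'   `n_qualifying_variants`, `chrom`, `start`, `end`.
#' @export
pcg_select <- function(cohort, gene_models = NULL,
                       impact_set = c("HIGH", "MODERATE"),
                       min_variants = 5, include_utr = FALSE) {
  ann <- cohort$ann
  empty <- data.frame(gene_id = character(0), gene_symbol = character(0),
                      n_qualifying_variants = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(empty)
  ann <- ann[!is.na(ann$gene_id) & ann$gene_id != "-", , drop = FALSE]
  if (nrow(ann) == 0) return(empty)
  # most severe consequence per (variant, gene), then the exonic/impact test
  key <- paste(ann$variant, ann$gene_id, sep = "\r")
  ord <- order(key, consequence_rank(ann$consequence))
  ann <- ann[ord, , drop = FALSE]
  ann <- ann[!duplicated(key[ord]), , drop = FALSE]
  qual <- is_exonic_consequence(ann$consequence, include_utr = include_utr) &
    ann$impact %in% impact_set
  ann <- ann[qual, , drop = FALSE]
  if (nrow(ann) == 0) return(empty)

  counts <- table(ann$gene_id)
  keep_genes <- names(counts)[counts >= min_variants]
  if (length(keep_genes) == 0) return(empty)

  rows <- lapply(keep_genes, function(gid) {
    sub <- ann[ann$gene_id == gid, , drop = FALSE]
    vpos <- cohort$variants$pos[sub$variant]
    vchrom <- cohort$variants$chrom[sub$variant[1]]
    start <- min(vpos); end <- max(vpos)
    if (!is.null(gene_models)) {
      gi <- match(gid, gene_models$genes$gene_id)
      if (!is.na(gi)) {
        start <- gene_models$genes$start[gi]
        end <- gene_models$genes$end[gi]
        vchrom <- gene_models$genes$chrom[gi]
      } else {
        warning("gene ", gid, " not in gene models; using variant span")
      }
    }
    data.frame(gene_id = gid, gene_symbol = sub$gene_symbol[1],
               n_qualifying_variants = nrow(sub), chrom = vchrom,
               start = start, end = end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(normalize_chrom(out$chrom),
                     c(as.character(1:31), "X")), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full fixed-variant cascade
#'
#' Applies, in order: fixed-alternate-allele filter, per-sample depth
#' filter, autosome restriction, and prioritized-candidate-gene selection,
#' recording the survivor count at every stage.
#'
#' @inheritParams fixed_alt_filter
#' @inheritParams depth_filter
#' @inheritParams pcg_select
#' @param autosomes_only restrict to autosomes (default `TRUE`).
#' @return A `fixed_scan` object: list with `stages` (stage, n_sites),
#'   `survivors` (the post-filter `variant_cohort`), and `pcg` (the
#'   candidate-gene table).
#' @export
fixed_scan <- function(cohort, min_dp = 10, impact_set = c("HIGH", "MODERATE"),
                       min_variants = 5, autosomes_only = TRUE,
                       allow_missing = FALSE, include_utr = FALSE,
                       gene_models = NULL) {
  s0 <- n_sites(cohort)
  fixed <- fixed_alt_filter(cohort, allow_missing = allow_missing)
  deep <- depth_filter(fixed, min_dp = min_dp)
  auto <- if (autosomes_only) {
    subset_sites(deep, which(is_autosome(deep$variants$chrom)))
  } else {
    deep
  }
  pcg <- pcg_select(auto, gene_models = gene_models, impact_set = impact_set,
                    min_variants = min_variants, include_utr = include_utr)
  # exonic high/moderate variants among survivors (the "73 exon variants" stage)
  ann <- auto$ann
  qual_variants <- if (nrow(ann) > 0) {
    unique(ann$variant[is_exonic_consequence(ann$consequence,
                                             include_utr = include_utr) &
                         ann$impact %in% impact_set])
  } else {
    integer(0)
  }
  stages <- data.frame(
    stage = c("input", "fixed_alt", "depth", "autosome",
              "exonic_high_moderate"),
    n_sites = c(s0, n_sites(fixed), n_sites(deep), n_sites(auto),
                length(qual_variants)),
    stringsAsFactors = FALSE
  )
  structure(list(stages = stages, survivors = auto, pcg = pcg),
            class = "fixed_scan")
}

#' @export
print.fixed_scan <- function(x, ...) {
  cat("Fixed-variant cascade\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-22s %d\n", x$stages$stage[i], x$stages$n_sites[i]))
  }
  cat(sprintf("  prioritized candidate genes: %d\n", nrow(x$pcg)))
  invisible(x)
}
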