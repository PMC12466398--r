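# Cohort-level summarization: per-chromosome counts, functional class
# counts, per-bin densities, and pipeline orchestration.

#' Round half up
#'
#' Decimal rounding with ties away from zero (the convention used for the
#' printed percentages in this package's reports), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Per-chromosome variant counts
#'
#' Counts all variants and biallelic variants, split into SNPs, indels and
#' mixed types, for each chromosome. Records on chromosomes outside the
#' known set (`1`..`31`, `X`, any alias) fall into an `unplaced` bucket that
#' is reported but excluded from the per-chromosome table and its totals
#' row; an autosomal subtotal excludes `X`.
#'
#' @param cohort a `variant_cohort`.
#' @return A `chrom_summary`: list with `table` (per-chromosome rows),
#'   `totals`, `autosomal` (named totals), `n_unplaced`, and
#'   `percent_biallelic` (share of placed variants that are biallelic,
#'   2 decimals, half-up).
#' @export
summarize_by_chromosome <- function(cohort) {
  cls <- classify_variants(cohort)
  chrom <- normalize_chrom(cohort$variants$chrom)
  known <- c(as.character(1:31), "X")
  placed <- chrom %in% known
  bi <- cls$allelicity == "biallelic"

  count_block <- function(sel) {
    c(indels = sum(sel & cls$type == "indel"),
      snps = sum(sel & cls$type == "SNP"),
      mixed = sum(sel & cls$type == "mixed"),
      total = sum(sel))
  }
  rows <- lapply(known, function(ch) {
    sel <- placed & chrom == ch
    all_c <- count_block(sel)
    bi_c <- count_block(sel & bi)
    data.frame(chrom = ch,
               all_indels = all_c["indels"], all_snps = all_c["snps"],
               all_mixed = all_c["mixed"], all_total = all_c["total"],
               bi_indels = bi_c["indels"], bi_snps = bi_c["snps"],
               bi_total = bi_c["total"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$all_total > 0 | tab$chrom %in% unique(chrom[placed]), ,
             drop = FALSE]
  rownames(tab) <- NULL
  totals <- colSums(tab[, -1, drop = FALSE])
  autosomal <- colSums(tab[tab$chrom != "X", -1, drop = FALSE])
  pct_bi <- if (totals[["all_total"]] > 0) {
    round_half_up(100 * totals[["bi_total"]] / totals[["all_total"]])
  } else {
    NA_real_
  }
  structure(list(table = tab, totals = totals, autosomal = autosomal,
                 n_unplaced = sum(!placed), percent_biallelic = pct_bi),
            class = "chrom_summary")
}

#' @export
print.chrom_summary <- function(x, ...) {
  cat(sprintf("chrom_summary: %d placed variants on %d chromosomes (+%d unplaced)\n",
              x$totals[["all_total"]], nrow(x$table), x$n_unplaced))
  cat(sprintf("  biallelic: %d (%.2f%%); autosomal biallelic: %d\n",
              x$totals[["bi_total"]], x$percent_biallelic,
              x$autosomal[["bi_total"]]))
  invisible(x)
}

#' Biallelic variant counts by functional class
#'
#' Reduces each biallelic variant to its single most severe consequence
#' across all its annotation records (so classes partition the biallelic
#' set), then counts SNPs and indels per class. Unknown consequence terms
#' are bucketed as `other` with a warning; unannotated variants likewise.
#'
#' @param cohort a `variant_cohort`.
#' @return A `class_summary`: list with `table` (class, snps, indels,
#'   total, pct_snps, pct_indels), `totals`, and `exonic_snp_percent`
#'   (exonic SNPs over all biallelic SNPs, 2 decimals, half-up).
#' @export
summarize_by_class <- function(cohort) {
  cls <- classify_variants(cohort)
  bi <- which(cls$allelicity == "biallelic" & cls$type != "mixed")
  ann <- cohort$ann[cohort$ann$variant %in% bi, , drop = FALSE]
  # most severe consequence per variant
  best <- rep(NA_character_, n_sites(cohort))
  if (nrow(ann) > 0) {
    ord <- order(ann$variant, consequence_rank(ann$consequence))
    ann1 <- ann[ord, , drop = FALSE]
    ann1 <- ann1[!duplicated(ann1$variant), , drop = FALSE]
    best[ann1$variant] <- ann1$consequence
  }
  consequence <- best[bi]
  unknown <- !is.na(consequence) & !(consequence %in% .CONSEQUENCE_SEVERITY)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with unknown consequence term -> 'other'")
    consequence[unknown] <- "other"
  }
  if (anyNA(consequence)) {
    warning(sum(is.na(consequence)), " unannotated biallelic variant(s) -> 'other'")
    consequence[is.na(consequence)] <- "other"
  }
  type <- cls$type[bi]
  classes <- c(.CONSEQUENCE_SEVERITY, "other")
  tab <- data.frame(
    class = classes,
    snps = vapply(classes, function(k) sum(consequence == k & type == "SNP"),
                  integer(1)),
    indels = vapply(classes, function(k) sum(consequence == k & type == "indel"),
                    integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$total <- tab$snps + tab$indels
  tab <- tab[tab$total > 0 | tab$class != "other", , drop = FALSE]
  totals <- c(snps = sum(tab$snps), indels = sum(tab$indels),
              total = sum(tab$total))
  tab$pct_snps <- if (totals[["snps"]] > 0) {
    round_half_up(100 * tab$snps / totals[["snps"]])
  } else {
    NA_real_
  }
  tab$pct_indels <- if (totals[["indels"]] > 0) {
    round_half_up(100 * tab$indels / totals[["indels"]])
  } else {
    NA_real_
  }
  # "exon region" classes in the reporting sense: every class that places the
  # variant inside a transcript exon or its splice boundary — i.e. everything
  # except intergenic, intron, upstream, downstream (UTR and splice terms
  # included). Narrower than the candidate-gene "exon variant" rule.
  nonexonic <- c("intergenic_variant", "intron_variant",
                 "upstream_gene_variant", "downstream_gene_variant", "other")
  exonic <- !(tab$class %in% nonexonic)
  exonic_snp_percent <- if (totals[["snps"]] > 0) {
    round_half_up(100 * sum(tab$snps[exonic]) / totals[["snps"]])
  } else {
    NA_real_
  }
  rownames(tab) <- NULL
  structure(list(table = tab, totals = totals,
                 exonic_snp_percent = exonic_snp_percent),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("class_summary: %d biallelic variants (%d SNPs, %d indels)\n",
              x$totals[["total"]], x$totals[["snps"]], x$totals[["indels"]]))
  top <- utils::head(x$table[order(-x$table$total), ], 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-36s %d\n", top$class[i], top$total[i]))
  }
  invisible(x)
}

#' Variant density per genomic bin
#'
#' Divides each chromosome into fixed-size bins and counts, per bin: all
#' variants, survivors of a supplied filter (e.g. the fixed-variant scan),
#' and the four display groups intron / intergenic / up-or-downstream /
#' other, assigned from each variant's most severe consequence. The groups
#' partition the binned total.
#'
#' @param cohort a `variant_cohort`.
#' @param bin bin width in bp (default 1e6).
#' @param survivors optional `variant_cohort` of filtered survivors to count
#'   alongside.
#' @return `data.frame` with `chrom`, `bin_start` (1-based), `bin_end`,
#'   `n_all`, `n_filtered`, `n_intron`, `n_intergenic`, `n_updown`,
#'   `n_other`.
#' @export
density_bins <- function(cohort, bin = 1e6, survivors = NULL) {
  v <- cohort$variants
  # most severe consequence per variant for grouping
  best <- rep("other", n_sites(cohort))
  if (nrow(cohort$ann) > 0) {
    ord <- order(cohort$ann$variant, consequence_rank(cohort$ann$consequence))
    a1 <- cohort$ann[ord, , drop = FALSE]
    a1 <- a1[!duplicated(a1$variant), , drop = FALSE]
    best[a1$variant] <- a1$consequence
  }
  group <- ifelse(best == "intron_variant", "intron",
           ifelse(best == "intergenic_variant", "intergenic",
           ifelse(best %in% c("upstream_gene_variant", "downstream_gene_variant"),
                  "updown", "other")))
  bin_of <- function(pos) (pos - 1) %/% bin
  chrom_lens <- cohort$contigs
  chroms <- if (!is.null(chrom_lens)) {
    union(names(chrom_lens), unique(v$chrom))
  } else {
    unique(v$chrom)
  }
  out <- list()
  for (chrom in chroms) {
    L <- if (!is.null(chrom_lens) && chrom %in% names(chrom_lens) &&
             !is.na(chrom_lens[[chrom]])) {
      chrom_lens[[chrom]]
    } else if (any(v$chrom == chrom)) {
      max(v$pos[v$chrom == chrom])
    } else {
      bin
    }
    n_bins <- max(1, ceiling(L / bin))
    sel <- v$chrom == chrom
    b <- bin_of(v$pos[sel])
    cnt <- function(cond) {
      tabulate(b[cond] + 1L, nbins = n_bins)
    }
    all_cond <- rep(TRUE, sum(sel))
    g <- group[sel]
    filt <- integer(n_bins)
    if (!is.null(survivors)) {
      sv <- survivors$variants
      sb <- bin_of(sv$pos[sv$chrom == chrom])
      filt <- tabulate(sb + 1L, nbins = n_bins)
    }
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom,
      bin_start = (seq_len(n_bins) - 1) * bin + 1,
      bin_end = pmin(seq_len(n_bins) * bin, L),
      n_all = cnt(all_cond),
      n_filtered = filt,
      n_intron = cnt(g == "intron"),
      n_intergenic = cnt(g == "intergenic"),
      n_updown = cnt(g == "updown"),
      n_other = cnt(g == "other"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
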