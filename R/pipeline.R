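# End-to-end orchestration: run every analysis stage and write the reports.

#' Run the full analysis pipeline
#'
#' Executes, in order: per-chromosome and per-class summaries, diversity
#' (heterozygosity and windowed nucleotide diversity on biallelic autosomal
#' sites), relatedness (GRM on MAF > `maf` biallelic autosomal SNPs, the
#' three inbreeding estimators, PCA), the fixed-variant cascade, and —
#' when a catalog is supplied — the trait-catalog segregation scan. All
#' tables are written as TSV under `outdir` plus a `summary.json` of the
#' headline numbers.
#'
#' @param cohort a `variant_cohort` (e.g. from [read_vcf()] or
#'   [simulate_cohort()]).
#' @param outdir output directory, created if needed; `NULL` skips writing.
#' @param gene_models optional `gene_models` for candidate-gene coordinates.
#' @param catalog optional trait-variant catalog `data.frame`.
#' @param maf minor-allele-frequency threshold (strict) for the
#'   relationship-matrix site set (default 0.05).
#' @param window,step nucleotide-diversity window and step in bp.
#' @param min_dp per-sample depth threshold of the fixed-variant cascade.
#' @param genome_size genome size(s) for the projected pairwise-difference
#'   count.
#' @param stages character subset of
#'   `c("summary", "diversity", "relatedness", "fixed", "catalog")`.
#' @return Invisibly, a list with elements `chrom_summary`, `class_summary`,
#'   `diversity`, `inbreeding`, `pca`, `fixed`, `segregation` (present for
#'   the stages run).
#' @export
run_pipeline <- function(cohort, outdir = NULL, gene_models = NULL,
                         catalog = NULL, maf = 0.05,
                         window = 10000, step = window, min_dp = 10,
                         genome_size = c(2.5e9, 2.7e9),
                         stages = c("summary", "diversity", "relatedness",
                                    "fixed", "catalog")) {
  stopifnot(inherits(cohort, "variant_cohort"))
  res <- list()
  wr <- function(df, name) {
    if (!is.null(outdir)) {
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  if ("summary" %in% stages) {
    res$chrom_summary <- summarize_by_chromosome(cohort)
    res$class_summary <- summarize_by_class(cohort)
    wr(res$chrom_summary$table, "variants_by_chromosome.tsv")
    wr(res$class_summary$table, "variants_by_class.tsv")
    wr(density_bins(cohort), "density_bins.tsv")
  }

  if ("diversity" %in% stages) {
    gm_div <- build_genotype_matrix(cohort, snps_only = FALSE,
                                    autosomes_only = TRUE)
    windows <- window_pi(gm_div, window = window, step = step,
                         chrom_lengths = cohort$contigs)
    res$diversity <- genome_diversity_report(gm_div, windows,
                                             genome_size = genome_size)
    res$windows <- windows
    wr(as.data.frame(windows), "pi_windows.tsv")
    wr(res$diversity$per_sample, "per_sample_heterozygosity.tsv")
  }

  if ("relatedness" %in% stages) {
    gm_rel <- build_genotype_matrix(cohort, snps_only = TRUE,
                                    autosomes_only = TRUE, maf = maf)
    res$inbreeding <- inbreeding(gm_rel)
    res$pca <- pca_from_grm(build_grm(gm_rel),
                            k = min(10, length(cohort$samples)))
    wr(res$inbreeding$samples, "inbreeding_per_sample.tsv")
    wr(res$inbreeding$summary, "inbreeding_summary.tsv")
    wr(data.frame(sample = rownames(res$pca$scores), res$pca$scores),
       "pca_scores.tsv")
  }

  if ("fixed" %in% stages) {
    res$fixed <- fixed_scan(cohort, min_dp = min_dp,
                            gene_models = gene_models)
    wr(res$fixed$stages, "fixed_scan_stages.tsv")
    wr(res$fixed$pcg, "prioritized_candidate_genes.tsv")
    wr(density_bins(cohort, survivors = res$fixed$survivors),
       "density_bins_filtered.tsv")
  }

  if ("catalog" %in% stages && !is.null(catalog)) {
    res$segregation <- segregation_report(catalog, cohort)
    wr(as.data.frame(res$segregation), "catalog_segregation.tsv")
  }

  if (!is.null(outdir)) {
    headline <- list(
      n_sites = n_sites(cohort),
      n_samples = n_samples(cohort)
    )
    if (!is.null(res$diversity)) {
      headline$ho_mean <- res$diversity$ho_mean
      headline$he_mean <- res$diversity$he_mean
      headline$pi_mean <- res$diversity$pi_mean
    }
    if (!is.null(res$inbreeding)) {
      headline$f_means <- stats::setNames(as.list(res$inbreeding$summary$mean),
                                          res$inbreeding$summary$method)
    }
    if (!is.null(res$fixed)) {
      headline$fixed_stage_counts <- stats::setNames(
        as.list(res$fixed$stages$n_sites), res$fixed$stages$stage)
      headline$n_pcg <- nrow(res$fixed$pcg)
    }
    if (!is.null(res$segregation)) {
      headline$n_segregating <- sum(res$segregation$status == "segregating")
    }
    jsonlite::write_json(headline, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
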