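# Per-chromosome / per-class summaries, density bins, pipeline orchestration.

test_that("per-chromosome counts match a hand-tallied fixture", {
  # 10 sites over 3 chromosomes: chrom 1 has 3 SNPs + 1 indel (1 multiallelic
  # SNP), chrom 2 has 2 SNPs, X has 3 SNPs + 1 indel; one unplaced record
  codes <- matrix(1L, 4, 11)
  co <- make_cohort(codes,
                    chrom = c("1", "1", "1", "1", "2", "2", "X", "X", "X", "X",
                              "scaffold_1"),
                    pos = c(10, 20, 30, 40, 10, 20, 10, 20, 30, 40, 10),
                    ref = c("A", "A", "A", "AT", "A", "A", "A", "A", "A", "ACC",
                            "A"),
                    alt = c("T", "C,G", "T", "A", "T", "T", "T", "T", "T", "A",
                            "T"))
  cs <- summarize_by_chromosome(co)
  r1 <- cs$table[cs$table$chrom == "1", ]
  expect_equal(r1$all_snps, 3)       # includes the multiallelic SNP
  expect_equal(r1$all_indels, 1)
  expect_equal(r1$all_total, 4)
  expect_equal(r1$bi_snps, 2)
  expect_equal(r1$bi_total, 3)
  rx <- cs$table[cs$table$chrom == "X", ]
  expect_equal(rx$all_total, 4)
  expect_equal(cs$n_unplaced, 1)
  expect_equal(unname(cs$totals[["all_total"]]), 10)
  expect_equal(unname(cs$autosomal[["all_total"]]), 6)   # X excluded
  # totals recomputed by summation, never stored
  expect_equal(unname(cs$totals[["bi_total"]]), sum(cs$table$bi_total))
})

test_that("published per-chromosome table sums reproduce its printed totals", {
  tab <- utils::read.delim(
    system.file("extdata", "horse_variant_counts_by_chromosome.tsv",
                package = "equifix"),
    colClasses = c(chrom = "character"))
  expect_equal(sum(tab$bi_total), 19958242)
  expect_equal(sum(tab$all_total), 20354948)
  expect_equal(sum(tab$bi_snps), 18245338)
  expect_equal(sum(tab$all_indels), 1990652)
  auto <- tab[tab$chrom != "X", ]
  expect_equal(sum(auto$bi_total), 19123873)
  expect_equal(sum(auto$bi_snps), 17495490)
  expect_equal(sum(auto$bi_indels), 1628383)
  # per-cell dominance the package asserts on every input
  expect_true(all(tab$bi_total <= tab$all_total))
})

test_that("published class-table identities hold under the package rounding", {
  tab <- utils::read.delim(
    system.file("extdata", "horse_biallelic_counts_by_class.tsv",
                package = "equifix"))
  expect_equal(sum(tab$snps), 18245338)
  expect_equal(sum(tab$total), 19958242)
  nonexonic <- c("intergenic_variant", "intron_variant",
                 "upstream_gene_variant", "downstream_gene_variant")
  exonic_snps <- sum(tab$snps[!(tab$class %in% nonexonic)])
  expect_equal(exonic_snps, 353056)
  expect_equal(round_half_up(100 * exonic_snps / sum(tab$snps)), 1.94)
  inter <- tab$snps[tab$class == "intergenic_variant"]
  expect_equal(round_half_up(100 * inter / sum(tab$snps)), 75.34)
  inter_i <- tab$indels[tab$class == "intergenic_variant"]
  expect_equal(round_half_up(100 * inter_i / sum(tab$indels)), 72.62)
})

test_that("class summary reduces to one most-severe consequence per variant", {
  codes <- matrix(1L, 4, 5)
  ann <- rbind(
    make_ann(1, "G1", "intergenic_variant"),
    make_ann(2, "G1", "intergenic_variant"),
    make_ann(3, "G1", "intergenic_variant"),
    make_ann(4, "G1", "intergenic_variant"),
    make_ann(5, "G1", "missense_variant"),
    make_ann(5, "G2", "intron_variant")    # same variant, less severe -> dropped
  )
  co <- make_cohort(codes, pos = 1:5 * 10, ann = ann)
  cls <- summarize_by_class(co)
  expect_equal(cls$table$snps[cls$table$class == "intergenic_variant"], 4)
  expect_equal(cls$table$snps[cls$table$class == "missense_variant"], 1)
  expect_equal(unname(cls$totals[["total"]]), 5)
  expect_equal(cls$table$pct_snps[cls$table$class == "intergenic_variant"], 80)
  expect_equal(cls$table$pct_snps[cls$table$class == "missense_variant"], 20)
})

test_that("density bins count and partition variants", {
  codes <- matrix(1L, 4, 3)
  co <- make_cohort(codes, chrom = "1", pos = c(5e5, 1.5e6, 1.6e6),
                    ann = rbind(make_ann(1, "G1", "intron_variant"),
                                make_ann(2, "G1", "intergenic_variant"),
                                make_ann(3, "G2", "upstream_gene_variant")),
                    contigs = c("1" = 2e6, "2" = 2e6))
  db <- density_bins(co, bin = 1e6)
  b1 <- db[db$chrom == "1", ]
  expect_equal(b1$n_all, c(1, 2))
  expect_equal(b1$n_intron + b1$n_intergenic + b1$n_updown + b1$n_other,
               b1$n_all)
  # an empty chromosome still reports all-zero bins
  b2 <- db[db$chrom == "2", ]
  expect_true(nrow(b2) >= 1 && all(b2$n_all == 0))
})

test_that("cross-table consistency holds on simulated cohorts", {
  sim <- small_sim(seed = 71, n_fixed = 10)
  cs <- summarize_by_chromosome(sim$cohort)
  cls <- summarize_by_class(sim$cohort)
  expect_equal(unname(cls$totals[["total"]]),
               unname(cs$totals[["bi_total"]]))
})

test_that("pipeline writes a deterministic, stage-selectable report set", {
  sim <- small_sim(seed = 81, n_fixed = 8)
  catalog <- data.frame(chrom = "1", pos = 12345, ref = "C", alt = "T",
                        variant_type = "missense", gene = "GX",
                        stringsAsFactors = FALSE)
  out1 <- tempfile(); out2 <- tempfile()
  res <- run_pipeline(sim$cohort, outdir = out1, catalog = catalog,
                      gene_models = sim$gene_models)
  expect_true(file.exists(file.path(out1, "variants_by_chromosome.tsv")))
  expect_true(file.exists(file.path(out1, "inbreeding_summary.tsv")))
  expect_true(file.exists(file.path(out1, "pi_windows.tsv")))
  expect_true(file.exists(file.path(out1, "fixed_scan_stages.tsv")))
  expect_true(file.exists(file.path(out1, "summary.json")))
  expect_s3_class(res$inbreeding, "inbreeding_est")
  # rerun is byte-identical
  run_pipeline(sim$cohort, outdir = out2, catalog = catalog,
               gene_models = sim$gene_models)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  # stage subset writes only what was asked
  out3 <- tempfile()
  res3 <- run_pipeline(sim$cohort, outdir = out3, stages = "summary")
  expect_false(file.exists(file.path(out3, "inbreeding_summary.tsv")))
  expect_null(res3$inbreeding)
})
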