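# Variant data model, VCF I/O, classification, annotation parsing.

test_that("variant classification follows allele geometry", {
  got <- classify_variants(data.frame(
    ref = c("C", "C", "AC", "G", "T", "AT"),
    alt = c("T", "T,CA", "A", "GTT", "<DEL>", "GC")
  ))
  expect_equal(got$allelicity,
               c("biallelic", "multiallelic", "biallelic", "biallelic",
                 "biallelic", "biallelic"))
  expect_equal(got$type, c("SNP", "mixed", "indel", "indel", "mixed", "mixed"))
  # total and pure: repeated calls agree
  expect_identical(got, classify_variants(data.frame(
    ref = c("C", "C", "AC", "G", "T", "AT"),
    alt = c("T", "T,CA", "A", "GTT", "<DEL>", "GC"))))
})

test_that("written VCFs read back bit-exactly (GT, DP, annotations)", {
  sim <- small_sim(seed = 5, n_fixed = 3)
  co <- sim$cohort
  f <- tempfile(fileext = ".vcf")
  write_vcf(co, f)
  back <- read_vcf(f)
  expect_identical(back$variants$chrom, co$variants$chrom)
  expect_identical(back$variants$pos, co$variants$pos)
  expect_identical(back$variants$ref, co$variants$ref)
  expect_identical(back$variants$alt, co$variants$alt)
  expect_identical(back$a1, co$a1)
  expect_identical(back$a2, co$a2)
  expect_identical(back$dp, co$dp)
  expect_identical(back$ann$consequence, co$ann$consequence)
  expect_identical(back$ann$gene_id, co$ann$gene_id)
  expect_identical(back$ann$impact, co$ann$impact)
  # second write of the re-read cohort is byte-identical
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("missing DP and missing genotypes are read as NA, not failures", {
  path <- write_vcf_text(c(
    "1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tG\tA\t.\tPASS\t.\tGT:DP\t0/0:12\t./.:.\t0/1:9"
  ))
  co <- read_vcf(path)
  expect_true(all(is.na(co$dp[1, ])))
  expect_equal(co$dp[2, ], c(12L, NA, 9L))
  expect_true(is.na(co$a1[2, 2]) && is.na(co$a2[2, 2]))
  expect_equal(co$a1[1, ] + co$a2[1, ], c(0L, 1L, 2L))
})

test_that("VEP CSQ and SnpEff ANN dialects map to one annotation schema", {
  csq_hdr <- "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations from VEP. Format: Allele|Gene|SYMBOL|Consequence|IMPACT\">"
  path <- write_vcf_text(c(
    "1\t100\t.\tC\tT\t.\tPASS\tCSQ=T|ENSG1|GENE1|missense_variant|MODERATE\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tG\tA\t.\tPASS\tCSQ=A|ENSG2|GENE2|missense_variant&splice_region_variant|MODERATE,A|ENSG3|GENE3|intron_variant|MODIFIER\tGT\t0/0\t0/0\t0/1"
  ), extra_header = csq_hdr)
  co <- read_vcf(path)
  expect_equal(co$ann$consequence[co$ann$variant == 1], "missense_variant")
  expect_equal(co$ann$impact[co$ann$variant == 1], "MODERATE")
  expect_true(co$ann$is_exonic[co$ann$variant == 1])
  # multi-term block reduced to its most severe term; both genes retained
  a2 <- co$ann[co$ann$variant == 2, ]
  expect_setequal(a2$gene_id, c("ENSG2", "ENSG3"))
  expect_equal(a2$consequence[a2$gene_id == "ENSG2"], "missense_variant")

  ann_hdr <- "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Annotation|Annotation_Impact|Gene_Name|Gene_ID'\">"
  path2 <- write_vcf_text(
    "1\t100\t.\tC\tT\t.\tPASS\tANN=T|stop_gained|HIGH|SYM9|ENSG9\tGT\t0/0\t0/1\t1/1",
    extra_header = ann_hdr
  )
  co2 <- read_vcf(path2)
  expect_equal(co2$ann$gene_id, "ENSG9")
  expect_equal(co2$ann$gene_symbol, "SYM9")
  expect_equal(co2$ann$consequence, "stop_gained")
  expect_equal(co2$ann$impact, "HIGH")
})

test_that("impact mapping is total over the ontology", {
  terms <- consequence_terms()
  imp <- impact_from_consequence(terms)
  expect_true(all(imp %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  expect_equal(impact_from_consequence(
    c("stop_gained", "frameshift_variant", "splice_donor_variant",
      "missense_variant", "inframe_deletion", "synonymous_variant",
      "splice_region_variant", "intron_variant", "coding_sequence_variant")),
    c("HIGH", "HIGH", "HIGH", "MODERATE", "MODERATE", "LOW", "LOW",
      "MODIFIER", "MODIFIER"))
})

test_that("chromosome aliases resolve both naming schemes", {
  expect_equal(normalize_chrom(c("NC_009144.3", "NC_009175.3", "NC_009153")),
               c("1", "X", "10"))
  expect_equal(normalize_chrom(c("chr5", "ECA12", "7")), c("5", "12", "7"))
  expect_equal(is_autosome(c("1", "31", "X", "NC_009175.3", "scaffold_9")),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("unknown sample subset is a configuration error", {
  path <- write_vcf_text("1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
  expect_error(read_vcf(path, samples = c("S1", "NOPE")), "NOPE")
  co <- read_vcf(path, samples = c("S3", "S1"))
  expect_equal(co$samples, c("S3", "S1"))
  expect_equal(co$a1[1, ] + co$a2[1, ], c(2L, 0L))
})

test_that("genotype matrix codes alt dosage and recomputes p", {
  codes <- rbind(c(0, 2, 1), c(1, 2, 0), c(2, 2, NA), c(NA, 2, 1))
  co <- make_cohort(codes, pos = c(100, 200, 300))
  gm <- build_genotype_matrix(co, snps_only = TRUE, autosomes_only = FALSE)
  expect_equal(gm$codes[, 1], c(S01 = 0, S02 = 1, S03 = 2, S04 = NA))
  expect_equal(gm$p[1], 3 / 6)           # hand count over non-missing alleles
  expect_equal(gm$p[2], 1)
  # invariant: mean(codes)/2 == p at every site
  expect_equal(colMeans(gm$codes, na.rm = TRUE) / 2, gm$p, tolerance = 1e-12)
})

test_that("matrix filters: multiallelic out, MAF threshold strict", {
  n <- 10
  codes <- matrix(0L, n, 5)
  codes[, 1] <- c(rep(1L, 5), rep(0L, 5))       # p = 0.25
  codes[1, 2] <- 1L                             # p = 0.05 -> fails MAF > 0.05
  codes[, 3] <- 1L                              # p = 0.5
  codes[1, 4] <- 1L
  codes[, 5] <- c(rep(2L, 5), rep(0L, 5))
  co <- make_cohort(codes, alt = c("T", "T", "T,G", "T,G", "T"))
  gm_bi <- build_genotype_matrix(co, autosomes_only = FALSE)
  expect_equal(ncol(gm_bi$codes), 3)            # 2 multiallelic excluded
  gm_maf <- build_genotype_matrix(co, autosomes_only = FALSE, maf = 0.05)
  expect_equal(ncol(gm_maf$codes), 3 - 1)       # p = 0.05 site excluded
  expect_error(build_genotype_matrix(co, autosomes_only = FALSE, maf = 0.6))
})

test_that("classification partitions every record (per-chromosome schema)", {
  sim <- small_sim(seed = 21)
  cls <- classify_variants(sim$cohort)
  n_bi_snp <- sum(cls$allelicity == "biallelic" & cls$type == "SNP")
  n_bi_ind <- sum(cls$allelicity == "biallelic" & cls$type == "indel")
  n_multi <- sum(cls$allelicity == "multiallelic")
  n_mixed <- sum(cls$allelicity == "biallelic" & cls$type == "mixed")
  expect_equal(n_bi_snp + n_bi_ind + n_multi + n_mixed, n_sites(sim$cohort))
  cs <- summarize_by_chromosome(sim$cohort)
  expect_true(all(cs$table$bi_total <= cs$table$all_total))
  expect_true(all(cs$table$bi_snps <= cs$table$all_snps))
})
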