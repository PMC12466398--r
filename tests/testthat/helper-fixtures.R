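# In-code fixture builders shared across the suite.

# Genotype matrix straight from a samples x sites dosage matrix.
make_gm <- function(codes, chrom = "1", pos = seq_len(ncol(codes))) {
  codes <- as.matrix(codes)
  sites <- data.frame(chrom = rep_len(chrom, ncol(codes)), pos = pos,
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  equifix:::new_genotype_matrix(codes, sprintf("S%02d", seq_len(nrow(codes))),
                                sites)
}

# Cohort from dosage codes (sites in columns). dp defaults to 30x everywhere.
make_cohort <- function(codes, chrom = "1", pos = seq_len(ncol(codes)),
                        ref = "A", alt = "T", dp = NULL, ann = NULL,
                        contigs = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes); n <- nrow(codes)
  a1 <- t(ifelse(codes == 2L, 1L, 0L))
  a2 <- t(ifelse(codes >= 1L, 1L, 0L))
  a1[t(is.na(codes))] <- NA_integer_
  a2[t(is.na(codes))] <- NA_integer_
  if (is.null(dp)) dp <- matrix(30L, m, n)
  variants <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                         ref = rep_len(ref, m), alt = rep_len(alt, m),
                         af = NA_real_, stringsAsFactors = FALSE)
  equifix:::new_variant_cohort(sprintf("S%02d", seq_len(n)), variants,
                               a1, a2, dp, ann, contigs)
}

# Annotation frame helper: one record per (variant index, gene, consequence).
make_ann <- function(variant, gene, consequence) {
  data.frame(
    variant = variant, gene_id = gene, gene_symbol = gene,
    consequence = consequence,
    impact = impact_from_consequence(consequence),
    is_exonic = is_exonic_consequence(consequence),
    stringsAsFactors = FALSE
  )
}

# Minimal hand-written VCF text, returned as a temp file path.
write_vcf_text <- function(body_lines, samples = c("S1", "S2", "S3"),
                           extra_header = character(0)) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    extra_header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, body_lines), path)
  path
}

bundled_catalog <- function() {
  read_trait_catalog(system.file("extdata", "omia_trait_variants.tsv",
                                 package = "equifix"))
}

# Small simulated cohort reused by several files.
small_sim <- function(seed = 11, ...) {
  simulate_cohort(cohort_spec(
    chromosomes = default_chromosomes(4e5)[c(1:3, 32)],
    site_density = 3e-4, seed = seed, ...
  ))
}
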