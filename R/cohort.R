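# Multi-sample variant container and VCF v4.2 input/output.
#
# A `variant_cohort` holds one multi-sample callset in memory:
#   samples  - ordered sample ids
#   variants - data.frame(chrom, pos, ref, alt, af); `alt` is a comma-joined
#              string for multiallelic sites; `af` is the INFO AF as called
#              (kept for reporting only, never used as the analysis frequency)
#   a1, a2   - integer matrices (sites x samples) of diploid allele indices
#              (0 = ref, 1.. = alt), NA = missing call
#   dp       - integer matrix (sites x samples) of per-genotype depth, NA = missing
#   ann      - annotation data.frame: variant (row index into `variants`),
#              gene_id, gene_symbol, consequence, impact, is_exonic
#   contigs  - named numeric vector of contig lengths (NA when unknown)

new_variant_cohort <- function(samples, variants, a1, a2, dp, ann = NULL,
                               contigs = NULL) {
  stopifnot(nrow(variants) == nrow(a1), ncol(a1) == length(samples),
            all(dim(a1) == dim(a2)), all(dim(a1) == dim(dp)))
  if (is.null(ann)) ann <- empty_annotation_frame()
  if (nrow(variants) > 0) {
    stopifnot(all(variants$pos >= 1))
  }
  structure(
    list(samples = samples, variants = variants, a1 = a1, a2 = a2,
         dp = dp, ann = ann, contigs = contigs),
    class = "variant_cohort"
  )
}

#' Number of sites / samples in a cohort
#'
#' @param cohort a `variant_cohort`.
#' @return Integer count.
#' @export
n_sites <- function(cohort) nrow(cohort$variants)

#' @rdname n_sites
#' @export
n_samples <- function(cohort) length(cohort$samples)

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("variant_cohort: %d sites x %d samples\n",
              n_sites(x), n_samples(x)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = " ")))
  cat(sprintf("  annotations: %d records\n", nrow(x$ann)))
  invisible(x)
}

#' Subset a cohort to a set of sites
#'
#' @param cohort a `variant_cohort`.
#' @param idx integer or logical index into the cohort's sites.
#' @return A `variant_cohort` restricted to the selected sites; annotation
#'   records are re-indexed accordingly.
#' @export
subset_sites <- function(cohort, idx) {
  if (is.logical(idx)) idx <- which(idx)
  ann <- cohort$ann[cohort$ann$variant %in% idx, , drop = FALSE]
  ann$variant <- match(ann$variant, idx)
  rownames(ann) <- NULL
  v <- cohort$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  new_variant_cohort(cohort$samples, v,
                     cohort$a1[idx, , drop = FALSE],
                     cohort$a2[idx, , drop = FALSE],
                     cohort$dp[idx, , drop = FALSE],
                     ann, cohort$contigs)
}

#' Classify variants by allelicity and type
#'
#' A site is `biallelic` iff it has exactly one alternate allele. The type is
#' `SNP` when reference and every alternate are single bases, `indel` when
#' every alternate differs from the reference in length, and `mixed`
#' otherwise (mixtures, MNPs, and symbolic alleles such as `<DEL>` or
#' breakends, which are excluded from genotype matrices downstream).
#'
#' @param cohort a `variant_cohort`, or a data.frame with `ref`/`alt` columns.
#' @return `data.frame` with columns `allelicity` (`"biallelic"`/
#'   `"multiallelic"`) and `type` (`"SNP"`/`"indel"`/`"mixed"`).
#' @export
#' @examples
#' classify_variants(data.frame(ref = c("C", "C", "AC"),
#'                              alt = c("T", "T,CA", "A")))
classify_variants <- function(cohort) {
  v <- if (inherits(cohort, "variant_cohort")) cohort$variants else cohort
  alts <- strsplit(as.character(v$alt), ",", fixed = TRUE)
  ref <- as.character(v$ref)
  allelicity <- ifelse(lengths(alts) == 1L, "biallelic", "multiallelic")
  type <- mapply(function(r, a) {
    if (any(grepl("[][<>]", a))) return("mixed")
    cls <- ifelse(nchar(a) != nchar(r), "indel",
                  ifelse(nchar(r) == 1L, "snp", "mnp"))
    if (all(cls == "snp")) "SNP"
    else if (all(cls == "indel")) "indel"
    else "mixed"
  }, ref, alts, USE.NAMES = FALSE)
  data.frame(allelicity = allelicity, type = type, stringsAsFactors = FALSE)
}

# ---- reading ----------------------------------------------------------------

#' Read a multi-sample VCF into a cohort
#'
#' Parses a VCF v4.2/4.3 file (via \pkg{vcfR}) into a `variant_cohort`.
#' Genotypes (`GT`) are required; per-genotype depth (`DP`), INFO `AF` and a
#' VEP `CSQ` or SnpEff `ANN` annotation field are used when present and left
#' empty otherwise. Annotation impact classes are recomputed from the
#' consequence term with the package's fixed mapping.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param samples optional character vector restricting (and ordering) the
#'   samples to load; unknown names are an error.
#' @return A `variant_cohort`.
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  all_samples <- colnames(vcf@gt)[-1]
  if (!is.null(samples)) {
    unknown <- setdiff(samples, all_samples)
    if (length(unknown) > 0) {
      stop("sample(s) not present in VCF: ", paste(unknown, collapse = ", "))
    }
  } else {
    samples <- all_samples
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, samples, drop = FALSE]
  split_allele <- function(k) {
    a <- sub(if (k == 1) "^([^/|]*)[/|].*$" else "^[^/|]*[/|]([^/|]*)$",
             "\\1", gt)
    a[a == "." | a == "" | !grepl("[/|]", gt)] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt),
                            dimnames = NULL))
  }
  a1 <- split_allele(1)
  a2 <- split_allele(2)

  dp <- tryCatch(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, samples, drop = FALSE],
    error = function(e) NULL
  )
  if (is.null(dp)) {
    dp <- matrix(NA_integer_, nrow = nrow(gt), ncol = length(samples))
  } else {
    dp <- matrix(as.integer(dp), nrow = nrow(gt))
  }

  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "AF")))

  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], af = af,
    stringsAsFactors = FALSE
  )

  # annotations: VEP CSQ preferred, SnpEff ANN accepted
  meta <- vcf@meta
  ann <- empty_annotation_frame()
  for (field in c("CSQ", "ANN")) {
    hdr <- grep(sprintf("^##INFO=<ID=%s[,>]", field), meta, value = TRUE)
    if (length(hdr) == 0) next
    fields <- parse_ann_format(hdr[1])
    if (is.null(fields)) next
    payload <- vcfR::extract.info(vcf, element = field)
    parsed <- lapply(seq_along(payload), function(i) {
      df <- parse_annotation_payload(payload[i], fields)
      if (nrow(df) > 0) cbind(variant = i, df) else NULL
    })
    parsed <- parsed[!vapply(parsed, is.null, logical(1))]
    if (length(parsed) > 0) ann <- do.call(rbind, parsed)
    break
  }

  contigs <- NULL
  cl <- grep("^##contig=", meta, value = TRUE)
  if (length(cl) > 0) {
    ids <- sub("^##contig=<ID=([^,>]+).*$", "\\1", cl)
    lens <- suppressWarnings(as.numeric(
      ifelse(grepl("length=", cl), sub("^.*length=([0-9]+).*$", "\\1", cl), NA)
    ))
    contigs <- stats::setNames(lens, ids)
  }

  new_variant_cohort(samples, variants, a1, a2, dp, ann, contigs)
}

# ---- writing ----------------------------------------------------------------

#' Write a cohort as an uncompressed VCF v4.2 file
#'
#' Emits `GT:DP` genotype columns, an `AF` INFO field recomputed from the
#' genotypes, and (when annotations are present) a VEP-style `CSQ` INFO field
#' with format `Allele|Gene|SYMBOL|Consequence|IMPACT`. Output is
#' byte-deterministic for a given cohort.
#'
#' @param cohort a `variant_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=equifix"
  )
  if (!is.null(cohort$contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(cohort$contigs),
                          as.integer(cohort$contigs)))
  }
  hdr <- c(
    hdr,
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency among called genotypes\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: Allele|Gene|SYMBOL|Consequence|IMPACT\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )

  m <- n_sites(cohort)
  # AF from genotypes (biallelic convention: frequency of allele index >= 1)
  nonmiss <- (!is.na(cohort$a1)) & (!is.na(cohort$a2))
  alt_cnt <- rowSums((cohort$a1 >= 1) * nonmiss, na.rm = TRUE) +
    rowSums((cohort$a2 >= 1) * nonmiss, na.rm = TRUE)
  tot <- 2 * rowSums(nonmiss)
  af <- ifelse(tot > 0, alt_cnt / tot, NA)

  csq <- rep(NA_character_, m)
  if (nrow(cohort$ann) > 0) {
    first_alt <- vapply(strsplit(v$alt, ",", fixed = TRUE), `[`, character(1), 1)
    blocks <- sprintf("%s|%s|%s|%s|%s",
                      first_alt[cohort$ann$variant],
                      cohort$ann$gene_id, cohort$ann$gene_symbol,
                      cohort$ann$consequence, cohort$ann$impact)
    agg <- tapply(blocks, cohort$ann$variant, paste, collapse = ",")
    csq[as.integer(names(agg))] <- unname(agg)
  }

  info <- ifelse(is.na(af), ".", sprintf("AF=%s", format(af, trim = TRUE, digits = 6)))
  has_csq <- !is.na(csq)
  info[has_csq] <- paste0(info[has_csq], ";CSQ=", csq[has_csq])

  gt_str <- matrix(".:.", nrow = m, ncol = n_samples(cohort))
  ok <- !is.na(cohort$a1) & !is.na(cohort$a2)
  gt_str[ok] <- paste0(cohort$a1[ok], "/", cohort$a2[ok])
  gt_str[!ok] <- "./."
  dp_str <- ifelse(is.na(cohort$dp), ".", as.character(cohort$dp))
  cells <- matrix(paste0(gt_str, ":", dp_str), nrow = m)

  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT:DP", sep = "\t")
  if (m > 0) {
    body <- paste(body, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con = con, sep = "\n")
  invisible(path)
}
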