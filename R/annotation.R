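# Consequence ontology, impact classes and annotation-string parsing.

# Sequence Ontology terms recognised by the package, ordered from most to
# least severe (Ensembl VEP severity ordering restricted to the classes
# handled here). The order is what "most severe consequence per variant"
# reductions use.
.CONSEQUENCE_SEVERITY <- c(
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_gained",
  "frameshift_variant",
  "stop_lost",
  "start_lost",
  "inframe_insertion",
  "inframe_deletion",
  "missense_variant",
  "protein_altering_variant",
  "splice_region_variant",
  "synonymous_variant",
  "stop_retained_variant",
  "coding_sequence_variant",
  "5_prime_UTR_variant",
  "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant",
  "intron_variant",
  "upstream_gene_variant",
  "downstream_gene_variant",
  "intergenic_variant"
)

.IMPACT_MAP <- c(
  splice_acceptor_variant            = "HIGH",
  splice_donor_variant               = "HIGH",
  stop_gained                        = "HIGH",
  frameshift_variant                 = "HIGH",
  stop_lost                          = "HIGH",
  start_lost                         = "HIGH",
  inframe_insertion                  = "MODERATE",
  inframe_deletion                   = "MODERATE",
  missense_variant                   = "MODERATE",
  protein_altering_variant           = "MODERATE",
  splice_region_variant              = "LOW",
  synonymous_variant                 = "LOW",
  stop_retained_variant              = "LOW"
)

# Consequence terms whose variant allele lies inside an exon.  Splice donor /
# acceptor sites are intronic and therefore excluded; UTR terms are exonic in
# the transcript sense but excluded from candidate-gene counting by default
# (see pcg_select(include_utr=)).
.EXONIC_TERMS <- c(
  "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
  "start_lost", "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "protein_altering_variant", "coding_sequence_variant",
  "stop_retained_variant", "non_coding_transcript_exon_variant"
)

.UTR_TERMS <- c("5_prime_UTR_variant", "3_prime_UTR_variant")

#' Consequence terms known to the package
#'
#' @return Character vector of Sequence Ontology consequence terms, ordered
#'   from most severe to least severe.
#' @export
consequence_terms <- function() .CONSEQUENCE_SEVERITY

#' Map consequence terms to VEP-style impact classes
#'
#' Applies the fixed published mapping: nonsense/splice-site/frameshift terms
#' are `HIGH`, protein-changing in-frame terms are `MODERATE`,
#' synonymous/splice-region terms are `LOW`, everything else is `MODIFIER`.
#'
#' @param consequence character vector of consequence terms (Sequence
#'   Ontology spelling, e.g. `"missense_variant"`).
#' @return Character vector of `"HIGH"`, `"MODERATE"`, `"LOW"` or
#'   `"MODIFIER"`, same length as `consequence`.
#' @export
#' @examples
#' impact_from_consequence(c("stop_gained", "missense_variant", "intron_variant"))
impact_from_consequence <- function(consequence) {
  out <- unname(.IMPACT_MAP[consequence])
  out[is.na(out)] <- "MODIFIER"
  out
}

#' Is a consequence term exonic?
#'
#' @param consequence character vector of consequence terms.
#' @param include_utr logical; if `TRUE`, 5' and 3' UTR terms count as exonic.
#' @return Logical vector.
#' @export
is_exonic_consequence <- function(consequence, include_utr = FALSE) {
  terms <- .EXONIC_TERMS
  if (include_utr) terms <- c(terms, .UTR_TERMS)
  consequence %in% terms
}

# Severity rank: 1 = most severe. Unknown terms rank after everything known.
consequence_rank <- function(consequence) {
  r <- match(consequence, .CONSEQUENCE_SEVERITY)
  r[is.na(r)] <- length(.CONSEQUENCE_SEVERITY) + 1L
  r
}

# Most severe single term from a "&"-joined multi-term consequence string.
most_severe_term <- function(x) {
  vapply(strsplit(x, "&", fixed = TRUE), function(terms) {
    terms[which.min(consequence_rank(terms))]
  }, character(1))
}

#' Chromosome alias table for the horse genome
#'
#' Maps plain chromosome names (`1`..`31`, `X`) to the EquCab3.0 RefSeq
#' accessions (`NC_009144.3` .. `NC_009175.3`).
#'
#' @return `data.frame` with columns `name` and `accession`.
#' @export
chrom_alias_table <- function() {
  data.frame(
    name = c(as.character(1:31), "X"),
    accession = sprintf("NC_0091%02d.3", 44:75),
    stringsAsFactors = FALSE
  )
}

#' Normalize chromosome names
#'
#' Strips `chr`/`ECA`/`ECC` prefixes and maps RefSeq accessions (with or
#' without version suffix) to plain names via [chrom_alias_table()].
#'
#' @param chrom character vector of chromosome labels.
#' @return Character vector of normalized labels (`"1"`..`"31"`, `"X"`, or the
#'   input stripped of prefixes when no alias matches).
#' @export
normalize_chrom <- function(chrom) {
  x <- as.character(chrom)
  x <- sub("^(chr|ECA|ECC)", "", x, ignore.case = TRUE)
  al <- chrom_alias_table()
  hit <- match(x, al$accession)
  miss <- is.na(hit)
  if (any(!miss)) x[!miss] <- al$name[hit[!miss]]
  # accession without version
  bare <- match(sub("\\.\\d+$", "", x[miss]), sub("\\.\\d+$", "", al$accession))
  x[miss][!is.na(bare)] <- al$name[bare[!is.na(bare)]]
  x
}

#' Is a chromosome an autosome?
#'
#' @param chrom character vector of chromosome labels (any alias accepted).
#' @return Logical vector: `TRUE` for purely numeric normalized names.
#' @export
is_autosome <- function(chrom) {
  grepl("^[0-9]+$", normalize_chrom(chrom))
}

# ---- annotation-string parsing ---------------------------------------------

# Parse the Format declaration out of a VEP CSQ / SnpEff ANN header line, e.g.
# Description="Consequence annotations ... Format: Allele|Gene|..." .
parse_ann_format <- function(description) {
  m <- regmatches(description, regexpr("Format:[^\"]+", description))
  if (length(m) == 1 && m != "") {
    fields <- sub("^Format:\\s*", "", m)
    return(trimws(strsplit(fields, "|", fixed = TRUE)[[1]]))
  }
  # SnpEff style: field list single-quoted inside the description
  m <- regmatches(description, regexpr("'[^']*\\|[^']*'", description))
  if (length(m) == 1 && m != "") {
    fields <- gsub("'", "", m)
    return(trimws(strsplit(fields, "|", fixed = TRUE)[[1]]))
  }
  NULL
}

# Parse one INFO annotation payload (comma-separated transcript blocks of
# pipe-separated fields) into an annotation data.frame. `fields` gives the
# field names from the header. Works for both VEP CSQ and SnpEff ANN by
# looking up either dialect's column names. Impact is always recomputed from
# the consequence term so a fixed mapping holds package-wide.
parse_annotation_payload <- function(payload, fields) {
  if (is.na(payload) || payload == "") {
    return(empty_annotation_frame())
  }
  blocks <- strsplit(payload, ",", fixed = TRUE)[[1]]
  parts <- strsplit(blocks, "|", fixed = TRUE)
  get <- function(part, names_wanted) {
    idx <- match(names_wanted, fields)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) return(NA_character_)
    v <- part[idx[1]]
    if (is.na(v) || v == "") NA_character_ else v
  }
  cons_raw <- vapply(parts, get, character(1),
                     names_wanted = c("Consequence", "Annotation"))
  gene_id <- vapply(parts, get, character(1),
                    names_wanted = c("Gene", "Gene_ID"))
  gene_symbol <- vapply(parts, get, character(1),
                        names_wanted = c("SYMBOL", "Gene_Name"))
  consequence <- most_severe_term(cons_raw)
  data.frame(
    gene_id = gene_id,
    gene_symbol = gene_symbol,
    consequence = consequence,
    impact = impact_from_consequence(consequence),
    is_exonic = is_exonic_consequence(consequence),
    stringsAsFactors = FALSE
  )
}

empty_annotation_frame <- function() {
  data.frame(
    variant = integer(0), gene_id = character(0), gene_symbol = character(0),
    consequence = character(0), impact = character(0), is_exonic = logical(0),
    stringsAsFactors = FALSE
  )
}
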