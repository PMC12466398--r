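# Synthetic cohort simulator: annotated multi-sample VCFs with known truth.
#
# Genotypes are drawn marginally from inbreeding-adjusted Hardy-Weinberg
# proportions: for alternate-allele frequency p and individual inbreeding F,
#   P(hom-ref) = (1-p)^2 + F p(1-p)
#   P(het)     = 2 p (1-p) (1-F)
#   P(hom-alt) = p^2 + F p(1-p)
# Negative probabilities (F below the feasible lower bound for extreme p) are
# clamped to zero and the triple renormalized, with a message.

#' Default simulated chromosome set
#'
#' 31 autosomes plus X, mirroring the horse karyotype, at a desk-scale
#' length of 2 Mb each.
#'
#' @param length_bp length of every simulated chromosome, in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
default_chromosomes <- function(length_bp = 2e6) {
  stats::setNames(rep(length_bp, 32), c(as.character(1:31), "X"))
}

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the simulator; the same spec with the same
#' seed always yields a byte-identical VCF. Defaults emulate the study
#' cohort this package was built around: 20 diploid horses, 31 autosomes + X,
#' a U-shaped Beta(0.5, 0.5) site-frequency spectrum, ~8.5% indels, and a
#' mean sequencing depth of 21x.
#'
#' @param n_samples number of diploid individuals.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param site_density expected variant sites per bp.
#' @param freq_model list describing the alternate-allele frequency
#'   distribution: `list(family = "beta", shape1, shape2)`,
#'   `list(family = "uniform", min, max)` or `list(family = "fixed", p = )`.
#' @param f_inbreeding per-sample inbreeding coefficient in `[-1, 1]`
#'   (scalar recycled).
#' @param indel_fraction proportion of sites simulated as indels.
#' @param mean_depth per-sample mean depth for Poisson DP simulation
#'   (scalar or length `n_samples`).
#' @param n_fixed number of extra sites injected with all samples homozygous
#'   alternate, placed uniformly at random.
#' @param pcg_gene_counts named integer vector: for each named gene, that
#'   many fixed homozygous-alternate exonic SNPs with HIGH or MODERATE
#'   consequence labels are planted inside its exons.
#' @param catalog optional trait-variant catalog `data.frame` (see
#'   [read_trait_catalog()]); its variants are injected at their stated
#'   positions.
#' @param catalog_het integer vector of target heterozygote counts, one per
#'   catalog row (remaining samples homozygous reference).
#' @param gene_models optional gene model table (see [read_gene_models()]);
#'   simulated when `NULL`.
#' @param genes_per_chrom number of genes simulated per chromosome when
#'   `gene_models` is `NULL`.
#' @param exon_snp_probs named probabilities of exonic consequence labels for
#'   SNPs (labels are assigned, not derived from codons).
#' @param exon_indel_probs same for indels.
#' @param seed integer seed controlling all randomness.
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_samples = 20,
                        chromosomes = default_chromosomes(),
                        site_density = 2e-4,
                        freq_model = list(family = "beta", shape1 = 0.5, shape2 = 0.5),
                        f_inbreeding = 0,
                        indel_fraction = 0.085,
                        mean_depth = 21,
                        n_fixed = 0,
                        pcg_gene_counts = NULL,
                        catalog = NULL,
                        catalog_het = NULL,
                        gene_models = NULL,
                        genes_per_chrom = 3,
                        exon_snp_probs = c(missense_variant = 0.52,
                                           synonymous_variant = 0.40,
                                           stop_gained = 0.04,
                                           start_lost = 0.02,
                                           stop_lost = 0.02),
                        exon_indel_probs = c(frameshift_variant = 0.70,
                                             inframe_deletion = 0.15,
                                             inframe_insertion = 0.15),
                        seed = 1L) {
  f <- rep_len(f_inbreeding, n_samples)
  stopifnot(all(f >= -1 & f <= 1), site_density > 0,
            indel_fraction >= 0, indel_fraction <= 1)
  if (!is.null(catalog)) {
    stopifnot(!is.null(catalog_het), length(catalog_het) == nrow(catalog),
              all(catalog_het <= n_samples), all(catalog_het >= 0))
  }
  structure(list(
    n_samples = n_samples, chromosomes = chromosomes,
    site_density = site_density, freq_model = freq_model,
    f_inbreeding = f, indel_fraction = indel_fraction,
    mean_depth = rep_len(mean_depth, n_samples),
    n_fixed = n_fixed, pcg_gene_counts = pcg_gene_counts,
    catalog = catalog, catalog_het = catalog_het,
    gene_models = gene_models, genes_per_chrom = genes_per_chrom,
    exon_snp_probs = exon_snp_probs, exon_indel_probs = exon_indel_probs,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Draw alternate-allele frequencies from a frequency model
#'
#' @param n number of sites.
#' @param freq_model model list as in [cohort_spec()].
#' @return Numeric vector of frequencies in (0, 1).
#' @export
draw_site_freqs <- function(n, freq_model) {
  p <- switch(freq_model$family,
    beta = stats::rbeta(n, freq_model$shape1, freq_model$shape2),
    uniform = stats::runif(n, freq_model$min, freq_model$max),
    fixed = rep_len(freq_model$p, n),
    stop("unknown frequency model family: ", freq_model$family)
  )
  pmin(pmax(p, 1e-4), 1 - 1e-4)
}

# Draw dosage codes (samples x sites) under F-adjusted HWE. `f` is per sample.
sample_genotype_codes <- function(p, f, n_samples, chunk = 20000L) {
  m <- length(p)
  f <- rep_len(f, n_samples)
  codes <- matrix(0L, n_samples, m)
  clamped <- FALSE
  for (s in seq(1, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    pp <- p[s:e]
    k <- length(pp)
    pq <- pp * (1 - pp)
    fpq <- outer(f, pq)                         # n x k
    p0 <- matrix((1 - pp)^2, n_samples, k, byrow = TRUE) + fpq
    p1 <- matrix(2 * pq, n_samples, k, byrow = TRUE) * (1 - f)
    p2 <- matrix(pp^2, n_samples, k, byrow = TRUE) + fpq
    if (any(p0 < 0) || any(p1 < 0) || any(p2 < 0)) {
      clamped <- TRUE
      p0[p0 < 0] <- 0; p1[p1 < 0] <- 0; p2[p2 < 0] <- 0
    }
    tot <- p0 + p1 + p2
    p0 <- p0 / tot
    p1 <- p1 / tot
    u <- matrix(stats::runif(n_samples * k), n_samples, k)
    codes[, s:e] <- (u >= p0) + (u >= p0 + p1)
  }
  if (clamped) {
    message("genotype sampler: negative class probabilities clamped to 0 ",
            "(inbreeding coefficient outside feasible range for some sites)")
  }
  codes
}

#' Simulate a genotype matrix directly
#'
#' Bypasses VCF generation: draws site frequencies and inbreeding-adjusted
#' genotypes, returning a `genotype_matrix` with the true frequencies and
#' per-sample F recorded as attributes. Intended for estimator
#' parameter-recovery work at large sample/site counts.
#'
#' @param n_samples number of diploid individuals.
#' @param n_sites number of biallelic SNP sites.
#' @param freq_model frequency model list (see [cohort_spec()]).
#' @param f per-sample inbreeding coefficient (scalar recycled).
#' @param seed integer seed.
#' @return A `genotype_matrix` with attributes `p_true` and `f_true`.
#' @export
simulate_genotype_matrix <- function(n_samples, n_sites,
                                     freq_model = list(family = "beta",
                                                       shape1 = 0.5, shape2 = 0.5),
                                     f = 0, seed = 1L) {
  set.seed(seed)
  p <- draw_site_freqs(n_sites, freq_model)
  codes <- sample_genotype_codes(p, f, n_samples)
  rownames(codes) <- sprintf("S%03d", seq_len(n_samples))
  sites <- data.frame(
    chrom = "1", pos = seq_len(n_sites),
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )
  gm <- new_genotype_matrix(codes, rownames(codes), sites)
  attr(gm, "p_true") <- p
  attr(gm, "f_true") <- rep_len(f, n_samples)
  gm
}

#' Simulate gene models
#'
#' Places `genes_per_chrom` non-overlapping genes on each chromosome, each
#' 10-30 kb long with 2-8 non-overlapping exons and random strand.
#'
#' @param chromosomes named numeric vector of chromosome lengths.
#' @param genes_per_chrom genes per chromosome.
#' @return A `gene_models` list with `genes` (gene_id, gene_symbol, chrom,
#'   start, end, strand) and `exons` (gene_id, start, end) data.frames.
#' @export
simulate_gene_models <- function(chromosomes, genes_per_chrom = 3) {
  genes <- list(); exons <- list()
  for (chrom in names(chromosomes)) {
    L <- chromosomes[[chrom]]
    k <- genes_per_chrom
    block <- floor(L / k)
    for (i in seq_len(k)) {
      glen <- round(stats::runif(1, 10000, min(30000, block - 4000)))
      lo <- (i - 1) * block + 1000
      start <- lo + floor(stats::runif(1, 0, block - glen - 2000))
      end <- start + glen - 1
      gid <- sprintf("GENE_%s_%02d", chrom, i)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(2:8, 1)
      # alternate exon/intron widths spanning the gene, exons first and last
      cuts <- sort(stats::runif(2 * n_ex - 2))
      widths <- diff(c(0, cuts, 1)) * glen
      b <- start
      ex <- list()
      for (j in seq_along(widths)) {
        w <- max(1, round(widths[j]))
        if (j %% 2 == 1) {  # exon segment
          ex[[length(ex) + 1]] <- data.frame(gene_id = gid, start = b,
                                             end = min(b + w - 1, end))
        }
        b <- b + w
      }
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = gid, gene_symbol = gid, chrom = chrom,
        start = start, end = end, strand = strand, stringsAsFactors = FALSE
      )
      exons[[length(exons) + 1]] <- do.call(rbind, ex)
    }
  }
  structure(list(genes = do.call(rbind, genes), exons = do.call(rbind, exons)),
            class = "gene_models")
}

#' Read / write gene models as a BED-like TSV
#'
#' The table has columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#' `feature` with `feature` either `"gene"` or `"exon"` (1-based inclusive
#' coordinates).
#'
#' @param path file path.
#' @return For `read_gene_models`, a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  genes <- df[df$feature == "gene", , drop = FALSE]
  exons <- df[df$feature == "exon", , drop = FALSE]
  structure(list(
    genes = data.frame(gene_id = genes$gene_id, gene_symbol = genes$gene_id,
                       chrom = genes$chrom, start = genes$start,
                       end = genes$end, strand = genes$strand,
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = exons$gene_id, start = exons$start,
                       end = exons$end, stringsAsFactors = FALSE)
  ), class = "gene_models")
}

#' @rdname read_gene_models
#' @param models a `gene_models` object.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  e <- models$exons
  e$chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  e$strand <- g$strand[match(e$gene_id, g$gene_id)]
  out <- rbind(
    data.frame(chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, gene_id = g$gene_id, feature = "gene"),
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               strand = e$strand, gene_id = e$gene_id, feature = "exon")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positionally annotate a site against gene models
#'
#' Pure geometry: `intergenic` when no gene lies within `flank_bp`;
#' `upstream`/`downstream` (strand-aware) within `flank_bp` of a gene
#' boundary; `intron` inside a gene but outside its exons; `exon` inside an
#' exon. When several genes overlap the site, the most gene-proximal region
#' wins (exon > intron > upstream/downstream), ties broken by lower gene id.
#'
#' @param chrom,pos site coordinates (scalars).
#' @param models a `gene_models` object.
#' @param flank_bp upstream/downstream window in bp (default 5000, the VEP
#'   default).
#' @return A one-row data.frame with `gene_id`, `gene_symbol` and `region`
#'   (one of `"intergenic"`, `"upstream"`, `"downstream"`, `"intron"`,
#'   `"exon"`); gene fields are `NA` for intergenic sites.
#' @export
annotate_site_position <- function(chrom, pos, models, flank_bp = 5000) {
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  best <- data.frame(gene_id = NA_character_, gene_symbol = NA_character_,
                     region = "intergenic", stringsAsFactors = FALSE)
  if (nrow(g) == 0) return(best)
  rank <- c(exon = 3, intron = 2, upstream = 1, downstream = 1, intergenic = 0)
  best_rank <- 0
  for (i in order(g$gene_id)) {
    region <- NULL
    if (pos >= g$start[i] && pos <= g$end[i]) {
      ex <- models$exons[models$exons$gene_id == g$gene_id[i], , drop = FALSE]
      inside_exon <- any(pos >= ex$start & pos <= ex$end)
      region <- if (inside_exon) "exon" else "intron"
    } else if (pos >= g$start[i] - flank_bp && pos < g$start[i]) {
      region <- if (g$strand[i] == "+") "upstream" else "downstream"
    } else if (pos > g$end[i] && pos <= g$end[i] + flank_bp) {
      region <- if (g$strand[i] == "+") "downstream" else "upstream"
    }
    if (!is.null(region) && rank[[region]] > best_rank) {
      best <- data.frame(gene_id = g$gene_id[i], gene_symbol = g$gene_symbol[i],
                         region = region, stringsAsFactors = FALSE)
      best_rank <- rank[[region]]
    }
  }
  best
}

# catalog variant_type -> consequence term used in the synthetic annotation
catalog_type_consequence <- function(type) {
  map <- c(missense = "missense_variant",
           "stop-gain" = "stop_gained",
           deletion = "frameshift_variant",
           regulatory = "upstream_gene_variant")
  out <- unname(map[type])
  out[is.na(out)] <- "intergenic_variant"
  out
}

random_bases <- function(n, size = 1) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i)
    paste(sample(bases, size, replace = TRUE), collapse = ""), character(1))
}

#' Simulate an annotated synthetic cohort
#'
#' Generates background variant sites along each chromosome, draws genotypes
#' under inbreeding-adjusted Hardy-Weinberg proportions, assigns positional
#' consequence annotations against (simulated or supplied) gene models,
#' injects fixed homozygous-alternate variants (random and/or planted inside
#' named genes), injects trait-catalog variants at requested heterozygote
#' counts, and simulates per-genotype Poisson depths. All randomness is
#' governed by `spec$seed`; the same spec yields byte-identical VCF output.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort_sim`: list with `cohort` (a
#'   `variant_cohort`), `truth` (per-site truth table with columns `chrom`,
#'   `pos`, `ref`, `alt`, `type`, `p_true`, `consequence`, `impact`,
#'   `gene_id`, `origin`, `het_target`), `gene_models`, and `spec`. The
#'   per-sample true inbreeding coefficients are in `attr(truth, "f_true")`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  chroms <- spec$chromosomes

  models <- spec$gene_models
  if (is.null(models)) {
    models <- simulate_gene_models(chroms, spec$genes_per_chrom)
  }

  site_chrom <- character(0); site_pos <- integer(0)
  used <- lapply(chroms, function(L) integer(0))

  # --- background sites
  for (chrom in names(chroms)) {
    L <- chroms[[chrom]]
    k <- stats::rpois(1, L * spec$site_density)
    pos <- sort(sample.int(L, min(k, L)))
    used[[chrom]] <- pos
    site_chrom <- c(site_chrom, rep(chrom, length(pos)))
    site_pos <- c(site_pos, pos)
  }
  m_bg <- length(site_pos)
  is_indel <- stats::runif(m_bg) < spec$indel_fraction
  ref <- random_bases(m_bg)
  alt <- character(m_bg)
  for (i in seq_len(m_bg)) {
    if (!is_indel[i]) {
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    } else if (stats::runif(1) < 0.5) {  # deletion: longer ref
      extra <- random_bases(1, sample(1:3, 1))
      alt[i] <- ref[i]
      ref[i] <- paste0(ref[i], extra)
    } else {                             # insertion: longer alt
      alt[i] <- paste0(ref[i], random_bases(1, sample(1:3, 1)))
    }
  }
  p_true <- draw_site_freqs(m_bg, spec$freq_model)
  codes <- sample_genotype_codes(p_true, spec$f_inbreeding, n)

  # --- positional annotation of background sites
  region <- character(m_bg); gene_id <- rep(NA_character_, m_bg)
  for (i in seq_len(m_bg)) {
    a <- annotate_site_position(site_chrom[i], site_pos[i], models)
    region[i] <- a$region
    gene_id[i] <- a$gene_id
  }
  consequence <- c(intergenic = "intergenic_variant",
                   upstream = "upstream_gene_variant",
                   downstream = "downstream_gene_variant",
                   intron = "intron_variant")[region]
  consequence <- unname(consequence)
  ex <- which(region == "exon")
  if (length(ex) > 0) {
    snp_ex <- ex[!is_indel[ex]]
    ind_ex <- ex[is_indel[ex]]
    if (length(snp_ex) > 0) {
      consequence[snp_ex] <- sample(names(spec$exon_snp_probs), length(snp_ex),
                                    replace = TRUE, prob = spec$exon_snp_probs)
    }
    if (length(ind_ex) > 0) {
      consequence[ind_ex] <- sample(names(spec$exon_indel_probs), length(ind_ex),
                                    replace = TRUE, prob = spec$exon_indel_probs)
    }
  }
  origin <- rep("background", m_bg)
  het_target <- rep(NA_integer_, m_bg)

  free_pos <- function(chrom, lo, hi) {
    repeat {
      cand <- lo + sample.int(hi - lo + 1L, 1) - 1L
      if (!(cand %in% used[[chrom]])) return(cand)
    }
  }

  add_site <- function(chrom, pos, ref1, alt1, cons, gid, codes_row, org,
                       p, het = NA_integer_) {
    site_chrom <<- c(site_chrom, chrom)
    site_pos <<- c(site_pos, pos)
    ref <<- c(ref, ref1); alt <<- c(alt, alt1)
    consequence <<- c(consequence, cons)
    gene_id <<- c(gene_id, gid)
    codes <<- cbind(codes, codes_row)
    p_true <<- c(p_true, p)
    origin <<- c(origin, org)
    het_target <<- c(het_target, het)
    used[[chrom]] <<- c(used[[chrom]], pos)
  }

  # --- random fixed-alternate injections
  if (spec$n_fixed > 0) {
    for (i in seq_len(spec$n_fixed)) {
      chrom <- sample(names(chroms), 1)
      pos <- free_pos(chrom, 1L, as.integer(chroms[[chrom]]))
      a <- annotate_site_position(chrom, pos, models)
      cons <- c(intergenic = "intergenic_variant",
                upstream = "upstream_gene_variant",
                downstream = "downstream_gene_variant",
                intron = "intron_variant",
                exon = "synonymous_variant")[[a$region]]
      r <- sample(c("A", "C", "G", "T"), 1)
      add_site(chrom, pos, r, sample(setdiff(c("A", "C", "G", "T"), r), 1),
               cons, a$gene_id, rep(2L, n), "fixed", 1)
    }
  }

  # --- planted candidate-gene fixed exonic variants
  if (!is.null(spec$pcg_gene_counts)) {
    for (gid in names(spec$pcg_gene_counts)) {
      gi <- match(gid, models$genes$gene_id)
      if (is.na(gi)) stop("pcg_gene_counts names unknown gene: ", gid)
      chrom <- models$genes$chrom[gi]
      ex_tab <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
      for (k in seq_len(spec$pcg_gene_counts[[gid]])) {
        row <- ex_tab[sample.int(nrow(ex_tab), 1), ]
        pos <- free_pos(chrom, as.integer(row$start), as.integer(row$end))
        cons <- sample(c("missense_variant", "stop_gained"), 1,
                       prob = c(0.8, 0.2))
        r <- sample(c("A", "C", "G", "T"), 1)
        add_site(chrom, pos, r, sample(setdiff(c("A", "C", "G", "T"), r), 1),
                 cons, gid, rep(2L, n), "fixed", 1)
      }
    }
  }

  # --- trait-catalog injections
  if (!is.null(spec$catalog)) {
    cat_tab <- spec$catalog
    for (i in seq_len(nrow(cat_tab))) {
      chrom <- as.character(cat_tab$chrom[i])
      if (!(chrom %in% names(chroms))) {
        stop("catalog chromosome not in simulated set: ", chrom)
      }
      pos <- as.integer(cat_tab$pos[i])
      if (pos %in% used[[chrom]]) {
        warning("catalog position collides with a simulated site; shifted +1 bp")
        pos <- pos + 1L
      }
      h <- spec$catalog_het[i]
      row <- integer(n)
      if (h > 0) row[sample.int(n, h)] <- 1L
      add_site(chrom, pos, as.character(cat_tab$ref[i]),
               as.character(cat_tab$alt[i]),
               catalog_type_consequence(as.character(cat_tab$variant_type[i])),
               as.character(cat_tab$gene[i]), row, "catalog",
               h / (2 * n), het = h)
    }
  }

  # --- order by chromosome then position
  ord <- order(match(site_chrom, names(chroms)), site_pos)
  site_chrom <- site_chrom[ord]; site_pos <- site_pos[ord]
  ref <- ref[ord]; alt <- alt[ord]
  consequence <- consequence[ord]; gene_id <- gene_id[ord]
  p_true <- p_true[ord]; origin <- origin[ord]; het_target <- het_target[ord]
  codes <- codes[, ord, drop = FALSE]
  dimnames(codes) <- NULL
  m <- length(site_pos)

  # --- depths
  dp <- matrix(0L, m, n)
  for (j in seq_len(n)) dp[, j] <- stats::rpois(m, spec$mean_depth[j])

  # genotypes: split dosage codes into unphased allele pairs
  a1 <- t(ifelse(codes == 2L, 1L, 0L))
  a2 <- t(ifelse(codes >= 1L, 1L, 0L))

  variants <- data.frame(chrom = site_chrom, pos = site_pos, ref = ref,
                         alt = alt, af = NA_real_, stringsAsFactors = FALSE)
  impact <- impact_from_consequence(consequence)
  has_gene <- !is.na(gene_id)
  ann <- data.frame(
    variant = which(has_gene | consequence != "intergenic_variant"),
    stringsAsFactors = FALSE
  )
  ann$gene_id <- ifelse(has_gene[ann$variant], gene_id[ann$variant], "-")
  ann$gene_symbol <- ann$gene_id
  ann$consequence <- consequence[ann$variant]
  ann$impact <- impact[ann$variant]
  ann$is_exonic <- is_exonic_consequence(ann$consequence)
  # intergenic sites also get an annotation record (gene-less), as VEP emits
  inter <- which(!(seq_len(m) %in% ann$variant))
  if (length(inter) > 0) {
    ann <- rbind(ann, data.frame(
      variant = inter, gene_id = "-", gene_symbol = "-",
      consequence = "intergenic_variant", impact = "MODIFIER",
      is_exonic = FALSE, stringsAsFactors = FALSE
    ))
    ann <- ann[order(ann$variant), , drop = FALSE]
    rownames(ann) <- NULL
  }

  samples <- sprintf("H%02d", seq_len(n))
  rownames(a1) <- NULL
  cohort <- new_variant_cohort(samples, variants, a1, a2, dp, ann,
                               contigs = chroms)

  truth <- data.frame(
    chrom = site_chrom, pos = site_pos, ref = ref, alt = alt,
    type = ifelse(nchar(ref) == nchar(alt), "SNP", "indel"),
    p_true = p_true, consequence = consequence, impact = impact,
    gene_id = gene_id, origin = origin, het_target = het_target,
    stringsAsFactors = FALSE
  )
  attr(truth, "f_true") <- spec$f_inbreeding

  structure(list(cohort = cohort, truth = truth, gene_models = models,
                 spec = spec),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("cohort_sim: %d samples, %d sites (%d fixed, %d catalog), seed %d\n",
              n_samples(x$cohort), n_sites(x$cohort),
              sum(x$truth$origin == "fixed"), sum(x$truth$origin == "catalog"),
              x$spec$seed))
  invisible(x)
}
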