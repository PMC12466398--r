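# Independent brute-force oracles, written as explicit loops from the
# printed formulas; deliberately share no code with the implementation.

oracle_freq <- function(codes) {
  apply(codes, 2, function(x) mean(x[!is.na(x)]) / 2)
}

oracle_grm <- function(codes) {
  p <- oracle_freq(codes)
  n <- nrow(codes); m <- ncol(codes)
  Z <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      x <- codes[i, k]
      Z[i, k] <- if (is.na(x)) 0 else x - 2 * p[k]
    }
  }
  denom <- 0
  for (k in seq_len(m)) denom <- denom + 2 * p[k] * (1 - p[k])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(m)) s <- s + Z[i, k] * Z[j, k]
      G[i, j] <- s / denom
    }
  }
  G
}

oracle_f_grm <- function(codes) {
  G <- oracle_grm(codes)
  diag(G) - 1
}

oracle_f_hom <- function(codes) {
  p <- oracle_freq(codes)
  n <- nrow(codes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    o_hom <- 0; e_hom <- 0; n_nm <- 0
    for (k in seq_len(ncol(codes))) {
      x <- codes[i, k]
      if (is.na(x)) next
      n_nm <- n_nm + 1
      if (x == 0 || x == 2) o_hom <- o_hom + 1
      e_hom <- e_hom + (1 - 2 * p[k] * (1 - p[k]))
    }
    out[i] <- (o_hom - e_hom) / (n_nm - e_hom)
  }
  out
}

oracle_f_uni <- function(codes) {
  p <- oracle_freq(codes)
  n <- nrow(codes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0; used <- 0
    for (k in seq_len(ncol(codes))) {
      x <- codes[i, k]
      if (is.na(x)) next
      used <- used + 1
      s <- s + (x^2 - (1 + 2 * p[k]) * x + 2 * p[k]^2) /
        (2 * p[k] * (1 - p[k]))
    }
    out[i] <- s / used
  }
  out
}

# Brute-force nucleotide diversity: expand every diploid into two sequences
# and average per-site mismatches over all sequence pairs, per window.
oracle_window_pi <- function(codes, pos, window, chrom_len) {
  starts <- seq(1, chrom_len, by = window)
  out <- data.frame(start = starts, pi = NA_real_)
  for (w in seq_along(starts)) {
    s <- starts[w]
    e <- min(s + window, chrom_len + 1)
    width <- e - s
    total <- 0
    for (k in which(pos >= s & pos < e)) {
      x <- codes[, k]
      alleles <- integer(0)
      for (i in seq_along(x)) {
        if (is.na(x[i])) next
        alleles <- c(alleles,
                     if (x[i] == 0) c(0L, 0L)
                     else if (x[i] == 1) c(0L, 1L)
                     else c(1L, 1L))
      }
      n <- length(alleles)
      if (n < 2) next
      diffs <- 0; pairs <- 0
      for (a in seq_len(n - 1)) {
        for (b in seq(a + 1, n)) {
          pairs <- pairs + 1
          if (alleles[a] != alleles[b]) diffs <- diffs + 1
        }
      }
      total <- total + diffs / pairs
    }
    out$pi[w] <- total / width
  }
  out
}
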