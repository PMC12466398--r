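# GRM, the three inbreeding estimators, and GRM-based PCA.

test_that("GRM matches the hand-computed closed forms", {
  # two samples, one site, codes (0, 2): Z = (-1, +1), denom = 0.5
  gm <- make_gm(matrix(c(0L, 2L), 2, 1))
  g <- build_grm(gm)
  expect_equal(unname(g$matrix), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_equal(g$site_weights_sum, 0.5)
  expect_equal(unname(f_grm(g)), c(1, 1))
  # all-heterozygous sample at p = 0.5 centers to zero: F_GRM = -1
  gm2 <- make_gm(rbind(rep(1L, 10), rep(1L, 10)))
  expect_equal(unname(f_grm(build_grm(gm2))), c(-1, -1))
})

test_that("F_HOM and F_UNI reproduce forced extremes and term values", {
  # two loci, both het, p = 0.5: (0 - 1)/(2 - 1) = -1
  gm_het <- make_gm(rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L)))
  expect_equal(unname(f_hom(gm_het)), rep(-1, 4))
  expect_equal(unname(f_uni(gm_het)), rep(-1, 4))   # cross-estimator agreement
  # both hom at p = 0.5: (2 - 1)/(2 - 1) = +1; F_UNI homozygote symmetry
  gm_hom <- make_gm(rbind(c(0L, 2L), c(2L, 0L)))
  expect_equal(unname(f_hom(gm_hom)), rep(1, 2))
  expect_equal(unname(f_uni(gm_hom)), rep(1, 2))
})

test_that("estimators equal the brute-force oracle on small matrices", {
  set.seed(77)
  for (rep in 1:4) {
    n <- sample(3:8, 1)
    m <- sample(10:30, 1)
    repeat {
      codes <- matrix(sample(0:2, n * m, replace = TRUE,
                             prob = c(0.4, 0.35, 0.25)), n, m)
      codes[sample(length(codes), round(0.04 * length(codes)))] <- NA
      p <- colMeans(codes, na.rm = TRUE) / 2
      if (all(!is.na(p) & p > 0 & p < 1)) break
    }
    gm <- make_gm(codes)
    expect_equal(unname(build_grm(gm)$matrix), oracle_grm(codes),
                 tolerance = 1e-10)
    expect_equal(unname(f_grm(build_grm(gm))), oracle_f_grm(codes),
                 tolerance = 1e-10)
    expect_equal(unname(f_hom(gm)), oracle_f_hom(codes), tolerance = 1e-10)
    expect_equal(unname(f_uni(gm)), oracle_f_uni(codes), tolerance = 1e-10)
  }
})

test_that("estimators are invariant to allele swap and site order", {
  set.seed(88)
  codes <- matrix(sample(0:2, 6 * 40, replace = TRUE), 6, 40)
  codes[1, 3] <- NA
  gm <- make_gm(codes)
  gm <- filter_maf(gm, 0)      # polymorphic only
  sw <- swap_alleles(gm)
  expect_equal(build_grm(gm)$matrix, build_grm(sw)$matrix, tolerance = 1e-12)
  expect_equal(f_hom(gm), f_hom(sw), tolerance = 1e-12)
  expect_equal(f_uni(gm), f_uni(sw), tolerance = 1e-12)
  perm <- sample(ncol(gm$codes))
  gm_perm <- make_gm(gm$codes[, perm], pos = perm)
  expect_equal(build_grm(gm)$matrix, build_grm(gm_perm)$matrix,
               tolerance = 1e-12)
  expect_equal(f_uni(gm), f_uni(gm_perm), tolerance = 1e-12)
})

test_that("monomorphic sites and all-missing samples are hard errors", {
  gm_mono <- make_gm(rbind(c(2L, 1L), c(2L, 0L)))   # site 1 has p = 1
  expect_error(build_grm(gm_mono), "monomorphic")
  expect_error(f_uni(gm_mono), "monomorphic")
  codes <- rbind(c(NA, NA), c(0L, 1L), c(2L, 1L))
  expect_error(build_grm(make_gm(codes)), "S01")
})

test_that("F_GRM recovers planted inbreeding from the diagonal", {
  gm <- simulate_genotype_matrix(200, 50000, f = 0.2, seed = 23)
  gm <- filter_maf(gm, 0.05)
  expect_lt(abs(mean(f_grm(build_grm(gm))) - 0.2), 0.02)
  # trace(GRM)/n -> 1 at F = 0
  gm0 <- filter_maf(simulate_genotype_matrix(100, 20000, f = 0, seed = 24),
                    0.05)
  g0 <- build_grm(gm0)
  expect_lt(abs(mean(diag(g0$matrix)) - 1), 0.02)
})

test_that("descriptive table shape and near-zero means at F = 0", {
  gm <- filter_maf(simulate_genotype_matrix(20, 20000, f = 0, seed = 25), 0.05)
  est <- inbreeding(gm)
  expect_equal(est$summary$method, c("F_GRM", "F_HOM", "F_UNI"))
  expect_true(all(est$summary$min <= est$summary$mean &
                    est$summary$mean <= est$summary$max))
  expect_true(all(abs(est$summary$mean) <= 0.05))
  # summary reproducible from per-sample values
  expect_equal(est$summary$mean[1], mean(est$samples$f_grm))
  expect_equal(est$summary$max[2], max(est$samples$f_hom))
})

test_that("PCA of the GRM follows the eigen closed forms", {
  g_id <- structure(list(matrix = diag(4), n_sites = 10,
                         site_weights_sum = 1, scaling = "pooled"),
                    class = "grm")
  pc <- pca_from_grm(g_id, k = 4)
  expect_equal(pc$eigenvalues, rep(1, 4))
  expect_equal(pc$explained, rep(25, 4))
  g2 <- structure(list(matrix = matrix(c(2, -2, -2, 2), 2), n_sites = 1,
                       site_weights_sum = 0.5, scaling = "pooled"),
                  class = "grm")
  pc2 <- pca_from_grm(g2, k = 2)
  expect_equal(pc2$eigenvalues, c(4, 0))
  expect_equal(pc2$explained, c(100, 0))
  expect_equal(abs(pc2$scores[, 1]), c(sqrt(2), sqrt(2)))
  expect_warning(pca_from_grm(g2, k = 5), "clamped")
})

test_that("PCA separates planted subpopulations with opposite-sign scores", {
  set.seed(33)
  m <- 60
  gA <- sample(0:2, m, replace = TRUE)
  codes <- rbind(matrix(rep(gA, each = 6), 6),      # subpopulation A, duplicated
                 matrix(rep(2L - gA, each = 6), 6)) # mirrored subpopulation B
  gm <- filter_maf(make_gm(codes), 0)
  pc <- pca_from_grm(build_grm(gm), k = 2)
  s1 <- pc$scores[1:6, 1]
  s2 <- pc$scores[7:12, 1]
  expect_true(all(sign(mean(s1)) * s1 > 0))
  expect_true(all(sign(mean(s2)) * s2 > 0))
  expect_true(sign(mean(s1)) != sign(mean(s2)))
})

test_that("per-site GRM scaling is available and distinct", {
  set.seed(44)
  codes <- matrix(sample(0:2, 8 * 50, replace = TRUE), 8, 50)
  gm <- filter_maf(make_gm(codes), 0)
  pooled <- build_grm(gm, scaling = "pooled")
  per_site <- build_grm(gm, scaling = "per_site")
  expect_false(isTRUE(all.equal(pooled$matrix, per_site$matrix)))
  expect_equal(per_site$matrix, t(per_site$matrix))
})
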