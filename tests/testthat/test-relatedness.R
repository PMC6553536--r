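# Relationship machinery: VanRaden GRM against a double-loop oracle,
# IBS allele-sharing, PCA structure recovery, LD decay and MAF spectra.

test_that("GRM matches the naive double-loop VanRaden oracle", {
  X <- rand_dosage(50, 500, seed = 21)
  K <- grm(X)
  expect_equal(unclass(K), naive_grm(X), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(K)))
  expect_lt(max(abs(rowSums(K))), 1e-8 * nrow(X))
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # duplicated individuals share row, column and diagonal values
  Xd <- rbind(X, X[1, , drop = FALSE])
  Kd <- unclass(grm(Xd))
  expect_equal(Kd[1, 1], Kd[1, 51], tolerance = 1e-12)
  expect_equal(Kd[51, 51], Kd[1, 1], tolerance = 1e-12)
  expect_error(grm(matrix(2, 4, 5)), "monomorphic")
})

test_that("IBS counts shared alleles", {
  expect_equal(unclass(ibs(rbind(a = c(0, 1, 2), b = c(0, 1, 2))))["a", "b"], 1)
  expect_equal(unclass(ibs(rbind(a = c(0, 0), b = c(2, 2))))["a", "b"], 0)
  expect_equal(unclass(ibs(rbind(a = 0, b = 1)))["a", "b"], 0.5)
  X <- rand_dosage(20, 200, seed = 22)
  K <- unclass(ibs(X))
  expect_true(isSymmetric(K))
  expect_true(all(K >= 0 & K <= 1))
  # missing-data path agrees with complete-data path where complete
  Xna <- X; Xna[1, 1] <- NA
  Kna <- unclass(ibs(Xna))
  expect_equal(Kna[2, 3], K[2, 3], tolerance = 1e-12)
  expect_error(ibs(rbind(c(NA, 0), c(1, NA))), "no non-missing")
})

test_that("PCA separates simulated subpopulations and matches eigen oracle", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = 30, n_markers = 800,
                    fst = 0.3, missing_rate = 0, seed = 23)
  sim <- simulate_structured_genotypes(cfg)
  pcs <- pca_genotypes(sim$geno, d = 4)
  expect_gt(silhouette_1d(pcs$scores[, 1], sim$geno$pop), 0.5)
  expect_true(all(diff(pcs$var_explained) <= 1e-12))
  # scores reproduce the top eigenvectors of the centered cross-product
  X <- rand_dosage(60, 300, seed = 24)
  p <- pca_genotypes(X, d = 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  for (j in 1:3) {
    ref <- eg$vectors[, j] * sqrt(eg$values[j])
    expect_lt(min(max(abs(p$scores[, j] - ref)),
                  max(abs(p$scores[, j] + ref))), 1e-6)
  }
  # duplicated individuals get identical scores
  Xd <- rbind(X, X[5, , drop = FALSE])
  pd <- pca_genotypes(Xd, d = 2)
  expect_equal(pd$scores[61, ], pd$scores[5, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_genotypes(X, d = 100), "rank")
})

test_that("LD decay reflects marker correlation over distance", {
  # duplicated marker column at distance ~0 gives r2 = 1
  X <- rand_dosage(40, 2, seed = 25)
  X[, 2] <- X[, 1]
  G <- geno_matrix(X, data.frame(marker = c("a", "b"), chrom = "chr1",
                                 pos = c(100, 101)))
  tab <- ld_decay(G, max_dist = 1000, n_bins = 2)
  expect_equal(tab$mean_r2[1], 1)
  # independent markers: mean r2 near the 1/(n-1) null floor, shrinking in n
  floor_r2 <- function(n, seed) {
    X <- rand_dosage(n, 400, seed = seed)
    G <- geno_matrix(X, data.frame(marker = paste0("m", 1:400),
                                   chrom = "chr1", pos = seq(1, 400) * 10))
    mean(ld_decay(G, max_dist = 4000, n_bins = 1)$mean_r2)
  }
  f30 <- floor_r2(30, 26); f120 <- floor_r2(120, 27)
  expect_lt(abs(f30 - 1 / 29), 0.01)
  expect_lt(f120, f30)
  # drift population (few founders) shows uniformly higher r2
  set.seed(28)
  founders <- rand_dosage(8, 400, seed = 29)
  Xf <- founders[sample(8, 60, replace = TRUE), ]
  rownames(Xf) <- paste0("i", 1:60)
  Gf <- geno_matrix(Xf, data.frame(marker = paste0("m", 1:400),
                                   chrom = "chr1", pos = seq(1, 400) * 10))
  expect_gt(mean(ld_decay(Gf, max_dist = 4000, n_bins = 1)$mean_r2), f30)
  # single marker per chromosome: empty table
  G1 <- geno_matrix(X[, 1, drop = FALSE],
                    data.frame(marker = "a", chrom = "chr1", pos = 1))
  expect_equal(nrow(ld_decay(G1)[ld_decay(G1)$n_pairs > 0, ]), 0)
})

test_that("MAF spectra order groups by their generating frequency ranges", {
  X <- cbind(rep(1, 6))  # all het: maf 0.5
  sp <- maf_spectrum(X, rep("g", 6))
  expect_true(all(sp$maf == 0.5))
  cfg_lo <- sim_config(n_subpops = 1, n_per_subpop = 60, n_markers = 800,
                       ancestral_maf_range = c(0.02, 0.2), fst = 0.05,
                       missing_rate = 0, seed = 30)
  cfg_hi <- sim_config(n_subpops = 1, n_per_subpop = 60, n_markers = 800,
                       ancestral_maf_range = c(0.25, 0.5), fst = 0.05,
                       missing_rate = 0, seed = 30)
  Xlo <- simulate_structured_genotypes(cfg_lo)$geno$dosage
  Xhi <- simulate_structured_genotypes(cfg_hi)$geno$dosage
  sp2 <- maf_spectrum(rbind(Xlo, Xhi),
                      rep(c("narrow", "wide"), each = 60))
  p95 <- sp2[sp2$percentile == 95, ]
  expect_lt(p95$maf[p95$group == "narrow"], p95$maf[p95$group == "wide"])
  for (g in unique(sp2$group))
    expect_true(all(diff(sp2$maf[sp2$group == g]) >= 0))
})
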