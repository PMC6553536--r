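# Generator properties: Balding-Nichols divergence, missingness, HWE
# within subpopulations, the Wahlund effect, trial-phenotype heritability,
# geography-linked breeding values, and read-depth simulation.

test_that("config invariants are enforced", {
  expect_error(sim_config(n_subpops = 0), "counts")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(h2_target = 1.2), "h2_target")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)), "maf_range")
})

test_that("subpopulation divergence matches the Hudson FST estimator", {
  cfg <- sim_config(n_subpops = 3, n_per_subpop = 50, n_markers = 2000,
                    fst = 0.3, missing_rate = 0, seed = 101)
  sim <- simulate_structured_genotypes(cfg)
  X <- sim$geno$dosage
  pop <- sim$geno$pop
  prs <- combn(levels(pop), 2)
  fsts <- apply(prs, 2, function(pr)
    hudson_fst(X[pop == pr[1], ], X[pop == pr[2], ]))
  expect_true(all(abs(fsts - 0.3) < 0.05))
})

test_that("panmixia limit leaves only sampling noise between subpops", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = 100, n_markers = 2000,
                    fst = 0, missing_rate = 0, seed = 102)
  sim <- simulate_structured_genotypes(cfg)
  X <- sim$geno$dosage; pop <- sim$geno$pop
  fst0 <- hudson_fst(X[pop == "pop1", ], X[pop == "pop2", ])
  expect_lt(abs(fst0), 0.01)
})

test_that("missingness rate is realized", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = 100, n_markers = 2000,
                    missing_rate = 0.1, seed = 103)
  sim <- simulate_structured_genotypes(cfg)
  frac <- mean(is.na(sim$geno$dosage))
  expect_gt(frac, 0.08); expect_lt(frac, 0.12)
})

test_that("HWE holds within subpopulations and pooling shows the Wahlund effect", {
  het_deficit <- function(fst, seed) {
    cfg <- sim_config(n_subpops = 3, n_per_subpop = 60, n_markers = 1000,
                      fst = fst, missing_rate = 0, seed = seed)
    sim <- simulate_structured_genotypes(cfg)
    X <- sim$geno$dosage
    # within-subpop HWE pass rate at alpha = 0.001
    for (s in levels(sim$geno$pop)) {
      sub <- X[sim$geno$pop == s, , drop = FALSE]
      st <- compute_marker_stats(sub)
      expect_gte(mean(st$hwe_p > 0.001), 0.99)
    }
    p <- colMeans(X) / 2
    obs_het <- colMeans(X == 1)
    exp_het <- 2 * p * (1 - p)
    ok <- exp_het > 0
    1 - sum(obs_het[ok]) / sum(exp_het[ok])
  }
  d <- vapply(c(0, 0.1, 0.3), het_deficit, numeric(1), seed = 104)
  expect_true(all(diff(d) > 0))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_subpops = 2, n_per_subpop = 20, n_markers = 300,
                    seed = 105)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$records, b$records)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$breeding_values, b$truth$breeding_values)
})

test_that("realized family-mean heritability tracks the target", {
  r2 <- vapply(1:20, function(r) {
    cfg <- sim_config(n_subpops = 1, n_per_subpop = 300, n_markers = 400,
                      n_qtl = 50, h2_target = 0.6, n_locations = 2,
                      n_blocks = 3, missing_rate = 0, fst = 0.05,
                      seed = 2000 + r)
    sim <- simulate_structured_genotypes(cfg)
    rec <- simulate_trial_phenotypes(sim$geno, sim$truth, cfg)
    fm <- tapply(rec$score, rec$family, mean)
    cor(fm, sim$truth$breeding_values[names(fm)])^2
  }, numeric(1))
  expect_gt(mean(r2), 0.5)
  expect_lt(mean(r2), 0.7)
})

test_that("zero QTL effects give a near-zero family variance component", {
  cfg <- sim_config(n_subpops = 1, n_per_subpop = 100, n_markers = 200,
                    n_qtl = 0, missing_rate = 0, seed = 106)
  sim <- simulate_structured_genotypes(cfg)
  rec <- simulate_trial_phenotypes(sim$geno, sim$truth, cfg)
  fit <- fit_random_model(rec, trial_model_terms("multi_location"))
  expect_lt(fit$vc[["family"]], 0.05 * fit$vc[["Residual"]])
})

test_that("full heritability with non-genetic terms is rejected", {
  cfg <- sim_config(n_subpops = 1, n_per_subpop = 20, n_markers = 100,
                    h2_target = 1, missing_rate = 0, seed = 107)
  sim <- simulate_structured_genotypes(cfg)
  expect_error(simulate_trial_phenotypes(sim$geno, sim$truth, cfg),
               "h2_target")
})

test_that("geography links breeding values to latitude and climate", {
  cfg <- sim_config(n_subpops = 24, n_per_subpop = 5, n_markers = 300,
                    geo_gradient = c(0.5, -0.3), missing_rate = 0,
                    seed = 108)
  sim <- simulate_structured_genotypes(cfg)
  meta <- assign_geography(levels(sim$geno$pop), cfg)
  expect_gt(abs(cor(meta$min_temp, meta$latitude)), 0.8)
  truth <- apply_geography(sim$truth, meta, sim$geno$pop)
  pop_bv <- tapply(truth$breeding_values, sim$geno$pop, mean)
  expect_gt(cor(pop_bv[meta$population], meta$latitude), 0)
  # null gradient: no systematic latitude alignment
  cfg0 <- sim_config(n_subpops = 24, n_per_subpop = 5, n_markers = 300,
                     geo_gradient = c(0, 0), missing_rate = 0, seed = 108)
  meta0 <- assign_geography(levels(sim$geno$pop), cfg0)
  truth0 <- apply_geography(sim$truth, meta0, sim$geno$pop)
  bv0 <- tapply(truth0$breeding_values, sim$geno$pop, mean)
  expect_lt(abs(cor(bv0[meta0$population], meta0$latitude)), 0.5)
})

test_that("allelic depths follow the ploidy dosage classes", {
  cfg <- sim_config(n_subpops = 1, n_per_subpop = 6, n_markers = 6000,
                    ancestral_maf_range = c(0.3, 0.5), fst = 0.05,
                    missing_rate = 0, seed = 109)
  sim <- simulate_structured_genotypes(cfg)
  lab <- rep(c("tetraploid", "octoploid"), each = 3)
  # deep sequencing: tetraploid fractions concentrate at 0.5
  ad_deep <- simulate_allelic_depths(sim$geno, lab, mean_depth = 200, seed = 1)
  fr <- ref_allele_fractions(ad_deep, min_depth = 50)
  tet <- fr[["fam1"]]
  expect_gt(length(tet), 500)
  expect_lt(mean(abs(tet - 0.5)), 0.05)
  # octoploid: side modes at 0.25 and 0.75 are populated
  oct <- fr[["fam4"]]
  expect_gt(mean(oct < 0.35), 0.15)
  expect_gt(mean(oct > 0.65), 0.15)
  # Poisson depth: mean total depth near the target
  ad20 <- simulate_allelic_depths(sim$geno, lab, mean_depth = 20, seed = 2)
  expect_gt(nrow(ad20), 5000)
  expect_gt(mean(ad20$total_depth), 19)
  expect_lt(mean(ad20$total_depth), 21)
  expect_error(simulate_allelic_depths(sim$geno, "hexaploid", 20),
               "unknown ploidy")
})
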