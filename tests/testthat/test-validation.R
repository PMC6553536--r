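# Geographic validation: population-adjusted GEBVs, correlation critical
# values, OLS against the normal-equations oracle, and phenotype-based
# prediction accuracy including the training-relatedness effect.

test_that("adjusted GEBVs are population least-squares means", {
  g <- c(1, 3, 2, 6, 10)
  pop <- c("a", "a", "b", "b", "c")
  adj <- adjust_gebv(g, pop)
  expect_equal(adj$adj_gebv, c(2, 4, 10))      # balanced: group means
  expect_equal(adj$adj_gebv[adj$population == "c"], 10)  # singleton
  shifted <- adjust_gebv(g + 7, pop)
  expect_equal(shifted$adj_gebv, adj$adj_gebv + 7)
  expect_error(adjust_gebv(g, factor(pop, levels = c("a", "b", "c", "d"))),
               "empty")
})

test_that("critical correlation values follow the t-distribution formula", {
  expect_equal(round(critical_r(168, 0.01), 3), 0.198)
  tq <- qt(0.995, 166)
  expect_equal(critical_r(168, 0.01), tq / sqrt(tq^2 + 166),
               tolerance = 1e-12)
})

test_that("geo correlations recover exact linear structure and flag significance", {
  meta <- data.frame(population = paste0("p", 1:10),
                     latitude = seq(30, 44, length.out = 10),
                     longitude = c(95, 80, 90, 85, 99, 76, 92, 81, 88, 78),
                     min_temp = 25 - 0.9 * seq(30, 44, length.out = 10))
  adj <- data.frame(population = meta$population,
                    adj_gebv = 2 * meta$latitude)
  tab <- geo_correlations(adj, meta)
  expect_equal(tab$r[tab$variable == "latitude"], 1, tolerance = 1e-12)
  expect_equal(tab$r[tab$variable == "min_temp"], -1, tolerance = 1e-12)
  expect_true(tab$significant[tab$variable == "latitude"])
  expect_error(geo_correlations(adj[1:3, ], meta[1:3, ]), "at least 4")
})

test_that("geo regression matches the normal-equations oracle", {
  meta <- data.frame(population = paste0("p", 1:12),
                     latitude = runif(12, 28, 45),
                     longitude = runif(12, 75, 100),
                     min_temp = 0)
  # exact plane: coefficients and R2 recovered perfectly
  adj <- data.frame(population = meta$population,
                    adj_gebv = 2 * meta$latitude + 1 * meta$longitude)
  reg <- suppressWarnings(geo_regression(adj, meta))  # exact fit
  expect_equal(reg$coefficients$estimate[reg$coefficients$term == "latitude"],
               2, tolerance = 1e-8)
  expect_equal(reg$coefficients$estimate[reg$coefficients$term == "longitude"],
               1, tolerance = 1e-8)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  # random instances against (X'X)^-1 X'y
  set.seed(91)
  for (k in 1:5) {
    adj$adj_gebv <- rnorm(12)
    reg <- geo_regression(adj, meta)
    X <- cbind(1, meta$latitude, meta$longitude)
    beta <- solve(crossprod(X), crossprod(X, adj$adj_gebv))
    expect_equal(reg$coefficients$estimate, drop(beta), tolerance = 1e-10)
    # permuting population order changes nothing
    pm <- sample(12)
    reg_p <- geo_regression(adj[pm, ], meta[pm, ])
    expect_equal(reg_p$coefficients$estimate, reg$coefficients$estimate,
                 tolerance = 1e-12)
    expect_equal(reg_p$r2, reg$r2, tolerance = 1e-12)
  }
})

test_that("prediction accuracy handles levels, ids and the null", {
  x <- setNames(rnorm(30), paste0("i", 1:30))
  expect_equal(prediction_accuracy(x, x), 1)
  expect_error(prediction_accuracy(x, setNames(rnorm(30), paste0("j", 1:30))),
               "unmatched")
  pop <- rep(paste0("p", 1:10), each = 3)
  obs <- x + rnorm(30)
  acc_pop <- prediction_accuracy(x, obs, level = "population", pop = pop)
  expect_equal(acc_pop, cor(tapply(x, pop, mean), tapply(obs, pop, mean)))
  # null sampling distribution at 23 populations
  set.seed(92)
  exceed <- mean(replicate(300, abs(cor(rnorm(23), rnorm(23))) > 0.45))
  expect_lte(exceed, 0.05)
})

test_that("prediction into a related population beats a diverged one", {
  # natural-population MAF spectra are rare-allele heavy, so causal loci
  # drift toward fixation in the diverged training set and carry no
  # information there -- the mechanism behind the training-relatedness effect
  wins <- vapply(1:15, function(r) {
    cfg <- sim_config(n_subpops = 2, n_per_subpop = 60, n_markers = 600,
                      fst = 0.3, ancestral_maf_range = c(0.05, 0.3),
                      missing_rate = 0, h2_target = 0.6,
                      geo_gradient = c(0, 0), seed = 1100 + r)
    st <- simulate_study(cfg)
    K <- unclass(grm(st$geno))
    fv <- family_values(fit_random_model(st$records,
                                         trial_model_terms("multi_location")))
    y <- setNames(fv$value, fv$family)[rownames(st$geno$dosage)]
    set.seed(r)
    test <- sample(61:120, 20)                  # hold-out from pop2
    same <- sample(setdiff(61:120, test), 40)   # related training set
    div <- sample(1:60, 40)                     # diverged, equal size
    acc <- vapply(list(same, div), function(tr) {
      fit <- fit_gblup(y[tr], K[tr, tr])
      cor(st$truth$breeding_values[test], predict_gebv(fit, K, tr, test))
    }, numeric(1))
    acc[1] - acc[2]
  }, numeric(1))
  expect_gt(mean(wins), 0)
  expect_gte(sum(wins > 0), 8)
})
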