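test_that("noise-free world collapses to the latent truth", {
  cfg <- synth_config(n_samples = 50, sigma_dft = 0, sigma_exp = 0,
                      dft_bias = c(a = 0, b = 1), seed = 2)
  d <- synth_generate(cfg)
  expect_equal(d$reactions$dG_exp_kcal, d$truth$true_barrier)
  expect_equal(d$descriptors$dG_dft, d$truth$true_barrier)
})

test_that("config validation and reproducibility", {
  expect_error(synth_config(rho_cluster = 1), "rho_cluster")
  expect_error(synth_config(sigma_dft = 0.1, sigma_exp = 0.3), "sigma")
  d1 <- synth_generate(synth_config(n_samples = 40, seed = 9))
  d2 <- synth_generate(synth_config(n_samples = 40, seed = 9))
  expect_identical(d1, d2)
  d3 <- synth_generate(synth_config(n_samples = 40, seed = 10))
  expect_false(identical(d1$reactions$dG_exp_kcal,
                         d3$reactions$dG_exp_kcal))
})

test_that("emitted tables satisfy the external schemas and invariants", {
  d <- fixture_dataset()
  expect_true(all(d$descriptors$dG_dft > 0))
  expect_identical(names(d$descriptors),
                   c("rxn_id", feature_set_columns("X_full")))
  # Eyring consistency holds row-by-row by construction
  expect_silent(read_reactions(d$reactions))
  expect_true(all(d$reactions$solvent %in% d$solvents$solvent))
  # class labels carried consistently
  expect_true(all(table(d$reactions$electrophile_id,
                        d$reactions$leaving_class) %in%
                    c(0, table(d$reactions$electrophile_id))))
})

test_that("dft/exp correlation matches the analytic covariance value", {
  d <- synth_generate(synth_config(n_samples = 2000, seed = 21))
  b <- d$truth$config$dft_bias[["b"]]
  s_true <- var(d$truth$true_barrier)
  s_dft <- d$truth$config$sigma_dft^2
  s_exp <- d$truth$config$sigma_exp^2
  analytic <- b * s_true / sqrt((b^2 * s_true + s_dft) * (s_true + s_exp))
  emp <- cor(d$descriptors$dG_dft, d$reactions$dG_exp_kcal)
  expect_lt(abs(emp - analytic), 0.03)
})

test_that("within-cluster correlation realizes the configured value", {
  d <- synth_generate(synth_config(n_samples = 2000, rho_cluster = 0.9,
                                   class_shift_sd = 0, seed = 22))
  cl <- snarml:::.synth_clusters$sterics   # no class shift on this factor
  sub <- as.matrix(d$descriptors[, cl])
  rho <- cor(sub, method = "spearman")
  off <- abs(rho[upper.tri(rho)])
  # Spearman of bivariate normal: (6/pi) asin(rho/2)
  expected <- (6 / pi) * asin(0.9 / 2)
  expect_true(all(off >= 0.9 * expected))
})

test_that("raw-DFT baseline error matches its Monte-Carlo value", {
  d <- synth_generate(synth_config(n_samples = 4000, seed = 23))
  mae_raw <- mean(abs(d$descriptors$dG_dft - d$reactions$dG_exp_kcal))
  cfgp <- d$truth$config
  mc <- with_seed(99, {
    tr <- d$truth$true_barrier
    mean(abs(cfgp$dft_bias[["a"]] + (cfgp$dft_bias[["b"]] - 1) * tr +
               rnorm(length(tr), 0, cfgp$sigma_dft) -
               rnorm(length(tr), 0, cfgp$sigma_exp)))
  })
  expect_lt(abs(mae_raw - mc) / mc, 0.05)
})

test_that("competition generator respects its stated margins and classes", {
  comp <- synth_competitions(n = 300, margin = 1.4, sigma_pred = 0,
                             seed = 31)
  tr <- comp$truth
  margins <- tapply(tr$dG_true_kcal, tr$substrate_id,
                    function(v) diff(sort(v)))
  expect_true(all(abs(unlist(margins) - 1.4) < 1e-12))
  res <- top1_accuracy(comp$sites)
  expect_equal(res$overall, 1)
  expect_error(synth_competitions(margin = -1), "margin")
  expect_error(synth_competitions(n_sites = 1), "sites")
  # multi-site competitions work end-to-end
  c3 <- synth_competitions(n = 40, n_sites = 3, sigma_pred = 0.2, seed = 5)
  expect_equal(nrow(c3$sites), 120L)
  expect_true(all(table(c3$sites$substrate_id) == 3L))
})
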