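test_that("linear families recover exact linear structure", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 3 + 2 * X[, 1] - 0.5 * X[, 3]
  fit <- fit_model(snar_model("LR"), X, y)
  expect_lt(max(abs(predict(fit, X)$mean - y)), 1e-8)
  expect_true(all(is.na(predict(fit, X)$std)))

  ard <- fit_model(snar_model("ARD"), X, y)
  expect_lt(mean(abs(predict(ard, X)$mean - y)), 1e-3)

  # manifest mismatch is named
  Xbad <- X; colnames(Xbad) <- paste0("g", 1:4)
  expect_error(predict(fit, Xbad), "manifest")
})

test_that("DFT baselines: raw identity, exact OLS, degenerate input", {
  dft <- c(20, 25, 30, 22)
  expect_equal(predict(fit_dft_baseline(dft, dft, "raw"), dft), dft)
  b <- fit_dft_baseline(dft, 2 + 0.5 * dft, "linear_corrected")
  expect_equal(c(b$a, b$b), c(2, 0.5), tolerance = 1e-8)
  expect_error(fit_dft_baseline(rep(20, 4), dft, "linear_corrected"),
               "constant")
  raw <- fit_dft_baseline(dft, dft, "raw")
  expect_equal(c(raw$a, raw$b), c(0, 1))
})

test_that("RF is seed-deterministic and captures nonlinearity", {
  set.seed(3)
  X <- matrix(runif(600, -2, 2), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1]^2 + 2 * (X[, 2] > 0) + rnorm(200, 0, 0.1)
  cfg <- snar_model("RF", seed = 4, hyper = list(ntree = 50))
  f1 <- fit_model(cfg, X[1:150, ], y[1:150])
  f2 <- fit_model(cfg, X[1:150, ], y[1:150])
  expect_identical(predict(f1, X[151:200, ]), predict(f2, X[151:200, ]))
  mae_rf <- mean(abs(y[151:200] - predict(f1, X[151:200, ])$mean))
  mae_mean <- mean(abs(y[151:200] - mean(y[1:150])))
  expect_lt(mae_rf, 0.5 * mae_mean)
})

test_that("SVR fits smooth signal well and tunes over a grid when asked", {
  set.seed(5)
  X <- matrix(runif(240, -2, 2), 120, 2, dimnames = list(NULL, c("a", "b")))
  y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(120, 0, 0.05)
  fit <- fit_model(snar_model("SVR"), X[1:90, ], y[1:90])
  expect_lt(mean(abs(y[91:120] - predict(fit, X[91:120, ])$mean)), 0.25)
  fitg <- fit_model(snar_model("SVR", hyper = list(
    grid = list(cost = c(1, 10), epsilon = c(0.05, 0.2)))),
    X[1:90, ], y[1:90])
  expect_lt(mean(abs(y[91:120] - predict(fitg, X[91:120, ])$mean)), 0.25)
})

test_that("prediction intervals follow the Gaussian convention", {
  pred <- structure(data.frame(mean = c(20, 25), std = c(0, 1)),
                    class = c("snar_pred", "data.frame"))
  pi95 <- prediction_interval(pred, 0.95)
  expect_equal(pi95$lower[1], 20); expect_equal(pi95$upper[1], 20)
  expect_equal(pi95$upper[2] - pi95$mean[2], 1.959964, tolerance = 1e-6)
  expect_true(all(pi95$lower <= pi95$mean & pi95$mean <= pi95$upper))
  nostd <- data.frame(mean = 1, std = NA_real_)
  expect_error(prediction_interval(nostd), "Bayesian")
  expect_error(prediction_interval(pred, 1.2), "level")
})

test_that("model ordering on synthetic data: GPR/SVR <= RF <= LR in MAE", {
  # strongly nonlinear latent configuration: the regime where the family
  # ordering is expected; expectation over seeds, modest n for speed
  maes <- sapply(1:6, function(s) {
    d <- synth_generate(synth_config(n_samples = 260, nonlinearity = 5,
                                     seed = 300 + s))
    xy <- assemble_features(d$reactions, d$descriptors,
                            feature_set_spec("X_small"))
    tr <- 1:180; te <- 181:260
    vapply(c("LR", "RF", "SVR", "GPR"), function(fam) {
      hy <- if (fam == "GPR") list(restarts = 1) else
        if (fam == "RF") list(ntree = 150, mtry = 8, min_node = 3) else
          list()
      fit <- fit_model(snar_model(fam, seed = s, hyper = hy),
                       xy$X[tr, ], xy$y[tr])
      mean(abs(xy$y[te] - predict(fit, xy$X[te, ])$mean))
    }, numeric(1))
  })
  avg <- rowMeans(maes)
  expect_lt(avg["GPR"], avg["RF"])
  expect_lt(avg["SVR"], avg["RF"])
  expect_lt(avg["RF"], avg["LR"])
  # mean baseline is worst of all
  d <- synth_generate(synth_config(n_samples = 260, nonlinearity = 5,
                                   seed = 301))
  xy <- assemble_features(d$reactions, d$descriptors,
                          feature_set_spec("X_small"))
  fitm <- fit_model(snar_model("mean"), xy$X[1:180, ], xy$y[1:180])
  expect_gt(mean(abs(xy$y[181:260] - predict(fitm, xy$X[181:260, ])$mean)),
            max(avg))
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_model(snar_model("LR"), X, c(NA, rnorm(9))), "non-finite")
  expect_error(fit_model(snar_model("LR"), X[1, , drop = FALSE], 1),
               "at least 2")
})
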