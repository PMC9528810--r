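test_that("Matern-3/2 kernel has the defining properties", {
  X <- matrix(rnorm(40), 20, 2)
  K <- kernel_matern32(X, variance = 2.3, lengthscale = 0.9)
  expect_equal(diag(K), rep(2.3, 20))
  expect_equal(K, t(K))
  r <- seq(0, 5, by = 0.25)
  kr <- drop(kernel_matern32(matrix(r), matrix(0), lengthscale = 1.2,
                             variance = 1.7))
  expect_equal(kr[1], 1.7)
  expect_true(all(diff(kr) < 0))
  # closed form at a chosen distance
  u <- sqrt(3) * 2 / 1.2
  expect_equal(kr[r == 2], 1.7 * (1 + u) * exp(-u))
  ev <- eigen(K + diag(1e-6, 20), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("GPR posterior equals the dense linear-algebra oracle (n <= 50)", {
  for (case in 1:3) {
    set.seed(case)
    n <- c(5, 20, 50)[case]; d <- c(1, 3, 6)[case]
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n, sin(X[, 1]), 0.2)
    sf2 <- runif(1, 0.5, 3); ell <- runif(1, 0.5, 2); sn2 <- runif(1, 0.01, 0.3)
    fit <- fit_model(snar_model("GPR", standardize = FALSE,
                                hyper = list(sf2 = sf2, ell = ell, sn2 = sn2)),
                     X, y)
    Xq <- matrix(rnorm(7 * d), 7, d)
    p <- predict(fit, Xq)
    # oracle: direct solve of the GP equations on the scaled target
    ym <- mean(y); ys <- sd(y)
    K <- kernel_matern32(X, lengthscale = ell, variance = sf2)
    Ks <- kernel_matern32(Xq, X, lengthscale = ell, variance = sf2)
    Ki <- solve(K + diag(sn2 + 1e-10, n))
    mu <- ym + ys * drop(Ks %*% Ki %*% ((y - ym) / ys))
    sd_o <- ys * sqrt(sf2 - diag(Ks %*% Ki %*% t(Ks)) + sn2)
    expect_equal(p$mean, mu, tolerance = 1e-8)
    expect_equal(p$std, sd_o, tolerance = 1e-8)
  }
})

test_that("noise-free GP interpolates; far queries revert to the prior", {
  set.seed(7)
  X <- matrix(rnorm(10), 10, 1)
  y <- drop(sin(2 * X)) + 20
  fit <- fit_model(snar_model("GPR", standardize = FALSE,
                              hyper = list(sf2 = 1.5, ell = 1, sn2 = 1e-12,
                                           jitter = 1e-12)), X, y)
  p <- predict(fit, X)
  expect_equal(p$mean, y, tolerance = 1e-6)
  far <- predict(fit, matrix(1e4))
  expect_equal(far$mean, mean(y), tolerance = 1e-6)   # prior mean
  expect_equal(far$std, sd(y) * sqrt(1.5 + 1e-12), tolerance = 1e-6)
})

test_that("hyperparameter optimization recovers a sensible noise level", {
  set.seed(1)
  X <- matrix(runif(80, -2, 2), 80, 1)
  y <- sin(2 * X[, 1]) + rnorm(80, 0, 0.1)
  fit <- fit_model(snar_model("GPR", standardize = FALSE,
                              hyper = list(restarts = 2)), X, y)
  hp <- fit$fit$hyper
  expect_true(hp$sf2 > 0 && hp$ell > 0 && hp$sn2 > 0)
  # fitted noise sd on the original scale within a factor 2 of the truth
  expect_lt(abs(log(sqrt(hp$sn2) * fit$y_scale / 0.1)), log(2))
  expect_lt(mean(abs(predict(fit, X)$mean - sin(2 * X[, 1]))), 0.08)
})

test_that("fits are deterministic given seed and serialize exactly", {
  xy <- fixture_xy("X_small")
  idx <- 1:80
  cfg <- snar_model("GPR", seed = 9, hyper = list(restarts = 2))
  f1 <- fit_model(cfg, xy$X[idx, ], xy$y[idx])
  f2 <- fit_model(cfg, xy$X[idx, ], xy$y[idx])
  q <- xy$X[81:120, ]
  expect_identical(predict(f1, q), predict(f2, q))
  path <- tempfile(fileext = ".rds")
  save_model(f1, path)
  expect_identical(predict(load_model(path), q), predict(f1, q))
})
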