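test_that("metrics match hand values and a brute-force recomputation", {
  m <- suppressWarnings(metrics(c(0, 2), c(1, 1)))  # constant y_pred: no r2
  expect_equal(m$mae, 1); expect_equal(m$rmse, 1)
  m2 <- metrics(1:5, 1:5)
  expect_equal(c(m2$mae, m2$rmse), c(0, 0)); expect_equal(m2$r2, 1)
  set.seed(11)
  for (i in 1:5) {
    yt <- rnorm(10); yp <- rnorm(10)
    m3 <- metrics(yt, yp)
    e <- yt - yp
    expect_equal(m3$mae, sum(abs(e)) / 10, tolerance = 1e-12)
    expect_equal(m3$rmse, sqrt(sum(e^2) / 10), tolerance = 1e-12)
    expect_equal(m3$r2, cor(yt, yp)^2, tolerance = 1e-12)
    expect_true(m3$rmse >= m3$mae)
  }
  expect_warning(metrics(rep(1, 4), rnorm(4)), "zero variance")
})

test_that("k-fold partition is a seeded disjoint cover", {
  f <- kfold_indices(103, 10, seed = 2)
  expect_length(f, 10L)
  expect_setequal(unlist(f), 1:103)
  expect_identical(f, kfold_indices(103, 10, seed = 2))
  expect_error(kfold_indices(5, 6), "folds")
})

test_that("out-of-fold cells come from models that never saw the row", {
  set.seed(13)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(80, 0, 0.3)
  cfgs <- list(lr = list(model = snar_model("LR"), X = X))
  op <- snarml:::.oof_predictions(cfgs, y, folds = 5L, seed = 3L)
  expect_false(anyNA(op$oof))
  # oracle: refit on each fold complement and compare cell-by-cell
  for (f in seq_along(op$fold_idx)) {
    test <- op$fold_idx[[f]]
    fit <- fit_model(snar_model("LR"), X[-test, , drop = FALSE], y[-test])
    expect_equal(op$oof[test, 1],
                 predict(fit, X[test, , drop = FALSE])$mean,
                 tolerance = 1e-10)
  }
})

test_that("BBC core: single config has ~zero bias, dominance is respected", {
  set.seed(17)
  y <- rnorm(100)
  one <- matrix(y + rnorm(100, 0, 0.5), 100, 1)
  res <- bbc_from_predictions(one, y, n_boot = 500, seed = 1)
  expect_equal(res$winner, 1L)
  expect_lt(abs(res$selection_bias), 4 * res$se_corrected + 0.02)

  # a strictly dominating configuration is always selected
  dom <- cbind(good = y + rnorm(100, 0, 0.1))
  dom <- cbind(dom, bad = dom[, 1] + sign(y - dom[, 1]) * -2)
  err_good <- abs(dom[, 1] - y); err_bad <- abs(dom[, 2] - y)
  expect_true(all(err_good <= err_bad))
  res2 <- bbc_from_predictions(dom, y, n_boot = 200, seed = 2)
  expect_equal(res2$winner, 1L)
  # reproducibility
  expect_identical(unclass(res2)[c("corrected_mae", "selection_bias")],
                   unclass(bbc_from_predictions(dom, y, 200, 2))[
                     c("corrected_mae", "selection_bias")])
})

test_that("bbc_cv excludes failing configurations with a warning", {
  set.seed(19)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(60, 0, 0.2)
  Xbad <- X; Xbad[3, 1] <- NA   # fit_model refuses non-finite input
  cfgs <- list(ok = list(model = snar_model("LR"), X = X),
               broken = list(model = snar_model("LR"), X = Xbad))
  expect_warning(res <- bbc_cv(cfgs, y, folds = 5, n_boot = 100, seed = 1),
                 "excluded.*broken")
  expect_equal(nrow(res$pooled), 1L)
  expect_equal(res$pooled$config, "ok")
})

test_that("learning curves improve with data and validate sizes", {
  xy <- fixture_xy("X_small")
  cfg <- snar_model("GPR", seed = 1, hyper = list(restarts = 1))
  lc <- learning_curve(cfg, xy$X, xy$y, sizes = c(40, 200), repeats = 3,
                       seed = 5)
  expect_equal(lc$size, c(40, 200))
  expect_lt(lc$mae[2], lc$mae[1])
  expect_true(all(is.finite(lc$se)))
  expect_error(learning_curve(cfg, xy$X, xy$y, sizes = c(40, 10000)),
               "exceeds")
  expect_error(learning_curve(cfg, xy$X, xy$y, sizes = c(200, 40)),
               "increasing")
})

test_that("leave-one-group-out: singletons = LOO; exchangeable ~ random folds", {
  set.seed(23)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(60, 0.2)
  cfg <- snar_model("LR")
  # singleton groups: classic leave-one-out, verified directly
  lo <- leave_one_group_out(cfg, X, y, groups = seq_len(60))
  manual <- vapply(1:60, function(i) {
    f <- fit_model(cfg, X[-i, , drop = FALSE], y[-i])
    predict(f, X[i, , drop = FALSE])$mean
  }, numeric(1))
  expect_equal(lo$predictions$pred, manual, tolerance = 1e-10)
  expect_error(leave_one_group_out(cfg, X, y, rep("g", 60)), "2 groups")

  # exchangeable (random) groups behave like random folds
  groups <- sample(rep(1:6, 10))
  g <- leave_one_group_out(cfg, X, y, groups)
  f5 <- kfold_indices(60, 6, seed = 7)
  oof <- numeric(60)
  for (fd in f5) {
    fit <- fit_model(cfg, X[-fd, , drop = FALSE], y[-fd])
    oof[fd] <- predict(fit, X[fd, , drop = FALSE])$mean
  }
  mk <- metrics(y, oof)
  expect_lt(abs(g$metrics$mae - mk$mae), 2 * (g$metrics$se_mae + mk$se_mae))
})

test_that("grouped validation is harder than random folds under class shifts", {
  d <- fixture_dataset()
  xy <- fixture_xy("X_small")
  cfg <- snar_model("LR")
  gel <- leave_one_group_out(cfg, xy$X, xy$y,
                             d$reactions$electrophile_id)$metrics$mae
  f10 <- kfold_indices(nrow(xy$X), 10, seed = 1)
  oof <- numeric(nrow(xy$X))
  for (fd in f10) {
    fit <- fit_model(cfg, xy$X[-fd, ], xy$y[-fd])
    oof[fd] <- predict(fit, xy$X[fd, ])$mean
  }
  expect_gt(gel, metrics(xy$y, oof)$mae)
})
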