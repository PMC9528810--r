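test_that("DModX: zero in the latent plane, self-consistent, oracle match", {
  set.seed(41)
  Xtr <- matrix(rnorm(120), 20, 6)
  ytr <- Xtr[, 1] + 0.5 * Xtr[, 2] + rnorm(20, 0, 0.1)
  dm <- pls_dmodx(Xtr, ytr, Xtr, n_components = 2)
  model <- attr(dm, "model")

  # a query reconstructed from its own scores has zero residual
  Xs <- scale(Xtr, model$center, model$scale)
  E <- Xs
  Tm <- matrix(0, 20, 2)
  for (a in 1:2) {
    Tm[, a] <- E %*% model$W[, a]
    E <- E - tcrossprod(Tm[, a], model$P[, a])
  }
  recon <- (Xs - E)                       # lies exactly in the latent plane
  Xq <- sweep(sweep(recon, 2, model$scale, "*"), 2, model$center, "+")
  expect_equal(as.numeric(pls_dmodx(Xtr, ytr, Xq, 2)), rep(0, 20),
               tolerance = 1e-8)

  # self-consistency: training rows reproduce their own residual norms
  oracle <- sqrt(rowSums(E^2) / (6 - 2)) / model$s0
  expect_equal(as.numeric(dm), unname(oracle), tolerance = 1e-8)

  # exact invariance under a joint orthogonal rotation (centering-only
  # variant: per-column scaling is deliberately not rotation-equivariant)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  d1 <- pls_dmodx(Xtr, ytr, Xtr, 2, scale. = FALSE)
  d2 <- pls_dmodx(Xtr %*% Q, ytr, Xtr %*% Q, 2, scale. = FALSE)
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)

  expect_error(pls_dmodx(Xtr[, 1:2], ytr, Xtr[, 1:2], 5), "n_components")
})

test_that("accuracy curve: hand-enumerated prefixes and exact final point", {
  ac <- accuracy_curve(c(0.1, 0.2, 0.3), c(1, 2, 3))
  expect_equal(ac$mae, c(1, 1.5, 2))
  expect_equal(ac$fraction, c(1, 2, 3) / 3)

  flat <- accuracy_curve(runif(10), rep(0.7, 10))
  expect_true(all(abs(flat$mae - 0.7) < 1e-12))

  set.seed(43)
  err <- sort(abs(rnorm(50)))
  mono <- accuracy_curve(seq_along(err), err)
  expect_true(all(diff(mono$mae) >= 0))

  u <- runif(200); e <- abs(rnorm(200))
  expect_equal(accuracy_curve(u, e)$mae[200], mean(e))
})

test_that("interval coverage counts closed-interval membership", {
  y <- c(1, 2, 3)
  expect_equal(interval_coverage(cbind(lower = -1e6, upper = 1e6)[rep(1, 3), ],
                                 y), 1)
  expect_equal(interval_coverage(data.frame(lower = y + 1, upper = y + 1), y),
               0)
  # zero-width interval exactly at the value counts as covered (closed)
  expect_equal(interval_coverage(data.frame(lower = c(1, 1.5, 9),
                                            upper = c(1, 2, 9.5)), y), 2 / 3)
  expect_error(interval_coverage(data.frame(lower = 2, upper = 1), 1.5),
               "malformed")
})

test_that("domain gate applies the categorical rules with reasons", {
  train <- summarize_reactions(read_reactions(tiny_reactions()))
  ok <- domain_gate(tiny_reactions()[1, ], train)
  expect_true(ok$in_domain); expect_length(ok$reasons, 0L)

  carbanion <- data.frame(nucleophile_class = "C-anionic",
                          leaving_class = "F")
  g <- domain_gate(carbanion, train)
  expect_false(g$in_domain)
  expect_match(g$reasons, "unseen nucleophilic atom type", all = FALSE)

  odd_lg <- data.frame(nucleophile_class = "N-neutral", leaving_class = "I")
  g2 <- domain_gate(odd_lg, train)
  expect_false(g2$in_domain)
  expect_match(g2$reasons, "leaving", all = FALSE)

  other_rxn <- domain_gate(tiny_reactions()[1, ], train,
                           reaction_class = "SN2")
  expect_false(other_rxn$in_domain)
  expect_error(domain_gate(data.frame(nucleophile_class = NA,
                                      leaving_class = "F"), train),
               "nucleophile_class")
})

test_that("ad_report flags outliers beyond 2 kcal/mol", {
  pred <- structure(data.frame(mean = c(20, 25), std = c(0.5, 0.5)),
                    class = c("snar_pred", "data.frame"))
  rep <- ad_report(c("a", "b"), c(0.5, 3), pred, y_true = c(20.4, 28))
  expect_equal(rep$outlier, c(FALSE, TRUE))
  expect_equal(rep$covered, c(TRUE, FALSE))
})
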