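#' Configure a regression model
#'
#' One configuration object drives the whole model zoo compared for barrier
#' prediction: ordinary linear regression (`"LR"`), Bayesian linear
#' regression with automatic relevance determination (`"ARD"`), a random
#' forest (`"RF"`), RBF-kernel support-vector regression (`"SVR"`), Gaussian
#' process regression with a Matern-3/2 kernel (`"GPR"`), and the
#' mean-of-training baseline (`"mean"`). Only the GPR is Bayesian and
#' returns a predictive standard deviation.
#'
#' @param family Model family.
#' @param pf2 Expand features with all second-order squares and interactions
#'   (after standardization) before fitting; the classic companion of ARD.
#' @param standardize Z-score features with training statistics. Defaults to
#'   `TRUE` for all families except the random forest, which is
#'   scale-equivariant.
#' @param seed Integer seed controlling every stochastic element of the fit
#'   (forest bootstraps, optimizer restarts).
#' @param hyper Named list of family-specific hyperparameters. GPR:
#'   `ard` (per-dimension length-scales), `restarts` (default 5), `jitter`
#'   (default 1e-10), `opt_subsample` (optimize hyperparameters on a seeded
#'   subsample of this many rows, then condition on all rows), and
#'   optionally fixed `sf2`, `ell`, `sn2` to skip marginal-likelihood
#'   optimization. RF: `ntree` (100), `mtry`
#'   (`floor(d/3)`), `min_node` (5). SVR: `cost` (10), `epsilon` (0.1 on the
#'   scaled target), `gamma` (`1/d`), and optional `grid` (named list of
#'   candidate vectors tuned by inner 3-fold cross-validation on MAE).
#' @return Object of class `snar_model_config`.
#' @export
snar_model <- function(family = c("GPR", "LR", "ARD", "RF", "SVR", "mean"),
                       pf2 = FALSE, standardize = NULL, seed = 1L,
                       hyper = list()) {
  family <- match.arg(family)
  if (is.null(standardize)) standardize <- family != "RF"
  defaults <- switch(family,
    GPR = list(ard = FALSE, restarts = 5L, jitter = 1e-10,
               opt_subsample = NULL, sf2 = NULL, ell = NULL, sn2 = NULL),
    RF = list(ntree = 100L, mtry = NULL, min_node = 5L),
    SVR = list(cost = 10, epsilon = 0.1, gamma = NULL, grid = NULL),
    ARD = list(max_iter = 300L, tol = 1e-4),
    list())
  structure(list(family = family, pf2 = pf2, standardize = standardize,
                 seed = as.integer(seed),
                 hyper = modifyList(defaults, hyper)),
            class = "snar_model_config")
}

# ---- ARD linear regression (evidence approximation) ------------------------

.ard_fit <- function(X, y, max_iter = 300L, tol = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  alpha <- rep(1, d)
  beta <- 1 / max(var(y), 1e-8)
  m <- rep(0, d)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  for (it in seq_len(max_iter)) {
    keep <- alpha < 1e10
    Ak <- alpha[keep]
    Sk <- tryCatch(
      solve(diag(Ak, sum(keep)) + beta * XtX[keep, keep, drop = FALSE]),
      error = function(e) NULL)
    if (is.null(Sk)) break
    mk <- beta * Sk %*% Xty[keep, , drop = FALSE]
    gamma <- 1 - Ak * diag(Sk)
    new_alpha <- alpha
    new_alpha[keep] <- pmin(pmax(gamma / pmax(mk^2, 1e-12), 1e-8), 1e12)
    resid <- y - X[, keep, drop = FALSE] %*% mk
    beta <- max((n - sum(gamma)) / max(sum(resid^2), 1e-10), 1e-8)
    m_new <- rep(0, d); m_new[keep] <- mk
    if (max(abs(m_new - m)) < tol) { m <- m_new; alpha <- new_alpha; break }
    m <- m_new; alpha <- new_alpha
  }
  list(coef = m, alpha = alpha, beta = beta)
}

# ---- SVR: RBF kernel, squared epsilon-insensitive loss, quasi-Newton -------

.svr_objective <- function(par, K, y, cost, epsilon) {
  n <- length(y)
  a <- par[seq_len(n)]; b <- par[n + 1L]
  f <- drop(K %*% a) + b
  e <- y - f
  slack <- pmax(abs(e) - epsilon, 0)
  Ka <- drop(K %*% a)
  obj <- 0.5 * sum(a * Ka) + cost * sum(slack^2)
  gslack <- 2 * cost * slack * sign(e)
  grad_a <- Ka - drop(K %*% gslack)
  grad_b <- -sum(gslack)
  list(value = obj, grad = c(grad_a, grad_b))
}

.svr_fit_once <- function(X, y, cost, epsilon, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  K <- exp(-gamma * pmax(d2, 0))
  par0 <- c(rep(0, nrow(X)), mean(y))
  opt <- optim(par0,
               fn = function(p) .svr_objective(p, K, y, cost, epsilon)$value,
               gr = function(p) .svr_objective(p, K, y, cost, epsilon)$grad,
               method = "L-BFGS-B", control = list(maxit = 300))
  list(alpha = opt$par[seq_len(nrow(X))], b = opt$par[nrow(X) + 1L],
       gamma = gamma, cost = cost, epsilon = epsilon, Xtrain = X)
}

.svr_predict <- function(fit, X) {
  d2 <- outer(rowSums(X^2), rowSums(fit$Xtrain^2), "+") -
    2 * tcrossprod(X, fit$Xtrain)
  drop(exp(-fit$gamma * pmax(d2, 0)) %*% fit$alpha) + fit$b
}

.svr_fit <- function(X, y, hyper, seed) {
  gamma <- hyper$gamma %||% (1 / ncol(X))
  if (is.null(hyper$grid))
    return(.svr_fit_once(X, y, hyper$cost, hyper$epsilon, gamma))
  grid <- expand.grid(cost = hyper$grid$cost %||% hyper$cost,
                      epsilon = hyper$grid$epsilon %||% hyper$epsilon,
                      gamma = hyper$grid$gamma %||% gamma)
  folds <- kfold_indices(length(y), folds = 3L, seed = seed)
  cv_mae <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- unlist(lapply(seq_along(folds), function(f) {
      tr <- setdiff(seq_along(y), folds[[f]])
      fit <- .svr_fit_once(X[tr, , drop = FALSE], y[tr], grid$cost[g],
                           grid$epsilon[g], grid$gamma[g])
      abs(y[folds[[f]]] - .svr_predict(fit, X[folds[[f]], , drop = FALSE]))
    }))
    mean(errs)
  }, numeric(1))
  gbest <- which.min(cv_mae)
  .svr_fit_once(X, y, grid$cost[gbest], grid$epsilon[gbest], grid$gamma[gbest])
}

# ---- unified fit / predict -------------------------------------------------

#' Fit a configured model
#'
#' Applies the configuration's preprocessing (training-statistics z-scoring,
#' optional PF2 expansion, target centering/scaling for the kernel and
#' Bayesian families) and fits the requested family. Fits are deterministic
#' given `config$seed` and serializable with [save_model()].
#'
#' @param config A [snar_model()] configuration.
#' @param X Numeric feature matrix (columns named; the names become the
#'   prediction manifest).
#' @param y Numeric target (kcal/mol).
#' @return Object of class `snar_fit`.
#' @export
fit_model <- function(config, X, y) {
  stopifnot(inherits(config, "snar_model_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  manifest <- colnames(X)
  if (config$standardize) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd); x_scale[x_scale < 1e-12] <- 1
    Xs <- scale(X, center = x_center, scale = x_scale)
  } else {
    x_center <- rep(0, ncol(X)); x_scale <- rep(1, ncol(X))
    Xs <- X
  }
  if (config$pf2) Xs <- pf2_expand(Xs)
  scale_y <- config$family %in% c("GPR", "SVR", "ARD")
  y_center <- if (scale_y || config$family == "LR") mean(y) else 0
  y_scale <- if (scale_y) max(sd(y), 1e-8) else 1
  ys <- (y - y_center) / y_scale
  h <- config$hyper
  fit <- switch(config$family,
    mean = list(value = mean(y)),
    LR = {
      qrX <- qr(cbind(1, Xs))
      if (qrX$rank < ncol(Xs) + 1L)
        warning("rank-deficient design in LR; minimum-norm solution used")
      cf <- qr.coef(qrX, ys); cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    ARD = .ard_fit(Xs, ys, max_iter = h$max_iter, tol = h$tol),
    RF = .rf_fit(Xs, y, ntree = h$ntree, mtry = h$mtry,
                 min_node = h$min_node, seed = config$seed),
    SVR = with_seed(config$seed, .svr_fit(Xs, ys, h, config$seed)),
    GPR = {
      hp <- if (!is.null(h$sf2) && !is.null(h$ell) && !is.null(h$sn2)) {
        list(sf2 = h$sf2, ell = h$ell, sn2 = h$sn2)
      } else {
        # optional seeded subsample for the O(n^3) marginal-likelihood
        # optimization; the posterior always conditions on all rows
        rows <- if (!is.null(h$opt_subsample) &&
                    h$opt_subsample < nrow(Xs))
          with_seed(config$seed, sample.int(nrow(Xs), h$opt_subsample))
        else seq_len(nrow(Xs))
        .gpr_optimize(Xs[rows, , drop = FALSE], ys[rows], ard = h$ard,
                      restarts = h$restarts, seed = config$seed,
                      jitter = h$jitter)
      }
      post <- .gpr_posterior(Xs, ys, hp$sf2, hp$ell, hp$sn2,
                             jitter = h$jitter)
      c(post, list(hyper = hp))
    })
  structure(list(config = config, manifest = manifest,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale, fit = fit),
            class = c(paste0("snar_", tolower(config$family)), "snar_fit"))
}

.prep_newdata <- function(object, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && length(colnames(X))) {
    missing_cols <- setdiff(object$manifest, colnames(X))
    extra <- setdiff(colnames(X), object$manifest)
    if (length(missing_cols) || length(extra))
      stop("feature manifest mismatch; missing: [",
           paste(missing_cols, collapse = ", "), "] extra: [",
           paste(extra, collapse = ", "), "]")
    X <- X[, object$manifest, drop = FALSE]
  } else if (ncol(X) != length(object$manifest)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$manifest))
  }
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  if (object$config$pf2) Xs <- pf2_expand(Xs)
  Xs
}

#' Predict with a fitted model
#'
#' Returns the predictive mean and, for the Gaussian process family, the
#' predictive standard deviation (including the fitted noise variance);
#' non-Bayesian families return `NA` std.
#'
#' @param object A `snar_fit`.
#' @param newdata Feature matrix matching the training manifest.
#' @param ... Unused.
#' @return data.frame of class `snar_pred` with columns `mean` and `std`
#'   (kcal/mol).
#' @export
predict.snar_fit <- function(object, newdata, ...) {
  Xs <- .prep_newdata(object, newdata)
  fam <- object$config$family
  std <- rep(NA_real_, nrow(Xs))
  mu_s <- switch(fam,
    mean = rep(0, nrow(Xs)),   # y_center carries the value below for 'mean'
    LR = drop(cbind(1, Xs) %*% object$fit$coef),
    ARD = drop(Xs %*% object$fit$coef),
    RF = .rf_predict(object$fit, Xs),
    SVR = .svr_predict(object$fit, Xs),
    GPR = {
      p <- .gpr_predict(object$fit, Xs)
      std <- p$sd * object$y_scale
      p$mean
    })
  mu <- if (fam == "mean") rep(object$fit$value, nrow(Xs)) else
    object$y_center + object$y_scale * mu_s
  out <- data.frame(mean = mu, std = std)
  class(out) <- c("snar_pred", "data.frame")
  out
}

#' Two-sided Gaussian prediction interval
#'
#' `mean +/- z_(1+level)/2 * std`. The default 95 % level is a convention
#' knob: empirically the GP intervals on kinetic data are conservative
#' (higher observed coverage than nominal).
#'
#' @param pred A `snar_pred` (from [predict.snar_fit()]) or any data.frame
#'   with `mean` and `std` columns.
#' @param level Coverage level in (0, 1).
#' @return data.frame with `lower`, `mean`, `upper`.
#' @export
prediction_interval <- function(pred, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (all(is.na(pred$std)))
    stop("no predictive std available: use a Bayesian family such as GPR")
  z <- qnorm((1 + level) / 2)
  data.frame(lower = pred$mean - z * pred$std, mean = pred$mean,
             upper = pred$mean + z * pred$std)
}

# ---- DFT baselines ---------------------------------------------------------

#' Fit a DFT-barrier baseline
#'
#' The raw baseline predicts the experimental barrier by the DFT barrier
#' itself (intercept 0, slope 1); the linearly corrected baseline regresses
#' the experimental barrier on the DFT barrier by ordinary least squares,
#' compensating the systematic component of the DFT error.
#'
#' @param dG_dft,dG_exp Paired barriers in kcal/mol.
#' @param mode `"raw"` or `"linear_corrected"`.
#' @return Object of class `snar_dft` with intercept `a` and slope `b`.
#' @export
fit_dft_baseline <- function(dG_dft, dG_exp,
                             mode = c("raw", "linear_corrected")) {
  mode <- match.arg(mode)
  if (length(dG_dft) != length(dG_exp) || any(!is.finite(dG_dft)) ||
      any(!is.finite(dG_exp)))
    stop("dG_dft and dG_exp must be paired finite vectors")
  if (mode == "raw") {
    ab <- c(a = 0, b = 1)
  } else {
    if (length(dG_dft) < 2L) stop("linear mode needs n >= 2")
    if (sd(dG_dft) < 1e-12) stop("constant dG_dft: slope undefined")
    cf <- coef(lm(dG_exp ~ dG_dft))
    ab <- c(a = unname(cf[1]), b = unname(cf[2]))
  }
  structure(list(mode = mode, a = ab[["a"]], b = ab[["b"]]),
            class = "snar_dft")
}

#' @export
predict.snar_dft <- function(object, dG_dft, ...) {
  object$a + object$b * dG_dft
}

# ---- serialization ---------------------------------------------------------

#' Save / load a fitted model bundle
#'
#' The bundle carries the fit, its feature manifest, standardization
#' statistics, configuration and seed, plus the package version; reloading
#' reproduces predictions exactly.
#'
#' @param fit A `snar_fit`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` the fit.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "snar_fit"))
  bundle <- list(format = 1L,
                 package_version = as.character(utils::packageVersion("snarml")),
                 fit = fit)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (!is.list(bundle) || !inherits(bundle$fit, "snar_fit"))
    stop("not a snarml model bundle: ", path)
  bundle$fit
}
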