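#' Regression metrics with standard errors
#'
#' MAE = mean |e|, RMSE = sqrt(mean e^2), and the squared Pearson
#' correlation between observed and predicted as the headline `r2`
#' (the coefficient of determination is reported alongside as `r2_cod`).
#' Standard errors: `se_mae` is the standard error of the mean absolute
#' residual; `se_rmse` by the delta method.
#'
#' @param y_true,y_pred Equal-length finite vectors.
#' @return List of class `snar_metrics`: `n`, `mae`, `rmse`, `r2`,
#'   `r2_cod`, `se_mae`, `se_rmse`. `r2` is `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred)))
    stop("metrics requires finite vectors")
  n <- length(y_true)
  e <- y_true - y_pred
  mae <- mean(abs(e)); rmse <- sqrt(mean(e^2))
  r2 <- NA_real_; r2_cod <- NA_real_
  if (n >= 2L) {
    if (sd(y_true) < 1e-12 || sd(y_pred) < 1e-12) {
      warning("zero variance: r2 undefined")
    } else {
      r2 <- cor(y_true, y_pred)^2
    }
    r2_cod <- 1 - sum(e^2) / sum((y_true - mean(y_true))^2)
  }
  structure(list(n = n, mae = mae, rmse = rmse, r2 = r2, r2_cod = r2_cod,
                 se_mae = if (n >= 2L) sd(abs(e)) / sqrt(n) else NA_real_,
                 se_rmse = if (n >= 2L && rmse > 0)
                   sd(e^2) / (2 * rmse * sqrt(n)) else NA_real_),
            class = "snar_metrics")
}

#' @export
print.snar_metrics <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.3f (SE %.3f)  RMSE = %.3f  R2 = %.3f\n",
              x$n, x$mae, x$se_mae %||% NA, x$rmse, x$r2))
  invisible(x)
}

#' Seeded k-fold partition
#'
#' A seeded permutation of the sample indices cut into `folds` near-equal
#' parts (no stratification).
#'
#' @param n Number of samples.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of integer index vectors, one per fold.
#' @export
kfold_indices <- function(n, folds = 10L, seed = 1L) {
  if (folds < 2L || folds > n) stop("need 2 <= folds <= n")
  perm <- with_seed(seed, sample.int(n))
  split(perm, cut(seq_len(n), folds, labels = FALSE))
}

# fit/predict one configuration on one fold; configs are
# list(model = snar_model_config, X = matrix)
.oof_predictions <- function(configs, y, folds, seed) {
  n <- length(y)
  fold_idx <- kfold_indices(n, folds, seed)
  m <- length(configs)
  oof <- matrix(NA_real_, n, m,
                dimnames = list(NULL, names(configs) %||%
                                  paste0("cfg", seq_len(m))))
  failed <- character()
  for (j in seq_len(m)) {
    cfg <- configs[[j]]
    ok <- TRUE
    for (f in seq_along(fold_idx)) {
      test <- fold_idx[[f]]; train <- setdiff(seq_len(n), test)
      pred <- tryCatch({
        fit <- fit_model(cfg$model, cfg$X[train, , drop = FALSE], y[train])
        predict(fit, cfg$X[test, , drop = FALSE])$mean
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        failed <- c(failed, sprintf("%s (fold %d): %s",
                                    colnames(oof)[j], f, conditionMessage(pred)))
        ok <- FALSE
        break
      }
      oof[test, j] <- pred
    }
    if (!ok) oof[, j] <- NA_real_
  }
  if (length(failed))
    warning("configurations excluded from BBC-CV: ",
            paste(failed, collapse = "; "))
  list(oof = oof, fold_idx = fold_idx,
       kept = which(colSums(is.na(oof)) == 0L))
}

#' Bootstrap bias correction of an out-of-fold prediction matrix
#'
#' Core of BBC-CV: given the pooled out-of-fold prediction matrix (one
#' column per candidate configuration, built with a single shared fold
#' partition), each bootstrap resample of the sample indices selects the
#' configuration with the smallest MAE on the resample and scores it on the
#' out-of-bag indices. The mean out-of-bag score is an estimate of the
#' post-selection generalization error that removes the winner's-curse
#' optimism of simply reporting the best pooled score.
#'
#' @param oof n x m matrix of out-of-fold predictions.
#' @param y Observed targets (length n).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List of class `snar_bbc`: `winner` (column index of the smallest
#'   pooled MAE), `pooled` (per-configuration pooled metrics),
#'   `corrected_mae`, `se_corrected` (bootstrap SE of the corrected mean),
#'   `selection_bias` (= corrected - winner's pooled MAE), `n_boot`, `seed`.
#' @export
bbc_from_predictions <- function(oof, y, n_boot = 1000L, seed = 1L) {
  oof <- as.matrix(oof)
  n <- length(y); m <- ncol(oof)
  if (nrow(oof) != n) stop("nrow(oof) != length(y)")
  if (m < 1L) stop("need at least one configuration")
  abs_err <- abs(oof - y)
  pooled_mae <- colMeans(abs_err)
  winner <- unname(which.min(pooled_mae))
  scores <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sel <- which.min(colMeans(abs_err[idx, , drop = FALSE]))
      oob <- setdiff(seq_len(n), unique(idx))
      if (!length(oob)) return(NA_real_)
      mean(abs_err[oob, sel])
    }, numeric(1))
  })
  scores <- scores[!is.na(scores)]
  corrected <- mean(scores)
  structure(list(
    winner = winner,
    pooled = data.frame(config = colnames(oof) %||% seq_len(m),
                        mae = pooled_mae,
                        rmse = sqrt(colMeans((oof - y)^2)),
                        r2 = apply(oof, 2, function(p)
                          if (sd(p) < 1e-12) NA_real_ else cor(y, p)^2)),
    corrected_mae = corrected,
    se_corrected = sd(scores) / sqrt(length(scores)),
    selection_bias = corrected - pooled_mae[winner],
    n_boot = n_boot, seed = as.integer(seed)),
    class = "snar_bbc")
}

#' Bootstrap bias-corrected cross-validation (BBC-CV)
#'
#' Joint model selection and honest performance estimation: builds the
#' out-of-fold prediction matrix for every candidate (model configuration,
#' feature matrix) pair over one shared 10-fold partition, then applies
#' [bbc_from_predictions()]. Configurations that fail on any fold are
#' excluded with a warning, never silently scored.
#'
#' @param configs Named list; each element a list with `model` (a
#'   [snar_model()] config) and `X` (its feature matrix).
#' @param y Target vector shared by all configurations.
#' @param folds Number of folds (default 10).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed (fold partition and bootstrap).
#' @return A `snar_bbc` (see [bbc_from_predictions()]) with the additional
#'   fields `oof` (the prediction matrix) and `folds`.
#' @export
bbc_cv <- function(configs, y, folds = 10L, n_boot = 1000L, seed = 1L) {
  stopifnot(length(configs) >= 1L)
  op <- .oof_predictions(configs, y, folds, seed)
  if (!length(op$kept)) stop("every configuration failed cross-validation")
  res <- bbc_from_predictions(op$oof[, op$kept, drop = FALSE], y,
                              n_boot = n_boot, seed = seed)
  res$oof <- op$oof
  res$folds <- folds
  res
}

#' @export
print.snar_bbc <- function(x, ...) {
  cat(sprintf(
    "BBC-CV over %d configuration(s): winner '%s'\n",
    nrow(x$pooled), x$pooled$config[x$winner]))
  cat(sprintf("  pooled MAE %.3f, corrected %.3f (bias %+.3f, SE %.3f)\n",
              x$pooled$mae[x$winner], x$corrected_mae, x$selection_bias,
              x$se_corrected))
  invisible(x)
}

#' Learning curve by repeated random subsampling
#'
#' Holds out a fixed seeded evaluation set, then for each training size
#' draws `repeats` random subsamples of the remaining pool, fits, and
#' records the evaluation MAE.
#'
#' @param config A [snar_model()] configuration.
#' @param X,y Full feature matrix and target.
#' @param sizes Strictly increasing training sizes; must fit in the pool.
#' @param repeats Subsample repeats per size (>= 2 for a standard error).
#' @param seed Integer seed.
#' @param eval_fraction Held-out evaluation fraction (default 0.2).
#' @return data.frame: `size`, `mae` (mean over repeats), `se`.
#' @export
learning_curve <- function(config, X, y, sizes, repeats = 5L, seed = 1L,
                           eval_fraction = 0.2) {
  n <- length(y)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be increasing")
  eval_idx <- with_seed(seed, sample.int(n, max(2L, floor(eval_fraction * n))))
  pool <- setdiff(seq_len(n), eval_idx)
  if (max(sizes) > length(pool))
    stop("max size ", max(sizes), " exceeds training pool ", length(pool))
  rows <- lapply(seq_along(sizes), function(si) {
    maes <- vapply(seq_len(repeats), function(r) {
      tr <- with_seed(seed + 1000L * si + r,
                      sample(pool, sizes[si]))
      fit <- fit_model(config, X[tr, , drop = FALSE], y[tr])
      mean(abs(y[eval_idx] -
                 predict(fit, X[eval_idx, , drop = FALSE])$mean))
    }, numeric(1))
    data.frame(size = sizes[si], mae = mean(maes),
               se = if (repeats >= 2L) sd(maes) / sqrt(repeats) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Leave-one-group-out validation
#'
#' Each group (e.g. electrophile or nucleophile identity) is predicted by a
#' model trained on all other groups; metrics are pooled over all held-out
#' predictions. With singleton groups this is classic leave-one-out.
#'
#' @param config A [snar_model()] configuration.
#' @param X,y Feature matrix and target.
#' @param groups Group label per row (>= 2 distinct groups).
#' @return List: `metrics` (pooled [metrics()]) and `predictions`
#'   (data.frame with `group`, `y`, `pred`).
#' @export
leave_one_group_out <- function(config, X, y, groups) {
  if (length(groups) != length(y)) stop("groups must match y")
  if (any(is.na(groups))) stop("grouping key missing for some rows")
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups")
  pred <- numeric(length(y))
  for (g in gs) {
    test <- which(groups == g); train <- which(groups != g)
    fit <- fit_model(config, X[train, , drop = FALSE], y[train])
    pred[test] <- predict(fit, X[test, , drop = FALSE])$mean
  }
  list(metrics = metrics(y, pred),
       predictions = data.frame(group = groups, y = y, pred = pred))
}
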