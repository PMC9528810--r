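#' Cluster features by Spearman rank correlation
#'
#' Hierarchical average-linkage clustering on the distance 1 - |rho| between
#' feature columns, cut at `threshold`; features whose |Spearman rho|
#' exceeds `1 - threshold` end up merged. Because Spearman correlation
#' depends only on ranks, the partition is invariant to monotone
#' transformations of any column. One representative is kept per cluster:
#' the member with the highest mean |rho| to its fellow members.
#'
#' @param X Numeric feature matrix (>= 2 columns). Constant columns are
#'   excluded with a warning.
#' @param threshold Cut height on 1 - |rho| (default 0.3, i.e. merge at
#'   |rho| >= 0.7).
#' @return List of class `snar_clustering`: `clusters` (named integer
#'   vector), `representatives` (one column name per cluster), `linkage`
#'   (the hclust object), `excluded`.
#' @export
spearman_cluster <- function(X, threshold = 0.3) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 features")
  const <- apply(X, 2, function(c) sd(c) < 1e-12)
  if (all(const)) stop("all columns constant")
  if (any(const))
    warning("constant columns excluded: ",
            paste(colnames(X)[const], collapse = ", "))
  Xv <- X[, !const, drop = FALSE]
  rho <- cor(Xv, method = "spearman")
  D <- as.dist(1 - abs(rho))
  hc <- hclust(D, method = "average")
  cl <- cutree(hc, h = threshold)
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    if (length(members) == 1L) return(members)
    sub <- abs(rho[members, members])
    members[which.max((rowSums(sub) - 1) / (length(members) - 1))]
  }, character(1))
  structure(list(clusters = cl, representatives = reps, linkage = hc,
                 excluded = colnames(X)[const], threshold = threshold),
            class = "snar_clustering")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination of regressing feature j on all other features. Exact
#' collinearity yields `Inf`, reported without error.
#'
#' @param X Numeric matrix with more rows than columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X))
    stop("vif needs n > d (have n = ", nrow(X), ", d = ", ncol(X), ")")
  vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    if (sd(yj) < 1e-12) return(NA_real_)
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

#' Permutation feature importance (MAE degradation)
#'
#' `importance_j` is the mean increase in MAE over `n_repeats` independent
#' permutations of column j, relative to the unpermuted baseline, for an
#' already fitted model. Works for any family behind the common predict
#' contract.
#'
#' @param fit A fitted `snar_fit`.
#' @param X,y Evaluation data; column names must match the fit's manifest.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed (bit-reproducible).
#' @return data.frame: `feature`, `importance` (kcal/mol MAE degradation),
#'   `sd` across repeats.
#' @export
permutation_importance <- function(fit, X, y, n_repeats = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!setequal(colnames(X), fit$manifest))
    stop("X columns do not match the model manifest")
  X <- X[, fit$manifest, drop = FALSE]
  baseline <- mean(abs(y - predict(fit, X)$mean))
  imp <- with_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      deltas <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        mean(abs(y - predict(fit, Xp)$mean)) - baseline
      }, numeric(1))
      c(mean(deltas), sd(deltas))
    }, numeric(2))
  })
  data.frame(feature = colnames(X), importance = imp[1, ], sd = imp[2, ],
             row.names = NULL)
}

#' Bootstrapped permutation-importance ranking
#'
#' Stability analysis of the feature ranking: the model is refitted on each
#' of `n_bootstrap` resamples of the rows, permutation importances are
#' computed on that resample, and the per-resample ranks (1 = most
#' important) are collected. Intended to be run after clustering
#' ([spearman_cluster()]) so each feature represents one correlation
#' cluster. Resamples that drop a feature's variance to zero are skipped
#' with a message.
#'
#' @param config A [snar_model()] configuration.
#' @param X,y Data (typically the cluster representatives).
#' @param n_bootstrap Number of bootstrap resamples (default 10).
#' @param n_repeats Permutation repeats within each resample.
#' @param seed Integer seed.
#' @return List of class `snar_ranking`: `ranks` (features x resamples
#'   matrix), `mean_importance`, `n_bootstrap`, `seed`.
#' @export
bootstrapped_ranking <- function(config, X, y, n_bootstrap = 10L,
                                 n_repeats = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  d <- ncol(X)
  ranks <- matrix(NA_integer_, d, n_bootstrap,
                  dimnames = list(colnames(X), NULL))
  imps <- matrix(NA_real_, d, n_bootstrap)
  boots <- with_seed(seed, lapply(seq_len(n_bootstrap), function(b)
    sample.int(nrow(X), nrow(X), replace = TRUE)))
  for (b in seq_len(n_bootstrap)) {
    idx <- boots[[b]]
    Xb <- X[idx, , drop = FALSE]
    if (any(apply(Xb, 2, sd) < 1e-12)) {
      message("bootstrap resample ", b, " skipped: constant feature")
      next
    }
    fit <- fit_model(config, Xb, y[idx])
    pi_b <- permutation_importance(fit, Xb, y[idx], n_repeats = n_repeats,
                                   seed = seed + b)
    imps[, b] <- pi_b$importance
    ranks[, b] <- rank(-pi_b$importance, ties.method = "first")
  }
  structure(list(ranks = ranks,
                 mean_importance = rowMeans(imps, na.rm = TRUE),
                 n_bootstrap = n_bootstrap, seed = as.integer(seed)),
            class = "snar_ranking")
}
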