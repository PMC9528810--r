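# NIPALS PLS1 on standardized X and centered y; returns weights/loadings
# and the training residual matrix.
.pls_nipals <- function(Xs, yc, ncomp) {
  n <- nrow(Xs); d <- ncol(Xs)
  W <- matrix(0, d, ncomp); P <- matrix(0, d, ncomp); Tm <- matrix(0, n, ncomp)
  E <- Xs; f <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate X: cannot extract component ", a)
    w <- w / nw
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - q * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t
  }
  list(W = W, P = P, scores = Tm, residuals = E)
}

# deflate a query row through the fitted components; returns residual matrix
.pls_residual <- function(model, Xs) {
  E <- Xs
  for (a in seq_len(ncol(model$W))) {
    t <- drop(E %*% model$W[, a])
    E <- E - tcrossprod(t, model$P[, a])
  }
  E
}

#' Distance to Model in X-space (DModX) from a two-component PLS model
#'
#' Fits a PLS model (NIPALS) with `n_components` latent variables on the
#' standardized training descriptors and computes, for each query row, the
#' root-mean-square residual after deflation through the fitted components,
#' normalized by the pooled training residual standard deviation
#' (degrees-of-freedom corrected: training residual sum of squares divided
#' by (n - A - 1)(d - A)). A query lying in the training latent plane has
#' DModX 0; values well above 1 flag extrapolation in descriptor space.
#'
#' @param X_train Training descriptor matrix.
#' @param y_train Training response (PLS is supervised; see Details).
#' @param X_query Query rows (same columns).
#' @param n_components Latent dimensions (default 2).
#' @param scale. Standardize columns by training standard deviations
#'   (default). With `scale. = FALSE` (centering only) DModX is exactly
#'   invariant to joint orthogonal rotation of training and query rows.
#' @return Numeric DModX per query row, with the fitted model attached as
#'   attribute `"model"` (components, training s0, scaling).
#' @details The chemometric DModX convention leaves the normalization
#'   constant open; plain normalized RMS with the dof correction above is
#'   used here. `y_train` may be `NULL`, in which case principal components
#'   (unsupervised) replace the PLS latent space.
#' @export
pls_dmodx <- function(X_train, y_train, X_query, n_components = 2L,
                      scale. = TRUE) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  n <- nrow(X_train); d <- ncol(X_train)
  if (n_components >= min(n, d))
    stop("n_components must be < min(n, d)")
  ctr <- colMeans(X_train)
  scl <- if (scale.) apply(X_train, 2, sd) else rep(1, d)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X_train, ctr, scl)
  if (qr(Xs)$rank < n_components)
    stop("degenerate X: rank below n_components")
  model <- if (is.null(y_train)) {
    sv <- svd(Xs, nu = 0, nv = n_components)
    list(W = sv$v, P = sv$v,
         residuals = Xs - (Xs %*% sv$v) %*% t(sv$v))
  } else {
    .pls_nipals(Xs, y_train - mean(y_train), n_components)
  }
  s0 <- sqrt(sum(model$residuals^2) /
               ((n - n_components - 1) * (d - n_components)))
  Eq <- .pls_residual(model, scale(X_query, ctr, scl))
  dmodx <- sqrt(rowSums(Eq^2) / (d - n_components)) / s0
  attr(dmodx, "model") <- list(W = model$W, P = model$P, s0 = s0,
                               center = ctr, scale = scl,
                               n_components = n_components)
  dmodx
}

#' Integral accuracy averaging curve
#'
#' Orders predictions from most to least certain by an uncertainty measure
#' (GP predictive std, DModX, ...) and reports the MAE of each prefix. A
#' useful uncertainty measure yields a curve rising from left to right; the
#' final point equals the overall MAE exactly. Ties keep their original
#' order (stable sort).
#'
#' @param uncertainties Uncertainty value per prediction (ascending = more
#'   certain).
#' @param abs_errors Absolute prediction errors, same length.
#' @return data.frame of class `snar_accuracy_curve`: `fraction` (k/n) and
#'   `mae` (prefix mean).
#' @export
accuracy_curve <- function(uncertainties, abs_errors) {
  if (length(uncertainties) != length(abs_errors))
    stop("uncertainties and abs_errors must have equal length")
  n <- length(abs_errors)
  if (n < 1L) stop("empty input")
  o <- order(uncertainties)        # radix order is stable in ties
  e <- abs_errors[o]
  out <- data.frame(fraction = seq_len(n) / n, mae = cumsum(e) / seq_len(n))
  class(out) <- c("snar_accuracy_curve", "data.frame")
  out
}

#' Empirical coverage of prediction intervals
#'
#' Fraction of observations falling inside their closed intervals (ties at
#' a bound count as covered).
#'
#' @param intervals Two-column matrix or data.frame (`lower`, `upper`), or
#'   the output of [prediction_interval()].
#' @param y_true Observed values.
#' @return Coverage fraction in `[0, 1]`.
#' @export
interval_coverage <- function(intervals, y_true) {
  nm <- colnames(intervals)
  lo <- if ("lower" %in% nm) intervals[, "lower"] else intervals[, 1]
  hi <- if ("upper" %in% nm) intervals[, "upper"] else
    intervals[, ncol(intervals)]
  lo <- as.numeric(unlist(lo)); hi <- as.numeric(unlist(hi))
  if (length(lo) != length(y_true)) stop("interval/observation length mismatch")
  if (any(lo > hi)) stop("malformed intervals: lower > upper")
  mean(y_true >= lo & y_true <= hi)
}

#' Rule-based applicability-domain gate
#'
#' Hard rules preceding any graded uncertainty measure: the model applies
#' only to nucleophilic aromatic substitution, and only to (nucleophilic
#' atom class, leaving atom class) combinations represented in the training
#' set. Every violated rule is reported.
#'
#' @param record One-row reaction data.frame (needs `nucleophile_class` and
#'   `leaving_class`).
#' @param training_summary A [summarize_reactions()] result for the
#'   training set.
#' @param reaction_class Reaction class of the query (default `"SNAr"`).
#' @return List: `in_domain` (logical), `reasons` (character, empty when in
#'   domain).
#' @export
domain_gate <- function(record, training_summary, reaction_class = "SNAr") {
  if (is.null(record$nucleophile_class) || is.null(record$leaving_class) ||
      is.na(record$nucleophile_class[1]) || is.na(record$leaving_class[1]))
    stop("record must carry nucleophile_class and leaving_class")
  reasons <- character()
  if (!identical(reaction_class, "SNAr"))
    reasons <- c(reasons,
                 sprintf("reaction class '%s' is not SNAr", reaction_class))
  nuc <- as.character(record$nucleophile_class[1])
  lea <- as.character(record$leaving_class[1])
  if (!nuc %in% names(training_summary$class_counts$nucleophile))
    reasons <- c(reasons,
                 sprintf("unseen nucleophilic atom type '%s'", nuc))
  if (!lea %in% names(training_summary$class_counts$leaving))
    reasons <- c(reasons, sprintf("unseen leaving atom type '%s'", lea))
  combo <- paste(nuc, lea, sep = "/")
  if (!combo %in% names(training_summary$class_counts$combination) &&
      !length(reasons))
    reasons <- c(reasons,
                 sprintf("unseen nucleophile/leaving combination '%s'", combo))
  list(in_domain = !length(reasons), reasons = reasons)
}

#' Per-row applicability-domain report
#'
#' Convenience assembly of the applicability diagnostics for a test set:
#' DModX, GP predictive std, interval coverage flag and absolute error,
#' plus an outlier flag at the conventional |residual| > 2 kcal/mol.
#'
#' @param rxn_ids Identifiers.
#' @param dmodx From [pls_dmodx()].
#' @param pred A `snar_pred` with `mean` and `std`.
#' @param y_true Observed barriers.
#' @param level Interval level (default 0.95).
#' @return data.frame: `rxn_id`, `dmodx`, `gpr_std`, `covered`,
#'   `abs_error`, `outlier`.
#' @export
ad_report <- function(rxn_ids, dmodx, pred, y_true, level = 0.95) {
  pi <- prediction_interval(pred, level)
  data.frame(rxn_id = rxn_ids, dmodx = as.numeric(dmodx),
             gpr_std = pred$std,
             covered = y_true >= pi$lower & y_true <= pi$upper,
             abs_error = abs(y_true - pred$mean),
             outlier = abs(y_true - pred$mean) > 2)
}
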