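# Regression random forest (CART, variance-reduction splits, bootstrap
# resampling, feature subsampling). Compact pure-R implementation; the
# datasets in scope are a few hundred rows by a few dozen columns.

.rf_best_split <- function(X, y, idx, mtry, min_node) {
  n <- length(idx)
  feats <- sample.int(ncol(X), mtry)
  best <- list(gain = 0)
  sy <- sum(y[idx]); base <- sy^2 / n
  for (j in feats) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]; ys <- y[idx][o]
    cs <- cumsum(ys)
    k <- seq_len(n - 1L)
    valid <- xs[k] != xs[k + 1L] & k >= min_node & (n - k) >= min_node
    if (!any(valid)) next
    score <- cs[k]^2 / k + (sy - cs[k])^2 / (n - k)
    score[!valid] <- -Inf
    kb <- which.max(score)
    gain <- score[kb] - base
    if (gain > best$gain) {
      best <- list(gain = gain, var = j,
                   split = (xs[kb] + xs[kb + 1L]) / 2,
                   left = idx[o[seq_len(kb)]], right = idx[o[-seq_len(kb)]])
    }
  }
  best
}

.rf_grow_tree <- function(X, y, mtry, min_node) {
  boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
  nodes <- list()
  build <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()   # reserve slot before recursing
    if (length(idx) < 2L * min_node || var(y[idx]) < 1e-12) {
      nodes[[id]] <<- list(leaf = TRUE, value = mean(y[idx]))
      return(id)
    }
    sp <- .rf_best_split(X, y, idx, mtry, min_node)
    if (is.null(sp$var) || sp$gain <= 1e-12) {
      nodes[[id]] <<- list(leaf = TRUE, value = mean(y[idx]))
      return(id)
    }
    this <- id
    l <- build(sp$left); r <- build(sp$right)
    nodes[[this]] <<- list(leaf = FALSE, var = sp$var, split = sp$split,
                           left = l, right = r)
    this
  }
  build(boot)
  nodes
}

.rf_fit <- function(X, y, ntree = 100L, mtry = NULL, min_node = 5L,
                    seed = 1L) {
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  trees <- with_seed(seed, lapply(seq_len(ntree), function(t)
    .rf_grow_tree(X, y, mtry, min_node)))
  list(trees = trees, ntree = ntree, mtry = mtry, min_node = min_node)
}

.rf_predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  recur <- function(id, idx) {
    nd <- nodes[[id]]
    if (isTRUE(nd$leaf)) { out[idx] <<- nd$value; return(invisible()) }
    go_left <- X[idx, nd$var] <= nd$split
    if (any(go_left)) recur(nd$left, idx[go_left])
    if (any(!go_left)) recur(nd$right, idx[!go_left])
  }
  recur(1L, seq_len(nrow(X)))
  out
}

.rf_predict <- function(fit, X) {
  preds <- vapply(fit$trees, function(tr) .rf_predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}
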