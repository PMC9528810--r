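#' Matern-3/2 covariance matrix
#'
#' \eqn{k(r) = \sigma_f^2 (1 + \sqrt{3} r/\ell) \exp(-\sqrt{3} r/\ell)} with
#' \eqn{r} the Euclidean distance between rows. With a length-scale vector
#' (ARD) each dimension is scaled by its own \eqn{\ell_k} before the
#' distance is taken.
#'
#' @param X1,X2 Input matrices (rows = points). `X2 = NULL` means `X1`.
#' @param lengthscale Positive scalar or per-dimension vector.
#' @param variance Signal variance \eqn{\sigma_f^2}.
#' @return Covariance matrix `nrow(X1) x nrow(X2)`.
#' @export
kernel_matern32 <- function(X1, X2 = NULL, lengthscale = 1, variance = 1) {
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  if (any(lengthscale <= 0) || variance <= 0)
    stop("lengthscale and variance must be > 0")
  ls <- if (length(lengthscale) == 1L) rep(lengthscale, ncol(X1)) else
    lengthscale
  A <- sweep(X1, 2, ls, "/"); B <- sweep(X2, 2, ls, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 0))
  u <- sqrt(3) * r
  variance * (1 + u) * exp(-u)
}

# negative log marginal likelihood and its gradient in
# theta = (log sf2, log ell [1 or d], log sn2); X assumed preprocessed
.gpr_nll <- function(theta, X, y, ard, jitter = 1e-10) {
  d <- ncol(X); n <- nrow(X)
  sf2 <- exp(theta[1])
  ell <- exp(theta[2:(1 + if (ard) d else 1)])
  sn2 <- exp(theta[length(theta)])
  ls <- if (ard) ell else rep(ell, d)
  A <- sweep(X, 2, ls, "/")
  d2 <- outer(rowSums(A^2), rowSums(A^2), "+") - 2 * tcrossprod(A)
  r <- sqrt(pmax(d2, 0))
  u <- sqrt(3) * r
  E <- exp(-u)
  K <- sf2 * (1 + u) * E
  Ky <- K + diag(sn2 + jitter, n)
  L <- tryCatch(chol(Ky), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, length(theta))))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- Kinv - tcrossprod(alpha)          # dNLL/dK = 0.5 * W
  g_sf <- 0.5 * sum(W * K)               # dK/dlog sf2 = K
  if (ard) {
    g_ell <- vapply(seq_len(d), function(k) {
      Dk <- outer(X[, k], X[, k], "-")^2 / ls[k]^2
      0.5 * sum(W * (sf2 * 3 * E * Dk))
    }, numeric(1))
  } else {
    g_ell <- 0.5 * sum(W * (sf2 * u^2 * E))
  }
  g_sn <- 0.5 * sum(diag(W)) * sn2
  list(value = nll, grad = c(g_sf, g_ell, g_sn))
}

# Fit hyperparameters by type-II maximum likelihood with restarts.
# Returns list(sf2, ell, sn2, nll).
.gpr_optimize <- function(X, y, ard = FALSE, restarts = 5L, seed = 1L,
                          jitter = 1e-10) {
  d <- ncol(X)
  nl <- if (ard) d else 1L
  lower <- c(log(1e-4), rep(log(0.05), nl), log(1e-8))
  upper <- c(log(1e3), rep(log(1e3), nl), log(10))
  starts <- with_seed(seed, {
    s0 <- c(0, rep(log(max(sqrt(d), 1)), nl), log(0.1))
    # ARD: also start from uniformly short length-scales so dimensions with
    # fine-grained structure are not stuck on the large-scale plateau
    s1 <- if (ard) list(c(0, rep(log(1), nl), log(0.1))) else list()
    extra <- if (restarts > 1L)
      lapply(seq_len(restarts - 1L), function(i)
        runif(length(s0), min = pmax(lower, s0 - 2), max = pmin(upper, s0 + 2)))
    else list()
    c(list(s0), s1, extra)
  })
  # optim calls fn and gr at the same point back-to-back: cache one eval
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- .gpr_nll(p, X, y, ard, jitter)
      cache$key <- key
    }
    cache$res
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn = function(p) eval_at(p)$value,
            gr = function(p) eval_at(p)$grad,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("GPR hyperparameter optimization failed")
  th <- best$par
  list(sf2 = exp(th[1]), ell = exp(th[2:(1 + nl)]),
       sn2 = exp(th[length(th)]), nll = best$value)
}

# exact GP posterior given fixed hyperparameters (internal; the public
# interface is fit_model(snar_model("GPR"), ...))
.gpr_posterior <- function(X, y, sf2, ell, sn2, jitter = 1e-10) {
  K <- kernel_matern32(X, lengthscale = ell, variance = sf2)
  L <- chol(K + diag(sn2 + jitter, nrow(X)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  list(L = L, alpha = alpha, X = X, sf2 = sf2, ell = ell, sn2 = sn2,
       jitter = jitter)
}

.gpr_predict <- function(post, Xstar, include_noise = TRUE) {
  Ks <- kernel_matern32(Xstar, post$X, lengthscale = post$ell,
                        variance = post$sf2)
  mu <- drop(Ks %*% post$alpha)
  V <- forwardsolve(t(post$L), t(Ks))
  varf <- pmax(post$sf2 - colSums(V^2), 0)
  var_tot <- varf + if (include_noise) post$sn2 else 0
  list(mean = mu, sd = sqrt(var_tot))
}
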