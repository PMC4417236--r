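## Single-variance-component linear mixed model via the eigendecomposition
## of the relatedness matrix K = 2 * kinship (EMMA-style). The model is
##   y = X b + u + e,  cov(u) = sigma_g^2 K,  cov(e) = sigma_e^2 I,
## reparameterised as V = sigma2 * (h K + (1 - h) I) with h in [0, 1).
## Rotating by the eigenvectors of K diagonalises V, so REML in h is a
## one-dimensional optimisation and every downstream generalised
## least-squares fit is a weighted regression.

## Weighted LS on the rotated scale; returns estimates for all columns of X.
.gls_rot <- function(Xr, yr, w) {
  Wi <- 1 / w
  XtWX <- crossprod(Xr * Wi, Xr)
  XtWy <- crossprod(Xr * Wi, yr)
  R <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  res <- yr - Xr %*% beta
  rss <- sum(res^2 * Wi)
  XtWX_inv <- chol2inv(R)
  list(beta = drop(beta), rss = rss, XtWX_inv = XtWX_inv,
       logdet_XtWX = 2 * sum(log(diag(R))))
}

## REML criterion for a given h (to be maximised).
.reml_loglik <- function(h, Xr, yr, d) {
  w <- h * d + (1 - h)
  if (any(w <= 1e-10)) return(-Inf)
  fit <- .gls_rot(Xr, yr, w)
  if (is.null(fit)) return(-Inf)
  n <- length(yr); p <- ncol(Xr)
  sigma2 <- fit$rss / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(w)) +
          fit$logdet_XtWX)
}

#' Fit the null kinship mixed model by REML
#'
#' Estimates the heritability-like variance ratio
#' `h = sigma_g^2 / (sigma_g^2 + sigma_e^2)` and the total variance of the
#' model `y = X b + u + e` with `cov(u) = sigma_g^2 * 2 * kinship`, by
#' one-dimensional REML on the eigen-rotated scale. The returned object
#' carries the rotation, so per-marker generalised least-squares tests are a
#' single weighted regression each.
#'
#' @param y Numeric response (e.g. Blom-transformed CAC).
#' @param K Relatedness matrix `2 * kinship`, aligned with `y`.
#' @param X Fixed-effect design matrix (default intercept only).
#' @return A list of class `lmm_null` with elements `h2`, `sigma2`,
#'   `loglik`, `loglik_h0` (REML log-likelihood at `sigma_g^2 = 0`),
#'   `U`, `d`, `w`, `Xr`, `yr`.
#' @export
fit_lmm_null <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(K) != n || ncol(K) != n) stop("K must be n x n")
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("relatedness matrix 2*kinship is not positive semi-definite")
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)

  opt <- stats::optimize(.reml_loglik, interval = c(1e-6, 1 - 1e-6),
                         Xr = Xr, yr = yr, d = d, maximum = TRUE)
  ll0 <- .reml_loglik(0, Xr, yr, d)
  if (ll0 >= opt$objective) {
    h2 <- 0; ll <- ll0
  } else {
    h2 <- opt$maximum; ll <- opt$objective
  }
  w <- h2 * d + (1 - h2)
  fit <- .gls_rot(Xr, yr, w)
  sigma2 <- fit$rss / (n - ncol(Xr))
  structure(list(h2 = h2, sigma2 = sigma2, beta = fit$beta,
                 loglik = ll, loglik_h0 = ll0,
                 U = U, d = d, w = w, Xr = Xr, yr = yr, n = n),
            class = "lmm_null")
}

## Wald test of the last column of [X, x] under the null-model weights.
## xr is the rotated predictor. The residual scale is re-estimated from the
## marker model (so with K = I the result is exactly OLS); the variance
## ratio h stays fixed at its null-model REML estimate.
.lmm_wald <- function(null_fit, xr) {
  Zr <- cbind(null_fit$Xr, xr)
  fit <- .gls_rot(Zr, null_fit$yr, null_fit$w)
  if (is.null(fit)) return(c(beta = NA, se = NA, p = NA))
  n <- null_fit$n; p <- ncol(Zr)
  sigma2 <- fit$rss / (n - p)
  v <- fit$XtWX_inv[p, p] * sigma2
  if (!is.finite(v) || v <= 0) return(c(beta = NA, se = NA, p = NA))
  beta <- fit$beta[p]
  se <- sqrt(v)
  c(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}
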