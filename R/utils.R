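# Internal numerical helpers shared across modules.

# Symmetrize and clip eigenvalues below -tol to zero. Plug-in covariance
# estimates can carry tiny negative eigenvalues that break chol().
psd_repair <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= 0) return(M)
  lam <- pmax(e$values, 0)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    # beyond numeric noise: still repair, caller decides whether to error
    lam <- pmax(e$values, 0)
  }
  M2 <- e$vectors %*% (lam * t(e$vectors))
  (M2 + t(M2)) / 2
}

# Solve M x = b through Cholesky with an informative failure mode.
chol_solve <- function(M, b, context = "covariance matrix") {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    stop("singular ", context,
         "; consider pruning highly correlated instruments", call. = FALSE)
  }
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

chol_logdet <- function(M) {
  R <- chol(M)
  2 * sum(log(diag(R)))
}

# Gaussian log-likelihood of residual vector e with covariance W (up to const).
gauss_loglik <- function(e, W) {
  R <- tryCatch(chol(W), error = function(err) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, e, transpose = TRUE)
  -sum(log(diag(R))) - 0.5 * sum(z^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
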