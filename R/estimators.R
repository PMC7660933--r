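# Point estimation of the correlation-ratio parameter K. K = K_YX is the
# common mean of the per-SNP correlation ratios r_Yg/r_Xg, equal to
# beta_YX * sqrt(var(X)/var(Y)); |K| < 1 under the key condition and
# K = 0 iff there is no causal effect in that direction.

new_cd_estimate <- function(method, direction_label, K_hat, se_K, alpha,
                            b0_hat = NULL, se_b0 = NULL, sigma0_sq = NULL,
                            m_used, converged = TRUE, n_iter = 0L,
                            extra = list()) {
  z <- stats::qnorm(1 - alpha / 2)
  structure(c(list(
    method = method,
    direction_label = direction_label,
    K_hat = as.numeric(K_hat),
    se_K = as.numeric(se_K),
    ci = c(K_hat - z * se_K, K_hat + z * se_K),
    alpha = alpha,
    b0_hat = b0_hat,
    se_b0 = se_b0,
    sigma0_sq = sigma0_sq,
    m_used = as.integer(m_used),
    converged = converged,
    n_iter = as.integer(n_iter)
  ), extra), class = "cd_estimate")
}

#' @export
print.cd_estimate <- function(x, ...) {
  cat(sprintf("CD-%s estimate (%s), m = %d SNPs\n",
              switch(x$method, ratio = "Ratio", egger = "Egger", gls = "GLS",
                     mv_egger = "Egger (multivariable)", x$method),
              x$direction_label, x$m_used))
  cat(sprintf("  K = %.4f (SE %.4f), %d%% CI [%.4f, %.4f]\n",
              x$K_hat, x$se_K, round(100 * (1 - x$alpha)), x$ci[1], x$ci[2]))
  if (!is.null(x$b0_hat)) {
    cat(sprintf("  pleiotropy intercept b0 = %.4f (SE %.4f), sigma0^2 = %.5f\n",
                x$b0_hat, x$se_b0, x$sigma0_sq))
  }
  if (!is.null(x$K_YA)) {
    cat(sprintf("  adjustment trait: K_YA = %.4f (SE %.4f)\n", x$K_YA, x$se_K_YA))
  }
  if (!x$converged) cat("  WARNING: iteration did not converge\n")
  invisible(x)
}

#' CD-Ratio: GLS estimate of K from the correlation-ratio vector
#'
#' Under the valid-IV model every per-SNP ratio estimates the same
#' constant K, so K is estimated by exact one-parameter generalized least
#' squares: `K = (1' V^-1 ratio) / (1' V^-1 1)` with
#' `var(K) = 1 / (1' V^-1 1)`. No iteration is involved; the estimator is
#' the precision-weighted mean of the ratios.
#'
#' @param rs A `ratio_system`.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @param direction_label Direction tag carried into the result.
#' @return A `cd_estimate` with `method = "ratio"`.
#' @export
cd_ratio <- function(rs, alpha = 0.05, direction_label = NULL) {
  stopifnot(inherits(rs, "ratio_system"))
  ones <- rep(1, rs$m)
  Vi1 <- chol_solve(rs$V_ratio, ones, context = "ratio covariance")
  denom <- sum(Vi1)
  K <- sum(Vi1 * rs$ratio) / denom
  new_cd_estimate("ratio",
                  direction_label %||% paste0(rs$exposure, "->", rs$outcome),
                  K, sqrt(1 / denom), alpha, m_used = rs$m)
}

# one GLS step: theta = (X' W^-1 X)^-1 X' W^-1 y, with its covariance
gls_step <- function(X, y, W) {
  WiX <- chol_solve(W, X, context = "working covariance")
  XtWiX <- crossprod(X, WiX)
  cov_theta <- solve(XtWiX)
  theta <- drop(cov_theta %*% crossprod(WiX, y))
  list(theta = theta, cov = cov_theta)
}

check_design <- function(X, kappa_max = 1e8) {
  k <- kappa(scale(X, center = FALSE), exact = TRUE)
  if (!is.finite(k) || k > kappa_max) {
    stop("collinear design (intercept direction vs correlation columns)",
         call. = FALSE)
  }
}

# Shared alternating scheme for the Egger-family random-intercept models.
# Mean model y = X theta + eps, eps ~ N(0, W0 + sigma0^2 * S2), where
# y = r_Yg, X = [v, r_Xg(, r_Ag)], v = Sigma 1, S2 = Sigma %*% Sigma and
# W0 = V_Yg / nY (+ K^2 V_Xg / nX for CD-GLS, handled by the caller via
# `extra_W`). Alternates exact GLS for theta given sigma0^2 with a 1-D
# bounded maximization of the Gaussian log-likelihood over sigma0^2.
egger_iterate <- function(X, y, W0_fun, S2, sigma0_max = 10,
                          max_iter = 200, tol = 1e-8) {
  p <- ncol(X)
  theta <- rep(0, p); s0 <- 0
  converged <- FALSE; it <- 0L; fit <- NULL
  while (it < max_iter) {
    it <- it + 1L
    W <- W0_fun(theta) + s0 * S2
    fit <- gls_step(X, y, W)
    e <- y - drop(X %*% fit$theta)
    opt <- stats::optimize(function(s) gauss_loglik(e, W0_fun(fit$theta) + s * S2),
                           interval = c(0, sigma0_max), maximum = TRUE,
                           tol = 1e-10)
    s0_new <- opt$maximum
    # snap to the boundary when the likelihood is flat there
    if (gauss_loglik(e, W0_fun(fit$theta)) >= opt$objective) s0_new <- 0
    delta <- max(abs(fit$theta - theta), abs(s0_new - s0))
    theta <- fit$theta; s0 <- s0_new
    if (delta < tol) { converged <- TRUE; break }
  }
  W <- W0_fun(theta) + s0 * S2
  fit <- gls_step(X, y, W)
  list(theta = fit$theta, cov = fit$cov, sigma0_sq = s0, W = W,
       converged = converged, n_iter = it)
}

#' CD-Egger: pleiotropy-robust estimation of K with a random intercept
#'
#' Models the outcome-trait correlations as
#' `r_Yg = b0 * v + K * r_Xg + eps`, `eps ~ N(0, V_Yg / nY + sigma0^2 Sigma^2)`,
#' where `v = Sigma 1` (row sums of the LD matrix) and `Sigma^2` is the
#' matrix square `Sigma %*% Sigma`. The intercept `b0` is the mean of the
#' SNPs' direct (pleiotropic) effects on the outcome, on the
#' `1/sqrt(var(Y))` scale, and `sigma0^2` their variance; under the InSIDE
#' assumption (instrument strengths independent of direct effects) K
#' remains identified under directional pleiotropy. Given `sigma0^2` the
#' mean parameters solve a GLS problem, so the fit alternates exact GLS
#' for `(b0, K)` with a 1-D bounded maximum-likelihood update of
#' `sigma0^2 in [0, sigma0_max]`; the scheme is coordinate ascent on the
#' Gaussian likelihood. Standard errors come from the GLS information
#' matrix at the final working covariance.
#'
#' @param cx `correlation_set` for the exposure trait X.
#' @param cy `correlation_set` for the outcome trait Y.
#' @param ld `ld_matrix` on the same SNPs (same order).
#' @param alpha CI level is `1 - alpha`.
#' @param max_iter,tol Iteration schedule: stop when the largest absolute
#'   parameter change drops below `tol`, or after `max_iter` sweeps (then
#'   the last iterate is returned with `converged = FALSE` and a warning).
#' @param sigma0_max Upper bound for the pleiotropy variance.
#' @param direction_label Direction tag carried into the result.
#' @return A `cd_estimate` with `method = "egger"`, including `b0_hat`,
#'   `se_b0` and `sigma0_sq`.
#' @export
cd_egger <- function(cx, cy, ld, alpha = 0.05, max_iter = 200, tol = 1e-8,
                     sigma0_max = 10, direction_label = NULL) {
  stopifnot(inherits(cx, "correlation_set"), inherits(cy, "correlation_set"),
            inherits(ld, "ld_matrix"))
  m <- length(cx$r)
  if (m < 3) stop("CD-Egger needs at least 3 SNPs", call. = FALSE)
  sigma <- ld$sigma
  v <- rowSums(sigma)
  S2 <- sigma %*% sigma
  X <- cbind(v = v, rX = cx$r)
  check_design(X)
  W0 <- psd_repair(cy$V / cy$n)
  res <- egger_iterate(X, cy$r, function(theta) W0, S2,
                       sigma0_max = sigma0_max, max_iter = max_iter, tol = tol)
  if (!res$converged) {
    warning("CD-Egger did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  new_cd_estimate("egger",
                  direction_label %||% paste0(cx$trait_label, "->", cy$trait_label),
                  res$theta[2], sqrt(res$cov[2, 2]), alpha,
                  b0_hat = res$theta[1], se_b0 = sqrt(res$cov[1, 1]),
                  sigma0_sq = res$sigma0_sq, m_used = m,
                  converged = res$converged, n_iter = res$n_iter)
}

# profile log-likelihood of (K, sigma0^2) for CD-GLS, b0 profiled out
gls_profile_ll <- function(par, rx, ry, v, S2, WY, WX) {
  K <- par[1]; s0 <- par[2]
  if (s0 < 0) return(-Inf)
  W <- WY + s0 * S2 + K^2 * WX
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  resid0 <- ry - K * rx
  Wi_v <- backsolve(R, backsolve(R, v, transpose = TRUE))
  b0 <- sum(Wi_v * resid0) / sum(Wi_v * v)
  gauss_loglik(resid0 - b0 * v, W)
}

#' CD-GLS: pleiotropy-robust estimation propagating exposure noise
#'
#' Same mean model as [cd_egger()], but the working covariance also
#' carries the sampling noise of the exposure correlations through the
#' slope: `W(K) = V_Yg / nY + sigma0^2 Sigma^2 + K^2 V_Xg / nX`. The fit
#' runs the CD-Egger alternating scheme with `W` evaluated at the current
#' slope, then polishes `(K, sigma0^2)` by maximizing the profile
#' Gaussian likelihood (with `b0` profiled out in closed form), so the
#' reported fit maximizes the working-model likelihood. With a large
#' exposure GWAS (`V_Xg / nX -> 0`) CD-GLS and CD-Egger coincide. The
#' K-squared propagation form of the working covariance is this package's
#' reading of "account for the variability of r_Xg" and is flagged as a
#' reconstruction.
#'
#' @inheritParams cd_egger
#' @return A `cd_estimate` with `method = "gls"`.
#' @export
cd_gls <- function(cx, cy, ld, alpha = 0.05, max_iter = 200, tol = 1e-8,
                   sigma0_max = 10, direction_label = NULL) {
  stopifnot(inherits(cx, "correlation_set"), inherits(cy, "correlation_set"),
            inherits(ld, "ld_matrix"))
  m <- length(cx$r)
  if (m < 3) stop("CD-GLS needs at least 3 SNPs", call. = FALSE)
  sigma <- ld$sigma
  v <- rowSums(sigma)
  S2 <- sigma %*% sigma
  X <- cbind(v = v, rX = cx$r)
  check_design(X)
  WY <- psd_repair(cy$V / cy$n)
  WX <- psd_repair(cx$V / cx$n)
  res <- egger_iterate(X, cy$r, function(theta) WY + theta[2]^2 * WX, S2,
                       sigma0_max = sigma0_max, max_iter = max_iter, tol = tol)
  # polish to the maximum of the working-model likelihood
  opt <- stats::optim(c(res$theta[2], res$sigma0_sq), gls_profile_ll,
                      rx = cx$r, ry = cy$r, v = v, S2 = S2, WY = WY, WX = WX,
                      method = "L-BFGS-B",
                      lower = c(-Inf, 0), upper = c(Inf, sigma0_max),
                      control = list(fnscale = -1, factr = 10, pgtol = 1e-14,
                                     ndeps = c(1e-7, 1e-7)))
  # Nelder-Mead polish: the profile surface is very flat near the optimum
  opt2 <- stats::optim(opt$par, gls_profile_ll,
                       rx = cx$r, ry = cy$r, v = v, S2 = S2, WY = WY, WX = WX,
                       method = "Nelder-Mead",
                       control = list(fnscale = -1, reltol = 1e-15,
                                      maxit = 5000))
  if (opt2$value > opt$value) opt <- opt2
  K <- opt$par[1]; s0 <- min(max(opt$par[2], 0), sigma0_max)
  W <- WY + s0 * S2 + K^2 * WX
  # ML intercept given (K, sigma0^2); SEs from the GLS information at W
  Wi_v <- chol_solve(W, v, context = "working covariance")
  b0 <- sum(Wi_v * (cy$r - K * cx$r)) / sum(Wi_v * v)
  fit <- gls_step(X, cy$r, W)
  if (!res$converged && opt$convergence != 0) {
    warning("CD-GLS did not converge", call. = FALSE)
  }
  new_cd_estimate("gls",
                  direction_label %||% paste0(cx$trait_label, "->", cy$trait_label),
                  K, sqrt(fit$cov[2, 2]), alpha,
                  b0_hat = b0, se_b0 = sqrt(fit$cov[1, 1]),
                  sigma0_sq = s0, m_used = m,
                  converged = res$converged || opt$convergence == 0,
                  n_iter = res$n_iter)
}

#' Multivariable CD-Egger: adjust for a third trait
#'
#' Extends [cd_egger()] by a third, observed trait A (for example a
#' measured confounder), with mean model
#' `r_Yg = b0 * v + K_YX * r_Xg + K_YA * r_Ag + eps` and the CD-Egger
#' covariance and iteration. The design matrix is `[v, r_Xg, r_Ag]`; the
#' companion goodness-of-fit test therefore has `m - 3` degrees of
#' freedom.
#'
#' @param cx,cy,ca `correlation_set`s for X, Y and the adjustment trait A,
#'   harmonized to identical SNPs in identical order.
#' @inheritParams cd_egger
#' @return A `cd_estimate` with `method = "mv_egger"`; `K_hat` is K_YX,
#'   with `K_YA` and `se_K_YA` attached.
#' @export
mv_cd_egger <- function(cx, cy, ca, ld, alpha = 0.05, max_iter = 200,
                        tol = 1e-8, sigma0_max = 10, direction_label = NULL) {
  stopifnot(inherits(cx, "correlation_set"), inherits(cy, "correlation_set"),
            inherits(ca, "correlation_set"), inherits(ld, "ld_matrix"))
  m <- length(cx$r)
  if (m < 4) stop("MV-CD-Egger needs at least 4 SNPs", call. = FALSE)
  if (!identical(as.character(cx$snp_ids), as.character(ca$snp_ids))) {
    stop("adjustment-trait correlation set must share SNPs and order",
         call. = FALSE)
  }
  sigma <- ld$sigma
  v <- rowSums(sigma)
  S2 <- sigma %*% sigma
  X <- cbind(v = v, rX = cx$r, rA = ca$r)
  check_design(X)
  W0 <- psd_repair(cy$V / cy$n)
  res <- egger_iterate(X, cy$r, function(theta) W0, S2,
                       sigma0_max = sigma0_max, max_iter = max_iter, tol = tol)
  if (!res$converged) {
    warning("MV-CD-Egger did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  new_cd_estimate("mv_egger",
                  direction_label %||% paste0(cx$trait_label, "->", cy$trait_label),
                  res$theta[2], sqrt(res$cov[2, 2]), alpha,
                  b0_hat = res$theta[1], se_b0 = sqrt(res$cov[1, 1]),
                  sigma0_sq = res$sigma0_sq, m_used = m,
                  converged = res$converged, n_iter = res$n_iter,
                  extra = list(
                    K_YA = res$theta[3],
                    se_K_YA = sqrt(res$cov[3, 3]),
                    ci_K_YA = c(res$theta[3] - z * sqrt(res$cov[3, 3]),
                                res$theta[3] + z * sqrt(res$cov[3, 3]))
                  ))
}

#' Bi-directional CD-Ratio
#'
#' Runs CD-Ratio on two disjoint instrument sets: `rs1` built from
#' instruments for X (ratios `r_Yg1 / r_Xg1`, estimating the X-to-Y
#' parameter K1) and `rs2` from instruments for Y (ratios `r_Xg2 / r_Yg2`,
#' estimating the Y-to-X parameter K2). An arm supports a causal effect
#' when its confidence interval lies entirely within `[-1, 0)` or
#' `(0, 1]`; an interval covering 0 supports no effect on that arm
#' (endpoints exactly at 0 or at either unit boundary count as covering).
#'
#' @param rs1 `ratio_system` for the X-to-Y arm (instrument set g1).
#' @param rs2 `ratio_system` for the Y-to-X arm (instrument set g2).
#' @param alpha CI level is `1 - alpha`.
#' @return A list of class `bi_cd_result` with `K1`, `K2` (both
#'   `cd_estimate`s) and `verdict` in
#'   `none / x_to_y / y_to_x / bidirectional`.
#' @export
bi_cd_ratio <- function(rs1, rs2, alpha = 0.05) {
  if (rs1$m < 1 || rs2$m < 1) stop("empty instrument set on one arm", call. = FALSE)
  shared <- intersect(rs1$snp_ids, rs2$snp_ids)
  if (length(shared)) {
    stop("instrument sets must be disjoint; shared: ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  K1 <- cd_ratio(rs1, alpha = alpha, direction_label = "X->Y")
  K2 <- cd_ratio(rs2, alpha = alpha, direction_label = "Y->X")
  eff1 <- ci_inside_unit(K1$ci)
  eff2 <- ci_inside_unit(K2$ci)
  verdict <- if (eff1 && eff2) "bidirectional"
  else if (eff1) "x_to_y"
  else if (eff2) "y_to_x"
  else "none"
  structure(list(K1 = K1, K2 = K2, verdict = verdict, alpha = alpha),
            class = "bi_cd_result")
}

#' @export
print.bi_cd_result <- function(x, ...) {
  cat("Bi-directional CD-Ratio\n")
  cat(sprintf("  K1 (X->Y) = %.4f, CI [%.4f, %.4f]\n",
              x$K1$K_hat, x$K1$ci[1], x$K1$ci[2]))
  cat(sprintf("  K2 (Y->X) = %.4f, CI [%.4f, %.4f]\n",
              x$K2$K_hat, x$K2$ci[1], x$K2$ci[2]))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
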