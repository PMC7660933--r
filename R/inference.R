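# Goodness-of-fit tests, decision rules, and the key-condition check.

# CI geometry helpers, inclusive-boundary convention: an endpoint exactly
# at 0 or +-1 counts as covering that point, which can only push a
# decision toward inconclusive.
ci_inside_unit <- function(ci) {
  (ci[1] > -1 && ci[2] < 0) || (ci[1] > 0 && ci[2] < 1)
}
ci_outside_unit <- function(ci) {
  ci[1] > 1 || ci[2] < -1
}
ci_covers_zero <- function(ci) {
  ci[1] <= 0 && ci[2] >= 0
}

new_gof_result <- function(method, Q, df) {
  structure(list(method = method, Q = as.numeric(Q), df = as.integer(df),
                 pval = stats::pchisq(Q, df = df, lower.tail = FALSE)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Q_%s = %.3f, df = %d, p = %.4g\n",
              switch(x$method, ratio = "Ratio", egger = "Egger",
                     gls = "GLS", mv_egger = "Egger (MV)", x$method),
              x$Q, x$df, x$pval))
  invisible(x)
}

#' Goodness-of-fit test for CD-Ratio
#'
#' Quadratic-form residual statistic
#' `Q = (ratio - K 1)' V_ratio^-1 (ratio - K 1)`, with asymptotic null
#' distribution chi-squared on `m - 1` degrees of freedom when all SNPs
#' are valid instruments. Rejection suggests the per-SNP ratios do not
#' share one mean, e.g. because of horizontal pleiotropy.
#'
#' @param rs The `ratio_system` the estimate was computed from.
#' @param est A `cd_estimate` for K (any consistent estimate; normally
#'   from [cd_ratio()]).
#' @return A `gof_result`.
#' @export
q_ratio <- function(rs, est) {
  stopifnot(inherits(rs, "ratio_system"))
  if (rs$m < 2) stop("goodness-of-fit needs at least 2 SNPs", call. = FALSE)
  e <- rs$ratio - est$K_hat
  Q <- sum(e * chol_solve(rs$V_ratio, e, context = "ratio covariance"))
  new_gof_result("ratio", Q, rs$m - 1L)
}

#' Goodness-of-fit test for the Egger-family models
#'
#' Quadratic form of the fitted-model residuals
#' `Q = (r_Yg - b0 v - K r_Xg)' W^-1 (r_Yg - b0 v - K r_Xg)` with `W`
#' rebuilt at the fitted `sigma0^2` (plug-in). Degrees of freedom are
#' `m - 2` for CD-Egger and CD-GLS and `m - 3` for the multivariable
#' model. Rejection suggests remaining model violations, e.g.
#' instruments correlated with hidden confounders.
#'
#' @param cx,cy `correlation_set`s for X and Y (and the estimate's SNPs).
#' @param ld `ld_matrix` on the same SNPs.
#' @param est A `cd_estimate` from [cd_egger()], [cd_gls()] or
#'   [mv_cd_egger()].
#' @param ca `correlation_set` for the adjustment trait; required when
#'   `est$method == "mv_egger"`.
#' @return A `gof_result`.
#' @export
q_egger <- function(cx, cy, ld, est, ca = NULL) {
  stopifnot(inherits(est, "cd_estimate"))
  m <- length(cx$r)
  if (m < 3) stop("goodness-of-fit needs at least 3 SNPs", call. = FALSE)
  sigma <- ld$sigma
  v <- rowSums(sigma)
  S2 <- sigma %*% sigma
  W <- psd_repair(cy$V / cy$n) + est$sigma0_sq * S2
  e <- cy$r - est$b0_hat * v - est$K_hat * cx$r
  df <- m - 2L
  if (est$method == "gls") {
    W <- W + est$K_hat^2 * psd_repair(cx$V / cx$n)
  } else if (est$method == "mv_egger") {
    if (is.null(ca)) stop("multivariable GOF needs the adjustment-trait set", call. = FALSE)
    e <- e - est$K_YA * ca$r
    df <- m - 3L
  }
  if (df < 1) stop("no residual degrees of freedom", call. = FALSE)
  Q <- sum(e * chol_solve(W, e, context = "working covariance"))
  new_gof_result(est$method, Q, df)
}

#' Three-outcome decision rule on the two directional estimates
#'
#' Takes the estimate of the X-to-Y parameter and the estimate of the
#' Y-to-X parameter (both |K| < 1 under their key conditions when the
#' corresponding direction is true). The direction X to Y is concluded
#' when the X-to-Y interval lies entirely inside `[-1, 0)` or `(0, 1]`
#' while the Y-to-X interval lies entirely outside `[-1, 1]`; Y to X by
#' symmetry; otherwise no conclusion. Endpoints exactly at 0 or +-1 count
#' as covering (conservative). Separately, `existence_flag` reads the
#' zero-coverage of the two intervals: both covering 0 supports no causal
#' relationship, neither covering 0 supports one, otherwise ambiguous.
#'
#' @param est_xy `cd_estimate` for the X-to-Y direction.
#' @param est_yx `cd_estimate` for the Y-to-X direction (same `alpha`).
#' @return A list of class `direction_decision` with `outcome`
#'   (`x_to_y / y_to_x / inconclusive`), `existence_flag`
#'   (`causal_supported / no_causal_supported / ambiguous`), `ci_xy`,
#'   `ci_yx` and `alpha`.
#' @export
decide <- function(est_xy, est_yx) {
  stopifnot(inherits(est_xy, "cd_estimate"), inherits(est_yx, "cd_estimate"))
  if (!isTRUE(all.equal(est_xy$alpha, est_yx$alpha))) {
    stop("both estimates must use the same alpha", call. = FALSE)
  }
  ci_xy <- est_xy$ci; ci_yx <- est_yx$ci
  outcome <- if (ci_inside_unit(ci_xy) && ci_outside_unit(ci_yx)) "x_to_y"
  else if (ci_inside_unit(ci_yx) && ci_outside_unit(ci_xy)) "y_to_x"
  else "inconclusive"
  z0_xy <- ci_covers_zero(ci_xy); z0_yx <- ci_covers_zero(ci_yx)
  existence <- if (z0_xy && z0_yx) "no_causal_supported"
  else if (!z0_xy && !z0_yx) "causal_supported"
  else "ambiguous"
  structure(list(outcome = outcome, existence_flag = existence,
                 ci_xy = ci_xy, ci_yx = ci_yx, alpha = est_xy$alpha),
            class = "direction_decision")
}

#' @export
print.direction_decision <- function(x, ...) {
  cat(sprintf("Decision at alpha = %.3g\n", x$alpha))
  cat(sprintf("  CI (X->Y): [%.4f, %.4f]\n", x$ci_xy[1], x$ci_xy[2]))
  cat(sprintf("  CI (Y->X): [%.4f, %.4f]\n", x$ci_yx[1], x$ci_yx[2]))
  cat("  direction:", x$outcome, "| existence:", x$existence_flag, "\n")
  invisible(x)
}

#' Check the key variance condition for |K| < 1
#'
#' The ratio parameterization needs `var(Y) > beta_YX^2 * var(X)`. With
#' only summary data, each SNP's marginal model reconstructs the trait
#' variance as `var(T) = beta^2 var(g) + (n - 2) se^2 var(g)` with
#' `var(g) = 2 eaf (1 - eaf)` under Hardy-Weinberg. The per-SNP
#' reconstructions of `var(Y) / var(X)` (matched by SNP id) are summarized
#' and compared against `beta_yx^2`; an externally supplied estimate of
#' the trait-trait variance-explained `r2` is echoed for the common
#' heuristic that the condition almost always holds when it is below 0.2
#' (reported, never enforced).
#'
#' @param statsX,statsY `summary_stats` tables sharing SNP ids.
#' @param beta_yx External estimate of the causal effect of X on Y
#'   (e.g. from an MR fit).
#' @param r2 Optional estimate of the X-on-Y variance explained.
#' @return A list of class `key_condition_report` with `per_snp_varX`,
#'   `per_snp_varY`, `ratio_summary` (min, mean, max of varY/varX),
#'   `beta_sq`, `condition_holds` and `r2_heuristic`.
#' @export
key_condition_check <- function(statsX, statsY, beta_yx, r2 = NULL) {
  shared <- intersect(statsX$snp_id, statsY$snp_id)
  if (length(shared) == 0) stop("no shared SNPs", call. = FALSE)
  X <- statsX[match(shared, statsX$snp_id), , drop = FALSE]
  Y <- statsY[match(shared, statsY$snp_id), , drop = FALSE]
  if (any(is.na(X$eaf)) || any(is.na(Y$eaf))) {
    stop("allele frequencies required for the variance reconstruction",
         call. = FALSE)
  }
  reconstruct <- function(s) {
    varg <- 2 * s$eaf * (1 - s$eaf)
    s$beta^2 * varg + (s$n - 2) * s$se^2 * varg
  }
  vX <- reconstruct(X)
  vY <- reconstruct(Y)
  if (any(vX <= 0) || any(vY <= 0)) stop("nonpositive reconstructed variance", call. = FALSE)
  ratio <- vY / vX
  structure(list(
    snp_ids = shared,
    per_snp_varX = vX,
    per_snp_varY = vY,
    ratio_summary = c(min = min(ratio), mean = mean(ratio), max = max(ratio)),
    beta_sq = beta_yx^2,
    condition_holds = beta_yx^2 < min(ratio),
    r2_heuristic = r2
  ), class = "key_condition_report")
}

#' @export
print.key_condition_report <- function(x, ...) {
  cat(sprintf("var(Y)/var(X) over %d SNPs: min %.3f, mean %.3f, max %.3f\n",
              length(x$snp_ids), x$ratio_summary["min"],
              x$ratio_summary["mean"], x$ratio_summary["max"]))
  cat(sprintf("  beta_YX^2 = %.4f -> condition %s\n", x$beta_sq,
              if (x$condition_holds) "holds" else "fails"))
  if (!is.null(x$r2_heuristic)) {
    cat(sprintf("  variance explained R^2 = %.3f (heuristic threshold 0.2)\n",
                x$r2_heuristic))
  }
  invisible(x)
}
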