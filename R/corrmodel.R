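#' SNP-trait sample correlation from marginal GWAS statistics
#'
#' Recovers the sample Pearson correlation between a trait and a SNP from
#' the marginal per-allele effect estimate and its standard error,
#' `r = beta / sqrt(beta^2 + (n - 2) * se^2)`. This is an exact algebraic
#' identity with the OLS t statistic, so the result equals the
#' individual-level sample correlation.
#'
#' @param beta Marginal effect estimate.
#' @param se Its standard error (`> 0`).
#' @param n GWAS sample size (`> 2`).
#' @return The sample correlation (vectorized over inputs).
#' @export
corr_from_summary <- function(beta, se, n) {
  if (any(n <= 2)) stop("sample size must exceed 2", call. = FALSE)
  if (any(se < 0)) stop("standard errors must be nonnegative", call. = FALSE)
  beta / sqrt(beta^2 + (n - 2) * se^2)
}

#' Asymptotic covariance of a vector of SNP-trait correlations
#'
#' Covariance matrix of `sqrt(n) * (r - rho)` for the sample correlations
#' of one trait with `m` possibly LD-correlated SNPs, using the classical
#' normal-theory covariance of two correlations sharing one variable
#' (Pearson-Filon / Olkin-Steiger family):
#' `V_ij = rho_ij * (1 - r_i^2 - r_j^2) - r_i * r_j * (1 - r_i^2 - r_j^2 - rho_ij^2) / 2`,
#' which reduces to `(1 - r_i^2)^2` on the diagonal. Population
#' correlations are replaced by plug-in values: the sample `r` for
#' SNP-trait, the reference-panel LD for SNP-SNP.
#'
#' @param r Vector of SNP-trait correlations, `|r_i| < 1`.
#' @param ld An `ld_matrix` (or a plain correlation matrix) of the SNPs.
#' @return The `m x m` covariance matrix (per unit `sqrt(n)` scaling).
#' @export
corr_covariance <- function(r, ld) {
  sigma <- if (inherits(ld, "ld_matrix")) ld$sigma else as.matrix(ld)
  m <- length(r)
  if (nrow(sigma) != m) stop("dimension mismatch between r and ld", call. = FALSE)
  if (any(abs(r) >= 1)) stop("correlations must satisfy |r| < 1", call. = FALSE)
  rr <- outer(r^2, r^2, "+")   # r_i^2 + r_j^2
  pp <- outer(r, r)            # r_i * r_j
  V <- sigma * (1 - rr) - 0.5 * pp * (1 - rr - sigma^2)
  (V + t(V)) / 2
}

#' Build a correlation set for one trait from a summary table
#'
#' Converts each SNP's marginal estimate to a sample correlation and
#' attaches the plug-in asymptotic covariance under the supplied LD.
#'
#' @param stats A `summary_stats` table (one trait, harmonized SNP order).
#' @param ld An `ld_matrix` on the same SNPs in the same order.
#' @param trait_label Label used in printing and direction bookkeeping.
#' @return A list of class `correlation_set` with `trait_label`,
#'   `snp_ids`, `r`, `n` (scalar cohort size, the median of the per-SNP
#'   sample sizes) and `V` (covariance of `sqrt(n) * (r - rho)`).
#' @export
correlation_set <- function(stats, ld, trait_label = "trait") {
  stopifnot(inherits(ld, "ld_matrix"))
  if (!identical(as.character(stats$snp_id), as.character(ld$snp_ids))) {
    stop("SNP order of stats and ld must match (harmonize first)", call. = FALSE)
  }
  r <- corr_from_summary(stats$beta, stats$se, stats$n)
  structure(list(
    trait_label = trait_label,
    snp_ids = stats$snp_id,
    r = as.numeric(r),
    n = as.numeric(stats::median(stats$n)),
    V = corr_covariance(r, ld)
  ), class = "correlation_set")
}

#' Delta-method distribution of the correlation-ratio vector
#'
#' Forms the elementwise ratios `r_Y / r_X` and their covariance by the
#' delta method. Writing `J` for the Jacobian of the ratio map (entries
#' `1 / r_Xi` against `r_Yi` and `-r_Yi / r_Xi^2` against `r_Xi`) and
#' using the independence of the two GWAS cohorts,
#' `V_ratio = J' blockdiag(V_Y / nY, V_X / nX) J`, i.e.
#' `V_ratio[i, j] = V_Y[i, j] / (nY r_Xi r_Xj) +
#'  r_Yi r_Yj V_X[i, j] / (nX r_Xi^2 r_Xj^2)`.
#' The result is symmetrized and eigenvalue-clipped (PSD repair) before
#' downstream inversion.
#'
#' @param cx `correlation_set` for the exposure trait X (denominator).
#' @param cy `correlation_set` for the outcome trait Y (numerator).
#' @param tau_den Weak-denominator guard: error if any `|r_Xi| < tau_den`
#'   (the delta method fails near `r_X = 0`).
#' @return A list of class `ratio_system` with `snp_ids`, `ratio`,
#'   `V_ratio`, `m` and the direction labels.
#' @export
ratio_system <- function(cx, cy, tau_den = 1e-4) {
  stopifnot(inherits(cx, "correlation_set"), inherits(cy, "correlation_set"))
  if (length(cx$r) != length(cy$r) ||
      !identical(as.character(cx$snp_ids), as.character(cy$snp_ids))) {
    stop("correlation sets must share SNPs and order", call. = FALSE)
  }
  weak <- abs(cx$r) < tau_den
  if (any(weak)) {
    stop("denominator correlation too close to 0 for SNP(s): ",
         paste(cx$snp_ids[weak], collapse = ", "), call. = FALSE)
  }
  rx <- cx$r; ry <- cy$r
  ratio <- ry / rx
  a <- 1 / rx                # d(ratio_i)/d(r_Yi)
  b <- -ry / rx^2            # d(ratio_i)/d(r_Xi)
  V <- outer(a, a) * cy$V / cy$n + outer(b, b) * cx$V / cx$n
  structure(list(
    snp_ids = cx$snp_ids,
    ratio = as.numeric(ratio),
    V_ratio = psd_repair(V),
    m = length(ratio),
    exposure = cx$trait_label,
    outcome = cy$trait_label
  ), class = "ratio_system")
}
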