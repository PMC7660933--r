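#' Fisher's Z-transformation of the magnitude of a correlation
#'
#' `F(|r|) = log((1 + |r|) / (1 - |r|)) / 2`. The absolute value is taken
#' first, matching the directionality test's comparison of correlation
#' magnitudes; the output is nonnegative and monotone in `|r|`. For
#' finite samples the folded transform can be poorly approximated by a
#' normal; no small-sample correction is applied.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  0.5 * log((1 + abs(r)) / (1 - abs(r)))
}

#' Single-SNP Steiger directionality test
#'
#' Compares the Fisher-transformed correlation magnitudes of one SNP with
#' the two traits: `Z_g = F(|r_x|) - F(|r_y|)` with
#' `var(Z_g) = 1/(n_x - 3) + 1/(n_y - 3)`; the standardized statistic is
#' referred to a standard normal (two-sided). A significant positive
#' `Z_g` is read as the causal direction X to Y, a significant negative
#' one as Y to X, otherwise no conclusion. Note the test presumes a
#' causal relationship exists: under pure confounding it still forces a
#' directional call whenever the two correlation magnitudes differ.
#'
#' @param r_x,r_y Sample correlations of the SNP with traits X and Y.
#' @param n_x,n_y The two GWAS sample sizes (both `> 3`).
#' @param alpha Significance level for the decision (default 0.05).
#' @param snp_id Optional SNP identifier carried into the result.
#' @return A list of class `steiger_result` with `z_x`, `z_y`, `z_g`,
#'   `var_z`, `stat`, `pval` and `decision` in
#'   `x_to_y / y_to_x / inconclusive`.
#' @export
steiger_test <- function(r_x, r_y, n_x, n_y, alpha = 0.05, snp_id = NA_character_) {
  if (n_x <= 3 || n_y <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  z_x <- fisher_z(r_x)
  z_y <- fisher_z(r_y)
  z_g <- z_x - z_y
  var_z <- 1 / (n_x - 3) + 1 / (n_y - 3)
  stat <- z_g / sqrt(var_z)
  pval <- 2 * stats::pnorm(-abs(stat))
  decision <- if (pval > alpha) "inconclusive" else if (z_g > 0) "x_to_y" else "y_to_x"
  structure(list(snp_id = snp_id, z_x = z_x, z_y = z_y, z_g = z_g,
                 var_z = var_z, stat = stat, pval = pval, decision = decision,
                 alpha = alpha),
            class = "steiger_result")
}

#' Aggregate single-SNP Steiger results across instruments
#'
#' Reports the relative frequencies of the three single-SNP decisions
#' ("Steiger-Prop") and a majority-vote overall decision ("Steiger-MV");
#' ties are resolved conservatively as inconclusive.
#'
#' @param results A nonempty list of `steiger_result`s.
#' @return A list of class `steiger_aggregate` with `prop` (named
#'   frequencies summing to 1) and `mv_decision`.
#' @export
steiger_aggregate <- function(results) {
  if (length(results) == 0) stop("empty result list", call. = FALSE)
  decisions <- vapply(results, function(x) x$decision, character(1))
  levs <- c("x_to_y", "y_to_x", "inconclusive")
  counts <- table(factor(decisions, levels = levs))
  prop <- as.numeric(counts) / length(decisions)
  names(prop) <- levs
  top <- max(counts)
  winners <- levs[counts == top]
  mv <- if (length(winners) == 1) winners else "inconclusive"
  structure(list(prop = prop, mv_decision = mv, n = length(decisions)),
            class = "steiger_aggregate")
}
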