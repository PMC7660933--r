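# Shared fixture builders and independent oracles for the test suite.
# Fixtures are generated in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# minimal well-formed summary-stats data frame (default column names)
make_sumstats_df <- function(n_snp = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    SNP = paste0("rs", seq_len(n_snp)),
    CHR = "1",
    BP = seq_len(n_snp) * 1000L,
    A1 = rep(c("A", "C", "G"), length.out = n_snp),
    A2 = rep(c("G", "T", "A"), length.out = n_snp),
    BETA = round(stats::rnorm(n_snp, 0, 0.05), 6),
    SE = round(stats::runif(n_snp, 0.005, 0.02), 6),
    N = 10000L,
    EAF = round(stats::runif(n_snp, 0.1, 0.9), 4),
    P = round(stats::runif(n_snp, 1e-10, 0.05), 12),
    stringsAsFactors = FALSE
  )
}

as_ss <- function(df) {
  names(df) <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "n", "eaf", "pval")
  as_summary_stats(df)
}

# build a correlation_set directly from a correlation vector
make_corrset <- function(r, n, sigma, label = "T") {
  structure(list(trait_label = label,
                 snp_ids = paste0("s", seq_along(r)),
                 r = r, n = n, V = corr_covariance(r, sigma)),
            class = "correlation_set")
}

make_ld <- function(sigma) {
  as_ld_matrix(sigma, paste0("s", seq_len(ncol(sigma))))
}

cs_matrix <- function(m, rho) {
  S <- matrix(rho, m, m); diag(S) <- 1; S
}

# independent two-pass Pearson correlation (oracle for estimate_ld)
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# independent negative log-likelihood of the Egger-family working model,
# built from determinant() and solve() (different route than the package)
egger_nll_oracle <- function(par, rx, ry, v, sigma, VY, nY, VX = NULL, nX = NULL) {
  b0 <- par[1]; K <- par[2]; s0 <- par[3]
  if (s0 < 0) return(1e10)
  S2 <- sigma %*% sigma
  W <- VY / nY + s0 * S2
  if (!is.null(VX)) W <- W + K^2 * VX / nX
  e <- ry - b0 * v - K * rx
  ld <- determinant(W, logarithm = TRUE)
  if (ld$sign <= 0) return(1e10)
  0.5 * as.numeric(ld$modulus) + 0.5 * sum(e * solve(W, e))
}

# multivariate normal draw via chol (for Monte-Carlo oracles)
rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L
}
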