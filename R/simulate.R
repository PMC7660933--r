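#' Define a simulation scenario
#'
#' Bundles every parameter of the generative models behind the two-cohort
#' simulation study. Defaults reproduce the main study conditions:
#' 22 SNPs, cohorts of n = 97,800, per-SNP instrument effects drawn from
#' a standard normal truncated to `|beta| >= 0.5`, a shared confounder
#' `U ~ N(0, 1)` with unit loadings on both traits, error variances of 4,
#' per-SNP direct (pleiotropic) effects `alpha_i ~ N(mu_alpha,
#' sigma_alpha^2)`, and 500 replicates. Synthetic genotypes draw each
#' SNP's allele frequency from `maf_range` and impose block LD (latent
#' Gaussian blocks thresholded to Hardy-Weinberg genotype frequencies);
#' alternatively a real reference panel can be tiled
#' (`genotype_source = "replicate_panel"`).
#'
#' @param m Number of SNPs.
#' @param n Cohort size (each of the two cohorts).
#' @param beta_YX Causal effect of X on Y.
#' @param mu_alpha,sigma_alpha Mean and SD of the per-SNP direct effects
#'   on Y (`0, 0` = no pleiotropy; `0, >0` = balanced; `!=0` =
#'   directional).
#' @param beta_XU,beta_YU Confounder loadings (default 1).
#' @param err_var Error variance of both structural equations (default 4).
#' @param beta_X0,beta_Y0 Intercepts (default 0).
#' @param beta_min Truncation bound for the instrument effects.
#' @param genotype_source `"synthetic"` or `"replicate_panel"`.
#' @param panel_reps Number of panel tilings in replicate mode.
#' @param maf_range Allele-frequency range for synthetic SNPs.
#' @param n_blocks,block_cor Synthetic LD structure: number of contiguous
#'   blocks and the latent within-block correlation.
#' @param n_reps Number of study replicates.
#' @param seed Seed controlling the whole study.
#' @param mode `"unidirectional"`, `"bidirectional"` or `"multivariable"`.
#' @param fix_beta_Xg Draw the instrument effects once and reuse them in
#'   every replicate (single true K per study) instead of redrawing each
#'   replicate.
#' @param beta1,beta2,gamma1,gamma2 Bi-directional mode: causal effects
#'   X to Y (`beta1`) and Y to X (`beta2`), and the per-SNP effects of the
#'   two disjoint instrument sets on their own traits. Requires
#'   `beta1 * beta2 != 1`.
#' @param beta_Ag,beta_AX,beta_XA,beta_AU,beta_YA Multivariable mode:
#'   scale of the SNP effects on the third trait A and the structural
#'   coefficients linking A to X, Y and the confounder.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(m = 22, n = 97800, beta_YX = 0,
                         mu_alpha = 0, sigma_alpha = 0,
                         beta_XU = 1, beta_YU = 1, err_var = 4,
                         beta_X0 = 0, beta_Y0 = 0, beta_min = 0.5,
                         genotype_source = c("synthetic", "replicate_panel"),
                         panel_reps = 200, maf_range = c(0.05, 0.5),
                         n_blocks = 4, block_cor = 0.3,
                         n_reps = 500, seed = 1L,
                         mode = c("unidirectional", "bidirectional",
                                  "multivariable"),
                         fix_beta_Xg = FALSE,
                         beta1 = 0.2, beta2 = 0, gamma1 = 0.5, gamma2 = 0.5,
                         beta_Ag = 0.5, beta_AX = 0, beta_XA = 0,
                         beta_AU = 1, beta_YA = 0) {
  genotype_source <- match.arg(genotype_source)
  mode <- match.arg(mode)
  stopifnot(sigma_alpha >= 0, err_var > 0, m >= 1, n > 3)
  if (mode == "bidirectional" && isTRUE(all.equal(beta1 * beta2, 1))) {
    stop("bidirectional mode requires beta1 * beta2 != 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_scenario")
}

# standard normal truncated to |x| >= bound, by rejection
rtrunc_normal <- function(k, bound) {
  out <- numeric(0)
  while (length(out) < k) {
    x <- stats::rnorm(2 * (k - length(out)) + 8)
    out <- c(out, x[abs(x) >= bound])
  }
  out[seq_len(k)]
}

#' Simulate a genotype dosage matrix
#'
#' Synthetic mode: each SNP's effect-allele frequency is drawn from the
#' scenario's `maf_range`; SNPs are split into contiguous LD blocks, a
#' latent Gaussian with compound-symmetric within-block correlation is
#' drawn per individual, and each SNP's latent value is thresholded at
#' the Hardy-Weinberg genotype-frequency quantiles to produce dosages
#' 0/1/2. Replicate-panel mode tiles the rows of a supplied panel
#' `panel_reps` times (truncating with a warning when the target size is
#' not a multiple of the panel size).
#'
#' @param scn A `sim_scenario`.
#' @param panel A `reference_panel` (or plain dosage matrix), required in
#'   replicate mode.
#' @param maf Optional vector of allele frequencies overriding the draw.
#' @return An `n x m` dosage matrix with SNP ids as column names and the
#'   allele frequencies attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(scn, panel = NULL, maf = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (scn$genotype_source == "replicate_panel") {
    if (is.null(panel)) stop("replicate_panel mode needs a panel", call. = FALSE)
    P <- if (inherits(panel, "reference_panel")) panel$dosages else as.matrix(panel)
    n_target <- scn$panel_reps * nrow(P)
    if (!is.null(scn$n) && scn$n != n_target) {
      n_target <- scn$n
      if (scn$n %% nrow(P) != 0) {
        warning("cohort size is not a multiple of the panel size; ",
                "last tile truncated", call. = FALSE)
      }
    }
    reps <- ceiling(n_target / nrow(P))
    G <- P[rep(seq_len(nrow(P)), reps)[seq_len(n_target)], , drop = FALSE]
    rownames(G) <- NULL
    attr(G, "maf") <- colMeans(G) / 2
    return(G)
  }
  m <- scn$m; n <- scn$n
  if (is.null(maf)) maf <- stats::runif(m, scn$maf_range[1], scn$maf_range[2])
  blocks <- sort(rep_len(seq_len(min(scn$n_blocks, m)), m))
  G <- matrix(0L, n, m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    k <- length(idx)
    rho <- scn$block_cor
    Z <- matrix(stats::rnorm(n * k), n, k)
    if (rho > 0 && k > 1) {
      shared <- stats::rnorm(n)
      Z <- sqrt(rho) * shared + sqrt(1 - rho) * Z
    }
    for (j in seq_len(k)) {
      f <- maf[idx[j]]
      q1 <- stats::qnorm((1 - f)^2)   # P(G = 0)
      q2 <- stats::qnorm(1 - f^2)     # P(G <= 1)
      G[, idx[j]] <- (Z[, j] > q1) + (Z[, j] > q2)
    }
  }
  storage.mode(G) <- "double"
  colnames(G) <- paste0("snp", seq_len(m))
  attr(G, "maf") <- maf
  G
}

#' Simulate trait values from the structural models
#'
#' Unidirectional mode draws the instrument effects (truncated normal),
#' the per-SNP direct effects, the confounder and the errors, and forms
#' `X = beta_X0 + g beta_Xg + beta_XU U + eps_X`,
#' `Y = beta_Y0 + beta_YX X + g alpha + beta_YU U + eps_Y`.
#' Bi-directional mode splits the SNPs into two disjoint instrument sets
#' and generates the traits from the reduced form of the simultaneous
#' system; multivariable mode adds a third trait A with its own SNP
#' effects and confounder loading. The analytic true value of K (and of
#' the companion parameters in the extended modes) is computed from the
#' drawn coefficients and the realized genotype covariance.
#'
#' @param G Dosage matrix from [simulate_genotypes()].
#' @param scn The `sim_scenario`.
#' @param params Optional parameter draw from a previous call (reused so
#'   the two cohorts of a replicate share structural parameters).
#' @return A list with trait vectors (`X`, `Y`, and `A` in multivariable
#'   mode), the drawn `params`, and `true_K` (plus `true_K1`/`true_K2` or
#'   `true_K_YA` in the extended modes).
#' @export
simulate_traits <- function(G, scn, params = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  n <- nrow(G); m <- ncol(G)
  C <- stats::cov(G)
  if (scn$mode == "bidirectional") {
    return(simulate_traits_bidir(G, scn, params, C))
  }
  if (is.null(params)) {
    params <- list(beta_Xg = rtrunc_normal(m, scn$beta_min),
                   alpha = stats::rnorm(m, scn$mu_alpha, scn$sigma_alpha))
    if (scn$mode == "multivariable") {
      params$beta_Ag_vec <- scn$beta_Ag * rtrunc_normal(m, scn$beta_min)
    }
  }
  b <- params$beta_Xg; a <- params$alpha
  U <- stats::rnorm(n)
  epsX <- stats::rnorm(n, sd = sqrt(scn$err_var))
  epsY <- stats::rnorm(n, sd = sqrt(scn$err_var))

  if (scn$mode == "multivariable") {
    ag <- params$beta_Ag_vec
    epsA <- stats::rnorm(n, sd = sqrt(scn$err_var))
    D <- 1 - scn$beta_AX * scn$beta_XA
    if (isTRUE(all.equal(D, 0))) stop("beta_AX * beta_XA must differ from 1", call. = FALSE)
    A0 <- drop(G %*% ag) + scn$beta_AU * U + epsA
    X0 <- drop(G %*% b) + scn$beta_XU * U + epsX
    A <- (A0 + scn$beta_AX * X0) / D
    X <- (X0 + scn$beta_XA * A0) / D
    Y <- scn$beta_Y0 + scn$beta_YX * X + scn$beta_YA * A +
      drop(G %*% a) + scn$beta_YU * U + epsY
    # coefficient vectors of (g, U, eA, eX, eY) for exact variances
    cX <- (b + scn$beta_XA * ag) / D
    cA <- (ag + scn$beta_AX * b) / D
    dX <- (scn$beta_XU + scn$beta_XA * scn$beta_AU) / D
    dA <- (scn$beta_AU + scn$beta_AX * scn$beta_XU) / D
    varX <- drop(t(cX) %*% C %*% cX) + dX^2 +
      scn$err_var * (1 + scn$beta_XA^2) / D^2
    varA <- drop(t(cA) %*% C %*% cA) + dA^2 +
      scn$err_var * (1 + scn$beta_AX^2) / D^2
    cY <- scn$beta_YX * cX + scn$beta_YA * cA + a
    dY <- scn$beta_YX * dX + scn$beta_YA * dA + scn$beta_YU
    # error loadings of Y on (eA, eX, eY)
    eYA <- (scn$beta_YX * scn$beta_XA + scn$beta_YA) / D
    eYX <- (scn$beta_YX + scn$beta_YA * scn$beta_AX) / D
    varY <- drop(t(cY) %*% C %*% cY) + dY^2 +
      scn$err_var * (eYA^2 + eYX^2 + 1)
    return(list(X = X, Y = Y, A = A, params = params,
                true_K = scn$beta_YX * sqrt(varX / varY),
                true_K_YA = scn$beta_YA * sqrt(varA / varY)))
  }

  X <- scn$beta_X0 + drop(G %*% b) + scn$beta_XU * U + epsX
  Y <- scn$beta_Y0 + scn$beta_YX * X + drop(G %*% a) + scn$beta_YU * U + epsY
  varX <- drop(t(b) %*% C %*% b) + scn$beta_XU^2 + scn$err_var
  covXa <- drop(t(b) %*% C %*% a)
  varY <- scn$beta_YX^2 * varX + drop(t(a) %*% C %*% a) +
    2 * scn$beta_YX * covXa + scn$beta_YU^2 + scn$err_var +
    2 * scn$beta_YX * scn$beta_XU * scn$beta_YU
  list(X = X, Y = Y, params = params,
       true_K = scn$beta_YX * sqrt(varX / varY))
}

simulate_traits_bidir <- function(G, scn, params, C) {
  n <- nrow(G); m <- ncol(G)
  if (m < 2) stop("bidirectional mode needs at least 2 SNPs", call. = FALSE)
  if (is.null(params)) {
    g1 <- seq_len(ceiling(m / 2))
    params <- list(g1 = g1, g2 = setdiff(seq_len(m), g1))
  }
  D <- 1 - scn$beta1 * scn$beta2
  w1 <- numeric(m); w1[params$g1] <- scn$gamma1   # effects of g1 on X
  w2 <- numeric(m); w2[params$g2] <- scn$gamma2   # effects of g2 on Y
  U <- stats::rnorm(n)
  e1 <- stats::rnorm(n, sd = sqrt(scn$err_var))
  e2 <- stats::rnorm(n, sd = sqrt(scn$err_var))
  gX <- (w1 + scn$beta2 * w2) / D
  gY <- (w2 + scn$beta1 * w1) / D
  dX <- (scn$beta_XU + scn$beta2 * scn$beta_YU) / D
  dY <- (scn$beta_YU + scn$beta1 * scn$beta_XU) / D
  X <- drop(G %*% gX) + dX * U + (e1 + scn$beta2 * e2) / D
  Y <- drop(G %*% gY) + dY * U + (e2 + scn$beta1 * e1) / D
  varX <- drop(t(gX) %*% C %*% gX) + dX^2 + scn$err_var * (1 + scn$beta2^2) / D^2
  varY <- drop(t(gY) %*% C %*% gY) + dY^2 + scn$err_var * (1 + scn$beta1^2) / D^2
  list(X = X, Y = Y, params = params,
       true_K1 = scn$beta1 * sqrt(varX / varY),
       true_K2 = scn$beta2 * sqrt(varY / varX),
       true_K = scn$beta1 * sqrt(varX / varY))
}

# fast marginal scan given centered genotypes and their sums of squares
marginal_scan_core <- function(Gc, Sxx, y) {
  n <- length(y)
  yc <- y - mean(y)
  Sxy <- drop(crossprod(Gc, yc))
  beta <- Sxy / Sxx
  rss <- pmax(sum(yc^2) - beta * Sxy, 0)
  se <- sqrt(rss / ((n - 2) * Sxx))
  se <- pmax(se, .Machine$double.xmin)  # exact-fit floor
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  list(beta = beta, se = se, pval = p)
}

#' Per-SNP marginal GWAS scan of one trait
#'
#' Simple per-SNP ordinary least squares of the trait on each dosage
#' column: slope, standard error (residual variance with `n - 2` degrees
#' of freedom), two-sided t-based p-value, sample size and empirical
#' effect-allele frequency, assembled into a summary-statistics table.
#' An exact linear fit is handled by flooring the standard error at the
#' smallest positive double.
#'
#' @param G Dosage matrix (individuals by SNPs, column names = SNP ids).
#' @param trait Numeric trait vector.
#' @return A `summary_stats` table with one row per SNP.
#' @export
gwas_scan <- function(G, trait) {
  n <- length(trait)
  if (n <= 2 || n != nrow(G)) stop("need n > 2 trait values matching G rows", call. = FALSE)
  mu <- colMeans(G)
  Gc <- sweep(G, 2, mu)
  Sxx <- colSums(Gc^2)
  if (any(Sxx == 0)) {
    stop("zero-variance SNP(s): ",
         paste(colnames(G)[Sxx == 0], collapse = ", "), call. = FALSE)
  }
  sc <- marginal_scan_core(Gc, Sxx, trait)
  m <- ncol(G)
  ids <- colnames(G) %||% paste0("snp", seq_len(m))
  out <- data.frame(
    snp_id = ids, chrom = "1", pos = seq_len(m),
    effect_allele = "A", other_allele = "G",
    beta = sc$beta, se = sc$se, n = n,
    eaf = pmin(pmax(mu / 2, 1e-6), 1 - 1e-6),
    pval = sc$pval, stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Run a full replicated simulation study
#'
#' Runs `n_reps` replicates of the two-cohort design: structural
#' parameters are drawn per replicate (unless `fix_beta_Xg`), both
#' cohorts share the study's genotype matrix (generated once, mirroring a
#' fixed replicated reference panel) but use independent confounder and
#' error draws; cohort one is scanned for trait X and cohort two for
#' trait Y, the requested estimators are applied in both directions, the
#' per-SNP Steiger tests are aggregated, and the three-outcome decision
#' rule is evaluated per method. Estimator failures in a replicate are
#' recorded and excluded from the summaries.
#'
#' @param scn A `sim_scenario`.
#' @param panel Optional panel for replicate-mode genotypes.
#' @param estimators Subset of `c("ratio", "egger", "gls")` to run.
#' @param steiger Run the per-SNP Steiger tests and their aggregation.
#' @param decisions Evaluate the decision rule (needs both directions;
#'   when `FALSE` only the X-to-Y direction is fitted, roughly halving
#'   the run time).
#' @return A list of class `cd_study`: `summary` (per method: mean, sd of
#'   K estimates, mean SE, decision frequencies), `estimates`
#'   (per-replicate long table), `true_K` per replicate, `n_failed`, and
#'   the scenario.
#' @export
run_study <- function(scn, panel = NULL,
                      estimators = c("ratio", "egger", "gls"),
                      steiger = TRUE, decisions = TRUE) {
  stopifnot(inherits(scn, "sim_scenario"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (!is.null(scn$seed)) set.seed(scn$seed)
  G <- simulate_genotypes(scn, panel)
  ld <- as_ld_matrix(stats::cor(G))
  mu <- colMeans(G)
  Gc <- sweep(G, 2, mu)
  Sxx <- colSums(Gc^2)
  m <- ncol(G); n <- nrow(G)
  ids <- colnames(G)

  fixed_params <- if (scn$fix_beta_Xg) simulate_traits(G, scn)$params else NULL

  rows <- list(); true_K <- numeric(scn$n_reps)
  steiger_mv <- character(scn$n_reps)
  steiger_prop <- matrix(NA_real_, scn$n_reps, 3,
                         dimnames = list(NULL, c("x_to_y", "y_to_x", "inconclusive")))
  n_failed <- 0L

  mk_corrset <- function(sc, label) {
    r <- corr_from_summary(sc$beta, sc$se, n)
    structure(list(trait_label = label, snp_ids = ids, r = as.numeric(r),
                   n = n, V = corr_covariance(r, ld)),
              class = "correlation_set")
  }

  for (rep in seq_len(scn$n_reps)) {
    t1 <- simulate_traits(G, scn, params = fixed_params)
    t2 <- simulate_traits(G, scn, params = t1$params)
    true_K[rep] <- t1$true_K
    res <- tryCatch({
      scX <- marginal_scan_core(Gc, Sxx, t1$X)
      scY <- marginal_scan_core(Gc, Sxx, t2$Y)
      cx <- mk_corrset(scX, "X")
      cy <- mk_corrset(scY, "Y")
      out <- list()
      if ("ratio" %in% estimators) {
        rs <- ratio_system(cx, cy)
        out$ratio <- list(xy = cd_ratio(rs, direction_label = "X->Y"))
      }
      if ("egger" %in% estimators) {
        out$egger <- list(xy = cd_egger(cx, cy, ld, direction_label = "X->Y"))
      }
      if ("gls" %in% estimators) {
        out$gls <- list(xy = cd_gls(cx, cy, ld, direction_label = "X->Y"))
      }
      if (decisions) {
        if ("ratio" %in% estimators) {
          rs_yx <- ratio_system(cy, cx)
          out$ratio$yx <- cd_ratio(rs_yx, direction_label = "Y->X")
        }
        if ("egger" %in% estimators) {
          out$egger$yx <- cd_egger(cy, cx, ld, direction_label = "Y->X")
        }
        if ("gls" %in% estimators) {
          out$gls$yx <- cd_gls(cy, cx, ld, direction_label = "Y->X")
        }
      }
      if (steiger) {
        st <- lapply(seq_len(m), function(i) {
          steiger_test(cx$r[i], cy$r[i], n, n, snp_id = ids[i])
        })
        agg <- steiger_aggregate(st)
        steiger_mv[rep] <- agg$mv_decision
        steiger_prop[rep, ] <- agg$prop
      }
      out
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    for (meth in names(res)) {
      est <- res[[meth]]$xy
      dec <- if (decisions && !is.null(res[[meth]]$yx)) {
        decide(est, res[[meth]]$yx)$outcome
      } else NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        rep = rep, method = meth, K_hat = est$K_hat, se_K = est$se_K,
        ci_lo = est$ci[1], ci_hi = est$ci[2],
        covers0 = ci_covers_zero(est$ci),
        decision = dec, true_K = t1$true_K, stringsAsFactors = FALSE
      )
    }
  }
  estimates <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(estimates, estimates$method), function(d) {
    data.frame(method = d$method[1],
               mean_K = mean(d$K_hat), sd_K = stats::sd(d$K_hat),
               mean_se = mean(d$se_K), mean_true_K = mean(d$true_K),
               n_ok = nrow(d),
               freq_x_to_y = mean(d$decision == "x_to_y"),
               freq_y_to_x = mean(d$decision == "y_to_x"),
               freq_inconclusive = mean(d$decision == "inconclusive"),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = estimates, true_K = true_K,
                 steiger_mv = if (steiger) steiger_mv else NULL,
                 steiger_prop = if (steiger) colMeans(steiger_prop, na.rm = TRUE) else NULL,
                 n_failed = n_failed, scenario = scn),
            class = "cd_study")
}

#' @export
print.cd_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates, m = %d SNPs, n = %d per cohort\n",
              x$scenario$n_reps, x$scenario$m, x$scenario$n))
  cat(sprintf("  mean true K = %.4f; failed replicates: %d\n",
              mean(x$true_K), x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$steiger_prop)) {
    cat("  Steiger-Prop (mean over replicates):",
        paste(sprintf("%s %.3f", names(x$steiger_prop), x$steiger_prop),
              collapse = ", "), "\n")
  }
  invisible(x)
}
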