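test_that("CD-Ratio is the GLS mean: single SNP, constant ratios, optimizer oracle", {
  sig <- matrix(1)
  rs1 <- ratio_system(make_corrset(0.2, 5000, sig, "X"),
                      make_corrset(0.1, 5000, sig, "Y"))
  est1 <- cd_ratio(rs1)
  expect_equal(est1$K_hat, 0.5)
  expect_equal(est1$se_K, sqrt(rs1$V_ratio[1, 1]))
  expect_equal(est1$ci, est1$K_hat + c(-1, 1) * qnorm(0.975) * est1$se_K)

  # constant ratios: GLS returns the constant whatever the weights
  sig3 <- cs_matrix(3, 0.25)
  cx <- make_corrset(c(0.2, 0.1, 0.15), 4000, sig3, "X")
  cyc <- make_corrset(0.37 * cx$r, 4000, sig3, "Y")
  expect_equal(cd_ratio(ratio_system(cx, cyc))$K_hat, 0.37, tolerance = 1e-12)

  # random instances vs brute-force 1-D minimization of the GLS objective
  set.seed(51)
  for (case in 1:5) {
    rx <- runif(3, 0.08, 0.3) * sample(c(-1, 1), 3, TRUE)
    ry <- runif(3, 0.02, 0.2) * sample(c(-1, 1), 3, TRUE)
    rs <- ratio_system(make_corrset(rx, 3000, sig3, "X"),
                       make_corrset(ry, 5000, sig3, "Y"))
    obj <- function(K) {
      e <- rs$ratio - K
      sum(e * solve(rs$V_ratio, e))
    }
    coarse <- optimize(obj, c(-50, 50), tol = 1e-10)$minimum
    K_brute <- optimize(obj, coarse + c(-1e-3, 1e-3), tol = 1e-15)$minimum
    expect_lt(abs(cd_ratio(rs)$K_hat - K_brute), 1e-8)
  }
})

test_that("CD-Egger collapses to intercept-augmented WLS when LD is identity and sigma0 = 0", {
  set.seed(61)
  m <- 8
  sig <- diag(m)
  rx <- runif(m, 0.1, 0.3)
  # exact mean model with heterogeneity far below noise -> sigma0 ~ 0
  ry <- 0.01 + 0.4 * rx
  cx <- make_corrset(rx, 20000, sig, "X")
  cy <- make_corrset(ry, 20000, sig, "Y")
  est <- cd_egger(cx, cy, make_ld(sig))
  w <- 20000 / (1 - ry^2)^2
  fit <- lm(ry ~ rx, weights = w)
  expect_equal(est$b0_hat, unname(coef(fit)[1]), tolerance = 1e-6)
  expect_equal(est$K_hat, unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(est$sigma0_sq, 0, tolerance = 1e-8)
  expect_true(est$converged)
})

test_that("CD-Egger and CD-GLS fixed points match a generic full-likelihood optimizer", {
  # fixed toy instance, m = 4, with real LD and visible dispersion
  sig <- cs_matrix(4, 0.3)
  rx <- c(0.22, -0.15, 0.11, 0.18)
  ry <- c(0.15, 0.02, 0.09, -0.02)
  nX <- 3000; nY <- 2500
  cx <- make_corrset(rx, nX, sig, "X")
  cy <- make_corrset(ry, nY, sig, "Y")
  ld <- make_ld(sig)
  v <- rowSums(sig)

  est_e <- cd_egger(cx, cy, ld)
  oracle_e <- optim(c(0, 0, 0.001), egger_nll_oracle, rx = rx, ry = ry, v = v,
                    sigma = sig, VY = cy$V, nY = nY,
                    control = list(maxit = 5000, reltol = 1e-15))
  oracle_e <- optim(oracle_e$par, egger_nll_oracle, rx = rx, ry = ry, v = v,
                    sigma = sig, VY = cy$V, nY = nY, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(est_e$K_hat, oracle_e$par[2], tolerance = 1e-6)
  expect_equal(est_e$b0_hat, oracle_e$par[1], tolerance = 1e-6)
  expect_equal(est_e$sigma0_sq, oracle_e$par[3], tolerance = 1e-5)

  est_g <- cd_gls(cx, cy, ld)
  oracle_g <- optim(c(0, 0, 0.001), egger_nll_oracle, rx = rx, ry = ry, v = v,
                    sigma = sig, VY = cy$V, nY = nY, VX = cx$V, nX = nX,
                    control = list(maxit = 5000, reltol = 1e-15))
  oracle_g <- optim(oracle_g$par, egger_nll_oracle, rx = rx, ry = ry, v = v,
                    sigma = sig, VY = cy$V, nY = nY, VX = cx$V, nX = nX,
                    method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15,
                                   ndeps = rep(1e-6, 3)))
  oracle_g <- optim(oracle_g$par, egger_nll_oracle, rx = rx, ry = ry, v = v,
                    sigma = sig, VY = cy$V, nY = nY, VX = cx$V, nX = nX,
                    control = list(maxit = 10000, reltol = 1e-15))
  expect_equal(est_g$K_hat, oracle_g$par[2], tolerance = 1e-6)
  expect_equal(est_g$b0_hat, oracle_g$par[1], tolerance = 1e-6)
})

test_that("CD-GLS coincides with CD-Egger when the exposure GWAS noise vanishes", {
  sig <- cs_matrix(5, 0.2)
  set.seed(71)
  rx <- runif(5, 0.1, 0.3)
  ry <- 0.02 + 0.3 * rx + rnorm(5, sd = 0.01)
  cy <- make_corrset(ry, 4000, sig, "Y")
  cx_inf <- make_corrset(rx, 1e12, sig, "X")   # V_X / nX -> 0
  ld <- make_ld(sig)
  e1 <- cd_egger(cx_inf, cy, ld)
  e2 <- cd_gls(cx_inf, cy, ld)
  expect_equal(e2$K_hat, e1$K_hat, tolerance = 1e-8)
  expect_equal(e2$b0_hat, e1$b0_hat, tolerance = 1e-8)
})

test_that("the pleiotropy intercept absorbs most of the directional bias that breaks CD-Ratio", {
  # conditional design: instrument effects fixed across replicates so the
  # directional pleiotropy cannot cancel by sign symmetry; equal allele
  # frequencies keep the random-intercept model exactly correct. Truth is
  # the per-replicate generative value from the variance expansion.
  scn <- sim_scenario(m = 12, n = 20000, beta_YX = 0.2, mu_alpha = 0.4,
                      sigma_alpha = 0.1, maf_range = c(0.3, 0.3),
                      n_reps = 60, seed = 81, fix_beta_Xg = TRUE)
  st <- run_study(scn, estimators = c("ratio", "egger"), steiger = FALSE,
                  decisions = FALSE)
  dr <- st$estimates
  err <- function(meth) {
    d <- dr[dr$method == meth, ]
    d$K_hat - d$true_K
  }
  e_ratio <- err("ratio"); e_egger <- err("egger")
  # CD-Ratio: clearly biased
  expect_gt(abs(mean(e_ratio)), 3 * sd(e_ratio) / sqrt(length(e_ratio)))
  # CD-Egger: bias at most a quarter of CD-Ratio's
  expect_lt(abs(mean(e_egger)), abs(mean(e_ratio)) / 4)
})

test_that("CD-Egger confidence intervals attain nominal coverage under its own model", {
  set.seed(91)
  scn <- sim_scenario(m = 12, n = 20000, beta_YX = 0.2, mu_alpha = 0,
                      sigma_alpha = 0.1, maf_range = c(0.3, 0.3),
                      n_reps = 150, seed = 91)
  st <- run_study(scn, estimators = "egger", steiger = FALSE, decisions = FALSE)
  d <- st$estimates
  cover <- mean(d$ci_lo <= d$true_K & d$true_K <= d$ci_hi)
  mc_se <- sqrt(0.95 * 0.05 / nrow(d))
  expect_lt(abs(cover - 0.95), 3.5 * mc_se)
})

test_that("multivariable CD-Egger nests CD-Egger and books m - 3 degrees of freedom", {
  set.seed(101)
  m <- 10
  sig <- cs_matrix(m, 0.2)
  rx <- runif(m, 0.12, 0.3)
  ra <- runif(m, 0.1, 0.25)          # third trait unrelated to Y given X
  ry <- 0.01 + 0.35 * rx + rnorm(m, sd = 0.015)
  cx <- make_corrset(rx, 30000, sig, "X")
  cy <- make_corrset(ry, 30000, sig, "Y")
  ca <- make_corrset(ra, 30000, sig, "A")
  ld <- make_ld(sig)
  mv <- mv_cd_egger(cx, cy, ca, ld)
  uv <- cd_egger(cx, cy, ld)
  expect_lt(abs(mv$K_hat - uv$K_hat), uv$se_K)
  expect_true(mv$ci_K_YA[1] <= 0 && mv$ci_K_YA[2] >= 0)
  g <- q_egger(cx, cy, ld, mv, ca = ca)
  expect_equal(g$df, m - 3L)
})

test_that("multivariable CD-Egger jointly recovers both causal parameters", {
  set.seed(111)
  scn <- sim_scenario(m = 12, n = 20000, beta_YX = 0.2, beta_YA = 0.3,
                      beta_Ag = 0.7, mu_alpha = 0, sigma_alpha = 0.05,
                      maf_range = c(0.3, 0.3), mode = "multivariable", seed = 111)
  G <- simulate_genotypes(scn)
  ld <- as_ld_matrix(cor(G))
  err_KX <- err_KA <- se_KX <- se_KA <- numeric(40)
  for (b in 1:40) {
    t1 <- simulate_traits(G, scn)
    t2 <- simulate_traits(G, scn, params = t1$params)
    t3 <- simulate_traits(G, scn, params = t1$params)
    cx <- correlation_set(gwas_scan(G, t1$X), ld, "X")
    cy <- correlation_set(gwas_scan(G, t2$Y), ld, "Y")
    ca <- correlation_set(gwas_scan(G, t3$A), ld, "A")
    mv <- mv_cd_egger(cx, cy, ca, ld)
    err_KX[b] <- mv$K_hat - t1$true_K
    err_KA[b] <- mv$K_YA - t1$true_K_YA
  }
  expect_lt(abs(mean(err_KX)), 3 * sd(err_KX) / sqrt(40))
  expect_lt(abs(mean(err_KA)), 3 * sd(err_KA) / sqrt(40))
})

test_that("CD-Ratio is equivariant under joint allele recoding", {
  sig <- cs_matrix(4, 0.3)
  set.seed(121)
  rx <- runif(4, 0.1, 0.3); ry <- 0.4 * rx + rnorm(4, sd = 0.02)
  base <- cd_ratio(ratio_system(make_corrset(rx, 4000, sig, "X"),
                                make_corrset(ry, 6000, sig, "Y")))
  F <- diag(c(-1, 1, -1, 1))
  sig_f <- F %*% sig %*% F
  flip <- cd_ratio(ratio_system(make_corrset(drop(F %*% rx), 4000, sig_f, "X"),
                                make_corrset(drop(F %*% ry), 6000, sig_f, "Y")))
  expect_equal(flip$K_hat, base$K_hat, tolerance = 1e-12)
  expect_equal(flip$se_K, base$se_K, tolerance = 1e-12)
})

test_that("bi-directional CD-Ratio separates no, uni- and bi-directional relationships", {
  run_bidir <- function(beta1, beta2, reps, seed, n = 20000) {
    scn <- sim_scenario(m = 8, n = n, mode = "bidirectional",
                        beta1 = beta1, beta2 = beta2,
                        gamma1 = 0.6, gamma2 = 0.6, seed = seed)
    set.seed(seed)
    G <- simulate_genotypes(scn)
    ld <- as_ld_matrix(cor(G))
    g1 <- paste0("snp", 1:4); g2 <- paste0("snp", 5:8)
    verdicts <- character(reps)
    for (b in seq_len(reps)) {
      t1 <- simulate_traits(G, scn)
      t2 <- simulate_traits(G, scn, params = t1$params)
      cx <- correlation_set(gwas_scan(G, t1$X), ld, "X")
      cy <- correlation_set(gwas_scan(G, t2$Y), ld, "Y")
      sub <- function(cs, ids) {
        idx <- match(ids, cs$snp_ids)
        structure(list(trait_label = cs$trait_label, snp_ids = ids,
                       r = cs$r[idx], n = cs$n,
                       V = cs$V[idx, idx, drop = FALSE]),
                  class = "correlation_set")
      }
      rs1 <- ratio_system(sub(cx, g1), sub(cy, g1))   # X->Y arm
      rs2 <- ratio_system(sub(cy, g2), sub(cx, g2))   # Y->X arm
      verdicts[b] <- bi_cd_ratio(rs1, rs2)$verdict
    }
    verdicts
  }
  v_uni <- run_bidir(0.2, 0, reps = 40, seed = 131)
  expect_gt(mean(v_uni == "x_to_y"), 0.7)
  v_null <- run_bidir(0, 0, reps = 60, seed = 132)
  p_none <- mean(v_null == "none")
  expect_lt(abs(p_none - 0.95^2), 3 * sqrt(0.95^2 * (1 - 0.95^2) / 60) + 0.02)
  v_bi <- run_bidir(0.3, 0.3, reps = 40, seed = 133)
  expect_gt(mean(v_bi == "bidirectional"), 0.6)
  # power grows with sample size: smaller n should not beat larger n badly
  expect_error(bi_cd_ratio(
    ratio_system(make_corrset(0.2, 100, matrix(1), "X"),
                 make_corrset(0.1, 100, matrix(1), "Y")),
    ratio_system(make_corrset(0.2, 100, matrix(1), "Y"),
                 make_corrset(0.1, 100, matrix(1), "X"))), "disjoint")
})
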