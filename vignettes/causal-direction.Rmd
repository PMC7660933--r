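---
title: "Inferring causal direction from GWAS summary statistics with correlation ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring causal direction from GWAS summary statistics with correlation ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmr)
```

## The problem and the estimand

Two-sample Mendelian randomization uses genetic variants as instruments
to probe whether an exposure $X$ causally affects an outcome $Y$.
Usually the direction of the putative effect is assumed; `cdmr`
addresses the harder question of inferring both the *existence* and the
*direction* of a causal relationship, from nothing but two independent
GWAS summary datasets and a reference panel for linkage disequilibrium
(LD).

Under a linear structural model with a hidden confounder $U$,

$$X = \beta_{X0} + \beta_{Xg}\, g + \beta_{XU} U + \epsilon_X, \qquad
  Y = \beta_{Y0} + \beta_{YX} X + \beta_{YU} U + \epsilon_Y,$$

the population correlations of any valid instrument $g$ with the two
traits satisfy

$$\frac{\rho_{Yg}}{\rho_{Xg}} \;=\; \beta_{YX}\sqrt{\frac{\mathrm{var}(X)}{\mathrm{var}(Y)}} \;\equiv\; K_{YX},$$

a constant that does not depend on which instrument is used. Three
facts make $K_{YX}$ a useful estimand:

1. $K_{YX} = 0$ exactly when $\beta_{YX} = 0$, so testing $K_{YX}=0$
   tests the existence of a causal effect in that direction;
2. under the **key condition** $\mathrm{var}(Y) > \beta_{YX}^2\,\mathrm{var}(X)$
   (automatic without confounding; plausible whenever the variance
   explained between the traits is modest, say $R^2 < 0.2$), the true
   direction has $|K| < 1$ while the reverse-direction parameter has
   magnitude $> 1$;
3. being common to all instruments, per-SNP estimates of $K$ can be
   pooled for power — including across SNPs in LD.

Sample correlations are recovered from marginal GWAS output through the
exact identity
$r = \hat\beta_M \big/ \sqrt{\hat\beta_M^2 + (n-2)\,\mathrm{se}^2}$,
implemented in `corr_from_summary()`.

## Distribution theory

For $m$ SNPs and one trait, $\sqrt{n}(r - \rho)$ is asymptotically
normal with a covariance determined by the SNP–trait and SNP–SNP
correlations. We use the classical normal-theory covariance of two
correlations sharing one variable (the Pearson–Filon / Olkin–Steiger
family),

$$V_{ij} = \rho_{ij}\,(1 - r_i^2 - r_j^2) - \tfrac12 r_i r_j (1 - r_i^2 - r_j^2 - \rho_{ij}^2),$$

with plug-in values: the sample $r$ for SNP–trait and the reference
panel's dosage correlation for SNP–SNP (`corr_covariance()`,
`estimate_ld()`). The covariance of the elementwise ratio vector
$r_{Yg}/r_{Xg}$ follows by the delta method with a block-diagonal
two-cohort structure (`ratio_system()`); a tolerance
`tau_den = 1e-4` rejects near-zero denominators, where the delta method
breaks down — the instrument-selection rule (significance for *both*
traits) keeps real analyses away from this regime.

This asymptotic machinery is verified against Monte-Carlo oracles in
the test suite (20,000-replicate covariance comparison at $m=3$,
$n=2000$). It is exact for jointly normal data; for discrete genotype
dosages the negative excess kurtosis of a binomial(2, f) variable makes
the plug-in covariance about 2–3% conservative, so the goodness-of-fit
tests below run slightly below their nominal size on genotype data —
the calibration tests therefore use Gaussian instruments, where the
chi-squared null is the mathematically exact claim.

## Estimators

**CD-Ratio** (`cd_ratio()`): exact one-parameter GLS on the ratio
vector, $\hat K = (\mathbf 1' V^{-1}\text{ratio})/(\mathbf 1' V^{-1}\mathbf 1)$ —
the precision-weighted mean of the per-SNP ratios. Valid when all
instruments are valid; no iteration.

**CD-Egger** (`cd_egger()`): when SNPs have direct (horizontally
pleiotropic) effects on the outcome, the outcome correlations gain a
per-SNP offset. Treating the direct effects as i.i.d.
$N(\mu_\alpha, \sigma_\alpha^2)$ draws (independent of instrument
strengths — the InSIDE assumption) and writing $\Sigma$ for the LD
matrix of standardized dosages, the offsets have mean proportional to
$v = \Sigma\mathbf 1$ and covariance proportional to the matrix square
$\Sigma^2 = \Sigma\Sigma$. The working model is

$$r_{Yg} = b_0\, v + K\, r_{Xg} + \varepsilon,\qquad
  \varepsilon \sim N(0,\; V_{Yg}/n_Y + \sigma_0^2\,\Sigma^2),$$

fit by alternating exact GLS for $(b_0, K)$ with a bounded 1-D
maximum-likelihood update of $\sigma_0^2 \in [0, 10]$ (convergence when
the largest parameter change falls below $10^{-8}$, at most 200
sweeps). The scheme is coordinate ascent on the Gaussian likelihood, so
it agrees with a generic joint optimizer — the test suite enforces
agreement to $10^{-6}$. $b_0$ estimates the mean pleiotropic effect
(on the $1/\sqrt{\mathrm{var}(Y)}$ scale); a nonzero $\hat b_0$ is
itself evidence of directional pleiotropy.

**CD-GLS** (`cd_gls()`): CD-Egger ignores the sampling noise of
$r_{Xg}$. CD-GLS propagates it through the slope with the working
covariance $W(K) = V_{Yg}/n_Y + \sigma_0^2 \Sigma^2 + K^2 V_{Xg}/n_X$,
a reconstruction we flag as such. Because the GLS step holds $W$ fixed,
a plain fixed point is not exactly the stationary point of the
working-model likelihood; the implementation therefore runs the
alternating scheme to get close and then maximizes the 2-D profile
likelihood in $(K, \sigma_0^2)$ (with $b_0$ profiled out in closed
form), so the reported fit is the working-model ML and matches the
generic-optimizer oracle. With large exposure GWAS the two estimators
coincide, which is also how they behave in practice.

**MV-CD-Egger** (`mv_cd_egger()`): adds a third, measured trait $A$
(e.g. a candidate confounder) with design $[v, r_{Xg}, r_{Ag}]$,
reporting $K_{YX}$ adjusted for $K_{YA}$.

**bi-CD-Ratio** (`bi_cd_ratio()`): with disjoint instrument sets for
each trait, CD-Ratio runs on each arm; an arm supports an effect when
its CI lies inside $[-1,0)\cup(0,1]$ and supports none when the CI
covers 0, so the pair classifies none / one-way / bi-directional
relationships.

One caveat shared with MR-Egger: the Egger-family estimators are not
invariant to allele recoding of individual SNPs, because the i.i.d.
direct-effect model fixes an allele orientation through
$v = \Sigma \mathbf 1$. CD-Ratio is fully recoding-invariant (tested).
Analyses should use a consistent (e.g. harmonized effect-allele)
orientation throughout, which `harmonize()` enforces.

## Decision rules and goodness of fit

With both directional estimates in hand (`decide()`), the direction
$X \to Y$ is concluded when the $X\to Y$ interval lies entirely inside
$[-1, 0)$ or $(0, 1]$ *and* the $Y\to X$ interval lies entirely outside
$[-1, 1]$; the mirror rule gives $Y \to X$; anything else is
inconclusive. Interval endpoints exactly at $0$ or $\pm 1$ count as
covering — the conservative resolution of a measure-zero ambiguity.
Separately, an existence flag reads zero-coverage: both CIs covering 0
supports no causal relationship, neither covering 0 supports one.

`q_ratio()` forms the residual quadratic form of the ratio fit,
asymptotically $\chi^2_{m-1}$ when all instruments are valid; rejection
signals pleiotropy (or other invalidity). `q_egger()` does the same for
the Egger-family fit with $W$ rebuilt at the fitted $\sigma_0^2$ and
$m-2$ reference degrees of freedom ($m-3$ for the multivariable
model). Two calibration facts, both verified by simulation in the test
suite and worth knowing when reading p-values:

* conditioning on one fixed genotype matrix (as when a small panel is
  tiled to cohort size) removes the genotype-sampling component of the
  correlation variance, making both tests mildly conservative;
* because $\sigma_0^2$ is estimated from only $m$ residuals, plugging
  $\hat\sigma_0^2$ into $W$ partially standardizes the quadratic form:
  whenever pleiotropy dispersion is non-negligible the null of
  `q_egger()` is *compressed* relative to $\chi^2_{m-2}$ (its type I
  error stays controlled — below nominal — but mid-range p-values
  should not be over-interpreted). $\chi^2_{m-1}$ for `q_ratio()` is
  accurate.

`key_condition_check()` reconstructs per-SNP trait variances from the
marginal model,
$\mathrm{var}(T) = \hat\beta_M^2\,\mathrm{var}(g) + (n-2)\,\mathrm{se}^2\,\mathrm{var}(g)$
with $\mathrm{var}(g) = 2\,\mathrm{eaf}(1-\mathrm{eaf})$, and compares
the distribution of $\mathrm{var}(Y)/\mathrm{var}(X)$ with
$\hat\beta_{YX}^2$ to probe the key condition from summary data alone.

## Instrument selection

`select_instruments()` mirrors the selection used in large biobank
analyses: keep SNPs with $p < 5\times 10^{-8}$ for *both* traits,
assign them to predefined approximately LD-independent loci, order
within locus by the sum of the two p-value ranks, then greedily prune
so all pairwise absolute correlations stay below 0.8. Ties in the rank
sum are broken by the smaller of the two p-values and then genomic
position — the procedure is deterministic. Ranks are computed within
locus; a global-ranking mode exists but is not the default.

## The simulator

`sim_scenario()` / `run_study()` reproduce the two-cohort simulation
design used to validate the method. Defaults are the main study
conditions: $m = 22$ SNPs, two cohorts of $n = 97{,}800$, instrument
effects drawn from a standard normal truncated to $|\beta| \ge 0.5$
(by rejection sampling), confounder $U \sim N(0,1)$ with unit loadings
on both traits, error variances of 4, per-SNP direct effects
$\alpha_i \sim N(\mu_\alpha, \sigma_\alpha^2)$, and 500 replicates.
Design choices worth stating explicitly:

* **Genotypes.** The reference design tiles a small real panel to
  cohort size; since the actual panel SNPs are not published, the
  default generates synthetic dosages: allele frequencies uniform on
  $(0.05, 0.5)$, four contiguous LD blocks with latent within-block
  correlation 0.3, latent Gaussians thresholded at the Hardy–Weinberg
  genotype-frequency quantiles. The genotype matrix is generated once
  per study and shared by both cohorts (mirroring the tiled-panel
  design); all trait-level randomness is redrawn per replicate and per
  cohort, so the two summary datasets are conditionally independent.
  Consequences: only *bias-type* quantities are comparable across
  genotype configurations (SDs and SEs depend on the unpublished SNPs),
  and empirical correlation variances are conditional rather than
  unconditional — see the calibration remarks above.
* **Cohort structure.** Two independent cohorts of equal size are
  scanned, one per trait (two-sample design); structural parameters
  ($\beta_{Xg}$, $\alpha$) are population quantities and are shared by
  both cohorts within a replicate.
* **Instrument effects** are redrawn each replicate by default (so the
  true $K$ varies slightly across replicates and sign-symmetry makes
  several conditional biases cancel marginally); `fix_beta_Xg = TRUE`
  fixes one draw for conditional experiments.
* **Truth.** Each replicate's true $K$ is computed analytically from
  the drawn coefficients and the realized genotype covariance via the
  variance expansion of the structural model (including pleiotropy and
  LD cross terms), not assumed.

What the simulator does *not* emulate: binary traits (all models are
linear), overlapping cohorts, instruments correlated with the hidden
confounder (a regime in which Egger-family methods are biased and which
this package deliberately does not attempt to solve), strand/allele
ambiguity, and imputation noise. Passing tests therefore demonstrate
correctness of the estimators under their stated models, not robustness
to these additional real-data complications.

Problem sizes in the shipped tests were chosen to keep the full suite
runnable on a laptop: the three headline replicated studies run at the
full $22 \times 97{,}800 \times 500$ configuration, while property
checks (coverage, calibration, recovery) use cohorts of 5,000–30,000
and tens to hundreds of replicates with three-Monte-Carlo-SE
tolerances.

## Numerical choices

* Plug-in covariances are symmetrized and eigenvalue-clipped at zero
  (tolerance $10^{-10}$) before inversion; genuinely singular systems
  raise an error advising pruning rather than silently regularizing.
* $\sigma_0^2$ is estimated by maximum likelihood (a 1-D bounded search
  per sweep), initialized at 0, bounded in $[0, 10]$, with an explicit
  snap to 0 when the boundary is at least as likely — whether the
  original formulation used ML, REML or moments is not documented, so
  ML was chosen and is pinned by the full-likelihood oracle tests.
* Standard errors come from the GLS information matrix at the final
  working covariance, matching normal-based confidence intervals; no
  degrees-of-freedom inflation is applied.
* The weak-denominator guard, PSD repair tolerance, and convergence
  thresholds are exported function arguments with the defaults above.

## Limitations

Everything rests on large-$n$, small-$m$ asymptotics for sample
correlations; hundreds of instruments or very high mutual LD will
degrade both the normal approximation and the conditioning of the
$m \times m$ covariances (prune first). Selection of instruments on
the same data used for estimation can bias results under directional
pleiotropy (mild under the both-traits significance rule). The Steiger
test is included for comparison; it presumes a causal relationship
exists and will confidently orient pure confounding — the replicated
studies in the test suite demonstrate exactly this failure mode, and
its small-sample behavior under the folded (absolute-value) transform
makes its nominal variance conservative under the double null.
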