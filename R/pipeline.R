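#' End-to-end causal-direction analysis of two summary datasets
#'
#' Ties the pipeline together: harmonize the two tables (and LD) to a
#' shared allele-aligned SNP set, optionally select instruments
#' (significance in both traits, locus assignment, rank-sum ordering, LD
#' pruning), build the correlation sets, fit the requested estimators in
#' both directions, run the goodness-of-fit tests, and apply the decision
#' rule per method.
#'
#' @param statsX,statsY `summary_stats` tables for the two traits.
#' @param ld An `ld_matrix` covering the candidate SNPs.
#' @param loci Optional `locus_table`; when supplied, instruments are
#'   selected with [select_instruments()] before estimation.
#' @param methods Subset of `c("ratio", "egger", "gls")`.
#' @param alpha CI level is `1 - alpha`.
#' @param p_cut,cor_cut Selection thresholds (see [select_instruments()]).
#' @param labels Length-2 character vector naming the traits.
#' @return A list of class `cd_analysis` with per-method `estimates`
#'   (both directions), `gof`, `decisions`, the `selection` result (if
#'   any), the harmonized pair, and `snp_ids` used.
#' @export
cd_analysis <- function(statsX, statsY, ld, loci = NULL,
                        methods = c("ratio", "egger", "gls"),
                        alpha = 0.05, p_cut = 5e-8, cor_cut = 0.8,
                        labels = c("X", "Y")) {
  methods <- match.arg(methods, several.ok = TRUE)
  hp <- harmonize(statsX, statsY, ld)
  selection <- NULL
  if (!is.null(loci)) {
    selection <- select_instruments(hp$statsX, hp$statsY, hp$ld, loci,
                                    p_cut = p_cut, cor_cut = cor_cut)
    keep <- match(selection$kept, hp$snp_ids)
    hp$snp_ids <- hp$snp_ids[keep]
    hp$statsX <- hp$statsX[keep, , drop = FALSE]
    hp$statsY <- hp$statsY[keep, , drop = FALSE]
    hp$ld <- subset_ld(hp$ld, hp$snp_ids)
  }
  cx <- correlation_set(hp$statsX, hp$ld, trait_label = labels[1])
  cy <- correlation_set(hp$statsY, hp$ld, trait_label = labels[2])
  lab_xy <- paste0(labels[1], "->", labels[2])
  lab_yx <- paste0(labels[2], "->", labels[1])

  estimates <- list(); gof <- list(); decisions <- list()
  if ("ratio" %in% methods) {
    rs_xy <- ratio_system(cx, cy)
    rs_yx <- ratio_system(cy, cx)
    e_xy <- cd_ratio(rs_xy, alpha = alpha, direction_label = lab_xy)
    e_yx <- cd_ratio(rs_yx, alpha = alpha, direction_label = lab_yx)
    estimates$ratio <- list(xy = e_xy, yx = e_yx)
    if (rs_xy$m >= 2) {
      gof$ratio <- list(xy = q_ratio(rs_xy, e_xy), yx = q_ratio(rs_yx, e_yx))
    }
    decisions$ratio <- decide(e_xy, e_yx)
  }
  for (meth in intersect(methods, c("egger", "gls"))) {
    fit <- if (meth == "egger") cd_egger else cd_gls
    e_xy <- fit(cx, cy, hp$ld, alpha = alpha, direction_label = lab_xy)
    e_yx <- fit(cy, cx, hp$ld, alpha = alpha, direction_label = lab_yx)
    estimates[[meth]] <- list(xy = e_xy, yx = e_yx)
    gof[[meth]] <- list(xy = q_egger(cx, cy, hp$ld, e_xy),
                        yx = q_egger(cy, cx, hp$ld, e_yx))
    decisions[[meth]] <- decide(e_xy, e_yx)
  }
  structure(list(estimates = estimates, gof = gof, decisions = decisions,
                 selection = selection, harmonized = hp,
                 snp_ids = hp$snp_ids, alpha = alpha, labels = labels),
            class = "cd_analysis")
}

#' @export
print.cd_analysis <- function(x, ...) {
  cat(sprintf("Causal-direction analysis: %s vs %s, %d SNPs\n",
              x$labels[1], x$labels[2], length(x$snp_ids)))
  for (meth in names(x$estimates)) {
    e <- x$estimates[[meth]]
    cat(sprintf("%-6s %s: K = %7.4f [%7.4f, %7.4f]   %s: K = %7.4f [%7.4f, %7.4f]",
                toupper(meth), e$xy$direction_label, e$xy$K_hat,
                e$xy$ci[1], e$xy$ci[2], e$yx$direction_label, e$yx$K_hat,
                e$yx$ci[1], e$yx$ci[2]))
    if (!is.null(x$gof[[meth]])) {
      cat(sprintf("   Q = %.1f (p = %.3g)", x$gof[[meth]]$xy$Q,
                  x$gof[[meth]]$xy$pval))
    }
    cat(sprintf("   -> %s\n", x$decisions[[meth]]$outcome))
  }
  invisible(x)
}

#' Serialize an analysis to a flat report table
#'
#' One row per method and direction with the estimate, CI, pleiotropy
#' intercept, goodness-of-fit statistic and the decision; written as TSV
#' (and optionally JSON when the `jsonlite` package is available).
#'
#' @param x A `cd_analysis`.
#' @param path Output path for the TSV report; `paste0(path, ".json")`
#'   additionally written when `json = TRUE`.
#' @param json Also write a JSON rendering.
#' @return The report data frame, invisibly.
#' @export
write_cd_report <- function(x, path, json = FALSE) {
  stopifnot(inherits(x, "cd_analysis"))
  rows <- list()
  for (meth in names(x$estimates)) {
    for (dir in c("xy", "yx")) {
      e <- x$estimates[[meth]][[dir]]
      g <- x$gof[[meth]][[dir]]
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, direction = e$direction_label,
        K_hat = e$K_hat, se_K = e$se_K, ci_lo = e$ci[1], ci_hi = e$ci[2],
        b0_hat = e$b0_hat %||% NA_real_, se_b0 = e$se_b0 %||% NA_real_,
        sigma0_sq = e$sigma0_sq %||% NA_real_,
        Q = if (is.null(g)) NA_real_ else g$Q,
        Q_df = if (is.null(g)) NA_integer_ else g$df,
        Q_pval = if (is.null(g)) NA_real_ else g$pval,
        m_used = e$m_used,
        decision = x$decisions[[meth]]$outcome,
        existence = x$decisions[[meth]]$existence_flag,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
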