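#' Select instruments by joint significance, rank sum, and LD pruning
#'
#' Reproduces the locus-wise selection procedure for instruments that are
#' significant for both traits:
#' \enumerate{
#'   \item restrict to SNPs with `p < p_cut` in both tables;
#'   \item assign each SNP to a predefined (approximately LD-independent)
#'     locus by chromosome and position; SNPs outside every locus are
#'     dropped with reason `no_locus`;
#'   \item within each locus, rank the SNPs' p-values ascending separately
#'     per trait, sum the two ranks to `I_i`, and reorder ascending in
#'     `I_i` (ties broken by the smaller of the two p-values, then
#'     position);
#'   \item greedily keep SNP i iff its absolute correlation with every
#'     already-kept SNP in the locus is below `cor_cut`; pruned SNPs are
#'     logged with the blocking SNP.
#' }
#'
#' @param statsX,statsY Harmonized `summary_stats` tables.
#' @param ld An `ld_matrix` covering the candidate SNPs.
#' @param loci A `locus_table` (see [read_loci()]).
#' @param p_cut Significance cutoff in both traits (default `5e-8`).
#' @param cor_cut Pairwise absolute-correlation bound (default 0.8,
#'   strict `<`).
#' @param global_ranks Rank p-values across all significant SNPs instead
#'   of within locus (non-default alternative reading of the procedure).
#' @return A list of class `selection_result` with `kept` (ordered SNP
#'   ids), `dropped` (data frame of snp_id, reason), `locus_of` and
#'   `rank_sum` named vectors.
#' @export
select_instruments <- function(statsX, statsY, ld, loci, p_cut = 5e-8,
                               cor_cut = 0.8, global_ranks = FALSE) {
  shared <- intersect(statsX$snp_id, statsY$snp_id)
  X <- statsX[match(shared, statsX$snp_id), , drop = FALSE]
  Y <- statsY[match(shared, statsY$snp_id), , drop = FALSE]
  sig <- X$pval < p_cut & Y$pval < p_cut
  ids <- shared[sig]
  if (length(ids) == 0) stop("no SNPs significant for both traits", call. = FALSE)
  X <- X[sig, , drop = FALSE]; Y <- Y[sig, , drop = FALSE]

  locus_of <- rep(NA_integer_, length(ids))
  for (k in seq_len(nrow(loci))) {
    hit <- X$chrom == loci$chrom[k] & X$pos >= loci$start[k] & X$pos <= loci$end[k]
    locus_of[hit & is.na(locus_of)] <- loci$locus_id[k]
  }
  dropped_id <- ids[is.na(locus_of)]
  dropped_reason <- rep("no_locus", length(dropped_id))
  in_locus <- !is.na(locus_of)
  ids <- ids[in_locus]; X <- X[in_locus, , drop = FALSE]
  Y <- Y[in_locus, , drop = FALSE]; locus_of <- locus_of[in_locus]
  if (length(ids) == 0) stop("no significant SNPs fall inside any locus", call. = FALSE)

  if (global_ranks) {
    Ii <- rank(X$pval, ties.method = "min") + rank(Y$pval, ties.method = "min")
  } else {
    Ii <- rep(NA_real_, length(ids))
    for (loc in unique(locus_of)) {
      idx <- which(locus_of == loc)
      Ii[idx] <- rank(X$pval[idx], ties.method = "min") +
        rank(Y$pval[idx], ties.method = "min")
    }
  }
  names(Ii) <- ids
  names(locus_of) <- ids

  kept <- character(0)
  for (loc in unique(locus_of)) {
    idx <- which(locus_of == loc)
    # ascending rank sum; ties by smaller min p-value, then position
    ord <- idx[order(Ii[idx], pmin(X$pval[idx], Y$pval[idx]), X$pos[idx])]
    kept_here <- character(0)
    for (i in ord) {
      if (length(kept_here) == 0) {
        kept_here <- ids[i]
        next
      }
      cors <- abs(ld$sigma[ids[i], kept_here])
      if (all(cors < cor_cut)) {
        kept_here <- c(kept_here, ids[i])
      } else {
        blocker <- kept_here[which.max(cors)]
        dropped_id <- c(dropped_id, ids[i])
        dropped_reason <- c(dropped_reason, paste0("pruned_by:", blocker))
      }
    }
    kept <- c(kept, kept_here)
  }
  structure(list(
    kept = kept,
    dropped = data.frame(snp_id = dropped_id, reason = dropped_reason,
                         stringsAsFactors = FALSE),
    locus_of = locus_of,
    rank_sum = Ii
  ), class = "selection_result")
}
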