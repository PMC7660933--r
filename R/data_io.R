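#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited text file with a header into a
#' validated summary-statistics table. Column names are mapped through
#' `column_map`, whose defaults follow the common GWAS dialect
#' (`SNP, CHR, BP, A1, A2, BETA, SE, N, EAF, P`). `A1` is the effect
#' allele: `BETA` is the marginal per-allele-dose effect of `A1`.
#'
#' Rows violating the table invariants (`se > 0`, `n > 3`,
#' `0 < eaf < 1`, `0 < p <= 1`, non-missing mandatory fields, duplicated
#' SNP ids) are dropped with a warning; the number of dropped rows is
#' attached as attribute `"n_dropped"`.
#'
#' @param path Path to the text file.
#' @param column_map Named character vector mapping canonical field names
#'   (`snp_id, chrom, pos, effect_allele, other_allele, beta, se, n, eaf,
#'   pval`) to the column names in the file. Unspecified entries fall back
#'   to the defaults.
#' @return A `data.frame` of class `summary_stats` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `n`,
#'   `eaf`, `pval`.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- data.frame(
    snp_id = as.character(raw[[map["snp_id"]]]),
    chrom = as.character(raw[[map["chrom"]]]),
    pos = as.integer(raw[[map["pos"]]]),
    effect_allele = toupper(as.character(raw[[map["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[map["other_allele"]]])),
    beta = as.numeric(raw[[map["beta"]]]),
    se = as.numeric(raw[[map["se"]]]),
    n = as.integer(raw[[map["n"]]]),
    eaf = as.numeric(raw[[map["eaf"]]]),
    pval = as.numeric(raw[[map["pval"]]]),
    stringsAsFactors = FALSE
  )
  as_summary_stats(x)
}

default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", beta = "BETA", se = "SE", n = "N", eaf = "EAF",
    pval = "P")
}

#' Validate a data frame as a summary-statistics table
#'
#' Enforces the table invariants, dropping offending rows with a warning.
#'
#' @param x A data frame with the canonical summary-statistics columns.
#' @return A validated `summary_stats` data frame; attribute `"n_dropped"`
#'   counts removed rows.
#' @export
as_summary_stats <- function(x) {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "n", "eaf", "pval")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- !is.na(x$snp_id) & !is.na(x$beta) & !is.na(x$se) & !is.na(x$n) &
    x$se > 0 & x$n > 3 &
    (is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1)) &
    (is.na(x$pval) | (x$pval > 0 & x$pval <= 1))
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(x$snp_id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(n_dropped, " row(s) dropped for violating summary-stats invariants",
            call. = FALSE)
  }
  x <- x[ok, required, drop = FALSE]
  if (nrow(x) == 0) stop("no valid rows after filtering", call. = FALSE)
  rownames(x) <- NULL
  class(x) <- c("summary_stats", "data.frame")
  attr(x, "n_dropped") <- n_dropped
  x
}

#' Write a summary-statistics table
#'
#' Writes the canonical columns back to a tab-delimited file using the
#' default column names, at full double precision so that a read/write
#' round trip reproduces every numeric field exactly.
#'
#' @param x A `summary_stats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  map <- default_column_map()
  out <- x[, names(map), drop = FALSE]
  names(out) <- unname(map)
  for (col in c("BETA", "SE", "EAF", "P")) {
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                         scientific = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference genotype panel
#'
#' Loads individual-level genotypes used only to estimate SNP-SNP
#' correlations (LD). Two formats are accepted: a tab-delimited dosage
#' matrix (first column the sample id, remaining columns one SNP each,
#' dosages in `[0, 2]`) or a VCF 4.x file whose `GT` field is converted to
#' an ALT-allele dosage (requires the `vcfR` package). Missing dosages are
#' mean-imputed per SNP; monomorphic SNPs are rejected.
#'
#' @param path Path to the panel file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A list of class `reference_panel` with `sample_ids`, `snp_ids`
#'   and the individuals-by-SNPs `dosages` matrix.
#' @export
read_reference_panel <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF panels requires the 'vcfR' package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), gt_to_dosage)
    dosages <- t(dos)
    snp_ids <- rownames(dos)
    if (any(is.na(snp_ids)) || any(snp_ids == ".")) {
      fix <- vcfR::getFIX(v)
      snp_ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
    }
    colnames(dosages) <- snp_ids
    sample_ids <- rownames(dosages)
  } else {
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    sample_ids <- as.character(raw[[1]])
    dosages <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(dosages) <- "double"
  }
  as_reference_panel(dosages, sample_ids = sample_ids)
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  sum(alleles != "0" & alleles != ".")
}

#' Construct a reference panel from a dosage matrix
#'
#' @param dosages Individuals-by-SNPs numeric matrix with dosages in
#'   `[0, 2]`; column names are the SNP ids.
#' @param sample_ids Optional sample identifiers.
#' @return A `reference_panel` object.
#' @export
as_reference_panel <- function(dosages, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(nrow(dosages)))
  # mean-impute missing dosages per SNP (deterministic, standard)
  for (j in seq_len(ncol(dosages))) {
    nas <- is.na(dosages[, j])
    if (any(nas)) dosages[nas, j] <- mean(dosages[!nas, j])
  }
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0 | is.na(v))) {
    stop("monomorphic SNP column(s) in panel: ",
         paste(colnames(dosages)[v == 0 | is.na(v)], collapse = ", "),
         call. = FALSE)
  }
  structure(list(sample_ids = sample_ids,
                 snp_ids = colnames(dosages),
                 dosages = dosages),
            class = "reference_panel")
}

#' Estimate an LD matrix from a reference panel
#'
#' Pairwise Pearson correlation of dosage columns, optionally shrunk
#' toward the identity, `(1 - lambda) * S + lambda * I`, for
#' near-singular loci.
#'
#' @param panel A `reference_panel`.
#' @param snp_ids SNPs to include (default: all, in panel order).
#' @param lambda Shrinkage weight toward the identity in `[0, 1]`
#'   (default 0, no shrinkage).
#' @return An `ld_matrix` object: list with `snp_ids` and the correlation
#'   matrix `sigma` (unit diagonal).
#' @export
estimate_ld <- function(panel, snp_ids = NULL, lambda = 0) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(snp_ids)) snp_ids <- panel$snp_ids
  missing_ids <- setdiff(snp_ids, panel$snp_ids)
  if (length(missing_ids)) {
    stop("SNP(s) not in panel: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  G <- panel$dosages[, snp_ids, drop = FALSE]
  v <- apply(G, 2, stats::var)
  if (any(v == 0)) {
    stop("monomorphic SNP(s): ", paste(snp_ids[v == 0], collapse = ", "),
         call. = FALSE)
  }
  sigma <- stats::cor(G)
  if (lambda > 0) sigma <- (1 - lambda) * sigma + lambda * diag(nrow(sigma))
  diag(sigma) <- 1
  as_ld_matrix(sigma, snp_ids)
}

#' Construct an LD matrix object
#'
#' @param sigma Symmetric SNP-by-SNP correlation matrix, unit diagonal.
#' @param snp_ids SNP identifiers in matrix order.
#' @return An `ld_matrix` object.
#' @export
as_ld_matrix <- function(sigma, snp_ids = NULL) {
  sigma <- as.matrix(sigma)
  if (is.null(snp_ids)) snp_ids <- colnames(sigma) %||% paste0("snp", seq_len(ncol(sigma)))
  stopifnot(nrow(sigma) == ncol(sigma), length(snp_ids) == ncol(sigma))
  sigma <- (sigma + t(sigma)) / 2
  if (max(abs(diag(sigma) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  diag(sigma) <- 1
  if (max(abs(sigma)) > 1 + 1e-8) stop("LD entries must be in [-1, 1]", call. = FALSE)
  dimnames(sigma) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, sigma = sigma), class = "ld_matrix")
}

#' Subset an LD matrix to a set of SNPs in a given order
#' @param ld An `ld_matrix`.
#' @param snp_ids SNPs to keep, in the desired order.
#' @return An `ld_matrix` on `snp_ids`.
#' @export
subset_ld <- function(ld, snp_ids) {
  stopifnot(inherits(ld, "ld_matrix"))
  missing_ids <- setdiff(snp_ids, ld$snp_ids)
  if (length(missing_ids)) {
    stop("SNP(s) not in LD matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  as_ld_matrix(ld$sigma[snp_ids, snp_ids, drop = FALSE], snp_ids)
}

PALINDROMIC <- c("AT", "TA", "CG", "GC")

#' Harmonize two summary datasets (and an LD matrix) to shared SNPs
#'
#' Restricts both tables to their shared SNP ids; where the effect/other
#' alleles are swapped between the datasets, the second dataset's `beta`
#' is negated and its `eaf` replaced by `1 - eaf`. SNPs whose allele pairs
#' cannot be reconciled are dropped, as are palindromic (A/T, C/G) SNPs by
#' default (no frequency-based strand inference is attempted). Every
#' action is recorded in `flip_log`.
#'
#' @param statsX,statsY `summary_stats` tables for the two traits.
#' @param ld Optional `ld_matrix`; subset to the retained SNPs.
#' @param strict_palindromes Drop palindromic SNPs (default `TRUE`).
#' @return A list of class `harmonized_pair` with `snp_ids`, `statsX`,
#'   `statsY`, `ld` and `flip_log` (data frame of snp_id, action).
#' @export
harmonize <- function(statsX, statsY, ld = NULL, strict_palindromes = TRUE) {
  shared <- intersect(statsX$snp_id, statsY$snp_id)
  if (!is.null(ld)) shared <- intersect(shared, ld$snp_ids)
  if (length(shared) == 0) stop("no shared SNPs between datasets", call. = FALSE)
  X <- statsX[match(shared, statsX$snp_id), , drop = FALSE]
  Y <- statsY[match(shared, statsY$snp_id), , drop = FALSE]
  log_id <- character(0); log_act <- character(0)
  keep <- logical(length(shared))
  for (i in seq_along(shared)) {
    ax <- c(X$effect_allele[i], X$other_allele[i])
    ay <- c(Y$effect_allele[i], Y$other_allele[i])
    if (strict_palindromes && paste0(ax[1], ax[2]) %in% PALINDROMIC) {
      log_id <- c(log_id, shared[i]); log_act <- c(log_act, "drop_palindromic")
      next
    }
    if (identical(ax, ay)) {
      keep[i] <- TRUE
    } else if (identical(ax, rev(ay))) {
      Y$beta[i] <- -Y$beta[i]
      Y$eaf[i] <- 1 - Y$eaf[i]
      tmp <- Y$effect_allele[i]
      Y$effect_allele[i] <- Y$other_allele[i]
      Y$other_allele[i] <- tmp
      keep[i] <- TRUE
      log_id <- c(log_id, shared[i]); log_act <- c(log_act, "flip_beta_Y")
    } else {
      log_id <- c(log_id, shared[i]); log_act <- c(log_act, "drop_allele_mismatch")
    }
  }
  kept <- shared[keep]
  if (length(kept) == 0) stop("no SNPs retained after harmonization", call. = FALSE)
  X <- X[keep, , drop = FALSE]; rownames(X) <- NULL
  Y <- Y[keep, , drop = FALSE]; rownames(Y) <- NULL
  class(X) <- class(Y) <- c("summary_stats", "data.frame")
  structure(list(
    snp_ids = kept,
    statsX = X,
    statsY = Y,
    ld = if (is.null(ld)) NULL else subset_ld(ld, kept),
    flip_log = data.frame(snp_id = log_id, action = log_act,
                          stringsAsFactors = FALSE)
  ), class = "harmonized_pair")
}

#' Read a locus-definition table from a BED file
#'
#' BED input is 0-based half-open; intervals are converted to 1-based
#' inclusive coordinates. An optional fourth column supplies locus ids,
#' otherwise loci are numbered in file order.
#'
#' @param path Path to a BED file (no header).
#' @return A data frame of class `locus_table` with `locus_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @export
read_loci <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    locus_id = if (ncol(raw) >= 4) as.integer(raw[[4]]) else seq_len(nrow(raw)),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("locus_table", "data.frame")
  out
}
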