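# Quantification-table I/O and downstream gene-level utilities.

.quant_columns <- c("transcript_id", "gene_id",
                    "exon_tpm_unlabeled", "intron_tpm_unlabeled",
                    "exon_tpm_labeled", "intron_tpm_labeled")

#' Read a per-transcript quantification table
#'
#' Expects a UTF-8, tab-separated file with header columns
#' `transcript_id`, `gene_id`, `exon_tpm_unlabeled`,
#' `intron_tpm_unlabeled`, `exon_tpm_labeled`, `intron_tpm_labeled`.
#' Abundances must be length-normalised (TPM or equivalent) so that
#' intronic and exonic values are proportional to molecule counts; the
#' package never converts raw counts. Missing columns are a hard error;
#' rows with non-finite or negative abundances are rejected with their
#' line numbers.
#'
#' @param path file path.
#' @return data.frame of validated transcript records.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(.quant_columns, names(df))
  if (length(missing)) {
    stop("quantification table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, .quant_columns]
  num_cols <- .quant_columns[3:6]
  for (cn in num_cols) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  if (nrow(df)) {
    bad <- rowSums(sapply(df[num_cols],
                          function(v) !is.finite(v) | v < 0)) > 0
    if (any(bad)) {
      stop("malformed abundance values on row(s): ",
           paste(utils::head(which(bad), 20), collapse = ", "),
           " (data line numbers, excluding header)", call. = FALSE)
    }
  }
  df
}

#' Observed intron-to-exon ratios
#'
#' `r_u = iota_u / chi_u` and `r_l = iota_l / chi_l` — the estimator's
#' only per-transcript input besides the pulse duration. Ratios are `NA`
#' where the exonic abundance is zero (undefined, later rejected).
#'
#' @param records quantification data.frame.
#' @return data.frame with columns `r_u`, `r_l`.
#' @export
compute_ratios <- function(records) {
  data.frame(
    r_u = ifelse(records$exon_tpm_unlabeled > 0,
                 records$intron_tpm_unlabeled / records$exon_tpm_unlabeled,
                 NA_real_),
    r_l = ifelse(records$exon_tpm_labeled > 0,
                 records$intron_tpm_labeled / records$exon_tpm_labeled,
                 NA_real_))
}

#' Filter transcripts by mean exonic expression
#'
#' Keeps records whose mean exonic abundance across the two pools,
#' `(chi_u + chi_l)/2`, strictly exceeds the threshold. Ratio estimates
#' degrade at low coverage, so analyses typically gate at 1 TPM for
#' transcript-level work and ~100 TPM for cross-study rate comparisons.
#'
#' @param records quantification data.frame.
#' @param min_exon_tpm threshold (same units as the table).
#' @return filtered data.frame.
#' @export
filter_by_expression <- function(records, min_exon_tpm) {
  keep <- (records$exon_tpm_unlabeled + records$exon_tpm_labeled) / 2 >
    min_exon_tpm
  records[keep, , drop = FALSE]
}

#' Aggregate transcript degradation rates to genes
#'
#' Expression-weighted mean of the per-transcript degradation rates:
#' \eqn{\gamma_{gene} = \sum_i w_i \gamma_i / \sum_i w_i} with
#' \eqn{w_i = (\chi_{u,i} + \chi_{l,i})/2}, over non-rejected transcripts
#' only. Also carries the expression-weighted mean `r_l` per gene, used
#' as a reliability weight (`1 - r_l`) in cross-study comparisons.
#'
#' @param results output of [estimate_rates()].
#' @param records the matching quantification data.frame (joined by
#'   `transcript_id`).
#' @return data.frame with `gene_id`, `gamma_gene`, `mean_r_l`,
#'   `weight_total`, `n_transcripts`.
#' @export
aggregate_genes <- function(results, records) {
  m <- match(results$transcript_id, records$transcript_id)
  if (any(is.na(m))) {
    stop("results contain transcript_ids absent from records",
         call. = FALSE)
  }
  w <- (records$exon_tpm_unlabeled[m] + records$exon_tpm_labeled[m]) / 2
  ok <- !startsWith(results$status, "rejected") &
    is.finite(results$gamma) & w > 0
  if (!any(ok)) {
    return(data.frame(gene_id = character(0), gamma_gene = numeric(0),
                      mean_r_l = numeric(0), weight_total = numeric(0),
                      n_transcripts = integer(0)))
  }
  g <- results$gene_id[ok]
  wg <- w[ok]
  sw <- tapply(wg, g, sum)
  swg <- tapply(wg * results$gamma[ok], g, sum)
  swr <- tapply(wg * results$r_l[ok], g, sum)
  cnt <- tapply(wg, g, length)
  ids <- names(sw)
  data.frame(gene_id = ids,
             gamma_gene = as.numeric(swg[ids] / sw[ids]),
             mean_r_l = as.numeric(swr[ids] / sw[ids]),
             weight_total = as.numeric(sw[ids]),
             n_transcripts = as.integer(cnt[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with observation weights: weighted means are
#' subtracted, and the weighted covariance is divided by the product of
#' weighted standard deviations. With equal weights this is the ordinary
#' Pearson correlation. A (near-)zero weighted variance makes the
#' correlation ill-defined; `NA` is returned with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, not all zero.
#' @return correlation in `[-1, 1]`, or `NA` if degenerate.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    stop("x, y and w must have the same length", call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= .Machine$double.eps * max(1, mx^2) ||
      vy <= .Machine$double.eps * max(1, my^2)) {
    warning("weighted variance is (near) zero; correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

#' Abundance / responsiveness frame
#'
#' Rotates the (log synthesis, log degradation) plane into a functionally
#' interpretable frame: `abundance = log(alpha) - log(gamma)` is the log
#' steady-state mRNA level, and `responsiveness = log(alpha) + log(gamma)`
#' measures how fast that steady state is reached. Genes in dynamic
#' processes sit high on the responsiveness axis at unchanged abundance.
#'
#' @param results output of [estimate_rates()] (non-rejected rows are
#'   used; rejected rows yield `NA`).
#' @return data.frame with `transcript_id`, `abundance`,
#'   `responsiveness`.
#' @export
responsiveness_frame <- function(results) {
  ok <- !startsWith(results$status, "rejected") &
    is.finite(results$alpha) & is.finite(results$gamma) &
    results$alpha > 0 & results$gamma > 0
  data.frame(
    transcript_id = results$transcript_id,
    abundance = ifelse(ok, log(results$alpha) - log(results$gamma),
                       NA_real_),
    responsiveness = ifelse(ok, log(results$alpha) + log(results$gamma),
                            NA_real_),
    stringsAsFactors = FALSE)
}

#' Write transcript- and gene-level rate tables
#'
#' Writes `<prefix>_transcript_rates.tsv` with the fixed column order
#' `transcript_id, gene_id, status, k, alpha, beta, gamma, r_u, r_l,
#' n_roots` and, when a gene table is supplied,
#' `<prefix>_gene_rates.tsv`. Missing values are encoded as `NA`.
#'
#' @param results output of [estimate_rates()].
#' @param gene_table optional output of [aggregate_genes()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_rates_table <- function(results, gene_table = NULL, prefix) {
  cols <- c("transcript_id", "gene_id", "status", "k", "alpha", "beta",
            "gamma", "r_u", "r_l", "n_roots")
  tpath <- paste0(prefix, "_transcript_rates.tsv")
  utils::write.table(results[, cols], tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  paths <- list(transcripts = tpath)
  if (!is.null(gene_table)) {
    gpath <- paste0(prefix, "_gene_rates.tsv")
    utils::write.table(gene_table, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths$genes <- gpath
  }
  invisible(paths)
}
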