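#' Aggregate transcript counts to gene (isogroup) counts
#'
#' Counts of all transcripts belonging to one isogroup are summed to give a
#' single count per gene and sample; per-sample totals are conserved exactly.
#'
#' @param transcript_counts Integer matrix, transcripts x samples, with
#'   transcript ids as rownames.
#' @param transcript_map Data frame with columns `transcript_id`, `gene_id`
#'   (as from [generate_transcript_map()]), or a named character vector
#'   mapping transcript to gene.
#' @return Integer matrix, genes x samples.
#' @export
aggregate_isoforms <- function(transcript_counts, transcript_map) {
  if (is.data.frame(transcript_map))
    map <- stats::setNames(transcript_map$gene_id, transcript_map$transcript_id)
  else map <- transcript_map
  tx <- rownames(transcript_counts)
  missing <- setdiff(tx, names(map))
  if (length(missing))
    stop("missing mapping for transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  out <- rowsum(transcript_counts, group = map[tx], reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Filter genes by counts-per-million support
#'
#' Keeps genes whose CPM is at least `min_cpm` in at least `min_samples`
#' samples. The default `(0, 0)` keeps every gene.
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_cpm Non-negative CPM threshold.
#' @param min_samples Non-negative number of samples required to pass.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 0, min_samples = 0L) {
  if (min_cpm <= 0 || min_samples <= 0) return(counts)
  lib <- colSums(counts)
  cpm <- sweep(counts, 2L, lib / 1e6, `/`)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values normalisation factors
#'
#' Computes between-sample scaling factors from trimmed, precision-weighted
#' mean log2 ratios of library-size-scaled count proportions against a
#' reference sample. The reference is the sample whose upper-quartile count
#' fraction is closest to the mean upper-quartile fraction. Genes with a zero
#' count in either sample are excluded; the most extreme `logratio_trim` of
#' M-values and `sum_trim` of A-values are trimmed on each side; weights are
#' inverse approximate binomial variances. Factors are rescaled so their
#' geometric mean is exactly 1.
#'
#' @param counts Integer matrix, genes x samples (>= 2 samples, every column
#'   sum positive).
#' @param logratio_trim Fraction of M-values trimmed each side (default 0.3).
#' @param sum_trim Fraction of A-values trimmed each side (default 0.05).
#' @return Data frame with columns `sample_id`, `library_size`, `tmm_factor`
#'   and `effective_library_size` (= `library_size * tmm_factor`).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2L)
    stop("TMM needs at least two samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("invalid input: sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "), call. = FALSE)
  uq <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  data.frame(
    sample_id = colnames(counts),
    library_size = lib,
    tmm_factor = f,
    effective_library_size = lib * f,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# One observation/reference TMM factor (unscaled).
.tmm_pair <- function(obs, ref, lib_obs, lib_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- as.numeric(obs[keep]); ref <- as.numeric(ref[keep])
  if (!length(obs)) return(1)
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  # delta-method variance of M under binomial sampling
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel)) return(1)
  2^(sum(m[sel] / v[sel]) / sum(1 / v[sel]))
}
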