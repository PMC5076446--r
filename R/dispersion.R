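#' Estimate per-gene NB dispersion by combining trended and tagwise estimates
#'
#' Dispersion (phi, with `var = mu + phi * mu^2`) is estimated in three
#' steps. (1) A method-of-moments estimate per gene from the pooled
#' within-treatment-group variance of library-size-normalised counts.
#' (2) A trend: binned medians of the method-of-moments estimates against
#' mean normalised abundance, linearly interpolated. (3) A tagwise estimate:
#' a per-gene Cox-Reid adjusted profile maximum likelihood (negative
#' binomial likelihood at the group-wise fitted means with the
#' `-0.5 * log det(X'WX)` adjustment, maximised on a log-dispersion grid)
#' shrunk toward the trend by a log-scale weighted mean with weights equal
#' to the residual degrees of freedom and `prior_df`. `prior_df = Inf`
#' returns the trend itself.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Data frame with `sample_id`, `caste`, `age` covering all
#'   columns of `counts`; treatment groups are the caste x age cells.
#' @param factors Normalisation table from [tmm_factors()].
#' @param prior_df Shrinkage weight toward the trend (default 10).
#' @param bins Number of abundance bins for the trend (default 20).
#' @return Data frame with columns `gene_id`, `mom`, `trend`, `tagwise`
#'   (all dispersions >= 0).
#' @export
estimate_dispersion <- function(counts, design, factors, prior_df = 10,
                                bins = 20L) {
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("design does not cover all samples in 'counts'", call. = FALSE)
  group <- interaction(design$caste, design$age, drop = TRUE)
  n <- ncol(counts)
  k <- nlevels(group)
  df_res <- n - k
  if (df_res < 2L)
    stop("insufficient replication: need >= 2 residual degrees of freedom",
         call. = FALSE)
  eff <- factors$effective_library_size[match(colnames(counts),
                                              factors$sample_id)]
  sf <- eff / mean(eff)
  q <- sweep(counts, 2L, sf, `/`)

  # pooled within-group moments on the normalised scale
  idx <- split(seq_len(n), group)
  gm <- vapply(idx, function(i) rowMeans(q[, i, drop = FALSE]),
               numeric(nrow(q)))
  ss <- Reduce(`+`, lapply(seq_along(idx), function(g) {
    i <- idx[[g]]
    rowSums((q[, i, drop = FALSE] - gm[, g])^2)
  }))
  s2 <- ss / df_res
  mu_bar <- rowMeans(q)
  mom <- ifelse(mu_bar > 0, pmax(0, (s2 - mu_bar) / mu_bar^2), 0)

  trend <- .dispersion_trend(mu_bar, mom, bins)

  # profile likelihood on a log10 grid, means from closed-form group fits
  mle <- .dispersion_profile_mle(counts, eff, group)

  tagwise <- if (is.infinite(prior_df)) trend
  else exp((df_res * log(pmax(mle, 1e-8)) + prior_df * log(pmax(trend, 1e-8))) /
             (df_res + prior_df))
  data.frame(gene_id = rownames(counts), mom = mom, trend = pmax(trend, 0),
             tagwise = pmax(tagwise, 0), row.names = NULL,
             stringsAsFactors = FALSE)
}

.dispersion_trend <- function(mu_bar, mom, bins) {
  ok <- mu_bar > 0
  if (sum(ok) < 2L) return(rep(stats::median(mom), length(mom)))
  lx <- log(mu_bar[ok])
  nb <- max(1L, min(bins, floor(sum(ok) / 10)))
  cut_idx <- as.integer(cut(rank(lx, ties.method = "first"),
                            breaks = nb, labels = FALSE))
  centers <- tapply(lx, cut_idx, stats::median)
  meds <- tapply(mom[ok], cut_idx, stats::median)
  fit <- if (length(centers) >= 2L)
    stats::approx(centers, meds, xout = log(pmax(mu_bar, min(mu_bar[ok]))),
                  rule = 2)$y
  else rep(meds[[1]], length(mu_bar))
  pmax(fit, 0)
}

# Per-gene Cox-Reid adjusted profile MLE of phi on a log grid, with
# group-wise Poisson-fitted means (mu_hat_gj = eff_j * sum_group(y) /
# sum_group(eff), the closed-form MLE of a group-mean log-link model, shared
# across phi values). The adjustment -0.5 * log det(X'WX) reduces the
# downward bias of the plain profile MLE that makes downstream LRTs
# anticonservative; for the group-means design X'WX is diagonal by group,
# so the determinant is a product of group-wise weight sums.
.dispersion_profile_mle <- function(counts, eff, group,
                                    grid = 10^seq(-8, 0.7, length.out = 45)) {
  idx <- split(seq_len(ncol(counts)), group)
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (i in idx) {
    rate <- rowSums(counts[, i, drop = FALSE]) / sum(eff[i])
    mu[, i] <- outer(rate, eff[i])
  }
  y <- counts
  mu_pos <- pmax(mu, 1e-10)
  apl <- matrix(-Inf, nrow(counts), length(grid))
  for (g in seq_along(grid)) {
    phi <- grid[g]
    ll <- rowSums(stats::dnbinom(y, size = 1 / phi, mu = mu_pos, log = TRUE))
    w <- mu_pos / (1 + phi * mu_pos)
    adj <- 0
    for (i in idx)
      adj <- adj + log(pmax(rowSums(w[, i, drop = FALSE]), 1e-300))
    apl[, g] <- ll - 0.5 * adj
  }
  best_idx <- max.col(apl, ties.method = "first")
  grid[best_idx]
}
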