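#' Signed P-value score
#'
#' The ranking statistic `s = c * (1 - P)`, where `c` is the direction sign
#' of the per-gene contrast (`-1` queen-biased, `+1` worker-biased) and `P`
#' its P-value. Strongly queen-biased genes score near -1, strongly
#' worker-biased genes near +1, and genes with `P` close to 1 land near 0,
#' i.e. the middle of the ranked list.
#'
#' @param c Integer sign(s) in `{-1, +1}`.
#' @param P P-value(s) in `(0, 1]`.
#' @return `c * (1 - P)`, vectorised.
#' @examples
#' signed_score(-1, 0.02)  # -0.98
#' @export
signed_score <- function(c, P) {
  if (!all(c %in% c(-1, 1)))
    stop("'c' must be -1 or +1", call. = FALSE)
  if (any(!is.finite(P)) || any(P <= 0) || any(P > 1))
    stop("invalid probability: P must lie in (0, 1]", call. = FALSE)
  c * (1 - P)
}

#' Rank all genes by signed P-value
#'
#' Orders genes by ascending signed score so that queen-biased genes with
#' small P-values sit at the low end, worker-biased genes with small
#' P-values at the high end, and unbiased genes in the middle. Ties are
#' broken deterministically by gene identifier (lexicographic), or randomly
#' under a seed if `tie_break = "random"`.
#'
#' @param scores Data frame with columns `gene_id`, `c`, `P` (an `s` column
#'   is recomputed if absent).
#' @param tie_break `"id"` (default) or `"random"`.
#' @param seed Seed used only for `tie_break = "random"`.
#' @return An object of class `"ranked_list"`: a data frame with columns
#'   `gene_id`, `s` in rank order, with attribute `N`.
#' @export
rank_genes <- function(scores, tie_break = c("id", "random"), seed = 1L) {
  tie_break <- match.arg(tie_break)
  if (anyDuplicated(scores$gene_id))
    stop("invalid input: duplicate gene_id(s)", call. = FALSE)
  s <- if ("s" %in% names(scores)) scores$s
  else signed_score(scores$c, scores$P)
  ord <- if (tie_break == "id") order(s, scores$gene_id)
  else .with_seed(.derive_seed(seed, "resample"),
                  order(s, sample.int(length(s))))
  out <- data.frame(gene_id = scores$gene_id[ord], s = s[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "N") <- nrow(out)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' GSEA running sum along a ranked list
#'
#' Walks the ranked list and adds 1 for each gene in the set and subtracts
#' `n / (N - n)` otherwise (`n` set members among `N` genes). The sum is 0
#' after the last gene by construction; the enrichment score is the maximum
#' absolute value the sum attains.
#'
#' @param ranked A `"ranked_list"` from [rank_genes()].
#' @param gene_set Character vector of member gene ids (or a list with a
#'   `genes` element); all members must appear in the ranked list and
#'   `1 <= n < N`.
#' @return Numeric vector of length `N` of partial sums.
#' @export
running_sum <- function(ranked, gene_set) {
  members <- if (is.list(gene_set) && !is.null(gene_set$genes)) gene_set$genes
  else gene_set
  members <- unique(members)
  N <- nrow(ranked)
  n <- length(members)
  if (n < 1L || n >= N)
    stop("degenerate set: need 1 <= n < N", call. = FALSE)
  missing <- setdiff(members, ranked$gene_id)
  if (length(missing))
    stop("missing gene(s) from ranked list: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  # accumulate in integer-scaled space (+ (N-n) per member, -n otherwise):
  # partial sums times (N-n) are integers, so the arithmetic is exact and
  # the final value is exactly zero
  inc <- rep(-n, N)
  inc[ranked$gene_id %in% members] <- N - n
  cumsum(inc) / (N - n)
}

#' Enrichment score of a running sum
#'
#' @param running Numeric vector of running-sum values (non-empty).
#' @param labels Length-2 labels for the two list extremes, low end first
#'   (default `c("queen", "worker")`: the ranked list puts queen-biased
#'   genes at the low end).
#' @return List with `ES` (max absolute running-sum value), `argmax_rank`
#'   (first position attaining it) and `direction` (`labels[1]` when the
#'   running sum at the maximum is positive, i.e. members cluster toward the
#'   low/queen end; `labels[2]` otherwise).
#' @export
enrichment_score <- function(running, labels = c("queen", "worker")) {
  if (!length(running))
    stop("invalid input: empty running sum", call. = FALSE)
  a <- abs(running)
  argmax <- which.max(a)   # first position attaining the maximum
  list(ES = a[argmax], argmax_rank = argmax,
       direction = if (running[argmax] >= 0) labels[1] else labels[2])
}

#' Resampling null distribution of the enrichment score
#'
#' Draws `B` random sets of `n` distinct genes uniformly from the ranked
#' list and records the enrichment score of each, giving the null against
#' which the observed score is judged.
#'
#' @param ranked A `"ranked_list"` (only its length matters) or a single
#'   integer `N`.
#' @param n Set size, `1 <= n < N`.
#' @param B Number of resampling iterations (default 5000).
#' @param seed Integer seed.
#' @return Numeric vector of `B` null enrichment scores (all >= 0).
#' @export
resample_null <- function(ranked, n, B = 5000L, seed = 1L) {
  N <- if (is.numeric(ranked) && length(ranked) == 1L) as.integer(ranked)
  else nrow(ranked)
  if (n < 1L || n >= N)
    stop("degenerate set: need 1 <= n < N", call. = FALSE)
  if (B < 1L) stop("'B' must be >= 1", call. = FALSE)
  .with_seed(.derive_seed(seed, "resample"), {
    vapply(seq_len(B), function(b)
      .es_from_ranks(sort.int(sample.int(N, n)), N), numeric(1))
  })
}

# Closed-form ES from sorted member positions. Between member positions the
# running sum decreases linearly, so its extremes occur at member positions
# (value k - (r_k - k) * n/(N-n) after the k-th member) and one position
# before each member (that value minus 1). Evaluated in the same
# integer-scaled space as running_sum(), so the result is exact. O(n).
.es_from_ranks <- function(r, N) {
  n <- length(r)
  k <- seq_len(n)
  s_at <- k * (N - n) - (r - k) * n
  max(abs(c(s_at, s_at - (N - n)))) / (N - n)
}

#' Empirical P-value of an observed enrichment score
#'
#' Computes `(k + 1) / (B + 1)` with `k` the number of null scores at least
#' as large as the observed one. The add-one convention never returns 0 and
#' is a valid test; when `k = 0` the result equals the resolution floor
#' `1 / (B + 1)` and is conventionally reported as `P < 1/B`.
#'
#' @param ES Observed enrichment score.
#' @param null_ES Numeric vector of null scores (non-empty).
#' @return The empirical P-value, with attributes `k` and `B`.
#' @export
empirical_p <- function(ES, null_ES) {
  if (!length(null_ES))
    stop("invalid input: empty null distribution", call. = FALSE)
  k <- sum(null_ES >= ES)
  B <- length(null_ES)
  structure((k + 1) / (B + 1), k = k, B = B)
}

#' Gene Set Enrichment Analysis on a signed-P ranked list
#'
#' The full test: rank genes by `c * (1 - P)`, accumulate the running sum
#' (+1 for set members, `-n/(N-n)` otherwise), take the enrichment score
#' `ES = max |running sum|`, build a null distribution by resampling random
#' sets of the same size (default 5000 iterations), and report the
#' empirical P-value `(k + 1)/(B + 1)`.
#'
#' @param scores Data frame with columns `gene_id`, `c`, `P`, or a
#'   `"ranked_list"` from [rank_genes()].
#' @param gene_set Character vector of member ids, or a list with `name` and
#'   `genes`.
#' @param B Resampling iterations (default 5000).
#' @param seed Integer seed for the resampling null.
#' @param labels Direction labels, low extreme first (see
#'   [enrichment_score()]); use `c("up_with_age", "down_with_age")` for
#'   age-contrast rankings.
#' @return Object of class `"gsea_result"`: list with `set_name`, `n`, `N`,
#'   `ES`, `direction`, `argmax_rank`, `running_sum`, `member_ranks`,
#'   `null_ES`, `k`, `B`, `empirical_P`.
#' @examples
#' scores <- data.frame(gene_id = sprintf("g%03d", 1:100),
#'                      c = rep(c(-1, 1), 50),
#'                      P = runif(100, 0.01, 1))
#' res <- gsea_test(scores, sample(scores$gene_id, 10), B = 200, seed = 1)
#' print(res)
#' @export
gsea_test <- function(scores, gene_set, B = 5000L, seed = 1L,
                      labels = c("queen", "worker")) {
  ranked <- if (inherits(scores, "ranked_list")) scores else rank_genes(scores)
  set_name <- if (is.list(gene_set) && !is.null(gene_set$name)) gene_set$name
  else "gene_set"
  members <- if (is.list(gene_set) && !is.null(gene_set$genes)) gene_set$genes
  else gene_set
  members <- unique(members)
  rs <- running_sum(ranked, members)
  es <- enrichment_score(rs, labels = labels)
  null_ES <- resample_null(ranked, length(members), B = B, seed = seed)
  p <- empirical_p(es$ES, null_ES)
  structure(list(
    set_name = set_name,
    n = length(members),
    N = nrow(ranked),
    ES = es$ES,
    direction = es$direction,
    argmax_rank = es$argmax_rank,
    running_sum = rs,
    member_ranks = which(ranked$gene_id %in% members),
    null_ES = null_ES,
    k = attr(p, "k"),
    B = attr(p, "B"),
    empirical_P = as.numeric(p)
  ), class = "gsea_result")
}

#' Render an empirical P-value the way resampling tests report it
#' @param x A `"gsea_result"`.
#' @return `"P < 1/B"` when no null score reached the observed one,
#'   otherwise `"P = (k+1)/(B+1)"` formatted.
#' @export
format_empirical_p <- function(x) {
  if (x$k == 0) sprintf("P < %.4g", 1 / x$B)
  else sprintf("P = %.4g", x$empirical_P)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("Gene Set Enrichment Analysis (running-sum, resampling null)\n")
  cat(sprintf("  set: %s (n = %d of N = %d genes)\n", x$set_name, x$n, x$N))
  cat(sprintf("  ES = %.3f at rank %d, direction: %s\n",
              x$ES, x$argmax_rank, x$direction))
  cat(sprintf("  %s  (k = %d of B = %d null scores >= ES)\n",
              format_empirical_p(x), x$k, x$B))
  invisible(x)
}

#' Plot a GSEA result: running sum and member positions
#'
#' Draws the ranked list as a horizontal axis with one vertical tick per set
#' member and the running-sum trace above it, the classic ranked-bar layout.
#'
#' @param x A `"gsea_result"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gsea_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_len(x$N), x$running_sum, type = "l",
                 xlab = "", ylab = "running sum",
                 main = sprintf("%s: ES = %.2f, %s", x$set_name, x$ES,
                                format_empirical_p(x)), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$argmax_rank, x$running_sum[x$argmax_rank], pch = 19)
  graphics::plot(NULL, xlim = c(1, x$N), ylim = c(0, 1), xlab = "rank",
                 ylab = "", yaxt = "n")
  graphics::segments(x$member_ranks, 0, x$member_ranks, 1)
  invisible(x)
}
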