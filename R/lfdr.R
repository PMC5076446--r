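#' Local false discovery rate from a P-value ensemble
#'
#' Fits the two-group model `f(p) = eta0 * 1 + (1 - eta0) * f1(p)` to the
#' observed P-values and returns `lfdr(p) = min(1, eta0 / f(p))`, the
#' posterior probability that a test with that P-value is null. The null
#' proportion `eta0` is estimated from the upper tail of the P distribution
#' (Storey's estimator at `lambda`, capped at 1); the marginal density `f`
#' is the Grenander estimator, the non-increasing density given by the slope
#' of the least concave majorant of the empirical distribution function.
#' Outputs are clamped to `[0, 1]` and made non-decreasing in `p` by a final
#' isotonic pass.
#'
#' @param pvalues Numeric vector of at least 20 P-values in `[0, 1]`.
#' @param lambda Tuning point of the null-proportion estimator (default 0.5).
#' @return Numeric vector of lfdr values, one per input, in input order.
#' @examples
#' p <- c(runif(190), runif(10, 0, 1e-4))
#' range(estimate_lfdr(p))
#' @export
estimate_lfdr <- function(pvalues, lambda = 0.5) {
  m <- length(pvalues)
  if (m < 20L)
    stop("too few tests: lfdr estimation needs >= 20 P-values", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("invalid probability: P-values must lie in [0, 1]", call. = FALSE)
  eta0 <- min(1, mean(pvalues > lambda) / (1 - lambda))

  f_hat <- .grenander_density(pvalues)
  lfdr <- pmin(1, eta0 / pmax(f_hat(pvalues), 1e-300))
  ord <- order(pvalues)
  lfdr[ord] <- cummax(lfdr[ord])
  lfdr
}

# Grenander estimator: slopes of the least concave majorant of the ECDF on
# [0, 1], computed by weighted pool-adjacent-violators on the raw slopes.
# Returns a step function of p.
.grenander_density <- function(p) {
  m <- length(p)
  x <- sort(unique(p))
  Fx <- cumsum(tabulate(match(sort(p), x), nbins = length(x))) / m
  if (x[1] > 0) { x <- c(0, x); Fx <- c(0, Fx) } else Fx <- c(Fx)
  if (x[length(x)] < 1) { x <- c(x, 1); Fx <- c(Fx, 1) }
  dx <- pmax(diff(x), 1e-12)
  dF <- Fx[-1] - Fx[-length(Fx)]
  slopes <- .pava_decreasing(dF / dx, dx)
  # value at a knot belongs to the interval ending there (left-open match)
  function(q) {
    idx <- findInterval(q, x[-length(x)], left.open = TRUE)
    slopes[pmax(pmin(idx, length(slopes)), 1L)]
  }
}

# Weighted PAVA for a non-increasing fit.
.pava_decreasing <- function(y, w) {
  n <- length(y)
  vals <- numeric(n); wts <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    vals[top] <- y[i]; wts[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && vals[top - 1L] < vals[top]) {
      wsum <- wts[top - 1L] + wts[top]
      vals[top - 1L] <- (vals[top - 1L] * wts[top - 1L] +
                           vals[top] * wts[top]) / wsum
      wts[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(vals[seq_len(top)], sz[seq_len(top)])
}
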