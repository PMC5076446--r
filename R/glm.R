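#' Fit per-gene negative binomial GLMs for caste and age contrasts
#'
#' Fits log-link negative binomial generalised linear models per gene by
#' iteratively reweighted least squares, with `log(effective library size)`
#' as offset and fixed per-gene dispersions. Caste and age enter as
#' categorical fixed effects (reference level: day-1 worker). Contrast
#' P-values come from likelihood-ratio tests of the dropped term against the
#' chi-squared distribution with 1 degree of freedom.
#'
#' By default the caste-within-age and age-within-caste contrasts are fitted
#' on the corresponding sample subsets (separate per-stratum fits), while the
#' interaction contrast and the reported coefficient table come from the
#' joint `~ caste * age` fit; `joint = TRUE` switches the stratum contrasts
#' to Wald-style single-coefficient drops within the joint model instead.
#'
#' Sign convention: each contrast record carries `c = -1` when expression is
#' queen-biased (or up-regulated with age, for age contrasts) and `c = +1`
#' otherwise, so that the signed score `c * (1 - P)` places queen-biased
#' (or age-up-regulated) genes at the low end of the ranked list.
#'
#' Genes whose IRLS fails to converge within the iteration cap are flagged
#' and assigned `P = 1` with a warning; genes with zero counts across all
#' samples must be removed beforehand (they have undefined normalisation
#' M-values) and trigger an error here.
#'
#' @param counts Integer matrix, genes x samples, no all-zero rows.
#' @param design Data frame with `sample_id`, `caste`, `age` covering the
#'   columns of `counts`.
#' @param factors Normalisation table from [tmm_factors()].
#' @param dispersions Either the data frame returned by
#'   [estimate_dispersion()] (its `tagwise` column is used) or a numeric
#'   vector of per-gene dispersions in row order of `counts`.
#' @param contrasts Character vector of contrasts to fit; any of
#'   `"caste_at_day1"`, `"caste_at_month2"`, `"age_in_queens"`,
#'   `"age_in_workers"`, `"interaction"`.
#' @param joint Logical; fit stratum contrasts inside the joint model rather
#'   than per-stratum (default `FALSE`).
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return An object of class `"caste_glm_fit"`: a list with `coefficients`
#'   (genes x 4 matrix of log2-scale joint-fit coefficients: intercept,
#'   caste, age, caste x age), `dispersion`, and `contrasts`, a named list of
#'   data frames with columns `gene_id`, `log2fc`, `c`, `P`, `converged`.
#' @seealso [contrast_pvalues()] to extract one contrast's records.
#' @examples
#' design <- generate_design("brain")
#' truth <- generate_truth(100, 10, seed = 1)
#' counts <- simulate_counts(truth, design, seed = 1)
#' counts <- counts[rowSums(counts) > 0, ]
#' nf <- tmm_factors(counts)
#' disp <- estimate_dispersion(counts, design, nf)
#' fit <- fit_glm(counts, design, nf, disp, contrasts = "caste_at_day1")
#' head(contrast_pvalues(fit, "caste_at_day1"))
#' @export
fit_glm <- function(counts, design, factors, dispersions,
                    contrasts = c("caste_at_day1", "caste_at_month2",
                                  "age_in_queens", "age_in_workers",
                                  "interaction"),
                    joint = FALSE, max_iter = 50L, tol = 1e-8) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  if (any(rowSums(counts) == 0))
    stop("remove all-zero genes before fitting (undefined normalisation)",
         call. = FALSE)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("design does not cover all samples in 'counts'", call. = FALSE)
  phi <- if (is.data.frame(dispersions)) dispersions$tagwise
  else rep_len(dispersions, nrow(counts))
  eff <- factors$effective_library_size[match(colnames(counts),
                                              factors$sample_id)]
  offset <- log(eff)
  caste <- factor(design$caste, levels = c("worker", "queen"))
  age <- factor(design$age, levels = c("day1", "month2"))

  # joint fit supplies the coefficient table (and the interaction LRT);
  # single-stratum inputs (one age or one caste present) fall back to the
  # within-stratum one-factor model, and only its contrasts are estimable
  ca2 <- nlevels(droplevels(caste)) == 2L
  ag2 <- nlevels(droplevels(age)) == 2L
  form <- if (ca2 && ag2) ~ caste * age
  else if (ca2) ~ caste
  else if (ag2) ~ age
  else stop("design matrix is not full rank: caste and age are both constant",
            call. = FALSE)
  X_full <- stats::model.matrix(form)
  if (qr(X_full)$rank < ncol(X_full))
    stop("design matrix is not full rank for ", deparse(form), call. = FALSE)
  estimable <- if (ca2 && ag2) c("caste_at_day1", "caste_at_month2",
                                 "age_in_queens", "age_in_workers",
                                 "interaction")
  else if (ca2) paste0("caste_at_", unique(as.character(age)))
  else paste0("age_in_", unique(as.character(caste)), "s")
  bad_ctr <- setdiff(contrasts, estimable)
  if (length(bad_ctr))
    stop("contrast(s) not estimable from this design: ",
         paste(bad_ctr, collapse = ", "), call. = FALSE)
  full <- .nb_glm_matrix(counts, X_full, offset, phi, max_iter, tol)
  coefs <- full$beta / log(2)
  colnames(coefs) <- if (ca2 && ag2)
    c("intercept", "caste_queen", "age_month2", "caste_queen:age_month2")
  else if (ca2) c("intercept", "caste_queen")
  else c("intercept", "age_month2")
  rownames(coefs) <- rownames(counts)

  out <- list(
    coefficients = coefs,
    dispersion = stats::setNames(phi, rownames(counts)),
    contrasts = list(),
    design = design,
    joint = joint
  )

  subset_lrt <- function(cols, term_x, reduce_to) {
    # per-stratum fit: model ~ term on the sample subset `cols`
    Xf <- stats::model.matrix(~ term_x)
    f <- .nb_glm_matrix(counts[, cols, drop = FALSE], Xf, offset[cols], phi,
                        max_iter, tol)
    Xr <- Xf[, reduce_to, drop = FALSE]
    r <- .nb_glm_matrix(counts[, cols, drop = FALSE], Xr, offset[cols], phi,
                        max_iter, tol)
    list(beta = f$beta[, 2], stat = pmax(2 * (f$ll - r$ll), 0),
         converged = f$converged & r$converged)
  }
  joint_lrt <- function(drop_col) {
    Xr <- X_full[, -drop_col, drop = FALSE]
    r <- .nb_glm_matrix(counts, Xr, offset, phi, max_iter, tol)
    list(beta = full$beta[, drop_col], stat = pmax(2 * (full$ll - r$ll), 0),
         converged = full$converged & r$converged)
  }

  for (ctr in contrasts) {
    res <- switch(ctr,
      caste_at_day1 = if (joint) joint_lrt(2L)
        else subset_lrt(which(age == "day1"), caste[age == "day1"], 1L),
      caste_at_month2 = if (joint) stop(
        "caste_at_month2 under joint = TRUE needs releveled age; use joint = FALSE",
        call. = FALSE)
        else subset_lrt(which(age == "month2"), caste[age == "month2"], 1L),
      age_in_queens = if (joint) stop(
        "age_in_queens under joint = TRUE needs releveled caste; use joint = FALSE",
        call. = FALSE)
        else subset_lrt(which(caste == "queen"), age[caste == "queen"], 1L),
      age_in_workers = if (joint) joint_lrt(3L)
        else subset_lrt(which(caste == "worker"), age[caste == "worker"], 1L),
      interaction = joint_lrt(4L)
    )
    P <- stats::pchisq(res$stat, df = 1L, lower.tail = FALSE)
    P[!res$converged] <- 1
    P <- pmin(pmax(P, .Machine$double.xmin), 1)
    n_bad <- sum(!res$converged)
    if (n_bad > 0)
      warning(sprintf("%s: %d gene(s) did not converge; assigned P = 1",
                      ctr, n_bad), call. = FALSE)
    out$contrasts[[ctr]] <- data.frame(
      gene_id = rownames(counts),
      log2fc = res$beta / log(2),
      c = ifelse(res$beta > 0, -1L, 1L),
      P = P,
      converged = res$converged,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  class(out) <- "caste_glm_fit"
  out
}

#' Extract signed contrast P-values from a fitted model
#'
#' Returns one record per retained gene with the direction sign `c`
#' (`-1` queen-biased / up-with-age, `+1` otherwise) and the
#' likelihood-ratio P-value, the inputs of the signed score `c * (1 - P)`.
#'
#' @param fit A `"caste_glm_fit"` object from [fit_glm()].
#' @param contrast One of the contrast names the fit contains.
#' @return Data frame with columns `gene_id`, `log2fc`, `c`, `P`.
#' @export
contrast_pvalues <- function(fit, contrast) {
  stopifnot(inherits(fit, "caste_glm_fit"))
  if (!contrast %in% names(fit$contrasts))
    stop("invalid contrast '", contrast, "'; available: ",
         paste(names(fit$contrasts), collapse = ", "), call. = FALSE)
  fit$contrasts[[contrast]][, c("gene_id", "log2fc", "c", "P")]
}

#' @export
print.caste_glm_fit <- function(x, ...) {
  cat("Negative binomial caste/age GLM fit\n")
  cat(sprintf("  genes: %d   samples: %d\n",
              nrow(x$coefficients), nrow(x$design)))
  cat(sprintf("  contrasts: %s\n", paste(names(x$contrasts), collapse = ", ")))
  cat(sprintf("  stratum contrasts fitted %s\n",
              if (isTRUE(x$joint)) "within the joint model" else "per stratum"))
  invisible(x)
}

#' @export
summary.caste_glm_fit <- function(object, alpha = 0.05, ...) {
  tab <- do.call(rbind, lapply(names(object$contrasts), function(ctr) {
    d <- object$contrasts[[ctr]]
    data.frame(
      contrast = ctr,
      genes = nrow(d),
      queen_biased = sum(d$c == -1L & d$P <= alpha),
      worker_biased = sum(d$c == 1L & d$P <= alpha),
      not_converged = sum(!d$converged),
      stringsAsFactors = FALSE
    )
  }))
  # for age contrasts the c = -1 column counts up-with-age genes
  structure(tab, class = c("summary.caste_glm_fit", "data.frame"),
            alpha = alpha)
}

#' @export
print.summary.caste_glm_fit <- function(x, ...) {
  cat(sprintf("Per-contrast calls at P <= %g (c = -1: queen-biased or up-with-age)\n",
              attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
coef.caste_glm_fit <- function(object, ...) object$coefficients

# Vectorised-across-genes NB IRLS with log link, fixed dispersions and
# offsets. Y: genes x samples; X: samples x p; phi: length-G vector.
# Returns beta (G x p, natural log scale), ll (NB log-likelihood at the
# fitted means) and a convergence flag per gene.
.nb_glm_matrix <- function(Y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  Y <- unname(as.matrix(Y))
  storage.mode(Y) <- "double"
  off <- matrix(offset, G, n, byrow = TRUE)

  # start from an unweighted LS fit to log counts
  Z0 <- log(pmax(Y, 0.5)) - off
  beta <- Z0 %*% X %*% t(solve(crossprod(X)))

  eta <- off + tcrossprod(beta, X)
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  dev_old <- .nb_ll(Y, mu, phi)
  active <- rep(TRUE, G)
  converged <- rep(FALSE, G)

  pair_a <- rep(seq_len(p), times = p)
  pair_b <- rep(seq_len(p), each = p)
  XX <- X[, pair_a, drop = FALSE] * X[, pair_b, drop = FALSE]  # n x p^2

  for (it in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    w <- mu[idx, , drop = FALSE] /
      (1 + phi[idx] * mu[idx, , drop = FALSE])
    z <- (eta[idx, , drop = FALSE] - off[idx, , drop = FALSE]) +
      (Y[idx, , drop = FALSE] - mu[idx, , drop = FALSE]) /
      mu[idx, , drop = FALSE]
    xtwx <- w %*% XX                         # G_a x p^2
    wz <- w * z
    xtwz <- wz %*% X                         # G_a x p
    bnew <- .solve_batch(xtwx, xtwz, p)
    bad <- !is.finite(rowSums(bnew))
    bnew[bad, ] <- beta[idx, , drop = FALSE][bad, ]
    beta[idx, ] <- bnew
    eta[idx, ] <- pmin(pmax(off[idx, , drop = FALSE] +
                              tcrossprod(bnew, X), -30), 30)
    mu[idx, ] <- exp(eta[idx, , drop = FALSE])
    ll_new <- .nb_ll(Y[idx, , drop = FALSE], mu[idx, , drop = FALSE],
                     phi[idx])
    done <- abs(ll_new - dev_old[idx]) <
      tol * (abs(dev_old[idx]) + 0.1)
    dev_old[idx] <- ll_new
    converged[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  list(beta = beta, ll = dev_old, mu = mu, converged = converged)
}

# Row-wise NB log-likelihood; phi <= 1e-10 treated as Poisson.
.nb_ll <- function(Y, mu, phi) {
  G <- nrow(Y)
  ll <- numeric(G)
  pois <- phi <= 1e-10
  if (any(pois))
    ll[pois] <- rowSums(stats::dpois(Y[pois, , drop = FALSE],
                                     lambda = mu[pois, , drop = FALSE],
                                     log = TRUE))
  if (any(!pois))
    ll[!pois] <- rowSums(stats::dnbinom(Y[!pois, , drop = FALSE],
                                        size = 1 / phi[!pois],
                                        mu = mu[!pois, , drop = FALSE],
                                        log = TRUE))
  ll
}

# Solve per-row p x p systems A[i,,] b = c[i,]; closed form for p <= 2,
# LAPACK otherwise.
.solve_batch <- function(xtwx, xtwz, p) {
  G <- nrow(xtwx)
  if (p == 1L) return(xtwz / xtwx)
  if (p == 2L) {
    a <- xtwx[, 1]; b <- xtwx[, 2]; d <- xtwx[, 4]
    det <- a * d - b * b
    cbind((d * xtwz[, 1] - b * xtwz[, 2]) / det,
          (a * xtwz[, 2] - b * xtwz[, 1]) / det)
  } else {
    out <- matrix(NA_real_, G, p)
    for (i in seq_len(G)) {
      A <- matrix(xtwx[i, ], p, p)
      out[i, ] <- tryCatch(solve(A, xtwz[i, ]),
                           error = function(e) rep(NA_real_, p))
    }
    out
  }
}
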