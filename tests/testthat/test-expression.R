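test_that("isoform aggregation sums transcripts and conserves totals", {
  tx <- matrix(c(3L, 4L, 5L, 1L, 2L, 7L), nrow = 3,
               dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  map <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("g", "g", "h"))
  agg <- aggregate_isoforms(tx, map)
  expect_equal(agg["g", "s1"], 7L)  # 3 + 4
  expect_equal(agg["h", ], c(s1 = 5L, s2 = 7L))

  # identity case: one transcript per gene
  map1 <- data.frame(transcript_id = rownames(tx), gene_id = rownames(tx))
  expect_equal(unname(aggregate_isoforms(tx, map1)), unname(tx))

  # conservation on a random 50-transcript matrix
  set.seed(3)
  tx50 <- matrix(rpois(50 * 4, 20), 50, 4,
                 dimnames = list(sprintf("t%02d", 1:50), paste0("s", 1:4)))
  map50 <- data.frame(transcript_id = rownames(tx50),
                      gene_id = sprintf("g%02d", sample(1:12, 50, TRUE)))
  expect_equal(colSums(aggregate_isoforms(tx50, map50)), colSums(tx50))

  expect_error(aggregate_isoforms(tx, map[-2, ]), "t2")
})

test_that("expression filter keeps exactly the genes that pass by recount", {
  set.seed(4)
  m <- matrix(rpois(100 * 6, 5), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  expect_identical(filter_low_expression(m, 0, 0), m)
  m["g001", ] <- 0L
  out <- filter_low_expression(m, 1, 1)
  expect_false("g001" %in% rownames(out))
  # direct recount oracle
  cpm <- sweep(m, 2, colSums(m) / 1e6, "/")
  expect_equal(nrow(filter_low_expression(m, 50, 3)),
               sum(rowSums(cpm >= 50) >= 3))
})

test_that("TMM factors satisfy their defining identities", {
  set.seed(5)
  base <- matrix(rnbinom(200 * 2, mu = 50, size = 5), 200, 2,
                 dimnames = list(sprintf("g%03d", 1:200), c("a", "b")))
  # identical samples -> unit factors
  same <- cbind(a = base[, 1], b = base[, 1])
  expect_equal(tmm_factors(same)$tmm_factor, c(1, 1))
  # uniform doubling: M-values on scaled proportions are all zero
  dbl <- cbind(a = base[, 1], b = 2L * base[, 1])
  expect_equal(tmm_factors(dbl)$tmm_factor, c(1, 1), tolerance = 1e-8)
  expect_error(tmm_factors(base[, 1, drop = FALSE]), "two samples")
  zero <- base; zero[, 2] <- 0L
  expect_error(tmm_factors(zero), "zero library size")
})

test_that("TMM agrees with a direct implementation of the trimmed weighted mean", {
  # independent scalar-loop oracle for the sample-vs-reference factor
  oracle_pair <- function(obs, ref) {
    No <- sum(obs); Nr <- sum(ref)
    M <- c(); A <- c(); w <- c()
    for (g in seq_along(obs)) {
      if (obs[g] > 0 && ref[g] > 0) {
        M <- c(M, log2((obs[g] / No) / (ref[g] / Nr)))
        A <- c(A, 0.5 * log2((obs[g] / No) * (ref[g] / Nr)))
        w <- c(w, (No - obs[g]) / (No * obs[g]) + (Nr - ref[g]) / (Nr * ref[g]))
      }
    }
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  set.seed(6)
  m <- matrix(rnbinom(200 * 4, mu = rexp(200, 1 / 100), size = 3), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  m <- m[rowSums(m) > 0, ]
  fac <- tmm_factors(m)
  lib <- colSums(m)
  uq <- apply(m, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  raw <- vapply(1:4, function(j) oracle_pair(m[, j], m[, ref]), numeric(1))
  raw <- raw / exp(mean(log(raw)))
  expect_equal(fac$tmm_factor, raw, tolerance = 1e-8)
  # geometric mean exactly one; effective sizes positive
  expect_equal(exp(mean(log(fac$tmm_factor))), 1, tolerance = 1e-9)
  expect_true(all(fac$effective_library_size > 0))
})

test_that("TMM matches edgeR and is invariant to uniform scaling of one sample", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  m <- matrix(rnbinom(300 * 6, mu = rexp(300, 1 / 150), size = 2), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6)))
  m <- m[rowSums(m) > 0, ]
  expect_equal(tmm_factors(m)$tmm_factor,
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-10)
  # composition-free scaling: doubling every count of one of two identical
  # samples moves its library size, not its proportions, so all M-values are
  # exactly zero and both factors stay at 1
  pair <- cbind(a = m[, 1], b = m[, 1])
  dbl <- pair; dbl[, 2] <- 2L * dbl[, 2]
  expect_equal(tmm_factors(dbl)$tmm_factor, c(1, 1), tolerance = 1e-8)
  # on heterogeneous data the precision weights depend on raw counts, so
  # scaling one sample may nudge its factor, but only slightly
  m2 <- m; m2[, 3] <- 2L * m2[, 3]
  f_ratio <- tmm_factors(m2)$tmm_factor / tmm_factors(m)$tmm_factor
  expect_equal(f_ratio[3] / exp(mean(log(f_ratio))), 1, tolerance = 0.05)
})

test_that("dispersion estimation recovers simulated values", {
  design <- generate_design("leg")
  # Poisson data: tagwise stays near zero
  tp <- generate_truth(400, 10, seed = 21, dispersion_mean = 0)
  cp <- simulate_counts(tp, design, seed = 21)
  cp <- cp[rowSums(cp) > 0, ]
  nf <- tmm_factors(cp)
  dp <- estimate_dispersion(cp, design, nf)
  expect_lt(median(dp$tagwise), 0.05)

  # NB phi = 0.2: median tagwise in [0.1, 0.4]
  tn <- generate_truth(400, 10, seed = 22)
  tn$dispersion <- 0.2
  cn <- simulate_counts(tn, design, seed = 22)
  cn <- cn[rowSums(cn) > 0, ]
  nfn <- tmm_factors(cn)
  dn <- estimate_dispersion(cn, design, nfn)
  expect_gt(median(dn$tagwise), 0.1)
  expect_lt(median(dn$tagwise), 0.4)

  # prior_df -> Inf collapses tagwise onto the trend
  dinf <- estimate_dispersion(cn, design, nfn, prior_df = Inf)
  expect_equal(dinf$tagwise, pmax(dinf$trend, 0))
  expect_true(all(dn$tagwise >= 0))

  # 5 samples spread over the 4 treatment cells: 1 residual df
  pick <- design$sample_id[c(1, 7, 13, 19, 2)]
  small <- cn[, pick]
  expect_error(
    estimate_dispersion(small, design[design$sample_id %in% pick, ],
                        tmm_factors(small)),
    "insufficient replication")
})

test_that("NB GLM with zero dispersion matches the Poisson IRLS oracle", {
  b <- make_bundle(60, 5, seed = 31)
  counts <- b$counts[rowSums(b$counts) > 0, ]
  nf <- tmm_factors(counts)
  fit <- fit_glm(counts, b$design, nf, rep(0, nrow(counts)),
                 contrasts = "caste_at_day1")
  sub <- b$design$age == "day1"
  caste <- factor(b$design$caste[sub], levels = c("worker", "queen"))
  off <- log(nf$effective_library_size[sub])
  for (g in sample(rownames(counts), 15)) {
    oracle <- stats::glm(counts[g, sub] ~ caste + offset(off),
                         family = stats::poisson())
    expect_equal(fit$contrasts$caste_at_day1$log2fc[match(g, rownames(counts))],
                 unname(coef(oracle)[2]) / log(2), tolerance = 1e-6)
  }
})

test_that("NB GLM coefficients match edgeR glmFit at fixed dispersion", {
  skip_if_not_installed("edgeR")
  b <- make_bundle(80, 5, seed = 32)
  counts <- b$counts[rowSums(b$counts) > 0, ]
  nf <- tmm_factors(counts)
  phi <- rep(0.15, nrow(counts))
  fit <- fit_glm(counts, b$design, nf, phi, contrasts = "interaction")
  caste <- factor(b$design$caste, levels = c("worker", "queen"))
  age <- factor(b$design$age, levels = c("day1", "month2"))
  X <- model.matrix(~ caste * age)
  ef <- edgeR::glmFit(counts, design = X, dispersion = 0.15,
                      offset = log(nf$effective_library_size), prior.count = 0)
  expect_equal(unname(coef(fit)), unname(ef$coefficients) / log(2),
               tolerance = 1e-4)
})

test_that("contrast records follow the sign convention and exclusion rules", {
  b <- make_bundle(100, 5, effects = list(lfc_caste = 2), seed = 33)
  counts <- b$counts[rowSums(b$counts) > 0, ]
  nf <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, b$design, nf)
  fit <- fit_glm(counts, b$design, nf, disp,
                 contrasts = c("caste_at_day1", "age_in_workers"))
  tab <- contrast_pvalues(fit, "caste_at_day1")
  # queen-biased focal genes must carry c = -1
  focal <- b$truth$gene_id[b$truth$in_focal_set]
  focal <- intersect(focal, tab$gene_id)
  strong <- tab[tab$gene_id %in% focal & tab$P < 0.01, ]
  expect_true(all(strong$c == -1L))
  expect_true(all(tab$P > 0 & tab$P <= 1))
  expect_true(all(tab$c %in% c(-1L, 1L)))
  # one record per retained gene
  expect_equal(nrow(tab), nrow(counts))
  expect_error(contrast_pvalues(fit, "interaction"), "invalid contrast")
  # all-zero genes are rejected up front
  bad <- counts; bad[1, ] <- 0L
  expect_error(fit_glm(bad, b$design, nf, disp), "all-zero")
})

test_that("caste log2 fold changes are recovered without bias", {
  # 50 genes with a true caste effect of 1 log2 unit embedded among 1950
  # null genes (a large one-sided DE fraction would contaminate the trimmed
  # normalisation itself), phi = 0.1, 6 queens vs 6 workers, mean 200
  design <- generate_design("leg")
  day1 <- design[design$age == "day1", ]
  truth <- data.frame(gene_id = sprintf("g%04d", 1:2000), base_mean = 200,
                      dispersion = 0.1,
                      lfc_caste = rep(c(1, 0), c(50, 1950)), lfc_age = 0,
                      lfc_interaction = 0, in_focal_set = FALSE)
  counts <- simulate_counts(truth, day1, seed = 35)
  counts <- counts[rowSums(counts) > 0, ]
  nf <- tmm_factors(counts)
  fit <- fit_glm(counts, day1, nf, rep(0.1, nrow(counts)),
                 contrasts = "caste_at_day1")
  tab <- contrast_pvalues(fit, "caste_at_day1")
  de <- tab$gene_id %in% sprintf("g%04d", 1:50)
  expect_lt(abs(mean(tab$log2fc[de]) - 1), 0.1)
  expect_lt(abs(mean(tab$log2fc[!de])), 0.1)
  # strongly detected DE genes are queen-biased by the sign convention
  expect_true(all(tab$c[de & tab$P < 1e-4] == -1L))
})
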