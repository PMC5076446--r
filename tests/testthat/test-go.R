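test_that("ancestor propagation closes over the ontology and is idempotent", {
  edges <- data.frame(child = c("GO:c", "GO:m"), parent = c("GO:m", "GO:p"),
                      relation = c("is_a", "part_of"))
  ann <- go_annotation(list(g1 = "GO:c", g2 = "GO:m"), edges)
  prop <- propagate_annotations(ann)
  expect_setequal(prop$gene2go$g1, c("GO:c", "GO:m", "GO:p"))
  expect_setequal(prop$gene2go$g2, c("GO:m", "GO:p"))
  expect_equal(propagate_annotations(prop)$gene2go, prop$gene2go)

  cyc <- go_annotation(list(g = "GO:a"),
                       data.frame(child = c("GO:a", "GO:b"),
                                  parent = c("GO:b", "GO:a"),
                                  relation = "is_a"))
  expect_error(propagate_annotations(cyc), "cycle")
})

test_that("propagation matches a per-gene breadth-first-search oracle", {
  set.seed(14)
  terms <- sprintf("GO:%03d", 1:30)
  # random DAG: edges only from higher to lower index (acyclic)
  pairs <- t(combn(30, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.1, , drop = FALSE]
  edges <- data.frame(child = terms[pick[, 2]], parent = terms[pick[, 1]],
                      relation = "is_a")
  genes <- sprintf("g%02d", 1:40)
  g2g <- lapply(genes, function(g) sample(terms, sample(1:4, 1)))
  names(g2g) <- genes
  prop <- propagate_annotations(go_annotation(g2g, edges))

  bfs_up <- function(start) {
    seen <- character(0); frontier <- start
    while (length(frontier)) {
      nxt <- edges$parent[edges$child %in% frontier]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  for (g in genes)
    expect_setequal(prop$gene2go[[g]], unique(c(g2g[[g]], bfs_up(g2g[[g]]))))
})

test_that("two-tailed KS statistic and exact P behave at the extremes", {
  # members on a uniform lattice: minimal displacement
  flat <- ks_two_tailed(c(3, 9, 15, 21, 27), 30)
  expect_gt(flat$P, 0.5)
  # members packed at the top of the list: maximal displacement
  top <- ks_two_tailed(1:5, 20)
  expect_equal(top$D, 1)
  # exact value by direct enumeration of all C(20,5) subsets
  all_sets <- combn(20, 5)
  d_of <- function(rk) {
    step <- rep(-1 / 15, 20); step[rk] <- 1 / 5
    max(abs(cumsum(step)))
  }
  d_all <- apply(all_sets, 2, d_of)
  expect_equal(top$P, mean(d_all >= top$D - 1e-12))
  expect_error(ks_two_tailed(integer(0), 10), "degenerate")
  expect_error(ks_two_tailed(1:10, 10), "degenerate")
  expect_error(ks_two_tailed(c(2, 2, 5), 10), "distinct")
})

test_that("lattice-path exact P agrees with stats::psmirnov", {
  set.seed(15)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    n1 <- sample(2:8, 1)
    rk <- sort(sample.int(N, n1))
    ks <- ks_two_tailed(rk, N)
    ref <- stats::psmirnov(ks$D - 1e-12, sizes = c(n1, N - n1),
                           lower.tail = FALSE)
    expect_equal(ks$P, ref, tolerance = 1e-9)
  }
})

test_that("asymptotic and exact KS P agree within 0.05 at n = 8, N = 30", {
  set.seed(16)
  diffs <- vapply(1:200, function(i) {
    rk <- sort(sample.int(30, 8))
    ex <- ks_two_tailed(rk, 30, exact = TRUE)$P
    as <- ks_two_tailed(rk, 30, exact = FALSE)$P
    abs(ex - as)
  }, numeric(1))
  expect_lt(max(diffs), 0.05)
})

test_that("term-level tests find a planted extreme term and stay calibrated", {
  ranked <- rank_genes(random_scores(500, seed = 17))
  genes <- ranked$gene_id
  g2g <- list()
  # term A: the 20 most queen-extreme genes; term B: a uniform lattice
  for (g in ranked$gene_id[1:20]) g2g[[g]] <- "GO:A"
  for (g in ranked$gene_id[seq(10, 500, by = 25)])
    g2g[[g]] <- c(g2g[[g]], "GO:B")
  set.seed(18)
  for (t in sprintf("GO:R%02d", 1:30)) {
    for (g in sample(genes, 25)) g2g[[g]] <- c(g2g[[g]], t)
  }
  ann <- go_annotation(g2g)
  rec <- test_all_terms(ranked, ann)
  expect_equal(nrow(rec), 32L)
  expect_equal(rec$term_id[which.min(rec$P)], "GO:A")
  expect_equal(rec$direction[rec$term_id == "GO:A"], "queen")
  expect_gt(rec$P[rec$term_id == "GO:B"], 0.1)
  # size floor: terms below min_size are dropped with a message
  tiny_host <- ranked$gene_id[250]
  g2g[[tiny_host]] <- c(g2g[[tiny_host]], "GO:tiny")
  expect_message(rec2 <- test_all_terms(ranked, go_annotation(g2g), min_size = 5),
                 "skipping")
  expect_false("GO:tiny" %in% rec2$term_id)
})

test_that("lfdr is calibrated on uniform and mixture inputs", {
  set.seed(19)
  u <- runif(1000)
  lu <- estimate_lfdr(u)
  expect_gte(median(lu), 0.9)
  expect_true(all(lu >= 0 & lu <= 1))
  # monotone non-decreasing in p
  ord <- order(u)
  expect_true(all(diff(lu[ord]) >= 0))

  spiked <- c(runif(900), runif(100, 0, 1e-4))
  ls <- estimate_lfdr(spiked)
  expect_lt(max(ls[901:1000]), 0.2)
  expect_gte(median(ls[1:900]), 0.5)

  # lfdr dominates the BH-style tail FDR: exact ordering in the bulk, and
  # for the vast majority overall (the two estimators can cross in the
  # far tail, where both are essentially zero)
  bh_q <- p.adjust(spiked, "BH")
  bulk <- spiked >= 0.01
  expect_true(all(ls[bulk] >= bh_q[bulk] - 1e-9))
  expect_gt(mean(ls >= bh_q - 1e-9), 0.9)

  expect_error(estimate_lfdr(runif(10)), "too few")
  expect_error(estimate_lfdr(c(runif(30), 2)), "invalid probability")
})

test_that("enrichment calls apply the inclusive lfdr threshold", {
  rec <- data.frame(term_id = c("a", "b", "c"),
                    lfdr = c(0.013, 0.05, 1))
  out <- call_enriched(rec)
  expect_equal(out$enriched, c(TRUE, TRUE, FALSE))
  expect_equal(out$term_id, c("a", "b", "c"))  # sorted ascending lfdr
  expect_error(call_enriched(data.frame(term_id = "a")), "lfdr")
})

test_that("go_enrichment flags a planted queen-extreme term", {
  ranked <- rank_genes(random_scores(600, seed = 20))
  g2g <- list()
  for (g in ranked$gene_id[1:25]) g2g[[g]] <- "GO:HIT"
  set.seed(21)
  for (t in sprintf("GO:R%02d", 1:40))
    for (g in sample(ranked$gene_id, 30)) g2g[[g]] <- c(g2g[[g]], t)
  res <- go_enrichment(ranked, go_annotation(g2g))
  expect_s3_class(res, "go_enrichment")
  hit <- res[res$term_id == "GO:HIT", ]
  expect_true(hit$enriched)
  expect_equal(hit$direction, "queen")
  expect_lt(mean(res$enriched), 0.2)
})

test_that("annotation round-trips through TSV and OBO-lite parses edges", {
  ann <- go_annotation(list(g1 = c("GO:1", "GO:2"), g2 = "GO:2"))
  path <- tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$gene2go, ann$gene2go)

  obo <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "is_a: GO:0000002 ! parent",
               "", "[Term]", "id: GO:0000003",
               "relationship: part_of GO:0000001 ! whole"), obo)
  edges <- read_obo_lite(obo)
  expect_equal(edges$child, c("GO:0000001", "GO:0000003"))
  expect_equal(edges$relation, c("is_a", "part_of"))
})
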