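# Shared fixture builders; everything is generated in code under fixed seeds.

make_bundle <- function(num_genes = 300, set_size = 10, tissue = "brain",
                        effects = list(), seed = 42) {
  design <- generate_design(tissue)
  truth <- generate_truth(num_genes, set_size, effects = effects, seed = seed)
  counts <- simulate_counts(truth, design, seed = seed)
  list(design = design, truth = truth, counts = counts)
}

# Independent brute-force ES: explicit position-by-position loop over the
# +1 / -n/(N-n) increments, tracked in integer-scaled space so the loop is
# exact arithmetic (partial sums times (N-n) are integers).
loop_es <- function(member_ranks, N) {
  n <- length(member_ranks)
  s <- 0
  best <- 0
  in_set <- logical(N)
  in_set[member_ranks] <- TRUE
  for (i in seq_len(N)) {
    s <- s + if (in_set[i]) (N - n) else -n
    if (abs(s) > best) best <- abs(s)
  }
  best / (N - n)
}

# Random scores table with unique gene ids.
random_scores <- function(N, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed(data.frame(
    gene_id = sprintf("g%05d", seq_len(N)),
    c = sample(c(-1L, 1L), N, replace = TRUE),
    P = runif(N, 1e-4, 1)
  ))
}

write_hit_lines <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

hit_row <- function(q, s, evalue, bits, pid = 90) {
  c(q, s, pid, 100, 5, 1, 1, 100, 1, 100,
    format(evalue, scientific = TRUE), bits)
}
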