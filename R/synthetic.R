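#' Build a full factorial caste x age sample design for one tissue
#'
#' Lays out the replicate structure of a two-caste (queen/worker), two-age
#' (1-day/2-month) factorial for a single tissue. The study layout this
#' emulates used six leg replicates and five brain replicates per treatment,
#' each treatment being one caste x age cell.
#'
#' @param tissue `"leg"` or `"brain"`.
#' @param replicates Replicates per treatment (caste x age cell); defaults to
#'   6 for legs and 5 for brains. Must be at least 2.
#' @return A data frame with columns `sample_id`, `caste` (`"queen"`,
#'   `"worker"`), `age` (`"day1"`, `"month2"`), `tissue` and `replicate`,
#'   one row per sample (`4 * replicates` rows). Deterministic.
#' @examples
#' design <- generate_design("leg")
#' table(design$caste, design$age)
#' @export
generate_design <- function(tissue = c("leg", "brain"), replicates = NULL) {
  tissue <- match.arg(tissue)
  if (is.null(replicates)) replicates <- if (tissue == "leg") 6L else 5L
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 2L)
    stop("invalid design: 'replicates' must be an integer >= 2", call. = FALSE)
  grid <- expand.grid(
    replicate = seq_len(replicates),
    age = c("day1", "month2"),
    caste = c("queen", "worker"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", tissue, grid$caste, grid$age,
                        grid$replicate),
    caste = grid$caste,
    age = grid$age,
    tissue = tissue,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

#' Draw per-gene ground truth for the count simulator
#'
#' Generates the gene-level parameters the negative binomial simulator
#' consumes: a log-normal baseline expression level, a gamma-distributed NB
#' dispersion, and log2 effects for caste, age and their interaction. A focal
#' gene set of `set_size` genes receives the configured interaction effect,
#' encoding the age-dependent caste bias (no caste difference at day 1,
#' caste-biased expression at month 2) as a single knob; positive log2 values
#' are queen-biased.
#'
#' @param num_genes Total number of genes.
#' @param set_size Size of the focal gene set (default 20). Must be smaller
#'   than `num_genes`.
#' @param effects Named list of effect configuration. Recognised entries:
#'   `lfc_caste`, `lfc_age`, `lfc_interaction` (log2 effects applied to the
#'   focal set; defaults 0, 0, 0) and `background` (a list with `lfc_caste`,
#'   `lfc_age`, `prop_caste`, `prop_age` giving effects assigned to random
#'   background genes; default none).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param base_meanlog,base_sdlog Log-normal parameters of the baseline mean
#'   (expected count at the reference level for a library of 1e6).
#' @param dispersion_shape,dispersion_mean Gamma parameters of the NB
#'   dispersion (shape and mean).
#' @return Data frame with columns `gene_id`, `base_mean`, `dispersion`,
#'   `lfc_caste` (log2 queen/worker at day 1), `lfc_age` (log2 month2/day1 in
#'   workers), `lfc_interaction` (extra log2 caste effect at month 2) and
#'   `in_focal_set`.
#' @examples
#' truth <- generate_truth(200, 20, effects = list(lfc_interaction = 0.5),
#'                         seed = 1)
#' sum(truth$in_focal_set)
#' @export
generate_truth <- function(num_genes, set_size = 20L, effects = list(),
                           seed = 1L, base_meanlog = log(100),
                           base_sdlog = 1.3, dispersion_shape = 2,
                           dispersion_mean = 0.1) {
  num_genes <- as.integer(num_genes)
  set_size <- as.integer(set_size)
  if (num_genes < 1L) stop("'num_genes' must be positive", call. = FALSE)
  if (set_size < 1L || set_size >= num_genes)
    stop("invalid configuration: 'set_size' must satisfy 1 <= set_size < num_genes",
         call. = FALSE)
  eff <- modifyList(
    list(lfc_caste = 0, lfc_age = 0, lfc_interaction = 0, background = NULL),
    effects
  )
  stopifnot(all(is.finite(c(eff$lfc_caste, eff$lfc_age, eff$lfc_interaction))))

  .with_seed(.derive_seed(seed, "truth"), {
    width <- max(4L, nchar(as.character(num_genes)))
    gene_id <- sprintf(paste0("g%0", width, "d"), seq_len(num_genes))
    base_mean <- stats::rlnorm(num_genes, meanlog = base_meanlog,
                               sdlog = base_sdlog)
    dispersion <- if (dispersion_mean > 0)
      stats::rgamma(num_genes, shape = dispersion_shape,
                    rate = dispersion_shape / dispersion_mean)
    else rep(0, num_genes)
    focal <- sort(sample.int(num_genes, set_size))

    lfc_caste <- lfc_age <- lfc_interaction <- numeric(num_genes)
    lfc_caste[focal] <- eff$lfc_caste
    lfc_age[focal] <- eff$lfc_age
    lfc_interaction[focal] <- eff$lfc_interaction
    bg <- eff$background
    if (!is.null(bg)) {
      pool <- setdiff(seq_len(num_genes), focal)
      pick <- function(prop) sample(pool, round(prop * length(pool)))
      if (!is.null(bg$prop_caste) && bg$prop_caste > 0) {
        idx <- pick(bg$prop_caste)
        lfc_caste[idx] <- bg$lfc_caste * sample(c(-1, 1), length(idx), TRUE)
      }
      if (!is.null(bg$prop_age) && bg$prop_age > 0) {
        idx <- pick(bg$prop_age)
        lfc_age[idx] <- bg$lfc_age * sample(c(-1, 1), length(idx), TRUE)
      }
    }
    data.frame(
      gene_id = gene_id, base_mean = base_mean, dispersion = dispersion,
      lfc_caste = lfc_caste, lfc_age = lfc_age,
      lfc_interaction = lfc_interaction,
      in_focal_set = seq_len(num_genes) %in% focal,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a negative binomial count matrix from truth and design
#'
#' Each count is drawn `NB(mu, phi)` with
#' `mu = lib_j * base_mean_i / 1e6 * 2^(design effects)` where the design
#' effects are `lfc_caste` for queens, `lfc_age` for month-2 samples and
#' `lfc_interaction` for month-2 queens (reference level: day-1 worker).
#' A dispersion of 0 degenerates to Poisson sampling.
#'
#' @param truth Data frame as returned by [generate_truth()].
#' @param design Data frame as returned by [generate_design()].
#' @param library_sizes Either a vector of one positive size per sample, or a
#'   length-2 range to draw log-uniform sizes from. Default: log-uniform on
#'   `[0.5e6, 2e6]`, which makes normalisation consequential.
#' @param seed Integer seed.
#' @return Integer matrix, genes x samples, with `gene_id` rownames and
#'   `sample_id` colnames.
#' @examples
#' truth <- generate_truth(50, 5, seed = 1)
#' counts <- simulate_counts(truth, generate_design("brain"), seed = 1)
#' dim(counts)
#' @export
simulate_counts <- function(truth, design, library_sizes = c(0.5e6, 2e6),
                            seed = 1L) {
  n_samp <- nrow(design)
  n_gene <- nrow(truth)
  if (any(library_sizes <= 0))
    stop("invalid input: library sizes must be positive", call. = FALSE)

  .with_seed(.derive_seed(seed, "counts"), {
    libs <- if (length(library_sizes) == n_samp) library_sizes
    else if (length(library_sizes) == 2L)
      exp(stats::runif(n_samp, log(library_sizes[1]), log(library_sizes[2])))
    else stop("'library_sizes' must give one size per sample or a range",
              call. = FALSE)

    is_queen <- design$caste == "queen"
    is_m2 <- design$age == "month2"
    # genes x samples matrix of log2 effects
    lfc <- outer(truth$lfc_caste, as.numeric(is_queen)) +
      outer(truth$lfc_age, as.numeric(is_m2)) +
      outer(truth$lfc_interaction, as.numeric(is_queen & is_m2))
    mu <- (truth$base_mean / 1e6) * 2^lfc
    mu <- sweep(mu, 2L, libs, `*`)

    counts <- matrix(0L, n_gene, n_samp,
                     dimnames = list(truth$gene_id, design$sample_id))
    phi <- truth$dispersion
    pois <- phi <= 0
    for (j in seq_len(n_samp)) {
      cj <- numeric(n_gene)
      if (any(pois)) cj[pois] <- stats::rpois(sum(pois), mu[pois, j])
      if (any(!pois)) cj[!pois] <- stats::rnbinom(sum(!pois),
                                                  size = 1 / phi[!pois],
                                                  mu = mu[!pois, j])
      counts[, j] <- as.integer(cj)
    }
    attr(counts, "library_sizes") <- stats::setNames(libs, design$sample_id)
    counts
  })
}

#' Generate a transcript-to-gene (isogroup) map
#'
#' Assembled transcriptomes group putative isoforms into isogroups that stand
#' in for genes; counts are later aggregated at that level. This generator
#' attaches 1 or more transcript identifiers to each gene.
#'
#' @param genes Character vector of gene identifiers.
#' @param isoforms_per_gene Single integer (fixed isoform count) or a
#'   length-2 inclusive range to sample from. Must be >= 1.
#' @param seed Integer seed (used only when a range is given).
#' @return Data frame with columns `transcript_id`, `gene_id`; every gene has
#'   at least one transcript and transcript ids are unique.
#' @export
generate_transcript_map <- function(genes, isoforms_per_gene = c(1L, 4L),
                                    seed = 1L) {
  stopifnot(length(genes) >= 1L)
  rng <- as.integer(isoforms_per_gene)
  if (any(is.na(rng)) || any(rng < 1L))
    stop("'isoforms_per_gene' must be >= 1", call. = FALSE)
  k <- if (length(rng) == 1L) rep(rng, length(genes))
  else .with_seed(.derive_seed(seed, "transcript_map"),
                  sample(seq(rng[1], rng[2]), length(genes), replace = TRUE))
  data.frame(
    transcript_id = unlist(mapply(function(g, n) sprintf("%s_t%d", g, seq_len(n)),
                                  genes, k, SIMPLIFY = FALSE), use.names = FALSE),
    gene_id = rep(genes, k),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic GO annotation universe
#'
#' Draws `num_terms` GO-like terms, each annotating a uniformly drawn number
#' of genes within `size_range` (sampled without replacement), mimicking
#' realistic term sizes such as the 244-gene "DNA repair" and 162-gene
#' proteasome-mediated catabolism sets.
#'
#' @param genes Character vector of gene identifiers (non-empty).
#' @param num_terms Number of terms to generate.
#' @param size_range Length-2 integer range of term sizes, within
#'   `[1, length(genes)]`.
#' @param seed Integer seed.
#' @return A [go_annotation] object mapping each gene to its term ids.
#' @export
generate_go_universe <- function(genes, num_terms, size_range = c(10L, 250L),
                                 seed = 1L) {
  if (length(genes) == 0L)
    stop("invalid input: empty gene list", call. = FALSE)
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] < 1L ||
      size_range[2] > length(genes) || size_range[1] > size_range[2])
    stop("'size_range' must lie within [1, number of genes]", call. = FALSE)
  .with_seed(.derive_seed(seed, "go_universe"), {
    term_ids <- sprintf("GO:%07d", seq_len(num_terms))
    sizes <- if (size_range[1] == size_range[2]) rep(size_range[1], num_terms)
    else sample(seq(size_range[1], size_range[2]), num_terms, replace = TRUE)
    term2gene <- lapply(sizes, function(s) sample(genes, s))
    names(term2gene) <- term_ids
    gene2go <- split(
      rep(term_ids, sizes),
      factor(unlist(term2gene, use.names = FALSE), levels = genes)
    )
    gene2go <- gene2go[lengths(gene2go) > 0]
    go_annotation(lapply(gene2go, as.character))
  })
}
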