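#' Cross-check counts, design, gene sets and annotation for consistency
#'
#' Verifies that every design sample has a count column (and vice versa),
#' that every gene set intersects the count matrix, and reports orphan
#' counts (set members or annotated genes absent from the matrix). Fails on
#' empty intersections or sample mismatches, naming the offenders.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Sample design data frame.
#' @param sets Optional named list of gene sets.
#' @param annotation Optional [go_annotation].
#' @return Invisibly, a list of per-check counts (class
#'   `"validation_report"`).
#' @export
validate_inputs <- function(counts, design, sets = NULL, annotation = NULL) {
  miss_d <- setdiff(design$sample_id, colnames(counts))
  if (length(miss_d))
    stop("validation error: design sample(s) absent from counts: ",
         paste(miss_d, collapse = ", "), call. = FALSE)
  miss_c <- setdiff(colnames(counts), design$sample_id)
  if (length(miss_c))
    stop("validation error: count column(s) absent from design: ",
         paste(miss_c, collapse = ", "), call. = FALSE)
  orphans <- list()
  if (!is.null(sets)) {
    inter <- vapply(sets, function(s) length(intersect(s, rownames(counts))),
                    integer(1))
    if (any(inter == 0L))
      stop("validation error: gene set(s) with no member in counts: ",
           paste(names(sets)[inter == 0L], collapse = ", "), call. = FALSE)
    orphans$set_members_absent <-
      sum(vapply(sets, function(s) length(setdiff(s, rownames(counts))),
                 integer(1)))
  }
  if (!is.null(annotation))
    orphans$annotated_genes_absent <-
      length(setdiff(names(annotation$gene2go), rownames(counts)))
  rep_ <- c(list(n_genes = nrow(counts), n_samples = ncol(counts),
                 n_sets = length(sets)), orphans)
  class(rep_) <- "validation_report"
  invisible(rep_)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation passed\n")
  for (nm in names(x)) cat(sprintf("  %s: %d\n", nm, x[[nm]]))
  invisible(x)
}

.CONTRAST_LABELS <- list(
  caste_at_day1 = c("queen", "worker"),
  caste_at_month2 = c("queen", "worker"),
  age_in_queens = c("up_with_age", "down_with_age"),
  age_in_workers = c("up_with_age", "down_with_age"),
  interaction = c("queen", "worker")
)

#' Run the full caste/age enrichment pipeline
#'
#' For each tissue (analysed fully independently, with its own
#' normalisation) and each requested contrast: fit the per-gene NB GLM,
#' build the signed-P ranked list, run the running-sum GSEA on every
#' configured gene set, and (when an annotation is supplied) the KS/lfdr GO
#' enrichment. All randomness derives from the single master seed. Writes
#' TSV reports and a JSON run manifest when `out_dir` is given.
#'
#' @param config A list. Either simulation parameters under `simulation`
#'   (a list with `num_genes`, `set_size`, `effects`, and optionally
#'   `replicates` per tissue, `num_go_terms`, `go_size_range`) or real
#'   inputs under `counts` (named list of per-tissue matrices or TSV paths)
#'   and `design` (data frame or TSV path). Optional fields: `tissues`
#'   (default `c("leg", "brain")` for simulation, else names of `counts`),
#'   `contrasts` (default all five), `gene_sets` (named list or GMT path;
#'   for simulations the simulated focal set is added automatically),
#'   `annotation` ([go_annotation] or annotation TSV path; for simulations
#'   generated when `num_go_terms` is set), `B` (default 5000),
#'   `lfdr_threshold` (default 0.05), `min_set_size` (default 5), `seed`
#'   (default 1), `out_dir` (optional output directory).
#' @return List with `gsea_report` (one row per tissue x contrast x set:
#'   `tissue`, `contrast`, `set`, `n`, `N`, `ES`, `direction`, `k`, `B`,
#'   `P`), `go_report` (per tissue x contrast x term, or `NULL`), `fits`
#'   (per-tissue `"caste_glm_fit"` objects), `truth` (per-tissue simulation
#'   truth, simulation runs only) and `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(
#'   simulation = list(num_genes = 300, set_size = 10,
#'                     effects = list(lfc_interaction = 1)),
#'   tissues = "brain", B = 200, seed = 7))
#' res$gsea_report
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(list(
    simulation = NULL, counts = NULL, design = NULL, tissues = NULL,
    contrasts = c("caste_at_day1", "caste_at_month2", "age_in_queens",
                  "age_in_workers", "interaction"),
    gene_sets = NULL, annotation = NULL, B = 5000L, lfdr_threshold = 0.05,
    min_set_size = 5L, min_go_terms = 20L, seed = 1L, out_dir = NULL
  ), config)
  if (is.null(cfg$simulation) && is.null(cfg$counts))
    stop("config must carry either 'simulation' parameters or 'counts' input",
         call. = FALSE)
  stopifnot(cfg$B >= 1L, cfg$lfdr_threshold > 0, cfg$lfdr_threshold < 1)

  if (is.character(cfg$design)) cfg$design <- read_design(cfg$design)
  if (is.character(cfg$gene_sets)) cfg$gene_sets <- read_gmt(cfg$gene_sets)
  if (is.character(cfg$annotation))
    cfg$annotation <- read_annotation(cfg$annotation)

  simulate_mode <- !is.null(cfg$simulation)
  tissues <- cfg$tissues
  if (is.null(tissues))
    tissues <- if (simulate_mode) c("leg", "brain") else names(cfg$counts)

  gsea_rows <- list(); go_rows <- list(); fits <- list(); truths <- list()
  log_counts <- list()

  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    tissue_seed <- .derive_seed(cfg$seed + 13L * ti, "pipeline")

    if (simulate_mode) {
      sim <- cfg$simulation
      reps <- if (!is.null(sim$replicates)) sim$replicates[[tissue]] else NULL
      design_t <- generate_design(tissue, reps)
      truth <- generate_truth(sim$num_genes, sim$set_size,
                              effects = if (is.null(sim$effects)) list()
                              else sim$effects,
                              seed = tissue_seed)
      counts_t <- simulate_counts(truth, design_t, seed = tissue_seed)
      truths[[tissue]] <- truth
      sets <- cfg$gene_sets
      sets$focal <- truth$gene_id[truth$in_focal_set]
      annotation <- cfg$annotation
      if (is.null(annotation) && !is.null(sim$num_go_terms))
        annotation <- generate_go_universe(
          truth$gene_id, sim$num_go_terms,
          if (is.null(sim$go_size_range)) c(10L, 250L) else sim$go_size_range,
          seed = tissue_seed)
    } else {
      counts_t <- cfg$counts[[tissue]]
      if (is.character(counts_t)) counts_t <- read_counts(counts_t)
      design_t <- cfg$design[cfg$design$tissue == tissue, , drop = FALSE]
      sets <- cfg$gene_sets
      annotation <- cfg$annotation
      validate_inputs(counts_t, design_t, sets, annotation)
    }

    keep <- rowSums(counts_t) > 0
    counts_t <- counts_t[keep, , drop = FALSE]
    nf <- tmm_factors(counts_t)
    disp <- estimate_dispersion(counts_t, design_t, nf)
    fit <- fit_glm(counts_t, design_t, nf, disp, contrasts = cfg$contrasts)
    fits[[tissue]] <- fit
    log_counts[[tissue]] <- list(genes_retained = sum(keep),
                                 genes_dropped_all_zero = sum(!keep),
                                 samples = ncol(counts_t))

    for (ctr in cfg$contrasts) {
      labels <- .CONTRAST_LABELS[[ctr]]
      ranked <- rank_genes(contrast_pvalues(fit, ctr))
      if (!is.null(sets)) {
        for (set_name in names(sets)) {
          members <- intersect(sets[[set_name]], ranked$gene_id)
          res <- gsea_test(ranked, list(name = set_name, genes = members),
                           B = cfg$B, seed = tissue_seed + match(ctr, cfg$contrasts),
                           labels = labels)
          gsea_rows[[length(gsea_rows) + 1L]] <- data.frame(
            tissue = tissue, contrast = ctr, set = set_name, n = res$n,
            N = res$N, ES = res$ES, direction = res$direction, k = res$k,
            B = res$B, P = res$empirical_P, stringsAsFactors = FALSE)
        }
      }
      if (!is.null(annotation)) {
        n_terms <- length(unique(unlist(annotation$gene2go,
                                        use.names = FALSE)))
        if (n_terms >= cfg$min_go_terms) {
          go <- go_enrichment(ranked, annotation,
                              min_size = cfg$min_set_size,
                              threshold = cfg$lfdr_threshold, labels = labels)
          go$tissue <- tissue; go$contrast <- ctr
          go_rows[[length(go_rows) + 1L]] <- as.data.frame(go)
        } else {
          message(sprintf("%s/%s: skipping GO enrichment (%d terms < %d needed for lfdr)",
                          tissue, ctr, n_terms, cfg$min_go_terms))
        }
      }
    }
  }

  gsea_report <- if (length(gsea_rows)) do.call(rbind, gsea_rows) else NULL
  go_report <- if (length(go_rows)) do.call(rbind, go_rows) else NULL
  manifest <- list(
    package = "casteGSEA",
    version = as.character(utils::packageVersion("casteGSEA")),
    seed = cfg$seed, B = cfg$B, lfdr_threshold = cfg$lfdr_threshold,
    tissues = tissues, contrasts = cfg$contrasts,
    mode = if (simulate_mode) "simulation" else "input",
    stage_counts = log_counts
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(gsea_report))
      utils::write.table(gsea_report, file.path(cfg$out_dir, "gsea_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(go_report))
      utils::write.table(go_report, file.path(cfg$out_dir, "go_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(gsea_report = gsea_report, go_report = go_report, fits = fits,
       truth = if (simulate_mode) truths else NULL, manifest = manifest)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
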