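#' GO annotation container
#'
#' A gene-to-term mapping plus an optional ontology edge table used for
#' ancestor propagation.
#'
#' @param gene2go Named list mapping each gene id to a character vector of
#'   GO term ids (no empty term ids, unique gene keys).
#' @param edges Optional data frame with columns `child`, `parent`,
#'   `relation` (`"is_a"` or `"part_of"`).
#' @return Object of class `"go_annotation"`.
#' @export
go_annotation <- function(gene2go, edges = NULL) {
  if (anyDuplicated(names(gene2go)))
    stop("duplicate gene ids in annotation", call. = FALSE)
  if (any(vapply(gene2go, function(x) any(!nzchar(x)), logical(1))))
    stop("empty term-id strings in annotation", call. = FALSE)
  structure(list(gene2go = gene2go, edges = edges), class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  terms <- unique(unlist(x$gene2go, use.names = FALSE))
  cat(sprintf("GO annotation: %d genes, %d terms%s\n",
              length(x$gene2go), length(terms),
              if (is.null(x$edges)) "" else sprintf(", %d ontology edges",
                                                    nrow(x$edges))))
  invisible(x)
}

#' Propagate annotations to ancestor terms
#'
#' Standard GO semantics: a gene annotated to a term is implicitly annotated
#' to every ancestor of that term along `is_a`/`part_of` edges. This closure
#' makes term gene counts include descendant annotations and is idempotent.
#'
#' @param annotation A [go_annotation] with a non-null edge table.
#' @return A [go_annotation] with the ancestor-closed mapping.
#' @export
propagate_annotations <- function(annotation) {
  stopifnot(inherits(annotation, "go_annotation"))
  edges <- annotation$edges
  if (is.null(edges) || nrow(edges) == 0L) return(annotation)
  parents <- split(edges$parent, edges$child)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, path = character(0)) {
    if (term %in% path)
      stop("invalid ontology: cycle involving term '", term, "'",
           call. = FALSE)
    if (exists(term, envir = anc_cache, inherits = FALSE))
      return(get(term, envir = anc_cache))
    ps <- parents[[term]]
    out <- if (is.null(ps)) character(0)
    else unique(c(ps, unlist(lapply(ps, ancestors, path = c(path, term)))))
    anc_cache[[term]] <- out
    out
  }
  gene2go <- lapply(annotation$gene2go, function(terms)
    unique(c(terms, unlist(lapply(terms, ancestors)))))
  go_annotation(gene2go, edges)
}

#' Two-tailed KS enrichment test for every GO term on a ranked list
#'
#' For each term with at least `min_size` annotated genes present in the
#' ranked list (and not covering the whole list), tests whether the term's
#' members are displaced toward either extreme of the signed-P ranking with
#' the two-tailed two-sample Kolmogorov-Smirnov test. Terms below the size
#' floor are skipped and counted in a message.
#'
#' @param ranked A `"ranked_list"` from [rank_genes()].
#' @param annotation A [go_annotation] (propagate ancestors first with
#'   [propagate_annotations()] if an ontology is available).
#' @param min_size Minimum term size among ranked genes (default 5).
#' @param labels Length-2 direction labels, low extreme first (default
#'   `c("queen", "worker")`).
#' @return Data frame with columns `term_id`, `member_count`, `D`, `P`,
#'   `direction` (sign of the members' mean signed score: negative means the
#'   low/queen extreme).
#' @export
test_all_terms <- function(ranked, annotation, min_size = 5L,
                           labels = c("queen", "worker")) {
  stopifnot(inherits(annotation, "go_annotation"))
  if (!length(annotation$gene2go))
    stop("empty annotation", call. = FALSE)
  N <- nrow(ranked)
  pos <- stats::setNames(seq_len(N), ranked$gene_id)
  g2g <- annotation$gene2go[names(annotation$gene2go) %in% ranked$gene_id]
  term2gene <- split(rep(names(g2g), lengths(g2g)),
                     unlist(g2g, use.names = FALSE))
  sizes <- lengths(term2gene)
  keep <- sizes >= min_size & sizes < N
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(sprintf("skipping %d term(s) below min_size = %d (or covering the full list)",
                    n_skipped, min_size))
  term2gene <- term2gene[keep]
  if (!length(term2gene))
    return(data.frame(term_id = character(0), member_count = integer(0),
                      D = numeric(0), P = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  rows <- lapply(names(term2gene), function(tm) {
    ranks <- unname(pos[term2gene[[tm]]])
    ks <- ks_two_tailed(ranks, N)
    mean_s <- mean(ranked$s[ranks])
    data.frame(term_id = tm, member_count = length(ranks), D = ks$D,
               P = ks$P, direction = if (mean_s < 0) labels[1] else labels[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call enriched GO terms at an lfdr threshold
#'
#' @param records Data frame with an `lfdr` column (e.g. the output of
#'   [test_all_terms()] augmented with [estimate_lfdr()]).
#' @param threshold Call threshold; a term is enriched when
#'   `lfdr <= threshold` (default 0.05, inclusive).
#' @return The records with an added logical `enriched` column, sorted by
#'   ascending lfdr.
#' @export
call_enriched <- function(records, threshold = 0.05) {
  if (is.null(records$lfdr))
    stop("'records' must carry an lfdr column", call. = FALSE)
  records$enriched <- records$lfdr <= threshold
  records[order(records$lfdr), , drop = FALSE]
}

#' GO-term enrichment on a signed-P ranked list
#'
#' Composition of [propagate_annotations()] (when an ontology is present),
#' [test_all_terms()], [estimate_lfdr()] across all tested terms, and
#' [call_enriched()]. Requires at least 20 testable terms for the lfdr
#' mixture fit.
#'
#' @inheritParams test_all_terms
#' @param threshold lfdr call threshold (default 0.05).
#' @param propagate Propagate ancestor annotations first (default `TRUE`;
#'   only effective when the annotation carries an edge table).
#' @return Object of classes `"go_enrichment"` and `"data.frame"`: the
#'   [test_all_terms()] records plus `lfdr` and `enriched`, sorted by lfdr.
#' @export
go_enrichment <- function(ranked, annotation, min_size = 5L,
                          threshold = 0.05, propagate = TRUE,
                          labels = c("queen", "worker")) {
  if (propagate) annotation <- propagate_annotations(annotation)
  records <- test_all_terms(ranked, annotation, min_size = min_size,
                            labels = labels)
  records$lfdr <- estimate_lfdr(records$P)
  out <- call_enriched(records, threshold = threshold)
  rownames(out) <- NULL
  class(out) <- c("go_enrichment", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.go_enrichment <- function(x, n = 10L, ...) {
  cat(sprintf("GO enrichment: %d terms tested, %d enriched at lfdr <= %g\n",
              nrow(x), sum(x$enriched), attr(x, "threshold")))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 3)
  if (nrow(x) > n) cat(sprintf("  ... %d more terms\n", nrow(x) - n))
  invisible(x)
}
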