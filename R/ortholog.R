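# Gene identification and annotation transfer from tabular similarity-search
# results (the standard 12-column "outfmt 6" dialect).

.HIT_COLS <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_opens",
               "q_start", "q_end", "s_start", "s_end", "e_value",
               "bit_score")

#' Parse a 12-column tabular similarity-search hit file
#'
#' @param path Path to a tab-separated file in the standard 12-column
#'   dialect (query, subject, percent identity, alignment length,
#'   mismatches, gap opens, query/subject start/end, e-value, bit score).
#' @return Data frame with typed columns; malformed lines abort with their
#'   line numbers.
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) {
    orig <- which(keep)[bad]
    stop("malformed hit line(s) (expected 12 columns): line ",
         paste(utils::head(orig, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (any(out$e_value < 0) || any(!is.finite(out$bit_score)))
    stop("invalid hit table: negative e-value or non-finite bit score",
         call. = FALSE)
  out
}

#' Write a hit table back to the 12-column tabular format
#' @param hits Data frame as returned by [parse_hit_table()].
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Top hit of a query
#'
#' Best record by descending bit score, ties broken by ascending e-value,
#' then lexicographic subject id (a deterministic rule; with default search
#' output bit-score and e-value orders coincide).
#'
#' @param hits Hit table.
#' @param query_id Query identifier.
#' @return The subject id, or `NA_character_` if the query has no hits.
#' @export
top_hit <- function(hits, query_id) {
  h <- hits[hits$query_id == query_id, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  h$subject_id[order(-h$bit_score, h$e_value, h$subject_id)][1]
}

# Vectorised top hit per query; returns named character vector.
.top_hits_all <- function(hits) {
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Reciprocal best hits between two search directions
#'
#' A pair (protein, contig) is accepted when the contig is the protein's top
#' hit in the forward search and the protein is the contig's top hit in the
#' reverse search — the classic reciprocal-top-hit rule for identifying the
#' transcriptome copy of a focal gene.
#'
#' @param forward Hit table of proteins searched against contigs.
#' @param reverse Hit table of contigs searched against proteins.
#' @return Data frame with columns `protein_id`, `contig_id`; each protein
#'   and each contig appears at most once.
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  fwd <- .top_hits_all(forward)
  rev_ <- .top_hits_all(reverse)
  keep <- !is.na(fwd) & fwd %in% names(rev_) &
    rev_[fwd] == names(fwd)
  data.frame(protein_id = names(fwd)[keep],
             contig_id = unname(fwd[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expand reciprocal-best-hit labels to whole isogroups
#'
#' A label attached to one contig is propagated to its isogroup (the gene)
#' and all sibling transcripts, since the contigs of an isogroup are
#' putative isoforms of the same gene. Two proteins resolving to the same
#' isogroup are both kept and flagged with a message.
#'
#' @param pairs Data frame with columns `protein_id`, `contig_id` (from
#'   [reciprocal_best_hits()]).
#' @param transcript_map Data frame with columns `transcript_id`, `gene_id`.
#' @return Data frame with columns `protein_id`, `gene_id`, `members`
#'   (comma-joined sibling transcript ids).
#' @export
expand_to_isogroup <- function(pairs, transcript_map) {
  map <- stats::setNames(transcript_map$gene_id, transcript_map$transcript_id)
  missing <- setdiff(pairs$contig_id, names(map))
  if (length(missing))
    stop("missing mapping for contig(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  gene <- unname(map[pairs$contig_id])
  siblings <- split(transcript_map$transcript_id, transcript_map$gene_id)
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    message("multiple proteins labelled the same isogroup: ",
            paste(dup, collapse = ", "))
  data.frame(
    protein_id = pairs$protein_id,
    gene_id = gene,
    members = vapply(siblings[gene], paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Transfer GO terms from top hits at an e-value cutoff
#'
#' Hits weaker than `evalue_cutoff` are discarded; each query then inherits
#' the GO terms of its surviving top hit. Queries with no surviving hit get
#' no annotation and are counted in a message.
#'
#' @param hits Hit table (queries searched against an annotated subject
#'   database).
#' @param subject_go Named list mapping subject ids to character vectors of
#'   GO term ids.
#' @param evalue_cutoff Maximum e-value for a hit to count (default `1e-4`).
#' @return A [go_annotation] for the annotated queries.
#' @export
assign_go_from_hits <- function(hits, subject_go, evalue_cutoff = 1e-4) {
  surviving <- hits[hits$e_value <= evalue_cutoff, , drop = FALSE]
  n_total <- length(unique(hits$query_id))
  tops <- .top_hits_all(surviving)
  n_lost <- n_total - length(tops)
  if (n_lost > 0)
    message(sprintf("%d quer%s with no hit at e-value <= %g left unannotated",
                    n_lost, if (n_lost == 1) "y" else "ies", evalue_cutoff))
  gene2go <- lapply(tops, function(s) subject_go[[s]])
  gene2go <- gene2go[!vapply(gene2go, is.null, logical(1))]
  go_annotation(gene2go)
}
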