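# Plain-text interchange: counts/design/truth as TSV, gene sets as GMT,
# GO annotations as gene TAB semicolon-joined term ids.

#' Read and write count matrices as TSV
#'
#' The on-disk layout is one header row (`gene_id` then sample ids) and one
#' row per gene with integer counts.
#'
#' @param path File path.
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @return `read_counts()` returns the matrix; `write_counts()` returns
#'   `path` invisibly.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample design tables as TSV
#' @param path File path.
#' @param design Data frame as from [generate_design()].
#' @export
read_design <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path File path.
#' @param sets Named list of character vectors of gene ids.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write gene-to-GO annotations as TSV
#'
#' Two tab-separated columns: gene id, then semicolon-joined GO term ids.
#'
#' @param path File path.
#' @param annotation A [go_annotation] object.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed annotation line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  gene2go <- lapply(parts, function(p)
    unique(strsplit(p[2], ";", fixed = TRUE)[[1]]))
  names(gene2go) <- vapply(parts, `[[`, character(1), 1L)
  go_annotation(gene2go)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  gene2go <- annotation$gene2go
  lines <- vapply(names(gene2go), function(g)
    paste0(g, "\t", paste(gene2go[[g]], collapse = ";")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology edge table or OBO-lite file
#'
#' `read_ontology_edges()` reads a 3-column TSV (child, parent, relation).
#' `read_obo_lite()` parses only `id:`, `is_a:` and
#' `relationship: part_of` lines of a [Term] stanza-structured OBO file.
#'
#' @param path File path.
#' @return Data frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @export
read_ontology_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("child", "parent", "relation")
  df
}

#' @rdname read_ontology_edges
#' @export
read_obo_lite <- function(path) {
  lines <- readLines(path)
  child <- NA_character_
  edges <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { child <- NA_character_; next }
    if (startsWith(ln, "id:")) {
      child <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:") && !is.na(child)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(child, parent, "is_a")
    } else if (startsWith(ln, "relationship: part_of") && !is.na(child)) {
      parent <- trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln)))
      edges[[length(edges) + 1L]] <- c(child, parent, "part_of")
    }
  }
  out <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  if (nrow(out)) names(out) <- c("child", "parent", "relation")
  out
}
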