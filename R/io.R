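# Readers/writers. Dialect: tab-separated, UTF-8, '#'-prefixed comment lines
# ignored everywhere; readers reject invariant violations, never repair.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (OTUs or genes). Parsing is strict: duplicate ids and non-numeric cells
#' are errors, never repaired.
#'
#' @param path path to a TSV file; lines starting with `#` are ignored.
#' @param kind `"abundance"` (returns an [abundance_matrix()]) or
#'   `"expression"` (returns an [expression_matrix()]).
#' @return An `abundance_matrix` or `expression_matrix`.
#' @export
read_matrix <- function(path, kind = c("abundance", "expression")) {
  kind <- match.arg(kind)
  lines <- .read_tsv_lines(path)
  if (length(lines) < 2L) stop("no features", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (!length(sample_ids)) stop("no sample columns", call. = FALSE)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncol_expected <- length(header)
  feature_ids <- character(length(rows))
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != ncol_expected) {
      stop(sprintf("row %d has %d fields, expected %d", i + 1L, length(r),
                   ncol_expected), call. = FALSE)
    }
    feature_ids[i] <- r[[1L]]
    num <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop(sprintf("non-numeric cell at row %d (feature '%s'), column '%s'",
                   i + 1L, r[[1L]], sample_ids[j]), call. = FALSE)
    }
    values[i, ] <- num
  }
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup)) {
    stop("duplicate feature id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  if (kind == "abundance") abundance_matrix(values) else expression_matrix(values)
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m an `abundance_matrix` or `expression_matrix`.
#' @param path output path.
#' @param id_column header name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  v <- m$values
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read node annotations from TSV
#'
#' Expects columns `node_id`, `kind`, `regulation`, `group` (header required,
#' any order). All [node_annotations()] invariants are enforced.
#'
#' @param path path to a TSV file.
#' @return A `node_annotations` table.
#' @export
read_annotations <- function(path) {
  lines <- .read_tsv_lines(path)
  if (length(lines) < 1L) stop("empty annotation file", call. = FALSE)
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = TRUE)
  need <- c("node_id", "kind", "regulation", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) df[[col]] <- trimws(df[[col]])
  node_annotations(df$node_id, df$kind, df$regulation, df$group)
}

#' Write node annotations to TSV
#' @param ann a `node_annotations` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Consumes the standard 12-column blastn tabular output (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`);
#' only `qseqid`, `sseqid`, `pident` and `evalue` are retained.
#'
#' @param path path to a BLAST outfmt-6 file.
#' @return data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `evalue`.
#' @export
read_blast_hits <- function(path) {
  lines <- .read_tsv_lines(path)
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 BLAST outfmt-6 columns", call. = FALSE)
  hits <- data.frame(query_id = as.character(df[[1L]]),
                     subject_id = as.character(df[[2L]]),
                     pident = as.numeric(df[[3L]]),
                     evalue = as.numeric(df[[11L]]),
                     stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("pident outside [0,100]", call. = FALSE)
  }
  if (any(hits$evalue < 0)) stop("negative evalue", call. = FALSE)
  hits
}

#' Write a host-microbial network
#'
#' `edge_tsv` writes one row per edge with columns `u`, `v`, `rho`,
#' `p_value`, `sign`, `origin`, endpoints sorted so `u < v`
#' lexicographically and rows sorted by (`u`,`v`); node annotations are not
#' stored (pair the file with its annotation TSV). `graphml` stores nodes
#' with their annotations and all edge attributes, and round-trips
#' losslessly through [read_network()].
#'
#' @param net an `hm_network`.
#' @param path output path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- net$edges
    if (nrow(e)) {
      swap <- e$u > e$v
      tmp <- e$u[swap]; e$u[swap] <- e$v[swap]; e$v[swap] <- tmp
      e <- e[order(e$u, e$v), ]
    }
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("u", "v", "rho", "p_value", "sign", "origin"),
                     collapse = "\t"), con)
    if (nrow(e)) {
      writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%s\t%s",
                         e$u, e$v, e$rho, e$p_value, e$sign, e$origin), con)
    }
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a host-microbial network
#'
#' @param path path written by [write_network()].
#' @param format `"edge_tsv"` or `"graphml"`.
#' @param annotations for `edge_tsv`, the `node_annotations` table defining
#'   the node set (edge lists do not store nodes, so isolated nodes and node
#'   attributes come from here); ignored for `graphml`.
#' @return An `hm_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml"),
                         annotations = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    if (is.null(annotations)) {
      stop("edge_tsv networks need an annotation table for the node set",
           call. = FALSE)
    }
    lines <- .read_tsv_lines(path)
    if (length(lines) < 1L) stop("missing edge header", call. = FALSE)
    if (length(lines) == 1L) {
      return(hm_network(annotations))
    }
    e <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
    hm_network(annotations, e)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    from_igraph(g)
  }
}

#' Convert a host-microbial network to an igraph object
#'
#' Node attributes `kind`, `regulation`, `group` and edge attributes `rho`,
#' `p_value`, `sign`, `origin` are carried over.
#'
#' @param net an `hm_network`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  vertices <- net$nodes
  names(vertices)[1L] <- "name"
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Convert an igraph object back to a host-microbial network
#' @param g an undirected igraph graph with the attributes written by
#'   [as_igraph()].
#' @return An `hm_network`.
#' @export
from_igraph <- function(g) {
  vdf <- igraph::as_data_frame(g, what = "vertices")
  ann <- node_annotations(vdf$name, vdf$kind, vdf$regulation, vdf$group)
  edf <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edf)) {
    names(edf)[1:2] <- c("u", "v")
    hm_network(ann, edf)
  } else {
    hm_network(ann)
  }
}

#' Write a centrality ranking table
#'
#' Columns: `node_id`, `kind`, `group`, `score`, `rank`.
#'
#' @param ranking a `bpbc_ranking` (see [bpbc()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
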