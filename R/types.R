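#' @keywords internal
"_PACKAGE"

# Closed vocabularies shared across the package.
KIND_LEVELS <- c("microbe", "gene")
REGULATION_LEVELS <- c("up", "down", "none")
GROUP_LEVELS <- c("cell_cycle", "antiviral_response",
                  "epithelial_cell_differentiation", "other", "microbe")
SIGN_LEVELS <- c("positive", "negative")
ORIGIN_LEVELS <- c("measured", "inferred")

#' Construct an abundance matrix
#'
#' An abundance matrix holds OTU-level microbial measurements: rows are OTUs,
#' columns are samples, entries are non-negative read counts or per-sample
#' proportions.
#'
#' @param values numeric matrix with OTU ids as rownames and sample ids as
#'   colnames; all entries must be non-negative and finite.
#' @param is_normalized logical; `TRUE` when every sample column holds
#'   proportions summing to one.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, is_normalized = FALSE) {
  values <- .check_feature_matrix(values, feature_what = "OTU")
  if (any(values < 0)) {
    stop("abundance values must be non-negative", call. = FALSE)
  }
  if (isTRUE(is_normalized)) {
    # proportions: each value in [0,1]; a column sums to 1 for a full OTU
    # set and to < 1 after row selection (top-k keeps proportions of the
    # original per-sample totals)
    sums <- colSums(values)
    if (any(values > 1) || any(sums > 1 + 1e-9)) {
      bad <- colnames(values)[which.max(sums)]
      stop("is_normalized = TRUE but column '", bad,
           "' is not made of proportions", call. = FALSE)
    }
  }
  structure(list(values = values, is_normalized = isTRUE(is_normalized)),
            class = "abundance_matrix")
}

#' Construct an expression matrix
#'
#' Host gene-expression values on the same samples as a companion abundance
#' matrix: rows are genes, columns are samples.
#'
#' @param values numeric matrix with gene symbols as rownames and sample ids
#'   as colnames.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- .check_feature_matrix(values, feature_what = "gene")
  structure(list(values = values), class = "expression_matrix")
}

.check_feature_matrix <- function(values, feature_what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L) stop("no features", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry ", feature_what, " rownames and sample colnames",
         call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) {
    stop("duplicate feature id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) {
    stop("duplicate sample id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite value in matrix", call. = FALSE)
  }
  values
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d OTUs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_normalized) "normalized proportions" else "raw counts"))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a node annotation table
#'
#' Each network node carries a kind (`microbe` or `gene`), a regulation label
#' (`up`, `down` for differentially expressed genes, `none` otherwise) and a
#' functional group. Genes belong to one of the four DEG categories
#' (`cell_cycle`, `antiviral_response`, `epithelial_cell_differentiation`,
#' `other`); microbes always carry group `microbe` and regulation `none`.
#'
#' @param node_id character vector of node identifiers.
#' @param kind character vector, `microbe` or `gene`.
#' @param regulation character vector, `up`, `down` or `none`.
#' @param group character vector over the closed group vocabulary.
#' @return A `data.frame` of class `node_annotations` with one row per node.
#' @export
node_annotations <- function(node_id, kind, regulation, group) {
  ann <- data.frame(node_id = as.character(node_id),
                    kind = as.character(kind),
                    regulation = as.character(regulation),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("node_id", "kind", "regulation", "group") %in% names(ann)))
  dup <- unique(ann$node_id[duplicated(ann$node_id)])
  if (length(dup)) {
    stop("duplicate node id in annotations: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(ann$kind), KIND_LEVELS)
  if (length(bad)) stop("unknown kind: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$regulation), REGULATION_LEVELS)
  if (length(bad)) stop("unknown regulation: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group: ", paste(bad, collapse = ", "), call. = FALSE)
  is_microbe <- ann$kind == "microbe"
  if (any(is_microbe & (ann$regulation != "none" | ann$group != "microbe"))) {
    bad <- ann$node_id[is_microbe & (ann$regulation != "none" | ann$group != "microbe")]
    stop("microbe node must have regulation 'none' and group 'microbe': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is_microbe & ann$group == "microbe")) {
    bad <- ann$node_id[!is_microbe & ann$group == "microbe"]
    stop("gene node cannot have group 'microbe': ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(ann) <- c("node_annotations", "data.frame")
  ann
}

#' Construct a host-microbial network
#'
#' An undirected graph whose nodes are microbes and host genes and whose
#' edges are thresholded Spearman correlations. Each edge records the
#' correlation coefficient `rho`, its `p_value`, a `sign`
#' (`positive`/`negative`, always matching the sign of `rho`) and an
#' `origin` (`measured` from the data, or `inferred` by the false-negative
#' correction rule).
#'
#' @param nodes a [node_annotations()] table; isolated nodes are retained.
#' @param edges data.frame with columns `u`, `v`, `rho`, `p_value`, `sign`,
#'   `origin`.
#' @param check logical; when `TRUE` (default) the network must be simple
#'   (no self-loops, no parallel edges). Set `FALSE` only to represent a raw
#'   uncorrected graph, e.g. the false-positive fixture.
#' @return An object of class `hm_network`.
#' @export
hm_network <- function(nodes, edges = NULL, check = TRUE) {
  nodes <- validate_annotations(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = character(), v = character(), rho = numeric(),
                        p_value = numeric(), sign = character(),
                        origin = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("u", "v", "rho", "p_value", "sign", "origin") %in% names(edges)))
  edges <- edges[, c("u", "v", "rho", "p_value", "sign", "origin")]
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  unknown <- setdiff(unique(c(edges$u, edges$v)), nodes$node_id)
  if (length(unknown)) {
    stop("edge endpoint not in node set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(edges$sign), SIGN_LEVELS)
  if (length(bad)) stop("unknown edge sign: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(edges$origin), ORIGIN_LEVELS)
  if (length(bad)) stop("unknown edge origin: ", paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(edges)) {
    mismatch <- (edges$sign == "positive") != (edges$rho > 0)
    if (any(mismatch & edges$u != edges$v)) {
      stop("edge sign must match the sign of rho", call. = FALSE)
    }
  }
  if (check) {
    # canonical orientation: u < v lexicographically
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    if (any(edges$u == edges$v)) stop("self-loop in simple network", call. = FALSE)
    key <- paste(edges$u, edges$v, sep = "\r")
    if (anyDuplicated(key)) stop("parallel edges in simple network", call. = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, simple = isTRUE(check)),
            class = "hm_network")
}

#' @export
print.hm_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(paste0("hm_network: %d nodes (%d microbes, %d genes), %d edges ",
                     "(%d positive, %d negative; %d measured, %d inferred)\n"),
              s$n_nodes, s$n_microbes, s$n_genes, s$n_edges,
              s$n_positive, s$n_negative, s$n_measured, s$n_inferred))
  invisible(x)
}

#' Canonical key for an unordered edge
#'
#' Endpoint order does not matter in an undirected network; this returns a
#' key that is identical for `(u, v)` and `(v, u)`, used for edge set
#' comparisons.
#'
#' @param u,v character vectors of endpoint ids (recycled pairwise).
#' @return character vector of keys.
#' @export
edge_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\r")
}

#' Test two networks for equality
#'
#' Node sets, annotations, edge sets and edge attributes are compared;
#' numeric attributes to within `tol`.
#'
#' @param a,b `hm_network` objects.
#' @param tol numeric tolerance for `rho` and `p_value`.
#' @return logical scalar.
#' @export
networks_equal <- function(a, b, tol = 1e-12) {
  na <- a$nodes[order(a$nodes$node_id), ]
  nb <- b$nodes[order(b$nodes$node_id), ]
  if (!identical(na$node_id, nb$node_id) || !identical(na$kind, nb$kind) ||
      !identical(na$regulation, nb$regulation) || !identical(na$group, nb$group)) {
    return(FALSE)
  }
  ea <- a$edges; eb <- b$edges
  if (nrow(ea) != nrow(eb)) return(FALSE)
  if (nrow(ea) == 0L) return(TRUE)
  ea <- ea[order(edge_key(ea$u, ea$v)), ]
  eb <- eb[order(edge_key(eb$u, eb$v)), ]
  all(edge_key(ea$u, ea$v) == edge_key(eb$u, eb$v)) &&
    all(abs(ea$rho - eb$rho) <= tol) &&
    all(abs(ea$p_value - eb$p_value) <= tol) &&
    identical(ea$sign, eb$sign) && identical(ea$origin, eb$origin)
}
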