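# OTU-table processing: per-sample proportion normalization, best-hit
# collapse maps from filtered BLAST hits, and top-k abundance selection.

#' Normalize OTU counts to per-sample proportions
#'
#' Each value is divided by its sample's column total, so every column of
#' the result sums to one. Sequencing depth varies across samples; relative
#' abundance makes them comparable.
#'
#' @param m an [abundance_matrix()] of raw counts.
#' @return A normalized `abundance_matrix`; the input is unmodified.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  totals <- colSums(m$values)
  if (any(totals <= 0)) {
    bad <- colnames(m$values)[totals <= 0]
    stop("zero-depth sample: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  abundance_matrix(sweep(m$values, 2L, totals, "/"), is_normalized = TRUE)
}

#' Filter BLAST hits on e-value and percent identity
#'
#' Keeps exactly the hits with `evalue < evalue_max` and
#' `pident > pident_min` — both strict, so a hit sitting exactly on a
#' threshold is dropped. Input order is preserved.
#'
#' @param hits data.frame as returned by [read_blast_hits()].
#' @param evalue_max e-value ceiling (default `1e-5`).
#' @param pident_min percent-identity floor (default `80`).
#' @return The filtered data.frame (possibly empty).
#' @export
filter_blast_hits <- function(hits, evalue_max = 1e-5, pident_min = 80) {
  stopifnot(is.finite(evalue_max) || evalue_max == Inf, is.finite(pident_min))
  keep <- hits$evalue < evalue_max & hits$pident > pident_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an OTU collapse map from filtered BLAST hits
#'
#' Each query OTU is assigned its best hit (lowest e-value, then highest
#' percent identity, then lexicographically smallest subject id). Queries
#' whose best hits share a reference subject are collapsed into one OTU
#' named `collapsed:<subject_id>`; OTUs with no surviving hit map to
#' themselves.
#'
#' @param hits filtered BLAST hits (see [filter_blast_hits()]).
#' @param otu_ids character vector of all OTU ids in the abundance matrix.
#' @return A list of class `collapse_map` with elements `member_of` (named
#'   character vector raw id -> collapsed id) and `members` (named list
#'   collapsed id -> character vector of raw ids).
#' @export
build_collapse_map <- function(hits, otu_ids) {
  unknown <- setdiff(unique(hits$query_id), otu_ids)
  if (length(unknown)) {
    stop("BLAST query id not in OTU table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  member_of <- stats::setNames(otu_ids, otu_ids)
  if (nrow(hits)) {
    ord <- order(hits$query_id, hits$evalue, -hits$pident, hits$subject_id)
    best <- hits[ord, ][!duplicated(hits$query_id[ord]), ]
    # only subjects hit by >= 2 queries trigger a merge; a lone best hit
    # leaves the OTU unrenamed
    subj_n <- table(best$subject_id)
    merged <- best[best$subject_id %in% names(subj_n)[subj_n >= 2L], ]
    if (nrow(merged)) {
      member_of[merged$query_id] <- paste0("collapsed:", merged$subject_id)
    }
  }
  members <- split(names(member_of), member_of)
  members <- lapply(members, sort)
  structure(list(member_of = member_of, members = members),
            class = "collapse_map")
}

#' Collapse rows of an abundance matrix
#'
#' Rows of OTUs mapping to the same collapsed id are summed (collapse
#' happens on raw counts, before normalization, so the arithmetic is exact
#' and per-sample totals are conserved). Row order follows the first
#' appearance of each collapsed id in the input.
#'
#' @param m an [abundance_matrix()] of raw counts.
#' @param cmap a `collapse_map` from [build_collapse_map()].
#' @return The collapsed `abundance_matrix`.
#' @export
collapse_matrix <- function(m, cmap) {
  stopifnot(inherits(m, "abundance_matrix"), inherits(cmap, "collapse_map"))
  ids <- rownames(m$values)
  miss <- setdiff(ids, names(cmap$member_of))
  if (length(miss)) {
    stop("collapse map does not cover OTU(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(cmap$member_of), ids)
  if (length(extra)) {
    stop("collapse map references unknown OTU(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  target <- cmap$member_of[ids]
  target <- factor(target, levels = unique(target))  # first-appearance order
  collapsed <- rowsum(m$values, group = target, reorder = FALSE)
  abundance_matrix(as.matrix(collapsed), is_normalized = m$is_normalized)
}

#' Select the top-k most abundant OTUs
#'
#' Abundance is ranked by mean per-sample relative abundance; ties are
#' broken lexicographically by OTU id. Less abundant microbes are unlikely
#' drivers of host response, so downstream network inference keeps only the
#' dominant ones (default `k = 259`).
#'
#' @param m a normalized [abundance_matrix()].
#' @param k number of OTUs to keep; if `k >= nrow`, all rows are kept.
#' @return The filtered `abundance_matrix`, rows ordered by decreasing mean
#'   abundance.
#' @export
select_top_k <- function(m, k = 259) {
  stopifnot(inherits(m, "abundance_matrix"), k >= 1)
  if (!m$is_normalized) {
    stop("select_top_k expects a normalized abundance matrix", call. = FALSE)
  }
  means <- rowMeans(m$values)
  ord <- order(-means, rownames(m$values))
  keep <- ord[seq_len(min(k, nrow(m$values)))]
  abundance_matrix(m$values[keep, , drop = FALSE], is_normalized = TRUE)
}
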