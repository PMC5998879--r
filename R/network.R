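# Spearman correlation over all node pairs, thresholding into an undirected
# host-microbial network, and coherence-based error correction.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average-ranked values (ties receive
#' their average rank). The two-sided p-value uses the large-sample t
#' approximation with `n - 2` degrees of freedom, which is standard at the
#' sample sizes (~58) this pipeline targets; an exact permutation p-value is
#' available for very small n.
#'
#' A constant vector has zero rank variance: the correlation is undefined
#' and both `rho` and `p_value` are returned as `NA`, a sentinel that can
#' never form an edge.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; ties allowed.
#' @param method `"t_approx"` (default) or `"permutation"` (exact
#'   enumeration over all `n!` orderings; only sensible for `n < 10`).
#' @return named numeric vector `c(rho = , p_value = )`.
#' @export
spearman <- function(x, y, method = c("t_approx", "permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(c(rho = NA_real_, p_value = NA_real_))
  }
  rho <- .rank_pearson(rx, ry)
  if (method == "t_approx") {
    p <- .spearman_p_t(rho, n)
  } else {
    if (n > 9L) stop("permutation p-value only supported for n < 10", call. = FALSE)
    perms <- .permutations(n)
    obs <- abs(rho)
    stat <- apply(perms, 1L, function(pr) abs(stats::cor(rx, ry[pr])))
    p <- mean(stat >= obs - 1e-12)
  }
  c(rho = rho, p_value = p)
}

# Pearson correlation of rank vectors. Ranks (and their mean) are exact
# multiples of 0.5, so the centered cross-products and sums of squares are
# exact in double precision; a single final division keeps simple rationals
# (e.g. 8/10) correctly rounded.
.rank_pearson <- function(rx, ry) {
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  num <- sum(cx * cy)
  den <- sqrt(sum(cx * cx) * sum(cy * cy))
  max(-1, min(1, num / den))
}

.spearman_p_t <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman correlations for every node pair
#'
#' Aligns the two matrices on their shared sample ids (the sets must be
#' equal; column order may differ) and computes the Spearman statistic for
#' every unordered pair across the union of microbe and gene nodes —
#' microbe-gene, microbe-microbe and gene-gene alike. Pairs involving a
#' constant feature (zero rank variance) are dropped.
#'
#' @param microbes an [abundance_matrix()].
#' @param genes an [expression_matrix()].
#' @return data.frame of correlation records with columns `u`, `v`, `rho`,
#'   `p_value`, one row per unordered pair, `u < v` lexicographically.
#' @export
correlate_all <- function(microbes, genes) {
  stopifnot(inherits(microbes, "abundance_matrix"),
            inherits(genes, "expression_matrix"))
  sa <- colnames(microbes$values); sb <- colnames(genes$values)
  if (!setequal(sa, sb)) {
    stop("sample ids differ between matrices: ",
         paste(c(setdiff(sa, sb), setdiff(sb, sa)), collapse = ", "),
         call. = FALSE)
  }
  shared_nodes <- intersect(rownames(microbes$values), rownames(genes$values))
  if (length(shared_nodes)) {
    stop("node id used for both a microbe and a gene: ",
         paste(shared_nodes, collapse = ", "), call. = FALSE)
  }
  samples <- sa
  m <- rbind(microbes$values[, samples, drop = FALSE],
             genes$values[, samples, drop = FALSE])
  .records_from_matrix(m)
}

# all-pairs Spearman on a node x sample matrix via Pearson on row ranks
.records_from_matrix <- function(m) {
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  ranks <- t(apply(m, 1L, rank))
  keep <- apply(ranks, 1L, stats::var) > 0
  ranks <- ranks[keep, , drop = FALSE]
  ids <- rownames(ranks)
  if (length(ids) < 2L) {
    return(data.frame(u = character(), v = character(), rho = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  C <- stats::cor(t(ranks))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[idx]
  rho <- pmin(1, pmax(-1, rho))
  p <- vapply(rho, .spearman_p_t, numeric(1), n = n)
  u <- ids[idx[, 1L]]; v <- ids[idx[, 2L]]
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  out <- data.frame(u = u, v = v, rho = rho, p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), ]
  rownames(out) <- NULL
  out
}

#' Threshold correlation records into a network
#'
#' An edge is created iff `|rho| > rho_min` and `p_value < p_max`, both
#' strict. The edge sign follows the sign of rho; all edges are marked
#' `origin = "measured"`. Nodes that end up with no edge are retained as
#' isolated nodes.
#'
#' @param records correlation records from [correlate_all()].
#' @param annotations a [node_annotations()] table covering every record
#'   endpoint (unannotated endpoints are an error).
#' @param rho_min correlation magnitude threshold (default 0.4).
#' @param p_max p-value threshold (default 0.05).
#' @param node_pairs `"all"` (default) keeps microbe-microbe and gene-gene
#'   edges too; `"microbe_gene"` restricts edges to cross-kind pairs.
#' @param bh_correction apply Benjamini-Hochberg adjustment to the record
#'   p-values before thresholding (off by default; the raw p < 0.05 rule is
#'   the reference behaviour).
#' @return An `hm_network`.
#' @export
build_network <- function(records, annotations, rho_min = 0.4, p_max = 0.05,
                          node_pairs = c("all", "microbe_gene"),
                          bh_correction = FALSE) {
  node_pairs <- match.arg(node_pairs)
  annotations <- validate_annotations(annotations)
  endpoints <- unique(c(records$u, records$v))
  unknown <- setdiff(endpoints, annotations$node_id)
  if (length(unknown)) {
    stop("unannotated node id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- records$p_value
  if (isTRUE(bh_correction)) p <- stats::p.adjust(p, method = "BH")
  ok <- !is.na(records$rho) & abs(records$rho) > rho_min & p < p_max
  if (node_pairs == "microbe_gene") {
    kind <- stats::setNames(annotations$kind, annotations$node_id)
    ok <- ok & kind[records$u] != kind[records$v]
  }
  e <- records[ok, , drop = FALSE]
  if (nrow(e) == 0L) return(hm_network(annotations))
  edges <- data.frame(u = e$u, v = e$v, rho = e$rho, p_value = e$p_value,
                      sign = ifelse(e$rho > 0, "positive", "negative"),
                      origin = "measured", stringsAsFactors = FALSE)
  hm_network(annotations, edges)
}

#' Remove false-positive edges
#'
#' A thresholded correlation can still be biologically incoherent. Four
#' scenes are treated as false positives and removed:
#' 1. negative edges joining two nodes with the same regulation label
#'    (both up or both down);
#' 2. positive edges joining an up-regulated and a down-regulated node;
#' 3. self-loops;
#' 4. parallel (duplicate) edges — the copy with the largest `|rho|`
#'    (then smallest p-value) survives.
#'
#' The coherence rules 1-2 apply only where both endpoints carry an up/down
#' label, i.e. gene-gene edges; microbes carry no regulation label and any
#' microbe-involved edge is untouched by them.
#'
#' @param net an `hm_network` (possibly non-simple).
#' @return A simple `hm_network`; the removed edges, with a `reason` column
#'   (`self_loop`, `parallel`, `incoherent_negative`, `incoherent_positive`),
#'   are attached as attribute `"removed_edges"`.
#' @export
remove_false_positives <- function(net) {
  e <- net$edges
  removed <- list()
  if (nrow(e)) {
    # scene 3: self-loops
    loop <- e$u == e$v
    if (any(loop)) {
      removed$self_loop <- cbind(e[loop, ], reason = "self_loop")
      e <- e[!loop, , drop = FALSE]
    }
    # scene 4: parallel edges; keep max |rho|, then min p
    if (nrow(e)) {
      key <- edge_key(e$u, e$v)
      ord <- order(key, -abs(e$rho), e$p_value)
      e <- e[ord, , drop = FALSE]
      dup <- duplicated(key[ord])
      if (any(dup)) {
        removed$parallel <- cbind(e[dup, ], reason = "parallel")
        e <- e[!dup, , drop = FALSE]
      }
    }
    # scenes 1-2: regulation/correlation coherence on labelled endpoints
    if (nrow(e)) {
      reg <- stats::setNames(net$nodes$regulation, net$nodes$node_id)
      ru <- reg[e$u]; rv <- reg[e$v]
      labelled <- ru %in% c("up", "down") & rv %in% c("up", "down")
      bad_neg <- labelled & e$sign == "negative" & ru == rv
      bad_pos <- labelled & e$sign == "positive" & ru != rv
      if (any(bad_neg)) {
        removed$incoherent_negative <-
          cbind(e[bad_neg, ], reason = "incoherent_negative")
      }
      if (any(bad_pos)) {
        removed$incoherent_positive <-
          cbind(e[bad_pos, ], reason = "incoherent_positive")
      }
      e <- e[!(bad_neg | bad_pos), , drop = FALSE]
    }
  }
  out <- hm_network(net$nodes, e)
  log <- if (length(removed)) do.call(rbind, removed) else
    cbind(net$edges[0, ], reason = character())
  rownames(log) <- NULL
  attr(out, "removed_edges") <- log
  out
}

#' Add inferred false-negative edges for collapsed OTUs
#'
#' Collapsing OTUs can hide real associations: if a collapsed OTU absorbs
#' several sub-OTUs and every one of them, on the uncollapsed data, is
#' strongly correlated with a gene in the same direction, the missing
#' collapsed-OTU-gene edge is treated as a false negative and added.
#'
#' Conditions for adding an edge between collapsed OTU `O` and gene `g`:
#' no existing `O`-`g` edge; `O` absorbs at least `min_subnodes` raw OTUs;
#' every sub-OTU's record against `g` passes `|rho| > rho_min` and
#' `p < p_max` with a common sign. The inferred edge takes `rho` = mean of
#' the sub-OTU rhos, `p_value` = max of their p-values (conservative), the
#' common sign, and `origin = "inferred"`.
#'
#' @param net a corrected `hm_network` over the collapsed node set.
#' @param cmap the `collapse_map` used to collapse the abundance matrix.
#' @param raw_records correlation records computed on the *uncollapsed*
#'   abundance matrix against the same genes (see [correlate_all()]).
#' @param rho_min,p_max thresholds; defaults match [build_network()].
#' @param min_subnodes minimum number of absorbed sub-OTUs (default 2).
#' @return An `hm_network` with the inferred edges added; the additions are
#'   attached as attribute `"added_edges"`.
#' @export
add_false_negatives <- function(net, cmap, raw_records, rho_min = 0.4,
                                p_max = 0.05, min_subnodes = 2L) {
  stopifnot(inherits(cmap, "collapse_map"))
  collapsed_ids <- names(cmap$members)[
    vapply(cmap$members, length, integer(1)) >= min_subnodes]
  collapsed_ids <- intersect(collapsed_ids, net$nodes$node_id)
  genes <- net$nodes$node_id[net$nodes$kind == "gene"]
  existing <- edge_key(net$edges$u, net$edges$v)
  rec_key <- edge_key(raw_records$u, raw_records$v)
  rec_index <- split(seq_len(nrow(raw_records)), rec_key)
  raw_nodes <- unique(c(raw_records$u, raw_records$v))
  added <- list()
  for (O in collapsed_ids) {
    subs <- cmap$members[[O]]
    miss <- setdiff(subs, raw_nodes)
    if (length(miss)) {
      stop("collapse map sub-OTU(s) absent from raw records: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (g in genes) {
      if (edge_key(O, g) %in% existing) next
      idx <- unlist(rec_index[edge_key(subs, g)], use.names = FALSE)
      if (length(idx) < length(subs)) next  # some pair had no record
      r <- raw_records[idx, ]
      pass <- abs(r$rho) > rho_min & r$p_value < p_max
      if (!all(pass)) next
      signs <- sign(r$rho)
      if (length(unique(signs)) != 1L) next
      added[[length(added) + 1L]] <- data.frame(
        u = O, v = g, rho = mean(r$rho), p_value = max(r$p_value),
        sign = if (signs[1L] > 0) "positive" else "negative",
        origin = "inferred", stringsAsFactors = FALSE)
    }
  }
  add_df <- if (length(added)) do.call(rbind, added) else net$edges[0, ]
  out <- hm_network(net$nodes, rbind(net$edges, add_df))
  attr(out, "added_edges") <- add_df
  out
}
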