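# Bi-partite betweenness centrality (BpBC): for two designated sub-networks
# S and T, g(v) = sum over pairs (s in S, t in T) of the fraction of
# unweighted shortest s-t paths that pass through v as an interior vertex.
# High g(v) marks nodes mediating the communication between the two groups.

#' Bi-partite betweenness centrality
#'
#' For every node `v`, computes
#' `g(v) = sum_{s in source, t in target} delta_st(v) / delta_st`, where
#' `delta_st` is the number of unweighted shortest paths between `s` and
#' `t`, and `delta_st(v)` the number of those with `v` strictly interior
#' (endpoints are excluded, as in standard betweenness). Each unordered
#' pair is counted once; pairs with no connecting path contribute 0. Every
#' node receives a score, including members of either group when they are
#' not an endpoint of the pair being counted.
#'
#' The implementation is a Brandes-style single-source accumulation
#' restricted to target-group endpoints, which equals the brute-force
#' definition exactly.
#'
#' @param net a simple undirected `hm_network`.
#' @param source_group,target_group distinct group labels from the closed
#'   vocabulary (e.g. `"microbe"` and `"antiviral_response"`); both groups
#'   must be non-empty in the network.
#' @return A data.frame of class `bpbc_ranking` with columns `node_id`,
#'   `kind`, `group`, `score`, `rank`, sorted by decreasing score with ties
#'   broken lexicographically by node id; the group pair is attached as
#'   attributes `source_group` and `target_group`.
#' @export
bpbc <- function(net, source_group, target_group) {
  stopifnot(inherits(net, "hm_network"))
  if (!isTRUE(net$simple)) stop("network must be simple", call. = FALSE)
  if (identical(source_group, target_group)) {
    stop("source and target groups must differ", call. = FALSE)
  }
  for (gl in c(source_group, target_group)) {
    if (!gl %in% GROUP_LEVELS) stop("unknown group label: ", gl, call. = FALSE)
    if (!any(net$nodes$group == gl)) stop("empty group: ", gl, call. = FALSE)
  }
  ids <- net$nodes$node_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  if (nrow(net$edges)) {
    ui <- idx[net$edges$u]; vi <- idx[net$edges$v]
    for (k in seq_along(ui)) {
      adj[[ui[k]]] <- c(adj[[ui[k]]], vi[k])
      adj[[vi[k]]] <- c(adj[[vi[k]]], ui[k])
    }
  }
  src <- which(net$nodes$group == source_group)
  is_target <- net$nodes$group == target_group
  score <- numeric(n)
  for (s in src) {
    score <- score + .bpbc_from_source(adj, n, s, is_target)
  }
  out <- data.frame(node_id = ids, kind = net$nodes$kind,
                    group = net$nodes$group, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node_id), ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  structure(out, class = c("bpbc_ranking", "data.frame"),
            source_group = source_group, target_group = target_group)
}

# Brandes (2001)-style dependency accumulation from one source, with the
# unit "pair mass" deposited only at target-group endpoints.
.bpbc_from_source <- function(adj, n, s, is_target) {
  dist <- rep.int(-1L, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  order_visited <- integer(0)
  while (head <= tail) {
    w <- queue[head]; head <- head + 1L
    order_visited <- c(order_visited, w)
    for (x in adj[[w]]) {
      if (dist[x] < 0L) {
        dist[x] <- dist[w] + 1L
        tail <- tail + 1L
        queue[tail] <- x
      }
      if (dist[x] == dist[w] + 1L) {
        sigma[x] <- sigma[x] + sigma[w]
        preds[[x]] <- c(preds[[x]], w)
      }
    }
  }
  delta <- numeric(n)
  for (w in rev(order_visited)) {
    coeff <- (delta[w] + as.numeric(is_target[w] && w != s)) / sigma[w]
    for (v in preds[[w]]) {
      delta[v] <- delta[v] + sigma[v] * coeff
    }
  }
  delta[s] <- 0
  delta
}

#' Rank candidate key factors for a set of group pairs
#'
#' Runs [bpbc()] for each (source, target) group pair and returns the
#' top-scoring nodes per pair: the candidate key risk factors mediating the
#' communication between the microbe sub-network and a functional gene
#' group.
#'
#' @param net a simple `hm_network`.
#' @param pairs a list of 2-element character vectors
#'   `c(source_group, target_group)`; defaults to the three reference
#'   pairs: microbe vs antiviral response, cell cycle, and epithelial cell
#'   differentiation.
#' @param top_n number of top-ranked nodes per pair (default 10).
#' @return A named list of `bpbc_ranking` tables (names
#'   `"source:target"`), each truncated to `top_n` rows.
#' @export
rank_key_factors <- function(net, pairs = default_group_pairs(), top_n = 10) {
  stopifnot(length(pairs) >= 1L, top_n >= 1)
  out <- list()
  for (p in pairs) {
    stopifnot(length(p) == 2L)
    r <- bpbc(net, p[[1L]], p[[2L]])
    out[[paste(p, collapse = ":")]] <- r[seq_len(min(top_n, nrow(r))), ]
  }
  out
}

#' The three reference group pairs
#'
#' Microbe sub-network against each of the three functional DEG groups:
#' antiviral response, cell cycle, epithelial cell differentiation.
#'
#' @return list of 2-element character vectors.
#' @export
default_group_pairs <- function() {
  list(c("microbe", "antiviral_response"),
       c("microbe", "cell_cycle"),
       c("microbe", "epithelial_cell_differentiation"))
}
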