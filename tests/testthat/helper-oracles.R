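# Shared fixtures and independent oracles used across test files.

# Brute-force bi-partite betweenness: enumerate every shortest path per
# (source, target) pair with igraph and count interior occurrences.
# Independent of the package's Brandes-style accumulation.
bpbc_bruteforce <- function(net, source_group, target_group) {
  g <- kfnet::as_igraph(net)
  ids <- net$nodes$node_id
  score <- stats::setNames(numeric(length(ids)), ids)
  src <- ids[net$nodes$group == source_group]
  tgt <- ids[net$nodes$group == target_group]
  for (s in src) {
    for (t in tgt) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
      if (!length(paths)) next
      n_paths <- length(paths)
      for (p in paths) {
        nm <- names(p)
        interior <- nm[-c(1L, length(nm))]
        if (length(interior)) {
          score[interior] <- score[interior] + 1 / n_paths
        }
      }
    }
  }
  score
}

# Seeded Erdos-Renyi hm_network with random disjoint source/target groups.
random_group_network <- function(seed, n = 10, p = 0.3,
                                 source_size = 3, target_size = 3) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  groups <- rep("other", n)
  pick <- sample(n, source_size + target_size)
  groups[pick[seq_len(source_size)]] <- "microbe"
  groups[pick[source_size + seq_len(target_size)]] <- "antiviral_response"
  ann <- kfnet::node_annotations(
    node_id = ids,
    kind = ifelse(groups == "microbe", "microbe", "gene"),
    regulation = ifelse(groups == "microbe", "none", "up"),
    group = groups)
  edges <- if (nrow(e)) {
    data.frame(u = ids[e[, 1L]], v = ids[e[, 2L]],
               rho = stats::runif(nrow(e), 0.41, 0.95),
               p_value = stats::runif(nrow(e), 0, 0.049),
               sign = "positive", origin = "measured",
               stringsAsFactors = FALSE)
  } else NULL
  kfnet::hm_network(ann, edges)
}

# Path graph s - v1 - ... - vk - t as an hm_network, with s a microbe and
# t a gene in a named group.
path_network <- function(k_interior = 3) {
  interior <- sprintf("MID_%d", seq_len(k_interior))
  ids <- c("SRC", interior, "TGT")
  ann <- kfnet::node_annotations(
    node_id = ids,
    kind = c("microbe", rep("gene", k_interior), "gene"),
    regulation = c("none", rep("up", k_interior + 1L)),
    group = c("microbe", rep("other", k_interior), "antiviral_response"))
  e <- data.frame(u = ids[-length(ids)], v = ids[-1L],
                  rho = 0.8, p_value = 0.001, sign = "positive",
                  origin = "measured", stringsAsFactors = FALSE)
  kfnet::hm_network(ann, e)
}

# Small abundance / expression fixture matrices built in code.
tiny_abundance <- function() {
  m <- matrix(c(2, 1, 5,
                2, 3, 5,
                0, 4, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                              c("s1", "s2", "s3")))
  kfnet::abundance_matrix(m)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
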