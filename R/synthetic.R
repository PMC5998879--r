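# Seeded synthetic co-measured abundance/expression generator. A latent
# Gaussian copula carries the planted pairwise Spearman correlations;
# microbial counts arise by pushing latent normals through a log-normal
# intensity and a per-sample multinomial read draw, expression by adding
# independent Gaussian noise to the latent variables.

#' Describe a synthetic co-measured dataset
#'
#' @param n_otus,n_genes numbers of OTU and gene features.
#' @param n_samples number of co-measured samples (default 58, the scale of
#'   a single-cohort carcinoma study).
#' @param planted_edges data.frame with columns `u`, `v`, `target_rho`
#'   (|target_rho| <= 1) naming node pairs whose population Spearman
#'   correlation is planted; all other pairs are independent in the latent
#'   copula. May be `NULL`.
#' @param deg_fraction_up fraction of genes labelled up-regulated
#'   (default 0.5).
#' @param group_proportions named numeric vector over the four gene groups,
#'   summing to 1.
#' @param collapse_groups list of character vectors of OTU ids; each group
#'   shares one reference BLAST hit and will collapse into a single OTU.
#' @param read_depth_range per-sample sequencing depth is drawn uniformly
#'   from this integer range (default 10000-50000, exercising unequal
#'   depths).
#' @param expression_noise_sd standard deviation of the independent
#'   Gaussian noise added to latent gene values (default 0.1; small so the
#'   planted Spearman strength is attenuated by well under the network
#'   threshold resolution).
#' @param seed integer seed; the same spec with the same seed generates
#'   bit-identical data.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_otus, n_genes, n_samples = 58,
                           planted_edges = NULL,
                           deg_fraction_up = 0.5,
                           group_proportions = c(cell_cycle = 0.25,
                                                 antiviral_response = 0.25,
                                                 epithelial_cell_differentiation = 0.25,
                                                 other = 0.25),
                           collapse_groups = list(),
                           read_depth_range = c(10000L, 50000L),
                           expression_noise_sd = 0.1,
                           seed = 1L) {
  stopifnot(n_otus >= 1, n_genes >= 1, n_samples >= 3,
            deg_fraction_up >= 0, deg_fraction_up <= 1,
            expression_noise_sd >= 0)
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    stop("group_proportions must sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(group_proportions), setdiff(GROUP_LEVELS, "microbe"))
  if (length(bad)) stop("unknown gene group: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
  gene_ids <- sprintf("GENE_%03d", seq_len(n_genes))
  if (!is.null(planted_edges)) {
    stopifnot(all(c("u", "v", "target_rho") %in% names(planted_edges)))
    unknown <- setdiff(unique(c(planted_edges$u, planted_edges$v)),
                       c(otu_ids, gene_ids))
    if (length(unknown)) {
      stop("planted edge references undeclared node: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(abs(planted_edges$target_rho) > 1)) {
      stop("|target_rho| must be <= 1", call. = FALSE)
    }
    if (any(planted_edges$u == planted_edges$v)) {
      stop("planted self-edge", call. = FALSE)
    }
  }
  unknown <- setdiff(unlist(collapse_groups), otu_ids)
  if (length(unknown)) {
    stop("collapse group references undeclared OTU: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(n_otus = n_otus, n_genes = n_genes, n_samples = n_samples,
                 otu_ids = otu_ids, gene_ids = gene_ids,
                 planted_edges = planted_edges,
                 deg_fraction_up = deg_fraction_up,
                 group_proportions = group_proportions,
                 collapse_groups = collapse_groups,
                 read_depth_range = as.integer(read_depth_range),
                 expression_noise_sd = expression_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic co-measured dataset
#'
#' Samples the latent Gaussian copula defined by the spec's planted
#' Spearman correlations (the latent Pearson correlation is set to
#' `2*sin(pi*rho_s/6)` so the population Spearman equals the target
#' exactly), then produces:
#' * abundance: per-OTU log-normal intensities (heterogeneous base
#'   abundances), converted to per-sample proportions and drawn as
#'   multinomial read counts at a per-sample depth uniform over the spec's
#'   range, so columns sum to their depth exactly;
#' * expression: the latent gene values plus independent Gaussian noise;
#' * annotations: genes labelled up/down and grouped per the spec, with
#'   planted gene-gene pairs forced sign-coherent (positive target rho ->
#'   same regulation label, negative -> opposite), so the false-positive
#'   coherence rules never remove a true planted edge;
#' * BLAST hits: each collapse group's members hit one shared reference
#'   subject passing the default filters, plus decoy hits that fail them;
#' * truth: the planted edge list with expected signs.
#'
#' A non-positive-semidefinite planted correlation structure is an error
#' raised before any sampling.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `abundance` (raw-count
#'   [abundance_matrix()]), `expression` ([expression_matrix()]),
#'   `annotations`, `blast_hits`, `truth`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ids <- c(spec$otu_ids, spec$gene_ids)
  d <- length(ids)
  Sigma <- diag(d)
  dimnames(Sigma) <- list(ids, ids)
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges)) {
    r <- 2 * sin(pi * spec$planted_edges$target_rho / 6)
    for (k in seq_along(r)) {
      u <- spec$planted_edges$u[k]; v <- spec$planted_edges$v[k]
      Sigma[u, v] <- r[k]; Sigma[v, u] <- r[k]
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("planted correlation structure is not positive semidefinite",
         call. = FALSE)
  }
  set.seed(spec$seed)
  # draw order is part of the determinism contract: OTU base means, depths,
  # latent matrix, expression noise, labels, groups
  mu <- stats::rnorm(spec$n_otus, mean = 0, sd = 1.5)
  depths <- sample(seq(spec$read_depth_range[1L], spec$read_depth_range[2L]),
                   spec$n_samples, replace = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  Z <- L %*% matrix(stats::rnorm(d * spec$n_samples), nrow = d)
  rownames(Z) <- ids
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))
  colnames(Z) <- sample_ids
  noise <- matrix(stats::rnorm(spec$n_genes * spec$n_samples,
                               sd = spec$expression_noise_sd),
                  nrow = spec$n_genes)
  regulation <- sample(c("up", "down"), spec$n_genes, replace = TRUE,
                       prob = c(spec$deg_fraction_up,
                                1 - spec$deg_fraction_up))
  groups <- sample(names(spec$group_proportions), spec$n_genes,
                   replace = TRUE, prob = spec$group_proportions)

  # abundance: log-normal intensity -> proportions -> multinomial counts
  intensity <- exp(mu + Z[spec$otu_ids, , drop = FALSE])
  counts <- matrix(0L, nrow = spec$n_otus, ncol = spec$n_samples,
                   dimnames = list(spec$otu_ids, sample_ids))
  for (j in seq_len(spec$n_samples)) {
    pr <- intensity[, j] / sum(intensity[, j])
    counts[, j] <- stats::rmultinom(1L, size = depths[j], prob = pr)[, 1L]
  }
  expr_vals <- Z[spec$gene_ids, , drop = FALSE] + noise

  # force sign coherence of planted gene-gene pairs
  names(regulation) <- spec$gene_ids
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges)) {
    for (k in seq_len(nrow(spec$planted_edges))) {
      u <- spec$planted_edges$u[k]; v <- spec$planted_edges$v[k]
      if (u %in% spec$gene_ids && v %in% spec$gene_ids) {
        same <- spec$planted_edges$target_rho[k] > 0
        regulation[v] <- if (same) regulation[u] else
          setdiff(c("up", "down"), regulation[u])
      }
    }
  }
  ann <- node_annotations(
    node_id = c(spec$otu_ids, spec$gene_ids),
    kind = rep(c("microbe", "gene"), c(spec$n_otus, spec$n_genes)),
    regulation = c(rep("none", spec$n_otus), unname(regulation)),
    group = c(rep("microbe", spec$n_otus), groups))

  # BLAST hits: one shared reference subject per collapse group, plus a
  # decoy per group failing the e-value filter
  hits <- list()
  for (k in seq_along(spec$collapse_groups)) {
    members <- spec$collapse_groups[[k]]
    subj <- sprintf("ref_%03d", k)
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = members, subject_id = subj,
      pident = 97.5, evalue = 1e-12, stringsAsFactors = FALSE)
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = members[1L], subject_id = sprintf("decoy_%03d", k),
      pident = 99.0, evalue = 1e-3, stringsAsFactors = FALSE)
  }
  blast_hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), subject_id = character(),
               pident = numeric(), evalue = numeric(),
               stringsAsFactors = FALSE)

  truth <- if (is.null(spec$planted_edges)) {
    data.frame(u = character(), v = character(), target_rho = numeric(),
               sign = character(), stringsAsFactors = FALSE)
  } else {
    cbind(spec$planted_edges,
          sign = ifelse(spec$planted_edges$target_rho > 0,
                        "positive", "negative"))
  }

  list(abundance = abundance_matrix(counts),
       expression = expression_matrix(expr_vals),
       annotations = ann,
       blast_hits = blast_hits,
       truth = truth)
}

#' Hand-built false-positive fixture network
#'
#' A small network containing exactly one instance of each false-positive
#' scene — an incoherent negative edge (two up-regulated genes), an
#' incoherent positive edge (an up- and a down-regulated gene), a
#' self-loop, and a parallel edge pair — plus coherent edges that must
#' survive correction.
#'
#' @return list with elements `network` (the raw, non-simple network),
#'   `expected` (the network after correct false-positive removal) and
#'   `n_false_positives` (4).
#' @export
make_fp_fixture <- function() {
  ann <- node_annotations(
    node_id = c("GENE_UP_A", "GENE_UP_B", "GENE_DN_A", "GENE_DN_B", "OTU_M1"),
    kind = c("gene", "gene", "gene", "gene", "microbe"),
    regulation = c("up", "up", "down", "down", "none"),
    group = c("antiviral_response", "antiviral_response", "cell_cycle",
              "epithelial_cell_differentiation", "microbe"))
  edges <- data.frame(
    u = c("GENE_UP_A", "GENE_UP_A", "OTU_M1", "OTU_M1", "OTU_M1",
          "GENE_UP_B", "GENE_DN_A", "OTU_M1"),
    v = c("GENE_UP_B", "GENE_DN_A", "OTU_M1", "GENE_UP_B", "GENE_UP_B",
          "GENE_DN_B", "GENE_DN_B", "GENE_DN_A"),
    rho = c(-0.60, 0.55, 0.50, 0.45, 0.62, -0.70, 0.50, -0.50),
    p_value = c(0.010, 0.020, 0.030, 0.040, 0.005, 0.001, 0.020, 0.030),
    sign = c("negative", "positive", "positive", "positive", "positive",
             "negative", "positive", "negative"),
    origin = "measured", stringsAsFactors = FALSE)
  raw <- hm_network(ann, edges, check = FALSE)
  kept <- edges[c(5L, 6L, 7L, 8L), ]
  expected <- hm_network(ann, kept)
  list(network = raw, expected = expected, n_false_positives = 4L)
}

#' Seeded bridge-topology fixture network
#'
#' Builds a network in which one designated microbe is the unique cut
#' vertex between the microbe sub-network and a gene group: every
#' microbe-to-gene shortest path must pass through it, so it must rank
#' first by bi-partite betweenness. The wiring within each side is
#' randomized under the seed.
#'
#' @param seed integer seed controlling the random wiring.
#' @param n_microbes,n_genes side sizes (defaults 8 and 8).
#' @param gene_group group label for the gene side (default
#'   `"antiviral_response"`).
#' @return list with `network` and `bridge` (the cut-vertex microbe id).
#' @export
make_bridge_fixture <- function(seed, n_microbes = 8, n_genes = 8,
                                gene_group = "antiviral_response") {
  stopifnot(n_microbes >= 3, n_genes >= 2)
  set.seed(seed)
  microbes <- sprintf("OTU_%02d", seq_len(n_microbes))
  genes <- sprintf("GENE_%02d", seq_len(n_genes))
  bridge <- microbes[n_microbes]
  others <- microbes[-n_microbes]
  rand_tree_edges <- function(nodes) {
    # random spanning tree: attach each node to a random earlier node
    if (length(nodes) < 2L) return(NULL)
    parent <- vapply(2:length(nodes),
                     function(i) nodes[sample.int(i - 1L, 1L)], character(1))
    data.frame(u = nodes[-1L], v = parent, stringsAsFactors = FALSE)
  }
  side_m <- rand_tree_edges(others)
  side_g <- rand_tree_edges(genes)
  # bridge attaches to one random microbe and a random subset of genes
  attach_m <- data.frame(u = bridge, v = others[sample.int(length(others), 1L)],
                         stringsAsFactors = FALSE)
  # >= 2 gene attachments, so no single gene is itself a cut vertex tying
  # the bridge's score
  k <- sample(2:max(2L, n_genes %/% 2L), 1L)
  attach_g <- data.frame(u = bridge, v = sample(genes, k),
                         stringsAsFactors = FALSE)
  e <- rbind(side_m, side_g, attach_m, attach_g)
  rho <- stats::runif(nrow(e), 0.45, 0.9)
  edges <- data.frame(u = e$u, v = e$v, rho = rho,
                      p_value = stats::runif(nrow(e), 1e-6, 0.04),
                      sign = "positive", origin = "measured",
                      stringsAsFactors = FALSE)
  ann <- node_annotations(
    node_id = c(microbes, genes),
    kind = rep(c("microbe", "gene"), c(n_microbes, n_genes)),
    regulation = c(rep("none", n_microbes),
                   rep("up", n_genes)),
    group = c(rep("microbe", n_microbes), rep(gene_group, n_genes)))
  list(network = hm_network(ann, edges), bridge = bridge)
}
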