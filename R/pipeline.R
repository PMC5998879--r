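# End-to-end orchestration: normalize -> collapse -> top-k -> correlate ->
# threshold -> error-correct -> BpBC -> rank, with a run manifest.

PIPELINE_KEYS <- c("abundance", "expression", "annotations", "blast",
                   "out_dir", "rho_min", "p_max", "top_k", "node_pairs",
                   "bh_correction", "min_subnodes", "pairs", "top_n", "seed")

#' Summarize a host-microbial network
#'
#' @param net an `hm_network`.
#' @return list with node counts by kind and edge counts by sign and
#'   origin; `n_positive + n_negative == n_edges` always holds.
#' @export
summarize_network <- function(net) {
  e <- net$edges
  s <- list(n_nodes = nrow(net$nodes),
            n_microbes = sum(net$nodes$kind == "microbe"),
            n_genes = sum(net$nodes$kind == "gene"),
            n_edges = nrow(e),
            n_positive = sum(e$sign == "positive"),
            n_negative = sum(e$sign == "negative"),
            n_measured = sum(e$origin == "measured"),
            n_inferred = sum(e$origin == "inferred"))
  stopifnot(s$n_positive + s$n_negative == s$n_edges)
  s
}

#' Resolve a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and validates it against the closed
#' key set; explicit `overrides` (e.g. command-line flags) win over file
#' values.
#'
#' @param config path to a YAML file, or a named list.
#' @param overrides named list of values overriding `config`.
#' @return validated configuration list with defaults filled in.
#' @export
resolve_config <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(blast = NULL, rho_min = 0.4, p_max = 0.05, top_k = 259,
                   node_pairs = "all", bh_correction = FALSE,
                   min_subnodes = 2L, pairs = default_group_pairs(),
                   top_n = 10L, seed = 1L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  need <- c("abundance", "expression", "annotations", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("config missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.list(config$pairs)) {
    config$pairs <- lapply(config$pairs, as.character)
  }
  config
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[kfnet] %-12s %6.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full key-factor pipeline
#'
#' Stages: read inputs; collapse OTUs via the BLAST best-hit map (when a
#' BLAST file is given); normalize to proportions; keep the top-k abundant
#' OTUs; Spearman-correlate all node pairs; threshold into a network;
#' remove false-positive edges; add inferred false-negative edges for
#' collapsed OTUs; compute BpBC rankings for each group pair. All outputs,
#' a correction log and a manifest (parameters, input checksums, seed) are
#' written into `out_dir`.
#'
#' @param config a YAML path or named list accepted by [resolve_config()];
#'   required keys: `abundance`, `expression`, `annotations` (input TSV
#'   paths) and `out_dir`. Optional: `blast` (outfmt-6 path), `rho_min`,
#'   `p_max`, `top_k`, `node_pairs`, `bh_correction`, `min_subnodes`,
#'   `pairs`, `top_n`, `seed`.
#' @param overrides named list overriding config values.
#' @return (invisibly) a list with the corrected `network`, the `rankings`,
#'   the network `summary` and the `out_dir`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- resolve_config(config, overrides)
  for (k in c("abundance", "expression", "annotations")) {
    if (!file.exists(cfg[[k]])) {
      stop("input not found: ", k, " (", cfg[[k]], ")", call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  ab_raw <- .stage("read", {
    ab <- read_matrix(cfg$abundance, "abundance")
    ex <- read_matrix(cfg$expression, "expression")
    ann <- read_annotations(cfg$annotations)
    list(ab = ab, ex = ex, ann = ann)
  })
  ab <- ab_raw$ab; ex <- ab_raw$ex; ann <- ab_raw$ann

  cmap <- NULL
  if (!is.null(cfg$blast)) {
    cmap <- .stage("collapse", {
      hits <- filter_blast_hits(read_blast_hits(cfg$blast))
      build_collapse_map(hits, rownames(ab$values))
    })
    ab_collapsed <- collapse_matrix(ab, cmap)
    # collapsed ids inherit microbe annotations
    new_ids <- setdiff(rownames(ab_collapsed$values), ann$node_id)
    if (length(new_ids)) {
      ann <- validate_annotations(rbind(
        ann, data.frame(node_id = new_ids, kind = "microbe",
                        regulation = "none", group = "microbe",
                        stringsAsFactors = FALSE)))
    }
  } else {
    ab_collapsed <- ab
  }

  norm <- .stage("normalize", normalize_counts(ab_collapsed))
  topk <- .stage("top_k", select_top_k(norm, cfg$top_k))
  write_matrix(topk, file.path(cfg$out_dir, "abundance_normalized.tsv"),
               id_column = "otu_id")

  records <- .stage("correlate", correlate_all(topk, ex))
  kept_nodes <- ann[ann$node_id %in% c(rownames(topk$values),
                                       rownames(ex$values)), ]
  raw_net <- .stage("threshold",
                    build_network(records, kept_nodes, rho_min = cfg$rho_min,
                                  p_max = cfg$p_max,
                                  node_pairs = cfg$node_pairs,
                                  bh_correction = cfg$bh_correction))
  net <- .stage("correct_fp", remove_false_positives(raw_net))
  removed <- attr(net, "removed_edges")

  added <- net$edges[0, ]
  if (!is.null(cmap)) {
    net <- .stage("correct_fn", {
      raw_norm <- normalize_counts(ab)
      raw_records <- correlate_all(raw_norm, ex)
      add_false_negatives(net, cmap, raw_records, rho_min = cfg$rho_min,
                          p_max = cfg$p_max,
                          min_subnodes = cfg$min_subnodes)
    })
    added <- attr(net, "added_edges")
  }

  write_network(raw_net, file.path(cfg$out_dir, "network_raw.tsv"))
  write_network(net, file.path(cfg$out_dir, "network_corrected.tsv"))
  write_network(net, file.path(cfg$out_dir, "network_corrected.graphml"),
                format = "graphml")
  log <- rbind(
    if (nrow(removed)) cbind(removed[, names(net$edges)], action = "removed",
                             reason = removed$reason),
    if (nrow(added)) cbind(added, action = "added",
                           reason = "collapsed_subnode_consensus"))
  if (is.null(log)) {
    log <- cbind(net$edges[0, ], action = character(), reason = character())
  }
  utils::write.table(log, file.path(cfg$out_dir, "correction_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rankings <- .stage("bpbc", {
    usable <- Filter(function(p) all(vapply(p, function(g)
      any(net$nodes$group == g), logical(1))), cfg$pairs)
    rank_key_factors(net, usable, top_n = cfg$top_n)
  })
  for (nm in names(rankings)) {
    write_ranking(rankings[[nm]],
                  file.path(cfg$out_dir,
                            paste0("bpbc_", gsub(":", "_vs_", nm), ".tsv")))
  }

  s <- summarize_network(net)
  inputs <- c(abundance = cfg$abundance, expression = cfg$expression,
              annotations = cfg$annotations,
              if (!is.null(cfg$blast)) c(blast = cfg$blast))
  manifest <- list(
    package_version = as.character(utils::packageVersion("kfnet")),
    parameters = cfg[setdiff(names(cfg),
                             c("abundance", "expression", "annotations",
                               "blast", "out_dir"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    summary = s)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(network = net, rankings = rankings, summary = s,
                 out_dir = cfg$out_dir))
}

#' Write a synthetic dataset to disk
#'
#' Serializes a [generate_dataset()] result as the pipeline's four input
#' files plus the ground-truth edge list (`truth.tsv`), so precision and
#' recall of a full run are computable without external data.
#'
#' @param dataset list from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_inputs <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(dataset$abundance, file.path(out_dir, "abundance.tsv"),
               id_column = "otu_id")
  write_matrix(dataset$expression, file.path(out_dir, "expression.tsv"),
               id_column = "gene_id")
  write_annotations(dataset$annotations, file.path(out_dir, "annotations.tsv"))
  h <- dataset$blast_hits
  if (nrow(h)) {
    blast12 <- data.frame(h$query_id, h$subject_id, h$pident, 250L, 3L, 0L,
                          1L, 250L, 1L, 250L, h$evalue, 400.0)
    utils::write.table(blast12, file.path(out_dir, "blast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    file.create(file.path(out_dir, "blast.tsv"))
  }
  utils::write.table(dataset$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
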