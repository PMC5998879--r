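test_that("spearman matches the rank-then-Pearson oracle, ties included", {
  # worked case: d = ranks difference, sum d^2 = 4, n = 5 -> 1 - 24/120
  expect_equal(unname(spearman(1:5, c(2, 1, 4, 3, 5))["rho"]), 0.8)
  expect_equal(unname(spearman(1:4, 1:4)["rho"]), 1)
  expect_equal(unname(spearman(1:4, 4:1)["rho"]), -1)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    y <- if (i %% 3) rnorm(n) else sample(1:4, n, replace = TRUE)
    got <- spearman(x, y)
    rho_oracle <- cor(rank(x), rank(y))
    expect_equal(unname(got["rho"]), rho_oracle, tolerance = 1e-12)
    if (abs(rho_oracle) < 1) {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      expect_equal(unname(got["p_value"]), ct$p.value, tolerance = 1e-9)
    }
  }
})

test_that("constant vectors yield the no-correlation sentinel", {
  out <- spearman(rep(2, 6), rnorm(6))
  expect_true(all(is.na(out)))
  # and a constant feature can never form an edge downstream
  ab <- abundance_matrix(matrix(c(1, 1, 1, 1, 5, 2, 8, 1), 2, 4, byrow = TRUE,
                                dimnames = list(c("OTU_flat", "OTU_x"),
                                                paste0("s", 1:4))))
  ex <- expression_matrix(matrix(rnorm(8), 2, 4,
                                 dimnames = list(c("G1", "G2"),
                                                 paste0("s", 1:4))))
  rec <- correlate_all(ab, ex)
  expect_false("OTU_flat" %in% c(rec$u, rec$v))
})

test_that("permutation p-value agrees with enumeration at tiny n", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  got <- spearman(x, y, method = "permutation")
  # enumeration oracle over all 5! orderings
  ranks_y <- rank(y)
  perm_idx <- expand.grid(rep(list(1:5), 5))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(r) length(unique(r)) == 5), ]
  stats <- apply(perm_idx, 1, function(pr) abs(cor(rank(x), ranks_y[pr])))
  expect_equal(unname(got["p_value"]), mean(stats >= 0.8 - 1e-12))
  expect_error(spearman(1:12, 12:1, method = "permutation"), "n < 10")
})

test_that("correlate_all covers every non-constant pair and aligns samples", {
  set.seed(21)
  samples <- paste0("s", 1:10)
  ab <- abundance_matrix(matrix(rpois(20, 30), 2, 10,
                                dimnames = list(c("OTU_1", "OTU_2"), samples)))
  ex <- expression_matrix(matrix(rnorm(20), 2, 10,
                                 dimnames = list(c("G1", "G2"), samples)))
  rec <- correlate_all(ab, ex)
  expect_identical(nrow(rec), 6L)
  # per-pair oracle
  all_vals <- rbind(ab$values, ex$values)
  for (i in seq_len(nrow(rec))) {
    o <- spearman(all_vals[rec$u[i], ], all_vals[rec$v[i], ])
    expect_equal(rec$rho[i], unname(o["rho"]), tolerance = 1e-12)
    expect_equal(rec$p_value[i], unname(o["p_value"]), tolerance = 1e-12)
  }
  # permuting sample columns of one matrix changes nothing
  ex_perm <- expression_matrix(ex$values[, sample(samples)])
  expect_equal(correlate_all(ab, ex_perm), rec)
  # sample mismatch lists the symmetric difference
  ex_bad <- expression_matrix(matrix(rnorm(20), 2, 10,
                                     dimnames = list(c("G1", "G2"),
                                                     paste0("t", 1:10))))
  expect_error(correlate_all(ab, ex_bad), "s1.*t1")
})

test_that("build_network applies strict thresholds and keeps isolated nodes", {
  ann <- node_annotations(c("OTU_1", "G1", "G2", "G3"),
                          c("microbe", "gene", "gene", "gene"),
                          c("none", "up", "up", "down"),
                          c("microbe", "other", "cell_cycle", "other"))
  rec <- data.frame(
    u = c("G1", "G1", "G2", "OTU_1"),
    v = c("G2", "G3", "G3", "G1"),
    rho = c(0.5, 0.40, -0.7, -0.45),
    p_value = c(0.01, 0.001, 0.2, 0.05),
    stringsAsFactors = FALSE)
  net <- build_network(rec, ann)
  # 0.5/0.01 passes; rho = 0.40 exactly fails; p = 0.2 fails; p = 0.05 exactly fails
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$u, "G1")
  expect_identical(net$edges$sign, "positive")
  # isolated nodes retained
  expect_identical(nrow(net$nodes), 4L)
  expect_error(build_network(data.frame(u = "G1", v = "NOPE", rho = 0.9,
                                        p_value = 0.001), ann),
               "unannotated")
  # microbe_gene mode drops within-kind edges
  rec2 <- data.frame(u = c("G1", "OTU_1"), v = c("G2", "G1"),
                     rho = c(0.9, 0.9), p_value = c(0.001, 0.001))
  mg <- build_network(rec2, ann, node_pairs = "microbe_gene")
  expect_identical(nrow(mg$edges), 1L)
  expect_identical(mg$edges$u, "G1")
  expect_identical(mg$edges$v, "OTU_1")
})

test_that("false-positive removal handles all four scenes and is idempotent", {
  fx <- make_fp_fixture()
  corrected <- remove_false_positives(fx$network)
  expect_true(networks_equal(corrected, fx$expected))
  log <- attr(corrected, "removed_edges")
  expect_identical(nrow(log), fx$n_false_positives)
  expect_setequal(log$reason, c("incoherent_negative", "incoherent_positive",
                                "self_loop", "parallel"))
  # parallel resolution kept the max-|rho| copy
  kept <- corrected$edges
  par_kept <- kept[edge_key(kept$u, kept$v) == edge_key("OTU_M1", "GENE_UP_B"), ]
  expect_equal(par_kept$rho, 0.62)
  # idempotent
  twice <- remove_false_positives(corrected)
  expect_true(networks_equal(twice, corrected))
  expect_identical(nrow(attr(twice, "removed_edges")), 0L)
  # coherent negative edge between up and down genes survives
  expect_true(edge_key("GENE_UP_B", "GENE_DN_B") %in%
                edge_key(kept$u, kept$v))
})

test_that("microbe-involved edges are untouched by the coherence rules", {
  ann <- node_annotations(c("OTU_1", "G_up"), c("microbe", "gene"),
                          c("none", "up"), c("microbe", "other"))
  e <- data.frame(u = "OTU_1", v = "G_up", rho = -0.6, p_value = 0.01,
                  sign = "negative", origin = "measured")
  net <- hm_network(ann, e)
  expect_true(networks_equal(remove_false_positives(net), net))
})

test_that("false-negative rule adds consensus sub-node edges once", {
  ann <- node_annotations(
    c("collapsed:ref1", "GENE_1", "GENE_2"),
    c("microbe", "gene", "gene"), c("none", "up", "down"),
    c("microbe", "antiviral_response", "other"))
  cmap <- build_collapse_map(
    data.frame(query_id = c("OTU_a", "OTU_b"), subject_id = "ref1",
               pident = 95, evalue = 1e-10),
    c("OTU_a", "OTU_b"))
  raw <- data.frame(
    u = c("GENE_1", "GENE_1", "GENE_2", "GENE_2"),
    v = c("OTU_a", "OTU_b", "OTU_a", "OTU_b"),
    rho = c(0.6, 0.7, 0.6, 0.2),
    p_value = c(0.01, 0.03, 0.01, 0.01),
    stringsAsFactors = FALSE)
  net <- hm_network(ann)
  out <- add_false_negatives(net, cmap, raw)
  added <- attr(out, "added_edges")
  # GENE_1: both sub-nodes pass with a common sign -> one inferred edge,
  # rho = mean(0.6, 0.7), p = max; GENE_2: one sub-node fails -> nothing
  expect_identical(nrow(added), 1L)
  expect_identical(added$v, "GENE_1")
  expect_equal(added$rho, 0.65)
  expect_equal(added$p_value, 0.03)
  expect_identical(added$origin, "inferred")
  # idempotent: edge now exists, second pass adds nothing
  again <- add_false_negatives(out, cmap, raw)
  expect_true(networks_equal(again, out))
  expect_identical(nrow(attr(again, "added_edges")), 0L)
  # opposite signs across sub-nodes block the edge
  raw_mixed <- raw
  raw_mixed$rho <- c(0.6, -0.6, 0.6, 0.6)
  out2 <- add_false_negatives(net, cmap, raw_mixed)
  expect_false("GENE_1" %in% attr(out2, "added_edges")$v)
  # cmap referencing sub-OTUs absent from the records is an error
  raw_missing <- raw[raw$v != "OTU_b", ]
  expect_error(add_false_negatives(net, cmap, raw_missing),
               "absent from raw records")
})

test_that("edge bookkeeping holds after every stage", {
  set.seed(5)
  for (seed in 1:5) {
    net <- random_group_network(seed, n = 12, p = 0.4)
    s <- summarize_network(net)
    expect_identical(s$n_positive + s$n_negative, s$n_edges)
    corrected <- remove_false_positives(net)
    expect_true(all(corrected$edges$u != corrected$edges$v))
    expect_false(anyDuplicated(edge_key(corrected$edges$u,
                                        corrected$edges$v)) > 0)
    expect_identical((corrected$edges$rho > 0),
                     (corrected$edges$sign == "positive"))
  }
})
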