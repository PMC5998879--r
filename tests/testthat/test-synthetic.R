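test_that("generator is deterministic under a fixed seed", {
  sp <- synthetic_spec(n_otus = 6, n_genes = 8, n_samples = 15, seed = 99,
                       planted_edges = data.frame(u = "OTU_001",
                                                  v = "GENE_002",
                                                  target_rho = 0.7),
                       collapse_groups = list(c("OTU_002", "OTU_003")))
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$abundance$values, d2$abundance$values)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$blast_hits, d2$blast_hits)
  # byte-identical serialization
  f1 <- tempfile(); f2 <- tempfile()
  write_synthetic_inputs(d1, f1); write_synthetic_inputs(d2, f2)
  for (f in list.files(f1)) {
    expect_identical(readLines(file.path(f1, f)), readLines(file.path(f2, f)))
  }
  # a different seed changes the data
  sp2 <- sp; sp2$seed <- 100L
  expect_false(identical(generate_dataset(sp2)$expression$values,
                         d1$expression$values))
})

test_that("abundance columns sum exactly to their sampled read depth", {
  sp <- synthetic_spec(n_otus = 12, n_genes = 4, n_samples = 25, seed = 5)
  d <- generate_dataset(sp)
  depths <- colSums(d$abundance$values)
  expect_true(all(depths >= 10000 & depths <= 50000))
  expect_true(all(depths == round(depths)))
  # normalization then behaves
  norm <- normalize_counts(d$abundance)
  expect_true(all(abs(colSums(norm$values) - 1) < 1e-9))
})

test_that("planted Spearman converges to its target at large n", {
  planted <- data.frame(u = c("GENE_001", "OTU_001"),
                        v = c("GENE_002", "GENE_003"),
                        target_rho = c(0.8, -0.6))
  sp <- synthetic_spec(n_otus = 30, n_genes = 4, n_samples = 1000,
                       planted_edges = planted, seed = 31)
  d <- generate_dataset(sp)
  gg <- spearman(d$expression$values["GENE_001", ],
                 d$expression$values["GENE_002", ])
  expect_equal(unname(gg["rho"]), 0.8, tolerance = 0.05)
  # the count observation layer (multinomial reads over compositional
  # proportions) attenuates microbe-side correlations by design; the bias
  # does not vanish with n, so the band is wider here
  norm <- normalize_counts(d$abundance)
  mg <- spearman(norm$values["OTU_001", ], d$expression$values["GENE_003", ])
  expect_equal(unname(mg["rho"]), -0.6, tolerance = 0.12)
  # unplanted pair stays near zero
  null <- spearman(d$expression$values["GENE_001", ],
                   d$expression$values["GENE_004", ])
  expect_lt(abs(null["rho"]), 0.1)
})

test_that("planted gene-gene pairs are labelled sign-coherently", {
  planted <- data.frame(u = c("GENE_001", "GENE_003"),
                        v = c("GENE_002", "GENE_004"),
                        target_rho = c(0.9, -0.9))
  sp <- synthetic_spec(n_otus = 3, n_genes = 6, n_samples = 30,
                       planted_edges = planted, seed = 12)
  d <- generate_dataset(sp)
  reg <- setNames(d$annotations$regulation, d$annotations$node_id)
  expect_identical(unname(reg["GENE_001"]), unname(reg["GENE_002"]))
  expect_false(reg["GENE_003"] == reg["GENE_004"])
})

test_that("collapse groups emit shared-subject hits passing the filters", {
  sp <- synthetic_spec(n_otus = 6, n_genes = 3, n_samples = 12, seed = 4,
                       collapse_groups = list(c("OTU_001", "OTU_002"),
                                              c("OTU_004", "OTU_005")))
  d <- generate_dataset(sp)
  kept <- filter_blast_hits(d$blast_hits)
  cmap <- build_collapse_map(kept, rownames(d$abundance$values))
  expect_setequal(cmap$members[["collapsed:ref_001"]],
                  c("OTU_001", "OTU_002"))
  expect_setequal(cmap$members[["collapsed:ref_002"]],
                  c("OTU_004", "OTU_005"))
  expect_identical(unname(cmap$member_of["OTU_003"]), "OTU_003")
  # decoys fail the e-value filter
  expect_true(any(d$blast_hits$evalue >= 1e-5))
  expect_true(all(kept$evalue < 1e-5))
})

test_that("an infeasible planted correlation structure errors before sampling", {
  planted <- data.frame(u = c("GENE_001", "GENE_001", "GENE_002"),
                        v = c("GENE_002", "GENE_003", "GENE_003"),
                        target_rho = c(0.95, 0.95, -0.95))
  sp <- synthetic_spec(n_otus = 2, n_genes = 3, n_samples = 10,
                       planted_edges = planted, seed = 1)
  expect_error(generate_dataset(sp), "positive semidefinite")
  expect_error(synthetic_spec(n_otus = 2, n_genes = 2, n_samples = 10,
                              planted_edges = data.frame(u = "GENE_001",
                                                         v = "GENE_009",
                                                         target_rho = 0.5)),
               "undeclared node")
})

test_that("fp fixture encodes one instance of each false-positive scene", {
  fx <- make_fp_fixture()
  expect_identical(nrow(fx$network$edges) - nrow(fx$expected$edges),
                   fx$n_false_positives)
  e <- fx$network$edges
  expect_identical(sum(e$u == e$v), 1L)                      # self-loop
  expect_identical(sum(duplicated(edge_key(e$u, e$v))), 1L)  # parallel pair
})

test_that("bridge fixture plants a unique microbe cut vertex", {
  for (seed in c(1, 2, 3)) {
    bf <- make_bridge_fixture(seed)
    g <- as_igraph(bf$network)
    expect_true(igraph::is_connected(g))
    # deleting the bridge separates every other microbe from every gene
    g2 <- igraph::delete_vertices(g, bf$bridge)
    microbes <- setdiff(bf$network$nodes$node_id[
      bf$network$nodes$kind == "microbe"], bf$bridge)
    genes <- bf$network$nodes$node_id[bf$network$nodes$kind == "gene"]
    d <- igraph::distances(g2, v = microbes, to = genes)
    expect_true(all(!is.finite(d)))
  }
})
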