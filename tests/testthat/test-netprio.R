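test_that("edge lists are deduplicated with self-loops removed", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC"), f)
  net <- load_edge_list(f, keep_isolated = FALSE)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)
  net_iso <- load_edge_list(f, keep_isolated = TRUE)
  expect_equal(n_nodes(net_iso), 3L)   # C survives as an isolated node
  expect_equal(n_edges(net_iso), 1L)

  writeLines(c("# comment", "gene_a\tgene_b\tcombined_score",
               "A\tB\t0.9", "A\tC\t0.2"), f)
  expect_equal(n_edges(load_edge_list(f, score_threshold = 0.5)), 1L)
  writeLines(c("A\tB", "loner"), f)
  expect_error(load_edge_list(f), "line 2")
  writeLines(character(0), f)
  expect_error(load_edge_list(f), "empty")
})

test_that("the packaged example edge list loads through the reader", {
  f <- system.file("extdata", "splicing_edges_example.tsv",
                   package = "splicedyn")
  net <- load_edge_list(f, score_threshold = 0.5)
  expect_true("SF3B1" %in% net$nodes)
  expect_false(any(net$edges$gene_a == net$edges$gene_b))
  # SF3B6 edge scored 0.35 is gated out but the gene remains isolated
  expect_true("SF3B6" %in% net$nodes)
  ct <- centralities(net)
  expect_equal(ct$degree[ct$gene == "SF3B6"], 0L)
  expect_true(is.na(ct$closeness[ct$gene == "SF3B6"]))
})

test_that("BFS distances match hand-checked paths and exclude other components", {
  path3 <- gene_network(data.frame(gene_a = c("A", "B"),
                                   gene_b = c("B", "C")))
  expect_equal(shortest_path_lengths(path3, "A"),
               c(A = 0L, B = 1L, C = 2L))
  k5genes <- LETTERS[1:5]
  pr <- t(combn(k5genes, 2))
  k5 <- gene_network(data.frame(gene_a = pr[, 1], gene_b = pr[, 2]))
  d <- shortest_path_lengths(k5, "C")
  expect_equal(unname(d[order(names(d))]), c(1L, 1L, 0L, 1L, 1L))
  two <- gene_network(data.frame(gene_a = c("A", "X"),
                                 gene_b = c("B", "Y")))
  expect_equal(sort(names(shortest_path_lengths(two, "A"))), c("A", "B"))
  expect_error(shortest_path_lengths(two, "ZZZ"), "unknown gene")
})

test_that("centralities match hand values on a path and complete graph", {
  path3 <- gene_network(data.frame(gene_a = c("A", "B"),
                                   gene_b = c("B", "C")))
  ct <- centralities(path3)
  b <- ct[ct$gene == "B", ]
  expect_equal(b$closeness, 1.0)
  expect_equal(b$eccentricity, 1L)
  expect_equal(b$radiality, 1.0)
  a <- ct[ct$gene == "A", ]
  expect_equal(a$closeness, 2 / 3)
  expect_equal(a$eccentricity, 2L)
  expect_equal(a$radiality, 0.75)

  k5genes <- LETTERS[1:5]
  pr <- t(combn(k5genes, 2))
  k5 <- gene_network(data.frame(gene_a = pr[, 1], gene_b = pr[, 2]))
  ck <- centralities(k5)
  expect_equal(ck$closeness, rep(1, 5))
  expect_equal(ck$radiality, rep(1, 5))
  expect_equal(ck$eccentricity, rep(1L, 5))

  iso <- gene_network(data.frame(gene_a = "A", gene_b = "B"), nodes = "Z")
  ci <- centralities(iso)
  expect_true(is.na(ci$closeness[ci$gene == "Z"]))
  expect_equal(ci$degree[ci$gene == "Z"], 0L)
})

test_that("centralities agree exactly with the Floyd-Warshall oracle", {
  for (s in 1:30) {
    withr::with_seed(2000 + s, {
      n <- sample(5:30, 1)
      p <- runif(1, 0.05, 0.4)
      src_pick <- sample(n, 1)
    })
    net <- random_test_network(n = n, p = p, seed = 1000 + s)
    got <- centralities(net)
    want <- fw_centralities(net$nodes, net$edges)
    expect_equal(got$eccentricity, want$eccentricity)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(got$radiality, want$radiality, tolerance = 1e-12)
    # BFS map equals the oracle row for a random source
    src <- net$nodes[src_pick]
    D <- fw_distances(net$nodes, net$edges)
    want_d <- D[src, ]
    want_d <- want_d[is.finite(want_d)]
    got_d <- shortest_path_lengths(net, src)
    expect_equal(unname(got_d), unname(want_d[names(got_d)]))
  }
})

test_that("radiality-closeness identity holds for every node", {
  for (s in 1:5) {
    net <- random_test_network(25, 0.15, seed = 60 + s)
    ct <- centralities(net)
    ok <- !is.na(ct$closeness)
    split_ct <- split(ct[ok, ], ct$component_id[ok])
    for (sub in split_ct) {
      if (nrow(sub) < 2) next
      # diameter = max eccentricity in the component
      diam <- max(sub$eccentricity)
      expect_equal(sub$radiality,
                   (diam + 1 - 1 / sub$closeness) / diam,
                   tolerance = 1e-12)
      expect_true(all(sub$closeness > 0 & sub$closeness <= 1))
      expect_true(all(sub$radiality > 0 & sub$radiality <= 1))
      expect_true(all(sub$eccentricity >= 1 & sub$eccentricity <= diam))
    }
  }
})

test_that("mutation records normalize COSMIC dialect and enforce ranges", {
  f <- system.file("extdata", "cosmic_example.csv", package = "splicedyn")
  rec <- read_mutation_table(f)
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$aa_change[1], "K700E")  # p. prefix stripped
  expect_equal(rec$mutation_type[4], "substitution_synonymous")
  expect_equal(rec$fathmm_class[5], "neutral")

  expect_error(mutation_records("G", "s", "Substitution - Missense",
                                "K700K", "h", "PATHOGENIC", 0.95),
               "unparseable")
  expect_error(mutation_records("G", "s", "Substitution - Missense",
                                "K700E", "h", "PATHOGENIC", 1.2),
               "outside")
  p <- parse_aa_change(c("p.K700E", "G83=", "?"))
  expect_equal(p$pos, c(700L, 83L, NA))
  expect_equal(p$alt, c("E", "=", NA))
})

test_that("mutation filtering applies all four criteria and is idempotent", {
  f <- system.file("extdata", "cosmic_example.csv", package = "splicedyn")
  rec <- read_mutation_table(f)
  kept <- filter_mutations(rec, "carcinoma", 0.9)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$sample_id, c("S001", "S002"))
  expect_identical(filter_mutations(kept, "carcinoma", 0.9), kept)
  expect_equal(nrow(filter_mutations(rec, "carcinoma", 1.0)), 0L)
  all_pm <- filter_mutations(rec, "carcinoma", 0.0)
  expect_true(all(all_pm$mutation_type == "substitution_missense" &
                    all_pm$fathmm_class == "pathogenic"))
  expect_equal(nrow(all_pm), 3L)  # S006 (score 0.85) now passes too
})

test_that("prioritization ranks by count with deterministic tie-breaks", {
  net <- gene_network(data.frame(gene_a = c("SF3B1", "SF3B1"),
                                 gene_b = c("DHX15", "PRPF19")))
  rec <- mutation_records(
    gene = c(rep("SF3B1", 3), rep("DHX15", 2), rep("AAA", 2), "ZZZ"),
    sample_id = sprintf("S%d", 1:8),
    mutation_type = "Substitution - Missense",
    aa_change = c("K700E", "K700E", "R625C", "A1V", "A2V", "G5D", "G5D",
                  "L9H"),
    histology = "carcinoma", fathmm_prediction = "PATHOGENIC",
    fathmm_score = 0.95
  )
  pr <- prioritize(net, rec)
  expect_equal(pr$gene, c("SF3B1", "AAA", "DHX15", "ZZZ"))
  expect_equal(pr$n_mutations, c(3L, 2L, 2L, 1L))
  expect_equal(pr$top_aa_change[1], "K700E")
  expect_equal(pr$top_change_n[1], 2L)
  # tie between A1V and A2V broken lexicographically
  expect_equal(pr$top_aa_change[pr$gene == "DHX15"], "A1V")
  expect_true(pr$off_network[pr$gene == "AAA"])
  expect_false(pr$off_network[pr$gene == "SF3B1"])
  expect_equal(nrow(prioritize(net, rec[0, ])), 0L)
})

test_that("prioritization output is invariant to record and edge order", {
  nm <- sample_network_and_mutations(seed = 3)
  kept <- filter_mutations(nm$records, "carcinoma", 0.9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report_tsv(prioritize(nm$network, kept), f1)
  withr::with_seed(99, {
    shuf_rec <- kept[sample(nrow(kept)), ]
    ed <- nm$network$edges[sample(nrow(nm$network$edges)), ]
  })
  net2 <- gene_network(ed, nodes = nm$network$nodes)
  write_report_tsv(prioritize(net2, shuf_rec), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the per-sample SF3B1 table reproduces the reported change counts", {
  tab <- sf3b1_sample_table(seed = 5)
  kept <- filter_mutations(tab, "carcinoma", 0.9)
  counts <- sort(table(kept$aa_change), decreasing = TRUE)
  expect_equal(as.integer(counts["K700E"]), 45L)
  expect_equal(as.integer(counts[c("K666Q", "R625C", "T935K")]), rep(2L, 3))
  # exact fraction reported, no rounding to a headline percentage
  expect_equal(45 / nrow(tab), 0.375)
  pr <- prioritize(gene_network(NULL, nodes = "SF3B1"), kept)
  expect_equal(pr$top_aa_change, "K700E")
  expect_equal(pr$top_change_n, 45L)
})
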