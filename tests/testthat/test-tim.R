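test_that("one-sided Fisher matches exhaustive enumeration on small tables", {
  expect_equal(fisher_exact_greater(3, 0, 0, 3), 1 / choose(6, 3),
               tolerance = 1e-14)
  expect_equal(fisher_exact_greater(0, 5, 3, 2), 1)
  expect_equal(fisher_exact_greater(1, 1, 1, 1), 5 / 6, tolerance = 1e-14)

  # every table with total <= 12 (acceptance re-checks totals <= 24)
  for (n in 0:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      expect_equal(fisher_exact_greater(a, b, c, d),
                   oracle_fisher_greater(a, b, c, d), tolerance = 1e-12)
    }
  }

  # agrees with the hypergeometric tail from stats as an independent check
  set.seed(2)
  for (i in 1:200) {
    a <- rpois(1, 5); b <- rpois(1, 5); c <- rpois(1, 5); d <- rpois(1, 5)
    expect_equal(fisher_exact_greater(a, b, c, d),
                 stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("node enrichment finds a planted clade and respects the null", {
  # 20-leaf tree: a pure 10-leaf clade all associated with one lineage
  tips_in <- paste0("in", 1:10)
  tips_out <- paste0("out", 1:10)
  nwk <- sprintf("((%s),(%s));",
                 paste(tips_in, collapse = ","),
                 paste(tips_out, collapse = ","))
  tree <- toy_tree(nwk)
  assoc <- tibble::tibble(otu_id = tips_in, taxon = "Haptophyta")
  res <- node_taxon_enrichment(tree, assoc, q_threshold = 0.05)
  top <- res[res$a == 10 & res$b == 0, ]
  expect_identical(nrow(top), 1L)
  expect_equal(top$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(top$significant)

  # associations spread evenly inside and outside every clade: nothing fires
  assoc_null <- tibble::tibble(otu_id = c(tips_in[1:5], tips_out[1:5]),
                               taxon = "Haptophyta")
  res_null <- node_taxon_enrichment(tree, assoc_null, q_threshold = 0.05)
  expect_false(any(res_null$significant))

  expect_error(node_taxon_enrichment(toy_tree("(A,B);"), assoc), ">= 3 leaves")
})

test_that("every node's contingency table matches a leaf-partition oracle", {
  tree <- toy_tree("(((A,B),C),((D,E),F));")
  assoc <- tibble::tibble(otu_id = c("A", "B", "D", "F"),
                          taxon = c("X", "X", "Y", "X"))
  res <- node_taxon_enrichment(tree, assoc, q_threshold = 0.05)
  sets <- vhocnet:::node_leaf_sets(tree)
  root_label <- tree$node.label[1]
  n_tests <- 0L
  for (nd in setdiff(names(sets), root_label)) {
    for (tx in c("X", "Y")) {
      members <- assoc$otu_id[assoc$taxon == tx]
      leaves <- sets[[nd]]
      a <- length(intersect(leaves, members))
      b <- length(leaves) - a
      c_ <- length(members) - a
      d <- length(setdiff(tree$tip.label, leaves)) - c_
      row <- res[res$node_id == nd & res$taxon == tx, ]
      expect_identical(c(row$a, row$b, row$c, row$d), c(a, b, c_, d))
      expect_equal(row$p, oracle_fisher_greater(a, b, c_, d),
                   tolerance = 1e-12)
      n_tests <- n_tests + 1L
    }
  }
  expect_identical(nrow(res), n_tests)  # root excluded, all others tested
})

test_that("nested clades dominate their parents in p-value", {
  # if a child keeps all associated leaves but sheds unassociated ones,
  # its enrichment p cannot exceed the parent's
  set.seed(41)
  for (i in 1:50) {
    a <- sample(1:8, 1); b_child <- sample(0:4, 1)
    b_parent <- b_child + sample(0:4, 1)
    c_ <- sample(0:6, 1)
    n <- 40
    d_child <- n - a - b_child - c_
    d_parent <- n - a - b_parent - c_
    expect_lte(fisher_exact_greater(a, b_child, c_, d_child),
               fisher_exact_greater(a, b_parent, c_, d_parent) + 1e-12)
  }
})

test_that("enrichment-based edge filtering is a subset and idempotent", {
  tips_in <- paste0("in", 1:10); tips_out <- paste0("out", 1:10)
  tree <- toy_tree(sprintf("((%s),(%s));",
                           paste(tips_in, collapse = ","),
                           paste(tips_out, collapse = ",")))
  tax <- taxonomy_table(tibble::tibble(
    otu_id = c("e1", "e2"), major_lineage = c("Haptophyta", "Metazoa")))
  edges <- edge_list(tibble::tibble(
    source = paste0("polB:", c(tips_in, tips_out[1:3])),
    target = paste0("V9:", c(rep("e1", 10), rep("e2", 3))),
    weight = 0.5))
  assoc <- tibble::tibble(otu_id = tips_in, taxon = "Haptophyta")
  res <- node_taxon_enrichment(tree, assoc, q_threshold = 0.05)
  kept <- filter_edges_by_enrichment(edges, res, tree, tax)
  # exactly the in-clade edges to the enriched lineage survive
  expect_setequal(kept$source, paste0("polB:", tips_in))
  expect_true(all(kept$target == "V9:e1"))
  # subset + idempotence
  expect_true(all(paste(kept$source, kept$target) %in%
                    paste(edges$source, edges$target)))
  kept2 <- filter_edges_by_enrichment(kept, res, tree, tax)
  expect_equal(kept2, kept)
  # no significant results -> empty output
  res0 <- res; res0$significant <- FALSE
  expect_identical(nrow(filter_edges_by_enrichment(edges, res0, tree, tax)), 0L)
  # endpoints missing from the tree are dropped with a message
  edges_x <- edge_list(tibble::tibble(source = "polB:ghost", target = "V9:e1",
                                      weight = 0.9))
  expect_message(out <- filter_edges_by_enrichment(edges_x, res, tree, tax),
                 "not a tree leaf")
  expect_identical(nrow(out), 0L)
})

test_that("the family-by-lineage summary counts enriched nodes", {
  tips_in <- paste0("in", 1:4); tips_out <- paste0("out", 1:4)
  tree <- toy_tree(sprintf("(((%s,%s),(%s,%s)),((%s,%s),(%s,%s)));",
                           tips_in[1], tips_in[2], tips_in[3], tips_in[4],
                           tips_out[1], tips_out[2], tips_out[3], tips_out[4]))
  fams <- tibble::tibble(otu_id = c(tips_in, tips_out),
                         viral_family = rep(c("Mimiviridae", "Poxviridae"),
                                            each = 4))
  assoc <- tibble::tibble(otu_id = tips_in, taxon = "Haptophyta")
  res <- node_taxon_enrichment(tree, assoc, q_threshold = 0.6)
  sig <- res[res$significant, ]
  net <- tim_network(res, tree, fams)
  expect_identical(sum(net$weight), nrow(sig))  # conservation
  expect_true(all(net$major_lineage == "Haptophyta"))
  expect_true(all(net$viral_family %in% c("Mimiviridae", "mixed")))
  # no significant results -> empty network
  res0 <- res; res0$significant <- FALSE
  expect_identical(nrow(tim_network(res0, tree, fams)), 0L)
  # rank-level taxa convert through the lineage map
  res_rank <- res
  res_rank$taxon <- "Calanoida"; res_rank$rank <- "order"
  lm <- tibble::tibble(taxon = "Calanoida", major_lineage = "Metazoa")
  net2 <- tim_network(res_rank, tree, fams, lineage_map = lm)
  if (nrow(net2)) expect_true(all(net2$major_lineage == "Metazoa"))
})
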