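make_pair_matrix <- function(x, y) {
  n <- length(x)
  abundance_table(
    tibble::tibble(otu_id = c("polB:v", "V9:h"),
                   !!!stats::setNames(as.data.frame(rbind(x, y)),
                                      paste0("s", seq_len(n)))),
    marker = "polB", unit = "counts")
}

test_that("spearman weights match the rank-statistic oracle and sign rules", {
  # monotone relationships give rho = +/- 1
  x <- 1:10
  e_up <- spearman_network(make_pair_matrix(x, x^2), alpha = 0.01)
  expect_equal(e_up$weight, 1)
  expect_identical(e_up$sign, "positive")
  e_dn <- spearman_network(make_pair_matrix(x, 11 - x), alpha = 0.01)
  expect_equal(e_dn$weight, -1)
  expect_identical(e_dn$sign, "negative")

  # tied data against the explicit average-rank formula
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  e <- spearman_network(make_pair_matrix(x, y), alpha = 1 - 1e-12)
  expect_equal(e$weight, oracle_spearman(x, y), tolerance = 1e-12)

  # random instances, 20 samples, 1e-12 agreement
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    if (runif(1) < 0.4) y[sample(20, 5)] <- y[sample(20, 5)]  # force ties
    # exp() is strictly monotone, so ranks (and rho) are unchanged
    e <- spearman_network(make_pair_matrix(exp(x), exp(y)), alpha = 1 - 1e-12)
    if (nrow(e) == 1L) {
      expect_equal(e$weight, oracle_spearman(x, y), tolerance = 1e-12)
    }
  }

  # constant profiles are skipped with a message
  expect_message(
    out <- spearman_network(make_pair_matrix(rep(2, 10), 1:10), alpha = 0.5),
    "constant")
  expect_identical(nrow(out), 0L)
})

test_that("network inference is invariant to sample and OTU order", {
  set.seed(8)
  n <- 20
  tbl <- tibble::tibble(
    otu_id = c(paste0("polB:v", 1:3), paste0("V9:h", 1:4)),
    !!!stats::setNames(as.data.frame(matrix(rpois(7 * n, 6), 7)),
                       paste0("s", 1:n)))
  m <- abundance_table(tbl, marker = "polB", unit = "counts")
  e1 <- spearman_network(m, alpha = 0.3)
  perm_rows <- sample(nrow(tbl)); perm_cols <- c(1, 1 + sample(n))
  m2 <- abundance_table(tbl[perm_rows, perm_cols], marker = "polB",
                        unit = "counts")
  e2 <- spearman_network(m2, alpha = 0.3)
  key <- function(e) dplyr::arrange(e[, c("source", "target", "weight")], source, target)
  expect_equal(key(e1), key(e2), tolerance = 1e-12)
})

test_that("meta-variable conditioning removes confounded edges, keeps real ones", {
  set.seed(21)
  n <- 100
  z <- rnorm(n)
  # x and y are exact monotone functions of z, hence independent given z
  x <- 2 * z
  y <- -3 * z
  m <- abundance_table(
    tibble::tibble(otu_id = c("polB:v", "V9:h"),
                   !!!stats::setNames(as.data.frame(rbind(exp(x), exp(y))),
                                      paste0("s", 1:n))),
    marker = "polB", unit = "counts")
  edges <- spearman_network(m, alpha = 0.01)
  expect_identical(nrow(edges), 1L)
  env <- tibble::tibble(sample_id = paste0("s", 1:n), temperature = z)
  res <- metavar_condition(edges, m, env, alpha = 0.01)
  expect_identical(nrow(res$edges), 0L)
  expect_identical(res$removed$variable, "temperature")

  # genuinely coupled pair survives conditioning on independent noise
  retained <- 0L
  for (r in 1:100) {
    x <- rnorm(n); y <- 0.8 * x + 0.6 * rnorm(n)
    m <- make_pair_matrix(exp(x), exp(y))
    edges <- spearman_network(m, alpha = 0.01)
    if (nrow(edges) == 0L) next
    env <- tibble::tibble(sample_id = paste0("s", 1:n), noise = rnorm(n))
    res <- metavar_condition(edges, m, env, alpha = 0.01)
    retained <- retained + nrow(res$edges)
  }
  expect_gte(retained / 100, 0.95)

  # empty meta-variable table is the identity
  e0 <- edge_list(tibble::tibble(source = "polB:v", target = "V9:h",
                                 weight = 0.5))
  res0 <- metavar_condition(e0, m, tibble::tibble(sample_id = character()),
                            alpha = 0.01)
  expect_equal(res0$edges, e0)
})

test_that("environmental association scan finds real drivers at ~alpha noise", {
  set.seed(13)
  n <- 60
  temp <- rnorm(n, 15, 5)
  tbl <- tibble::tibble(
    otu_id = paste0("polB:v", 1:21),
    !!!stats::setNames(as.data.frame(rbind(temp, matrix(rnorm(20 * n), 20))),
                       paste0("s", 1:n)))
  m <- abundance_table(tbl, marker = "polB", unit = "clr",
                       validate_clr_sum = FALSE)
  env <- tibble::tibble(sample_id = paste0("s", 1:n), temperature = temp)
  out <- detect_env_associations(m, env, alpha = 0.01)
  hit <- out[out$otu_id == "polB:v1", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$rho, 1)
  # the 20 noise OTUs yield roughly alpha * 20 false reports
  expect_lte(nrow(out) - 1L, 3L)
  empty <- detect_env_associations(m, tibble::tibble(sample_id = character()),
                                   alpha = 0.01)
  expect_identical(nrow(empty), 0L)
})

test_that("degree statistics count signed cross-marker edges per focal node", {
  edges <- edge_list(tibble::tibble(
    source = c("polB:v1", "polB:v1", "polB:v1", "polB:v2", "polB:v3", "polB:v3"),
    target = c("V9:h1", "V9:h2", "V9:h3", "V9:h1", "V9:h1", "V9:h2"),
    weight = c(0.5, 0.2, -0.1, 0.9, 0.4, 0.6)))
  d <- degree_stats(edges, focal_marker = "polB")
  v1 <- d$nodes[d$nodes$otu_id == "polB:v1", ]
  expect_identical(c(v1$positive_degree, v1$negative_degree), c(2L, 1L))
  expect_equal(d$means$mean_positive_degree, mean(c(2, 1, 2)))
  # isolated nodes simply do not appear
  expect_false("polB:v9" %in% d$nodes$otu_id)
  # sum of positive polB degrees equals the positive cross-marker edge count
  expect_identical(sum(d$nodes$positive_degree),
                   sum(edges$sign == "positive"))
})

test_that("group aggregation conserves edge totals and pools unannotated", {
  tax <- toy_taxonomy()
  edges <- edge_list(tibble::tibble(
    source = c("polB:v1", "polB:v1", "polB:v2", "polB:v2"),
    target = c("V9:h1", "V9:h1b", "V9:h2", "V9:hx"),
    weight = c(0.5, 0.3, -0.2, 0.7)))
  tax2 <- dplyr::bind_rows(tax, tibble::tibble(
    otu_id = "h1b", major_lineage = "Haptophyta"))
  agg <- aggregate_network(edges, tax2)
  mimi_hapto <- agg[agg$viral_family == "Mimiviridae" &
                      agg$eukaryote_group == "Haptophyta", ]
  expect_identical(mimi_hapto$count_positive, 2L)
  expect_identical(sum(agg$count_positive) + sum(agg$count_negative),
                   nrow(edges))
  expect_true("unclassified" %in% agg$eukaryote_group)
})
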