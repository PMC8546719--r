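test_that("reference grouping keeps the best hit and applies the threshold", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1"), subject_id = c("r1", "r2"),
    percent_identity = c(70, 68), percent_query_coverage = c(90, 90),
    e_value = c(1e-50, 1e-40), bitscore = c(200, 150))
  a <- assign_reference_groups(hits)
  expect_identical(a$reference_virus_id, "r1")

  # best hit below 65% identity leaves the OTU unassigned
  low <- tibble::tibble(query_id = "q1", subject_id = "r1",
                        percent_identity = 60, percent_query_coverage = 90,
                        e_value = 1e-80, bitscore = 300)
  expect_identical(nrow(assign_reference_groups(low)), 0L)
  expect_identical(nrow(assign_reference_groups(low,
                                                identity_threshold = 55)), 1L)

  # random tables agree with the exhaustive-scan oracle
  set.seed(17)
  for (i in 1:20) {
    h <- random_hit_table(10, paste0("q", 1:4), paste0("r", 1:5))
    got <- assign_reference_groups(h)
    want <- oracle_best_hits(h)
    expect_identical(nrow(got), length(want))
    for (q in names(want)) {
      expect_identical(got$reference_virus_id[got$otu_id == q], want[[q]])
    }
  }
})

test_that("condition-positive pairs expand multi-host references", {
  assignment <- tibble::tibble(otu_id = c("q1", "q2"),
                               reference_virus_id = c("r1", "r2"),
                               percent_identity = c(70, 80),
                               bitscore = c(200, 300))
  ref <- tibble::tibble(
    reference_virus_id = c("r1", "r2", "r2"),
    host_major_lineage = c("Haptophyta", "Metazoa", "Dinophyceae"))
  pos <- condition_positive_pairs(assignment, ref)
  expect_identical(nrow(pos), 3L)
  expect_setequal(pos$major_lineage[pos$otu_id == "q2"],
                  c("Metazoa", "Dinophyceae"))
  expect_identical(
    nrow(condition_positive_pairs(assignment[0, ], ref)), 0L)
  expect_error(
    condition_positive_pairs(
      tibble::tibble(otu_id = "q", reference_virus_id = "missing"),
      ref),
    "absent from reference table.*missing")
})

test_that("best-edge reduction keeps one edge per (otu, lineage, sign)", {
  tax <- toy_taxonomy()
  edges <- edge_list(tibble::tibble(
    source = c("polB:v1", "polB:v1", "polB:v1"),
    target = c("V9:h1", "V9:h1b", "V9:h2"),
    weight = c(0.3, 0.7, -0.4)))
  tax2 <- dplyr::bind_rows(tax, tibble::tibble(otu_id = "h1b",
                                               major_lineage = "Haptophyta"))
  red <- reduce_best_edges(edges, tax2)
  hapto <- red[red$major_lineage == "Haptophyta", ]
  expect_equal(hapto$weight, 0.7)  # keeps max |weight|
  # one positive and one negative edge to the same lineage both survive
  edges2 <- edge_list(tibble::tibble(
    source = c("polB:v1", "polB:v1"), target = c("V9:h1", "V9:h1b"),
    weight = c(0.5, -0.6)))
  expect_identical(nrow(reduce_best_edges(edges2, tax2)), 2L)

  # random instances against a brute-force group-by-max oracle
  set.seed(23)
  lineages <- c("Haptophyta", "Metazoa", "Dinophyceae")
  hosts <- tibble::tibble(otu_id = paste0("e", 1:9),
                          major_lineage = rep(lineages, 3))
  for (rep in 1:10) {
    n <- 20
    df <- tibble::tibble(
      source = paste0("polB:", sample(paste0("v", 1:3), n, replace = TRUE)),
      target = paste0("V9:", sample(hosts$otu_id, n, replace = TRUE)),
      weight = round(runif(n, -1, 1), 3),
      size_fraction = sample(c("a", "b"), n, replace = TRUE))
    df <- df[!duplicated(df[, c("source", "target", "size_fraction")]), ]
    red <- reduce_best_edges(edge_list(df), hosts)
    # oracle: exhaustive grouping
    df$lin <- hosts$major_lineage[match(sub("V9:", "", df$target), hosts$otu_id)]
    df$sgn <- ifelse(df$weight > 0, "positive", "negative")
    for (g in split(df, paste(df$source, df$lin, df$sgn))) {
      best <- g[order(-abs(g$weight), -g$weight, g$target), ][1, ]
      got <- red[red$otu_id == sub("polB:", "", best$source) &
                   red$major_lineage == best$lin & red$sign == best$sgn, ]
      expect_identical(nrow(got), 1L)
      expect_equal(got$weight, best$weight)
    }
    expect_identical(nrow(red),
                     length(unique(paste(df$source, df$lin, df$sgn))))
  }
})

test_that("confusion matrix partitions the toy 6-pair universe correctly", {
  reduced <- tibble::tibble(
    otu_id = c("v1", "v1", "v2"),
    major_lineage = c("Haptophyta", "Dinophyceae", "Haptophyta"),
    weight = c(0.8, 0.5, 0.6),
    sign = "positive",
    v9_otu = c("e1", "e2", "e3"))
  positives <- tibble::tibble(otu_id = c("v1", "v2"),
                              major_lineage = c("Haptophyta", "Metazoa"))
  lineages <- c("Haptophyta", "Metazoa", "Dinophyceae")
  cm <- confusion_matrix(reduced, positives, lineages, sign = "positive")
  expect_identical(c(cm$TP, cm$FP, cm$FN, cm$TN), c(1L, 2L, 1L, 2L))
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$fpr, 0.5)
  expect_equal(lr_plus(cm), 1.0)

  # no predictions: everything condition-positive becomes FN
  cm0 <- confusion_matrix(reduced[0, ], positives, lineages)
  expect_identical(c(cm0$TP, cm0$FP, cm0$FN), c(0L, 0L, 2L))
  expect_warning(expect_identical(lr_plus(cm0), NA_real_), "undefined")

  # cutoff above the largest weight behaves like no predictions
  cm_hi <- confusion_matrix(reduced, positives, lineages, weight_cutoff = 0.9)
  expect_identical(tidy(cm_hi), tidy(cm0))

  expect_error(confusion_matrix(reduced, positives[0, ], lineages),
               "empty candidate universe")
})

test_that("LR+ and FDR reproduce hand-computed values and sentinels", {
  cases <- list(
    # tp, fp, fn, tn, lr, fdr
    list(1, 1, 1, 3, (1 / 2) / (1 / 4), 1 / 2),
    list(1, 11, 0, 0, NA, 11 / 12),       # fpr = 1
    list(5, 0, 0, 5, Inf, 0),             # perfect, fpr = 0 -> +inf
    list(0, 0, 2, 4, NA, NA),             # no predictions
    list(0, 3, 2, 7, 0, 1),               # sensitivity 0, fpr > 0
    list(2, 2, 2, 2, (1 / 2) / (1 / 2), 1 / 2),  # sens = fpr -> LR+ = 1
    list(10, 5, 0, 85, 1 / (5 / 90), 5 / 15),
    list(3, 1, 7, 9, (3 / 10) / (1 / 10), 1 / 4),
    list(1, 3, 1, 11, (1 / 2) / (3 / 14), 3 / 4),
    list(4, 0, 6, 10, Inf, 0),
    list(0, 0, 0, 10, NA, NA),            # no condition positives at all
    list(7, 14, 3, 26, 0.7 / 0.35, 2 / 3),
    list(1, 99, 0, 0, NA, 0.99),
    list(6, 2, 4, 28, 0.6 / (2 / 30), 0.25),
    list(2, 8, 8, 32, 0.2 / 0.2, 0.8),    # another sens = fpr anchor
    list(9, 1, 1, 89, 0.9 / (1 / 90), 0.1),
    list(1, 0, 9, 90, Inf, 0),
    list(0, 10, 5, 35, 0, 1),
    list(12, 4, 4, 60, 0.75 / (4 / 64), 0.25),
    list(5, 5, 5, 5, (1 / 2) / (1 / 2), 1 / 2),
    list(8, 24, 2, 66, 0.8 / (24 / 90), 0.75))
  for (cs in cases) {
    cm <- vhocnet:::new_confusion(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    lr <- suppressWarnings(lr_plus(cm))
    fd <- suppressWarnings(fdr(cm))
    if (is.na(cs[[5]])) {
      if (cs[[1]] + cs[[3]] == 0 || (cm$fpr == 0 && cm$sensitivity == 0)) {
        expect_identical(lr, NA_real_)
      } else {
        # fpr = 1 cases: LR+ equals sensitivity
        expect_equal(lr, cm$sensitivity)
      }
    } else {
      expect_equal(lr, cs[[5]], tolerance = 1e-12)
    }
    if (is.na(cs[[6]])) expect_identical(fd, NA_real_) else
      expect_equal(fd, cs[[6]], tolerance = 1e-12)
  }
})

test_that("cutoff sweeps match per-cutoff recomputation and are monotone", {
  reduced <- tibble::tibble(
    otu_id = c("v1", "v1", "v2"),
    major_lineage = c("Haptophyta", "Dinophyceae", "Haptophyta"),
    weight = c(0.8, 0.5, 0.6), sign = "positive",
    v9_otu = c("e1", "e2", "e3"))
  positives <- tibble::tibble(otu_id = c("v1", "v2"),
                              major_lineage = c("Haptophyta", "Metazoa"))
  lineages <- c("Haptophyta", "Metazoa", "Dinophyceae")
  sw <- sweep_cutoffs(reduced, positives, lineages, cutoff_grid = c(0, 0.5))
  for (i in 1:2) {
    cm <- confusion_matrix(reduced, positives, lineages,
                           weight_cutoff = c(0, 0.5)[i])
    expect_identical(sw$TP[i], cm$TP)
    expect_identical(sw$FP[i], cm$FP)
  }
  expect_true(all(diff(sw$n_edges) <= 0))
  set.seed(3)
  for (rep in 1:5) {
    red <- tibble::tibble(
      otu_id = sample(c("v1", "v2"), 12, replace = TRUE),
      major_lineage = sample(lineages, 12, replace = TRUE),
      weight = runif(12), sign = "positive", v9_otu = paste0("e", 1:12))
    red <- red[!duplicated(red[, c("otu_id", "major_lineage")]), ]
    sw <- sweep_cutoffs(red, positives, lineages,
                        cutoff_grid = seq(0, 1, 0.2))
    expect_true(all(diff(sw$n_edges) <= 0))
  }
})

test_that("random host predictor centres at LR+ ~ 1", {
  set.seed(99)
  lineages <- paste0("L", 1:10)
  otus <- paste0("v", 1:30)
  positives <- tibble::tibble(otu_id = otus,
                              major_lineage = sample(lineages, 30, TRUE))
  reduced <- tibble::tibble(
    otu_id = rep(otus, each = 2),
    major_lineage = unlist(lapply(1:30, function(i) sample(lineages, 2))),
    weight = runif(60), sign = "positive", v9_otu = paste0("e", 1:60))
  out <- random_predictor_lr(reduced, positives, lineages, n_rep = 1000)
  expect_gt(out$mean_lr, 0.8)
  expect_lt(out$mean_lr, 1.2)
})
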