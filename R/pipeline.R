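#' Run the full benchmark pipeline on a synthetic data set
#'
#' Chains every stage of the package on one generated community:
#' preprocessing (clr + quartile filter + sample intersection), Spearman
#' network inference, reference grouping and condition labeling, best-edge
#' reduction, confusion matrix and LR+/FDR at cutoff 0, a random-predictor
#' LR+ baseline, the weight-cutoff sweep, and the phylogeny-guided
#' enrichment filter with its before/after assessment.
#'
#' @param params [synth_params()] describing the community (the seed lives
#'   here).
#' @param alpha Network significance level (default 0.01).
#' @param identity_threshold Reference-grouping identity threshold
#'   (default 65).
#' @param q_threshold Enrichment significance threshold (default 0.05).
#' @param quantile_level,min_samples Quartile-filter settings (defaults
#'   `"Q1"`, 5).
#' @param cutoff_grid Weight cutoffs for the sweep (default 0 to 0.9 by
#'   0.1).
#' @param n_random Random-predictor replicates (default 1000).
#' @return A list with the generated `data`, the inferred `edges`,
#'   `reduced` edges, reference `assignment`, condition `positives`,
#'   lineage `universe`, confusion matrices `cm_before` / `cm_after` (TIM),
#'   `random` baseline, `sweep`, `enrichment`, and `filtered` edges.
#' @export
run_benchmark <- function(params = synth_params(), alpha = 0.01,
                          identity_threshold = 65, q_threshold = 0.05,
                          quantile_level = "Q1", min_samples = 5,
                          cutoff_grid = seq(0, 0.9, by = 0.1),
                          n_random = 1000) {
  d <- synth_generate(params)
  prep <- preprocess_pair(d$polb, d$v9, quantile_level = quantile_level,
                          min_samples = min_samples)
  edges <- spearman_network(prep$merged, alpha = alpha)
  reduced <- reduce_best_edges(edges, d$taxonomy)
  assignment <- assign_reference_groups(d$hits,
                                        identity_threshold = identity_threshold)
  positives <- condition_positive_pairs(assignment, d$reference)
  universe <- sort(unique(stats::na.omit(d$taxonomy$major_lineage)))
  assigned <- unique(assignment$otu_id)
  cm_before <- confusion_matrix(reduced, positives, universe,
                                sign = "positive", weight_cutoff = 0,
                                assigned_otus = assigned)
  random <- random_predictor_lr(reduced, positives, universe,
                                sign = "positive", weight_cutoff = 0,
                                n_rep = n_random, assigned_otus = assigned)
  sweep <- sweep_cutoffs(reduced, positives, universe,
                         cutoff_grid = cutoff_grid, sign = "positive",
                         assigned_otus = assigned)
  edges_pos <- edges[edges$sign == "positive", ]
  assoc <- tibble::tibble(
    otu_id = sub("^[^:]*:", "", edges_pos$source),
    taxon = d$taxonomy$major_lineage[match(sub("^[^:]*:", "", edges_pos$target),
                                           d$taxonomy$otu_id)]) |>
    dplyr::filter(!is.na(.data$taxon)) |>
    dplyr::distinct()
  assoc <- assoc[assoc$otu_id %in% d$tree$tip.label, ]
  enrichment <- node_taxon_enrichment(d$tree, assoc, q_threshold = q_threshold)
  filtered <- filter_edges_by_enrichment(edges_pos, enrichment, d$tree,
                                         d$taxonomy)
  reduced_after <- reduce_best_edges(filtered, d$taxonomy)
  cm_after <- confusion_matrix(reduced_after, positives, universe,
                               sign = "positive", weight_cutoff = 0,
                               assigned_otus = assigned)
  list(data = d, prep = prep, edges = edges, reduced = reduced,
       assignment = assignment, positives = positives, universe = universe,
       assigned_otus = assigned, cm_before = cm_before, cm_after = cm_after,
       random = random, sweep = sweep, enrichment = enrichment,
       filtered = filtered, reduced_after = reduced_after)
}
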