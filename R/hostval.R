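#' Group environmental viral OTUs to reference viruses by best hit
#'
#' Each environmental polB OTU is assigned to the reference virus of its
#' single best homology hit (ranked by bitscore by default, ties broken by
#' higher percent identity then lexicographic subject id), provided the
#' best hit reaches the identity threshold. 65% identity is the default:
#' the level at which reference viruses sharing that much marker identity
#' infect hosts of the same major lineage. OTUs whose best hit falls below
#' the threshold remain unassigned and are excluded from validation.
#'
#' @param hits Hit tibble (queries = polB OTUs, subjects = reference
#'   viruses); see [read_hits()].
#' @param identity_threshold Minimum percent identity of the best hit
#'   (default 65).
#' @param rank_by `"bitscore"` (default) or `"evalue"`.
#' @return Tibble with columns `otu_id`, `reference_virus_id`,
#'   `percent_identity`, `bitscore`.
#' @export
assign_reference_groups <- function(hits, identity_threshold = 65,
                                    rank_by = c("bitscore", "evalue")) {
  rank_by <- match.arg(rank_by)
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(otu_id = character(), reference_virus_id = character(),
                          percent_identity = double(), bitscore = double()))
  }
  score <- if (rank_by == "bitscore") hits$bitscore else -hits$e_value
  best <- hits |>
    dplyr::mutate(.score = score) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$.score), dplyr::desc(.data$percent_identity),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  best <- best[best$percent_identity >= identity_threshold, ]
  tibble::tibble(otu_id = best$query_id,
                 reference_virus_id = best$subject_id,
                 percent_identity = best$percent_identity,
                 bitscore = best$bitscore)
}

#' Condition-positive (virus OTU, host lineage) pairs
#'
#' A pair (OTU, lineage) is condition positive iff the OTU's assigned
#' reference virus has a known host in that major lineage. Reference
#' viruses with several known host lineages contribute several pairs.
#'
#' @param assignment Output of [assign_reference_groups()].
#' @param ref Reference host tibble (see [reference_host_table()]).
#' @return Tibble with columns `otu_id`, `major_lineage`.
#' @export
condition_positive_pairs <- function(assignment, ref) {
  ref <- reference_host_table(ref)
  if (nrow(assignment) == 0L) {
    return(tibble::tibble(otu_id = character(), major_lineage = character()))
  }
  missing <- setdiff(assignment$reference_virus_id, ref$reference_virus_id)
  if (length(missing)) {
    stop("assigned reference virus absent from reference table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  dplyr::inner_join(assignment[, c("otu_id", "reference_virus_id")],
                    ref[, c("reference_virus_id", "host_major_lineage")],
                    by = "reference_virus_id",
                    relationship = "many-to-many") |>
    dplyr::transmute(otu_id = .data$otu_id,
                     major_lineage = .data$host_major_lineage) |>
    dplyr::distinct()
}

#' Reduce a network to the best edge per (virus, lineage, sign)
#'
#' Annotates each V9 endpoint with its major lineage, then for every
#' (polB OTU, lineage, sign) keeps exactly the edge with the largest
#' absolute weight (ties: larger signed weight, then lexicographic V9 id).
#' Pooled multi-fraction input is thereby also deduplicated to one edge
#' per (OTU, lineage, sign). Edges whose V9 endpoint lacks a lineage are
#' dropped.
#'
#' @param edges Edge list with marker-prefixed endpoints (polB on the
#'   source side for cross-marker edges).
#' @param tax Taxonomy tibble annotating the (unprefixed) V9 OTU ids with
#'   `major_lineage`.
#' @return Tibble with columns `otu_id` (unprefixed polB id),
#'   `major_lineage`, `weight`, `sign`, `v9_otu`.
#' @export
reduce_best_edges <- function(edges, tax) {
  edges <- edge_list(edges)
  tax <- taxonomy_table(tax)
  strip <- function(x) sub("^[^:]*:", "", x)
  lin <- tax$major_lineage[match(strip(edges$target), tax$otu_id)]
  keep <- !is.na(lin)
  edges <- edges[keep, ]
  lin <- lin[keep]
  if (nrow(edges) == 0L) {
    return(tibble::tibble(otu_id = character(), major_lineage = character(),
                          weight = double(), sign = character(),
                          v9_otu = character()))
  }
  tibble::tibble(otu_id = strip(edges$source), major_lineage = lin,
                 weight = edges$weight, sign = edges$sign,
                 v9_otu = strip(edges$target)) |>
    dplyr::group_by(.data$otu_id, .data$major_lineage, .data$sign) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)), dplyr::desc(.data$weight),
                   .data$v9_otu, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Confusion matrix over the (virus OTU, lineage) candidate universe
#'
#' The candidate universe is the cross product of the reference-assigned
#' OTUs with the supplied lineage vocabulary. Predicted positives are the
#' reduced edges of the requested sign with `|weight| > weight_cutoff`,
#' restricted to the universe. TP/FP/FN/TN partition the universe; the
#' derived rates (sensitivity, specificity, FPR, LR+, FDR) are attached.
#'
#' @param reduced Output of [reduce_best_edges()].
#' @param positives Condition-positive pairs
#'   ([condition_positive_pairs()]); OTUs appearing here define the
#'   assigned set unless `assigned_otus` is given.
#' @param universe_lineages Character vector of candidate host lineages.
#' @param sign `"positive"` or `"negative"`.
#' @param weight_cutoff Keep predictions with `|weight|` strictly above
#'   this (default 0).
#' @param assigned_otus Optional explicit set of reference-assigned OTUs
#'   (defaults to the OTUs in `positives`).
#' @return A `vh_confusion` object (see [tidy.vh_confusion()]).
#' @export
confusion_matrix <- function(reduced, positives, universe_lineages,
                             sign = c("positive", "negative"),
                             weight_cutoff = 0, assigned_otus = NULL) {
  sign <- match.arg(sign)
  universe_lineages <- unique(universe_lineages)
  if (is.null(assigned_otus)) assigned_otus <- unique(positives$otu_id)
  assigned_otus <- unique(assigned_otus)
  if (length(assigned_otus) == 0L || length(universe_lineages) == 0L) {
    stop("empty candidate universe (no assigned OTUs or no lineages)")
  }
  pos_key <- paste(positives$otu_id, positives$major_lineage)
  pred <- reduced[reduced$sign == sign & abs(reduced$weight) > weight_cutoff &
                    reduced$otu_id %in% assigned_otus &
                    reduced$major_lineage %in% universe_lineages, ]
  pred_key <- unique(paste(pred$otu_id, pred$major_lineage))
  pos_key <- unique(pos_key[positives$otu_id %in% assigned_otus &
                              positives$major_lineage %in% universe_lineages])
  universe_n <- length(assigned_otus) * length(universe_lineages)
  tp <- length(intersect(pred_key, pos_key))
  fp <- length(setdiff(pred_key, pos_key))
  fn <- length(setdiff(pos_key, pred_key))
  tn <- universe_n - tp - fp - fn
  new_confusion(tp, fp, fn, tn, sign = sign, weight_cutoff = weight_cutoff)
}

new_confusion <- function(tp, fp, fn, tn, sign = NA_character_,
                          weight_cutoff = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  cm <- list(TP = tp, FP = fp, FN = fn, TN = tn,
             sign = sign, weight_cutoff = weight_cutoff)
  cm$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  cm$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  cm$fpr <- if (!is.na(cm$specificity)) 1 - cm$specificity else NA_real_
  structure(cm, class = "vh_confusion")
}

#' @export
print.vh_confusion <- function(x, ...) {
  cat("Virus-host prediction confusion matrix\n")
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  sensitivity=%.4g  FPR=%.4g  LR+=%.4g  FDR=%.4g\n",
              x$sensitivity, x$fpr,
              suppressWarnings(lr_plus(x)), suppressWarnings(fdr(x))))
  invisible(x)
}

#' Positive likelihood ratio of a confusion matrix
#'
#' `LR+ = sensitivity / (1 - specificity)`. A value of 1 means the
#' prediction does not change the likelihood of a true virus-host pair;
#' values well above 1 mean a positive prediction raises it. When the
#' false-positive rate is zero with non-zero sensitivity, `Inf` is
#' returned; when both rates are zero, or there are no condition
#' positives, `NA` is returned with a warning.
#'
#' @param cm A `vh_confusion` object.
#' @return A number, `Inf`, or `NA`.
#' @export
lr_plus <- function(cm) {
  if (cm$TP + cm$FN == 0) {
    warning("no condition positives; LR+ undefined")
    return(NA_real_)
  }
  sens <- cm$sensitivity
  fpr <- cm$fpr
  if (is.na(fpr)) return(NA_real_)
  if (fpr == 0) {
    if (sens > 0) return(Inf)
    warning("sensitivity and FPR both zero; LR+ undefined")
    return(NA_real_)
  }
  sens / fpr
}

#' False discovery rate of a confusion matrix
#'
#' `FDR = FP / (FP + TP)`, the fraction of positive predictions that are
#' not known virus-host pairs. `NA` with a warning when there are no
#' positive predictions.
#'
#' @param cm A `vh_confusion` object.
#' @return A number in \[0, 1\] or `NA`.
#' @export
fdr <- function(cm) {
  if (cm$TP + cm$FP == 0) {
    warning("no positive predictions; FDR undefined")
    return(NA_real_)
  }
  cm$FP / (cm$FP + cm$TP)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix into one row per cell / one summary row
#'
#' @param x A `vh_confusion` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per confusion cell;
#'   `glance()` a one-row tibble of counts and derived rates.
#' @method tidy vh_confusion
#' @export
tidy.vh_confusion <- function(x, ...) {
  tibble::tibble(cell = c("TP", "FP", "FN", "TN"),
                 count = c(x$TP, x$FP, x$FN, x$TN))
}

#' @rdname tidy.vh_confusion
#' @method glance vh_confusion
#' @export
glance.vh_confusion <- function(x, ...) {
  tibble::tibble(TP = x$TP, FP = x$FP, FN = x$FN, TN = x$TN,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 fpr = x$fpr,
                 lr_plus = suppressWarnings(lr_plus(x)),
                 fdr = suppressWarnings(fdr(x)),
                 sign = x$sign, weight_cutoff = x$weight_cutoff)
}

#' Sweep the edge-weight cutoff and assess each operating point
#'
#' Recomputes the confusion matrix at every cutoff of an ascending grid
#' (one row per cutoff; the number of predicted edges is non-increasing in
#' the cutoff). When the reduced edges carry several size fractions and
#' `by_fraction = TRUE` the sweep is additionally computed per fraction.
#'
#' @inheritParams confusion_matrix
#' @param cutoff_grid Ascending numeric vector of weight cutoffs.
#' @return A tibble of class `vh_sweep` with columns `weight_cutoff`,
#'   `sign`, `n_edges`, `TP`, `FP`, `FN`, `TN`, `sensitivity`, `fpr`,
#'   `lr_plus`, `fdr`.
#' @export
sweep_cutoffs <- function(reduced, positives, universe_lineages,
                          cutoff_grid = seq(0, 0.9, by = 0.1),
                          sign = c("positive", "negative"),
                          assigned_otus = NULL) {
  sign <- match.arg(sign)
  stopifnot(!is.unsorted(cutoff_grid))
  rows <- purrr::map_dfr(cutoff_grid, function(cut) {
    cm <- confusion_matrix(reduced, positives, universe_lineages,
                           sign = sign, weight_cutoff = cut,
                           assigned_otus = assigned_otus)
    n_edges <- sum(reduced$sign == sign & abs(reduced$weight) > cut)
    dplyr::mutate(glance(cm), n_edges = n_edges, .before = 1)
  })
  out <- dplyr::relocate(rows, "weight_cutoff", "sign", "n_edges")
  class(out) <- c("vh_sweep", class(out))
  out
}

#' Mean LR+ of a uniform random host predictor
#'
#' Baseline for judging network LR+ values: each assigned OTU keeps the
#' number of lineage predictions it had, but the lineages are redrawn
#' uniformly at random (without replacement per OTU) from the universe.
#' The mean LR+ over replicates of such a predictor is ~1 by construction.
#'
#' @param reduced Reduced edges defining per-OTU prediction counts.
#' @param positives Condition-positive pairs.
#' @param universe_lineages Candidate lineage vocabulary.
#' @param sign Edge sign assessed (default `"positive"`).
#' @param weight_cutoff Cutoff applied to the real predictions before
#'   counting per-OTU predictions (default 0).
#' @param n_rep Number of randomizations (default 1000).
#' @param assigned_otus Optional explicit assigned-OTU set.
#' @return A list with `mean_lr` (mean over replicates with defined,
#'   finite LR+), `lr_values` (all replicate values) and `n_undefined`.
#' @export
random_predictor_lr <- function(reduced, positives, universe_lineages,
                                sign = "positive", weight_cutoff = 0,
                                n_rep = 1000, assigned_otus = NULL) {
  universe_lineages <- unique(universe_lineages)
  if (is.null(assigned_otus)) assigned_otus <- unique(positives$otu_id)
  pred <- reduced[reduced$sign == sign & abs(reduced$weight) > weight_cutoff &
                    reduced$otu_id %in% assigned_otus, ]
  k_per_otu <- table(factor(pred$otu_id, levels = assigned_otus))
  pos_key <- unique(paste(positives$otu_id, positives$major_lineage))
  n_lin <- length(universe_lineages)
  universe_n <- length(assigned_otus) * n_lin
  n_pos <- length(pos_key)
  lr <- vapply(seq_len(n_rep), function(r) {
    pred_key <- unlist(lapply(seq_along(assigned_otus), function(i) {
      k <- min(k_per_otu[[i]], n_lin)
      if (k == 0) return(character(0))
      paste(assigned_otus[i], sample(universe_lineages, k))
    }))
    tp <- sum(pred_key %in% pos_key)
    fp <- length(pred_key) - tp
    fn <- n_pos - tp
    tn <- universe_n - tp - fp - fn
    sens <- if (n_pos > 0) tp / n_pos else NA_real_
    fpr <- if (tn + fp > 0) fp / (fp + tn) else NA_real_
    if (is.na(sens) || is.na(fpr) || fpr == 0) return(NA_real_)
    sens / fpr
  }, double(1))
  ok <- is.finite(lr)
  list(mean_lr = mean(lr[ok]), lr_values = lr, n_undefined = sum(!ok))
}
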