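#' Infer a signed Spearman co-occurrence network
#'
#' For every candidate OTU pair, the edge weight is the Spearman rank
#' correlation of their abundance profiles across samples (ranks per OTU
#' across samples, average ranks for ties). An edge is kept iff its
#' two-sided p-value is below `alpha`; the sign follows the sign of rho.
#' The p-value uses the t-approximation with `n - 2` degrees of freedom;
#' for very small sample sizes (`n <= 10`) an exact permutation p-value is
#' available via `exact_perm = TRUE`. No multiple-testing correction is
#' applied on the default path (significance is thresholded raw, as is
#' conventional for these networks); `bh = TRUE` applies Benjamini-Hochberg
#' across candidate pairs first.
#'
#' Constant abundance vectors leave rho undefined; such pairs are skipped
#' and their count reported via a message.
#'
#' @param m A merged `vh_abund` table (clr or counts) whose OTU ids are
#'   marker-prefixed (`"polB:..."`, `"V9:..."`), as produced by
#'   [intersect_and_merge()].
#' @param alpha Significance level (default 0.01).
#' @param cross_group_only Only test polB-vs-V9 (cross-marker) pairs
#'   (default `TRUE`); otherwise all unordered pairs are tested.
#' @param min_shared_nonzero_samples Minimum number of samples where both
#'   members are non-zero (counts scale) for the pair to be considered;
#'   default 0 (no restriction). Only applies when the input carries
#'   counts.
#' @param bh Apply BH across candidate pairs before thresholding.
#' @param exact_perm Use an exact permutation p-value when `n <= 10`.
#' @return An edge list tibble (see [edge_list()]); sources are the
#'   first-marker OTUs when `cross_group_only`.
#' @export
spearman_network <- function(m, alpha = 0.01, cross_group_only = TRUE,
                             min_shared_nonzero_samples = 0,
                             bh = FALSE, exact_perm = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  vals <- abund_values(m)
  n <- ncol(vals)
  if (n < 5) stop("need >= 5 samples for network inference")
  markers <- sub(":.*", "", rownames(vals))
  has_prefix <- all(grepl(":", rownames(vals)))
  if (cross_group_only && !has_prefix) {
    stop("cross-group inference needs marker-prefixed OTU ids (use intersect_and_merge)")
  }
  ranks <- t(apply(vals, 1, rank))  # average ranks, per OTU across samples
  sds <- apply(ranks, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " constant OTU profile(s) skipped (rho undefined)")
  }
  if (cross_group_only) {
    # viral marker first, so edge orientation is independent of row order
    grp <- intersect(c("polB", "MCP", "V9"), unique(markers))
    if (length(grp) == 0L) grp <- sort(unique(markers), method = "radix")
    if (length(grp) != 2L) stop("expected exactly two markers, got: ",
                                paste(grp, collapse = ", "))
    ia <- which(markers == grp[1] & !constant)
    ib <- which(markers == grp[2] & !constant)
    if (!length(ia) || !length(ib)) {
      return(edge_list(tibble::tibble(source = character(), target = character(),
                                      weight = double())))
    }
    rho <- stats::cor(t(ranks[ia, , drop = FALSE]), t(ranks[ib, , drop = FALSE]))
    pairs <- expand.grid(i = seq_along(ia), j = seq_along(ib))
    src <- rownames(vals)[ia][pairs$i]
    tgt <- rownames(vals)[ib][pairs$j]
    rho_v <- rho[cbind(pairs$i, pairs$j)]
  } else {
    keep <- which(!constant)
    rho <- stats::cor(t(ranks[keep, , drop = FALSE]))
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    src <- rownames(vals)[keep][idx[, 1]]
    tgt <- rownames(vals)[keep][idx[, 2]]
    rho_v <- rho[idx]
  }
  if (min_shared_nonzero_samples > 0) {
    nzero <- vals > 0
    shared <- nzero[src, , drop = FALSE] & nzero[tgt, , drop = FALSE]
    ok <- rowSums(shared) >= min_shared_nonzero_samples
    src <- src[ok]; tgt <- tgt[ok]; rho_v <- rho_v[ok]
  }
  rho_v <- pmin(1, pmax(-1, rho_v))
  p <- if (exact_perm && n <= 10) {
    vapply(seq_along(src), function(k)
      spearman_perm_p(vals[src[k], ], vals[tgt[k], ]), double(1))
  } else {
    spearman_t_p(rho_v, n)
  }
  if (bh) p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < alpha & rho_v != 0
  edge_list(tibble::tibble(
    source = src[keep], target = tgt[keep], weight = rho_v[keep],
    p_value = p[keep], size_fraction = abund_fraction(m)))
}

# two-sided p for Spearman rho via t with n-2 df
spearman_t_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
}

# exact permutation two-sided p for one pair (n <= 10)
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- permutations_all(n)
  vals <- apply(perms, 1, function(pm) abs(stats::cor(rx, ry[pm])))
  mean(vals >= obs - 1e-12)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Filter edges by first-order partial Spearman correlation on covariates
#'
#' Environmental meta-variables can drive spurious co-occurrence between a
#' virus and a non-host. As an approximation of conditional-independence
#' pruning, an edge survives iff, for every meta-variable `z`, the
#' first-order partial Spearman correlation of the pair given `z` (Pearson
#' partial correlation of average ranks) remains significant at `alpha`.
#' Samples with a missing value for `z` are dropped pairwise; constant
#' meta-variables are skipped with a warning.
#'
#' @param edges Edge list tibble over OTUs of `m`.
#' @param m The `vh_abund` table the edges were inferred from.
#' @param env Meta-variable tibble (first column `sample_id`).
#' @param alpha Significance level (default 0.01).
#' @return A list with `edges` (surviving edge tibble) and `removed`
#'   (tibble of removed edges with the conditioning variable responsible).
#' @export
metavar_condition <- function(edges, m, env, alpha = 0.01) {
  edges <- edge_list(edges)
  if (nrow(edges) == 0L || ncol(env) <= 1L) {
    return(list(edges = edges, removed = edges[0, c("source", "target")] |>
                  dplyr::mutate(variable = character(0))))
  }
  vals <- abund_values(m)
  samples <- colnames(vals)
  env <- tibble::as_tibble(env)
  env <- env[match(samples, env$sample_id), , drop = FALSE]
  vars <- setdiff(names(env), "sample_id")
  keep <- rep(TRUE, nrow(edges))
  culprit <- rep(NA_character_, nrow(edges))
  for (v in vars) {
    z <- env[[v]]
    ok <- !is.na(z)
    if (sum(ok) < 5 || stats::sd(z[ok]) == 0) {
      warning("meta-variable '", v, "' constant or too sparse; skipped")
      next
    }
    rz <- rank(z[ok])
    for (k in which(keep)) {
      x <- vals[edges$source[k], ok]
      y <- vals[edges$target[k], ok]
      pp <- partial_spearman_p(x, y, rz)
      if (is.na(pp) || pp >= alpha) {
        keep[k] <- FALSE
        culprit[k] <- v
      }
    }
  }
  list(edges = edges[keep, ],
       removed = tibble::tibble(source = edges$source[!keep],
                                target = edges$target[!keep],
                                variable = culprit[!keep]))
}

# two-sided p of the first-order partial Spearman correlation of x,y | z
partial_spearman_p <- function(x, y, rz) {
  n <- length(x)
  if (n < 5) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den < 1e-12) return(NA_real_)
  pr <- (rxy - rxz * ryz) / den
  pr <- min(1 - 1e-15, max(-1 + 1e-15, pr))
  tstat <- abs(pr) * sqrt((n - 3) / (1 - pr^2))
  2 * stats::pt(tstat, df = n - 3, lower.tail = FALSE)
}

#' Spearman associations between OTUs and environmental variables
#'
#' Tests every OTU of the focal marker against every meta-variable and
#' reports the pairs significant at `alpha` (raw, uncorrected — mirroring
#' the network's own thresholding).
#'
#' @param m `vh_abund` table (marker-prefixed ids allowed).
#' @param env Meta-variable tibble.
#' @param alpha Significance level (default 0.01).
#' @param marker Restrict to OTUs with this marker prefix (default no
#'   restriction).
#' @return Tibble with columns `otu_id`, `variable`, `rho`, `p_value`.
#' @export
detect_env_associations <- function(m, env, alpha = 0.01, marker = NULL) {
  if (ncol(env) <= 1L) {
    return(tibble::tibble(otu_id = character(), variable = character(),
                          rho = double(), p_value = double()))
  }
  vals <- abund_values(m)
  if (!is.null(marker)) {
    vals <- vals[startsWith(rownames(vals), paste0(marker, ":")) |
                   !grepl(":", rownames(vals)), , drop = FALSE]
  }
  env <- tibble::as_tibble(env)
  env <- env[match(colnames(vals), env$sample_id), , drop = FALSE]
  vars <- setdiff(names(env), "sample_id")
  out <- purrr::map_dfr(vars, function(v) {
    z <- env[[v]]
    ok <- !is.na(z)
    if (sum(ok) < 5 || stats::sd(z[ok]) == 0) return(NULL)
    rz <- rank(z[ok])
    purrr::map_dfr(rownames(vals), function(o) {
      x <- vals[o, ok]
      if (stats::sd(x) == 0) return(NULL)
      rho <- stats::cor(rank(x), rz)
      tibble::tibble(otu_id = o, variable = v, rho = rho,
                     p_value = spearman_t_p(rho, sum(ok)))
    })
  })
  out[!is.na(out$p_value) & out$p_value < alpha, ]
}

#' Signed degree statistics of a network's focal nodes
#'
#' Counts, per focal-marker node, its positive and negative cross-marker
#' edges, and reports the network means over connected nodes.
#'
#' @param edges Edge list tibble with marker-prefixed endpoints.
#' @param focal_marker Marker prefix of the focal nodes (default `"polB"`).
#' @return A list with `nodes` (tibble: `otu_id`, `positive_degree`,
#'   `negative_degree`, `degree`) and `means` (tibble of per-network mean
#'   degrees over nodes with degree >= 1).
#' @export
degree_stats <- function(edges, focal_marker = "polB") {
  edges <- edge_list(edges)
  pref <- paste0(focal_marker, ":")
  long <- dplyr::bind_rows(
    tibble::tibble(otu_id = edges$source, other = edges$target, sign = edges$sign),
    tibble::tibble(otu_id = edges$target, other = edges$source, sign = edges$sign))
  long <- long[startsWith(long$otu_id, pref) & !startsWith(long$other, pref), ]
  nodes <- long |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(
      positive_degree = sum(.data$sign == "positive"),
      negative_degree = sum(.data$sign == "negative"),
      .groups = "drop") |>
    dplyr::mutate(degree = .data$positive_degree + .data$negative_degree)
  means <- tibble::tibble(
    mean_positive_degree = if (nrow(nodes)) mean(nodes$positive_degree) else NA_real_,
    mean_negative_degree = if (nrow(nodes)) mean(nodes$negative_degree) else NA_real_,
    mean_degree = if (nrow(nodes)) mean(nodes$degree) else NA_real_,
    n_nodes = nrow(nodes))
  list(nodes = nodes, means = means)
}

#' Aggregate an OTU network to taxonomic groups
#'
#' Collapses edges to (viral family, eukaryotic group) pairs, counting
#' positive and negative edges separately; endpoints without annotation
#' are pooled under `"unclassified"`. This is the group-level summary
#' network whose edge widths are association counts.
#'
#' @param edges Edge list with marker-prefixed endpoints (polB source
#'   side).
#' @param tax Taxonomy tibble; `viral_family` annotates polB OTUs and
#'   `major_lineage` the V9 OTUs. OTU ids in `tax` are unprefixed.
#' @return Tibble with columns `viral_family`, `eukaryote_group`,
#'   `count_positive`, `count_negative`, plus node-size tibbles as
#'   attributes `family_sizes` and `group_sizes`.
#' @export
aggregate_network <- function(edges, tax) {
  edges <- edge_list(edges)
  tax <- taxonomy_table(tax)
  strip <- function(x) sub("^[^:]*:", "", x)
  fam <- tax$viral_family[match(strip(edges$source), tax$otu_id)]
  grp <- tax$major_lineage[match(strip(edges$target), tax$otu_id)]
  fam[is.na(fam)] <- "unclassified"
  grp[is.na(grp)] <- "unclassified"
  agg <- tibble::tibble(viral_family = fam, eukaryote_group = grp,
                        sign = edges$sign) |>
    dplyr::group_by(.data$viral_family, .data$eukaryote_group) |>
    dplyr::summarise(count_positive = sum(.data$sign == "positive"),
                     count_negative = sum(.data$sign == "negative"),
                     .groups = "drop")
  attr(agg, "family_sizes") <- tibble::tibble(
    viral_family = fam, otu = strip(edges$source)) |>
    dplyr::distinct() |>
    dplyr::count(.data$viral_family, name = "n_otus")
  attr(agg, "group_sizes") <- tibble::tibble(
    eukaryote_group = grp, otu = strip(edges$target)) |>
    dplyr::distinct() |>
    dplyr::count(.data$eukaryote_group, name = "n_otus")
  agg
}
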