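#' Assign tree leaves to named clades via MRCA expansion
#'
#' Each clade is specified by a set of defining leaves; the clade is the
#' full leaf set under their most recent common ancestor. Expanded clades
#' must be pairwise disjoint; leaves covered by no clade are
#' `"unassigned"`. Assignment depends only on tree topology, not on the
#' stored child order.
#'
#' @param tree An [ape::phylo] tree (e.g. the virophage MCP tree).
#' @param clade_spec Named list of character vectors: clade label ->
#'   defining leaf labels; or a tibble with columns `clade`, `leaf`.
#' @return Tibble with columns `leaf`, `clade`.
#' @export
assign_clades <- function(tree, clade_spec) {
  if (is.data.frame(clade_spec)) {
    clade_spec <- split(clade_spec$leaf, clade_spec$clade)
  }
  stopifnot(length(clade_spec) >= 1, !is.null(names(clade_spec)))
  n_tip <- length(tree$tip.label)
  expand <- function(leaves) {
    missing <- setdiff(leaves, tree$tip.label)
    if (length(missing)) stop("defining leaf missing from tree: ",
                              paste(missing, collapse = ", "))
    if (length(leaves) == 1L) return(leaves)
    mrca <- ape::getMRCA(tree, leaves)
    tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1]]]
  }
  expanded <- lapply(clade_spec, expand)
  labs <- names(expanded)
  for (i in seq_along(expanded)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(expanded[[i]], expanded[[j]]))) {
        stop("clades overlap after MRCA expansion: ", labs[j], ", ", labs[i])
      }
    }
  }
  assign <- stats::setNames(rep("unassigned", n_tip), tree$tip.label)
  for (i in seq_along(expanded)) assign[expanded[[i]]] <- labs[i]
  tibble::tibble(leaf = tree$tip.label, clade = unname(assign[tree$tip.label]))
}

#' Clade-by-family enrichment of virophage-NCLDV associations
#'
#' For every (virophage clade, NCLDV family group), tests whether the
#' association edges above the weight cutoff emanating from that clade
#' are enriched in the family group relative to the edges from the other
#' clades (one-sided Fisher, BH over all tests). The counting unit is the
#' association edge. Edges from unassigned-clade virophages are excluded
#' (their count is reported).
#'
#' @param edges Edge list between MCP OTUs (source side, prefixed
#'   `"MCP:"`) and polB OTUs.
#' @param clades Tibble from [assign_clades()] (leaf ids unprefixed).
#' @param families Tibble with columns `otu_id`, `viral_family` for the
#'   polB endpoints.
#' @param weight_cutoff Keep edges with `|weight| > weight_cutoff`
#'   (default 0, i.e. all edges).
#' @param family_grouping Optional tibble with columns `viral_family`,
#'   `group` pooling families (e.g. everything except Mimiviridae and
#'   Phycodnaviridae into `"Other NCLDVs"`); families absent from the map
#'   keep their own name.
#' @param q_threshold BH significance threshold (default 0.05).
#' @return A `vh_enrichment` tibble with columns `clade`, `family_group`,
#'   `a`, `b`, `c`, `d`, `p`, `q`, `significant`.
#' @export
clade_family_enrichment <- function(edges, clades, families,
                                    weight_cutoff = 0, family_grouping = NULL,
                                    q_threshold = 0.05) {
  edges <- edge_list(edges)
  edges <- edges[abs(edges$weight) > weight_cutoff, ]
  if (nrow(edges) == 0L) {
    warning("no edges above cutoff; empty enrichment result")
    return(tibble::tibble(clade = character(), family_group = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p = double(), q = double(),
                          significant = logical()))
  }
  strip <- function(x) sub("^[^:]*:", "", x)
  cl <- clades$clade[match(strip(edges$source), clades$leaf)]
  fam <- families$viral_family[match(strip(edges$target), families$otu_id)]
  fam[is.na(fam)] <- "unclassified"
  if (!is.null(family_grouping)) {
    g <- family_grouping$group[match(fam, family_grouping$viral_family)]
    fam <- ifelse(is.na(g), fam, g)
  }
  drop <- is.na(cl) | cl == "unassigned"
  if (any(drop)) message(sum(drop), " edge(s) from unassigned clades excluded")
  cl <- cl[!drop]; fam <- fam[!drop]
  if (!length(cl)) {
    warning("no clade-assigned edges; empty enrichment result")
    return(tibble::tibble(clade = character(), family_group = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p = double(), q = double(),
                          significant = logical()))
  }
  rows <- purrr::map_dfr(unique(cl), function(ci) {
    purrr::map_dfr(unique(fam), function(fi) {
      a <- sum(cl == ci & fam == fi)
      b <- sum(cl == ci & fam != fi)
      c_ <- sum(cl != ci & fam == fi)
      d <- sum(cl != ci & fam != fi)
      tibble::tibble(clade = ci, family_group = fi, a = a, b = b, c = c_,
                     d = d, p = fisher_exact_greater(a, b, c_, d))
    })
  })
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < q_threshold
  class(rows) <- c("vh_enrichment", class(rows))
  attr(rows, "q_threshold") <- q_threshold
  rows
}

#' Horizontal-gene-transfer candidate pairs from paired hit tables
#'
#' A virophage MCP is an HGT candidate against an NCLDV genome when its
#' best hit in the NCLDV genome database (after E-value, coverage and
#' identity screening) has a lower E-value than every non-self hit it has
#' in the virophage MCP database. Queries with no non-self MCP hit are
#' candidates whenever they have any passing NCLDV hit; these are
#' reported as unguarded.
#'
#' @param mcp_vs_ncldv Hit table of MCP queries against NCLDV genomes.
#' @param mcp_vs_mcp Hit table of MCP queries against the MCP database
#'   (self-hits, `query_id == subject_id`, are ignored).
#' @param max_evalue,min_coverage,min_identity Screening thresholds on the
#'   NCLDV hits (defaults 1e-10, 50, 50).
#' @return Tibble with columns `mcp_id`, `ncldv_genome_id`, `e_value`,
#'   `best_self_evalue`, `unguarded`.
#' @export
hgt_candidates <- function(mcp_vs_ncldv, mcp_vs_mcp,
                           max_evalue = 1e-10, min_coverage = 50,
                           min_identity = 50) {
  pass <- mcp_vs_ncldv[
    !is.na(mcp_vs_ncldv$e_value) & mcp_vs_ncldv$e_value <= max_evalue &
      !is.na(mcp_vs_ncldv$percent_query_coverage) &
      mcp_vs_ncldv$percent_query_coverage >= min_coverage &
      !is.na(mcp_vs_ncldv$percent_identity) &
      mcp_vs_ncldv$percent_identity >= min_identity, ]
  if (nrow(pass) == 0L) {
    return(tibble::tibble(mcp_id = character(), ncldv_genome_id = character(),
                          e_value = double(), best_self_evalue = double(),
                          unguarded = logical()))
  }
  best_ncldv <- pass |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$e_value, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  selfdb <- mcp_vs_mcp[mcp_vs_mcp$query_id != mcp_vs_mcp$subject_id &
                         !is.na(mcp_vs_mcp$e_value), ]
  best_self <- if (nrow(selfdb) == 0L) {
    tibble::tibble(query_id = character(), best_self_evalue = double())
  } else {
    selfdb |>
      dplyr::group_by(.data$query_id) |>
      dplyr::summarise(best_self_evalue = min(.data$e_value),
                       .groups = "drop")
  }
  joined <- dplyr::left_join(best_ncldv, best_self, by = "query_id")
  cand <- joined[is.na(joined$best_self_evalue) |
                   joined$e_value < joined$best_self_evalue, ]
  n_unguarded <- sum(is.na(cand$best_self_evalue))
  if (n_unguarded) {
    message(n_unguarded,
            " candidate(s) have no non-self MCP-database hit (unguarded)")
  }
  tibble::tibble(mcp_id = cand$query_id, ncldv_genome_id = cand$subject_id,
                 e_value = cand$e_value,
                 best_self_evalue = cand$best_self_evalue,
                 unguarded = is.na(cand$best_self_evalue))
}
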