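#' One-sided Fisher exact test for enrichment (hypergeometric upper tail)
#'
#' For a 2x2 table with `a` in-clade associated, `b` in-clade not
#' associated, `c` out-clade associated, `d` out-clade not associated,
#' the enrichment p-value is `P(X >= a)` for `X` hypergeometric with
#' population `a+b+c+d`, `a+c` successes and `a+b` draws. Computed as a
#' log-space sum of `lchoose` terms for numerical stability at large
#' totals.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The upper-tail probability in \[0, 1\].
#' @export
#' @examples
#' fisher_exact_greater(3, 0, 0, 3)  # 1 / choose(6, 3)
fisher_exact_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  n <- a + b + c + d
  if (n == 0) return(1)
  K <- a + c          # successes in population
  m <- a + b          # draws
  kmax <- min(K, m)
  if (a == 0) return(1)
  ks <- seq.int(a, kmax)
  logp <- lchoose(K, ks) + lchoose(n - K, m - ks) - lchoose(n, m)
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} (m / j) p_(j)`, capped
#' at 1 and mapped back to input order. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order; elementwise `q >= p`.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# tip-label sets under every internal node; names are node labels
node_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (n_tip + 1L):(n_tip + tree$Nnode), "tips")
  stats::setNames(lapply(desc, function(i) tree$tip.label[i]), tree$node.label)
}

#' Phylogeny-guided enrichment of host taxa over viral tree nodes
#'
#' The core of the Taxon Interaction Mapper: for every internal node of
#' the viral tree (root excluded) and every host taxon observed in the
#' association map, tests whether the leaves under the node are enriched
#' in viruses associated with that taxon relative to the rest of the tree
#' (one-sided Fisher), then adjusts all (node, taxon) p-values jointly by
#' Benjamini-Hochberg. A leaf is "associated with taxon T" iff it appears
#' with T in `assoc`; leaves absent from `assoc` count as not associated.
#' Tables with `a = 0` cannot be enriched (p = 1) and are kept in the BH
#' family so the adjustment is honest about the number of tests.
#'
#' @param tree An [ape::phylo] tree over viral OTUs with labelled internal
#'   nodes (see [read_newick()] / [label_tree_nodes()]); >= 3 leaves.
#' @param assoc Tibble with columns `otu_id`, `taxon` and optionally
#'   `rank` (defaults to `"major_lineage"`): the retained network
#'   associations, one row per (virus, host taxon). Edge weights play no
#'   role here; the filter acts on topology only.
#' @param q_threshold Significance threshold on the adjusted p (default
#'   0.05).
#' @return A `vh_enrichment` tibble with columns `node_id`, `taxon`,
#'   `rank`, `a`, `b`, `c`, `d`, `p`, `q`, `significant`.
#' @export
node_taxon_enrichment <- function(tree, assoc, q_threshold = 0.05) {
  if (length(tree$tip.label) < 3L) stop("tree must have >= 3 leaves")
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree <- label_tree_nodes(tree)
  }
  assoc <- tibble::as_tibble(assoc)
  stopifnot(all(c("otu_id", "taxon") %in% names(assoc)))
  if (!"rank" %in% names(assoc)) assoc$rank <- "major_lineage"
  extra <- setdiff(unique(assoc$otu_id), tree$tip.label)
  if (length(extra)) {
    stop("association OTUs absent from tree: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  sets <- node_leaf_sets(tree)
  root_label <- tree$node.label[1]  # ape: root is first internal node
  sets <- sets[setdiff(names(sets), root_label)]
  n_tip <- length(tree$tip.label)
  taxa <- dplyr::distinct(assoc[, c("taxon", "rank")])
  assoc_sets <- split(assoc$otu_id, assoc$taxon)
  rows <- purrr::map_dfr(seq_len(nrow(taxa)), function(ti) {
    tx <- taxa$taxon[ti]
    members <- unique(assoc_sets[[tx]])
    k_total <- length(members)
    purrr::map_dfr(names(sets), function(nd) {
      leaves <- sets[[nd]]
      a <- sum(leaves %in% members)
      b <- length(leaves) - a
      c_ <- k_total - a
      d <- (n_tip - length(leaves)) - c_
      tibble::tibble(node_id = nd, taxon = tx, rank = taxa$rank[ti],
                     a = a, b = b, c = c_, d = d,
                     p = if (a == 0) 1 else fisher_exact_greater(a, b, c_, d))
    })
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(node_id = character(), taxon = character(),
                           rank = character(), a = integer(), b = integer(),
                           c = integer(), d = integer(), p = double())
  }
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < q_threshold
  class(rows) <- c("vh_enrichment", class(rows))
  attr(rows, "q_threshold") <- q_threshold
  rows
}

#' Filter network edges by tree-node enrichment
#'
#' Retains an association (virus OTU, host OTU) iff some significant
#' (node, taxon) result has the virus among the node's leaves and the
#' host OTU annotated with that taxon at the taxon's rank. Everything
#' else is dropped; the output is always a subset of the input and the
#' filter is idempotent. Edges whose viral endpoint is not a tree leaf
#' are dropped (trees are typically built from a length-filtered subset
#' of sequences) and their count reported.
#'
#' @param edges Edge list with marker-prefixed endpoints (virus on the
#'   source side).
#' @param results `vh_enrichment` tibble from [node_taxon_enrichment()].
#' @param tree The tree the results were computed on.
#' @param tax Taxonomy tibble for the (unprefixed) host OTU ids.
#' @return The retained edge tibble.
#' @export
filter_edges_by_enrichment <- function(edges, results, tree, tax) {
  edges <- edge_list(edges)
  tax <- taxonomy_table(tax)
  strip <- function(x) sub("^[^:]*:", "", x)
  v <- strip(edges$source)
  in_tree <- v %in% tree$tip.label
  if (any(!in_tree)) {
    message(sum(!in_tree), " edge(s) dropped: viral endpoint not a tree leaf")
  }
  edges <- edges[in_tree, ]
  v <- v[in_tree]
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L || nrow(edges) == 0L) return(edges[0, ])
  sets <- node_leaf_sets(tree)
  rank_col <- c(major_lineage = "major_lineage", order = "ncbi_order",
                class = "ncbi_class", phylum = "ncbi_phylum")
  keep <- rep(FALSE, nrow(edges))
  host <- strip(edges$target)
  for (i in seq_len(nrow(sig))) {
    col <- rank_col[[sig$rank[i]]]
    if (is.null(col)) stop("unknown taxon rank: ", sig$rank[i])
    ann <- tax[[col]][match(host, tax$otu_id)]
    keep <- keep | (v %in% sets[[sig$node_id[i]]] &
                      !is.na(ann) & ann == sig$taxon[i])
  }
  edges[keep, ]
}

#' Family-by-lineage summary network of enrichment results
#'
#' Attributes each significant (node, taxon) result to the viral family
#' of the node's subtree (a node counts for a family iff at least
#' `purity` of its leaves carry that family label; impure nodes are
#' pooled under `"mixed"`), converts taxa to major lineages via
#' `lineage_map`, and weights each (family, lineage) edge by the number
#' of enriched nodes.
#'
#' @param results `vh_enrichment` tibble.
#' @param tree The viral tree.
#' @param viral_families Tibble with columns `otu_id`, `viral_family`
#'   (leaves without a row count as `"unclassified"`).
#' @param lineage_map Optional tibble with columns `taxon`,
#'   `major_lineage` converting rank-level taxa; taxa absent from the map
#'   are assumed to already be major lineages.
#' @param purity Fraction of leaves that must share the family label
#'   (default 1).
#' @return Tibble with columns `viral_family`, `major_lineage`, `weight`.
#' @export
tim_network <- function(results, tree, viral_families, lineage_map = NULL,
                        purity = 1) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(tibble::tibble(viral_family = character(),
                          major_lineage = character(), weight = integer()))
  }
  viral_families <- tibble::as_tibble(viral_families)
  sets <- node_leaf_sets(tree)
  fam_of <- function(node_id) {
    leaves <- sets[[node_id]]
    fams <- viral_families$viral_family[match(leaves, viral_families$otu_id)]
    fams[is.na(fams)] <- "unclassified"
    tab <- sort(table(fams), decreasing = TRUE)
    if (tab[1] / length(fams) >= purity) names(tab)[1] else "mixed"
  }
  lin_of <- function(taxon) {
    if (!is.null(lineage_map)) {
      hit <- lineage_map$major_lineage[match(taxon, lineage_map$taxon)]
      if (!is.na(hit)) return(hit)
    }
    taxon
  }
  tibble::tibble(
    viral_family = vapply(sig$node_id, fam_of, character(1)),
    major_lineage = vapply(sig$taxon, lin_of, character(1))) |>
    dplyr::count(.data$viral_family, .data$major_lineage, name = "weight")
}
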