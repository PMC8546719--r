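#' Construct a validated OTU-by-sample abundance table
#'
#' The abundance table is the substrate of every inference step in the
#' package: a tibble with an `otu_id` column followed by one numeric column
#' per sample, carrying the marker gene (`polB` for NCLDVs, `V9` for
#' eukaryotic metabarcodes, `MCP` for virophages), the plankton size
#' fraction the samples were filtered from, and the unit of the values.
#'
#' @param x A data frame whose first column is `otu_id` (character) and
#'   whose remaining columns are numeric sample abundances.
#' @param marker One of `"polB"`, `"V9"`, `"MCP"`.
#' @param size_fraction Size-fraction label, e.g. `"0.8-5"`, `"0.8-inf"`,
#'   `"pico"`, `"femto"`.
#' @param unit One of `"counts"`, `"relative"`, `"clr"`. Values must be
#'   non-negative unless the unit is `clr`.
#' @param validate_clr_sum For `unit = "clr"`, check that every sample
#'   column sums to zero. This holds for a freshly transformed full matrix
#'   but not after subsetting OTUs, so subsetting operations disable it.
#' @return A tibble of class `vh_abund` with attributes `marker`,
#'   `size_fraction` and `unit`.
#' @export
#' @examples
#' abundance_table(
#'   tibble::tibble(otu_id = c("v1", "v2"), s1 = c(3, 0), s2 = c(1, 9)),
#'   marker = "polB", size_fraction = "pico", unit = "counts"
#' )
abundance_table <- function(x, marker = c("polB", "V9", "MCP"),
                            size_fraction = "pico",
                            unit = c("counts", "relative", "clr"),
                            validate_clr_sum = TRUE) {
  marker <- match.arg(marker)
  unit <- match.arg(unit)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) stop("abundance table needs an otu_id column plus >= 1 sample column")
  names(x)[1] <- "otu_id"
  x$otu_id <- as.character(x$otu_id)
  if (anyDuplicated(x$otu_id)) {
    stop("duplicate otu_id: ", paste(unique(x$otu_id[duplicated(x$otu_id)]), collapse = ", "))
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sample id: ", paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("sample columns must be numeric")
  if (anyNA(vals)) stop("abundance values must not be missing")
  if (unit != "clr" && any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at otu '", x$otu_id[bad[1]], "', sample '",
         colnames(vals)[bad[2]], "' with unit=", unit)
  }
  if (unit == "clr" && validate_clr_sum) {
    colsum <- colSums(vals)
    if (any(abs(colsum) > 1e-6)) {
      stop("clr columns must sum to 0; sample '",
           colnames(vals)[which.max(abs(colsum))], "' sums to ",
           format(max(abs(colsum))))
    }
  }
  structure(x,
            class = c("vh_abund", class(tibble::tibble()))[!duplicated(c("vh_abund", class(tibble::tibble())))],
            marker = marker, size_fraction = size_fraction, unit = unit)
}

#' @export
print.vh_abund <- function(x, ...) {
  cat(sprintf("# Abundance table: %d OTUs x %d samples [marker=%s, fraction=%s, unit=%s]\n",
              nrow(x), ncol(x) - 1L, abund_marker(x), abund_fraction(x), abund_unit(x)))
  NextMethod()
}

#' Accessors for abundance-table metadata
#'
#' @param x A `vh_abund` tibble.
#' @return `abund_marker()`, `abund_fraction()` and `abund_unit()` return the
#'   corresponding label; `abund_values()` returns the numeric matrix with
#'   OTU ids as rownames; `abund_samples()` the sample ids.
#' @export
abund_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$otu_id
  m
}

#' @rdname abund_values
#' @export
abund_samples <- function(x) names(x)[-1]

#' @rdname abund_values
#' @export
abund_marker <- function(x) attr(x, "marker") %||% "polB"

#' @rdname abund_values
#' @export
abund_fraction <- function(x) attr(x, "size_fraction") %||% "pico"

#' @rdname abund_values
#' @export
abund_unit <- function(x) attr(x, "unit") %||% "counts"

#' Read / write an abundance table as TSV
#'
#' TSV with OTU rows and sample columns; a header row names the samples and
#' lines starting with `#` are treated as comments. Cells must be numeric;
#' a malformed cell is reported with its row and column.
#'
#' @inheritParams abundance_table
#' @param path File path.
#' @return `read_abundance()` returns a `vh_abund` tibble;
#'   `write_abundance()` returns `path` invisibly.
#' @export
read_abundance <- function(path, marker = c("polB", "V9", "MCP"),
                           size_fraction = "pico",
                           unit = c("counts", "relative", "clr")) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  if (nrow(raw) == 0L) stop("empty abundance file: ", path)
  for (j in seq(2L, ncol(raw))) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad)) {
      stop("malformed numeric cell '", raw[[j]][bad[1]], "' at row '",
           raw[[1]][bad[1]], "', column '", names(raw)[j], "'")
    }
    raw[[j]] <- num
  }
  abundance_table(raw, marker = marker, size_fraction = size_fraction, unit = unit)
}

#' @rdname read_abundance
#' @param x A `vh_abund` tibble.
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Construct a validated signed edge list
#'
#' Edges are unordered OTU pairs with an association weight in \[-1, 1\]
#' (the network "weight"), an optional p-value, the size fraction the
#' network was inferred from, and a sign that must agree with the weight.
#'
#' @param x Data frame with columns `source`, `target`, `weight` and
#'   optionally `p_value`, `size_fraction`, `sign` (recomputed from the
#'   weight when absent).
#' @return A tibble with columns `source`, `target`, `weight`, `p_value`,
#'   `sign`, `size_fraction`.
#' @export
edge_list <- function(x) {
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          weight = double(), p_value = double(),
                          sign = character(), size_fraction = character()))
  }
  stopifnot(all(c("source", "target", "weight") %in% names(x)))
  if (!"p_value" %in% names(x)) x$p_value <- NA_real_
  if (!"size_fraction" %in% names(x)) x$size_fraction <- "pooled"
  x$sign <- ifelse(x$weight > 0, "positive", "negative")
  bad <- which(abs(x$weight) > 1 + 1e-12)
  if (length(bad)) stop("edge weight out of [-1,1]: ", x$source[bad[1]], "--", x$target[bad[1]])
  self <- which(x$source == x$target)
  if (length(self)) stop("self-edge not allowed: ", x$source[self[1]])
  key <- paste(pmin(x$source, x$target), pmax(x$source, x$target), x$size_fraction)
  if (anyDuplicated(key)) {
    stop("duplicate unordered edge within a size fraction: ",
         key[duplicated(key)][1])
  }
  x[, c("source", "target", "weight", "p_value", "sign", "size_fraction")]
}

#' Read / write edge lists
#'
#' The on-disk format is a TSV with columns `source`, `target`, `weight`,
#' `p_value`, `sign`, `size_fraction`, sorted by decreasing absolute weight
#' (ties by source then target) so the file is stable across runs and
#' loadable by graph-visualization tools.
#'
#' @param edges An edge list tibble (see [edge_list()]).
#' @param path File path.
#' @export
write_edges <- function(edges, path) {
  edges <- edge_list(edges)
  edges <- edges[order(-abs(edges$weight), edges$source, edges$target), ]
  readr::write_tsv(edges, path)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    weight = readr::col_double(), p_value = readr::col_double(),
    sign = readr::col_character(), size_fraction = readr::col_character()))
  edge_list(x)
}

#' Read a rooted viral marker-gene tree from newick
#'
#' Internal nodes without labels receive deterministic ids (`node` followed
#' by the node's post-order index, counting internal nodes in post-order
#' from the root's children upward) so that enrichment results are
#' reproducible across runs. Duplicate leaf labels are rejected.
#'
#' @param path Path to a newick file (support values on internal nodes are
#'   treated as labels only when non-numeric ids are present; numeric-only
#'   labels are replaced by post-order ids).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: could not read ", path)
  label_tree_nodes(tree)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign deterministic post-order ids to unnamed internal nodes
#'
#' @param tree An [ape::phylo] object.
#' @return The tree with unique leaf labels verified and every internal
#'   node labelled (existing non-empty, non-numeric labels are kept).
#' @export
label_tree_nodes <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  post <- postorder_internal(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_node)
  lab[is.na(lab)] <- ""
  numeric_like <- lab != "" & !is.na(suppressWarnings(as.numeric(lab)))
  lab[numeric_like] <- ""
  for (k in seq_along(post)) {
    idx <- post[k] - n_tip
    if (lab[idx] == "") lab[idx] <- paste0("node", k)
  }
  if (anyDuplicated(lab)) stop("duplicate internal node label after assignment")
  tree$node.label <- lab
  tree
}

# Post-order sequence of internal node numbers (ape numbering), children
# visited in stored edge order; the root comes last.
postorder_internal <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root <- n_tip + 1L
  out <- integer(0)
  stack <- list(list(node = root, visited = FALSE))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$visited) {
      out <- c(out, top$node)
    } else {
      stack[[length(stack) + 1L]] <- list(node = top$node, visited = TRUE)
      kids <- children[[as.character(top$node)]]
      for (k in rev(kids)) {
        if (k > n_tip) stack[[length(stack) + 1L]] <- list(node = k, visited = FALSE)
      }
    }
  }
  out
}

#' Read a tabular homology-search hit table
#'
#' Consumes the tab-separated output of protein/nucleotide homology
#' searches. The default layout is six columns: query, subject, percent
#' identity, percent query coverage, E-value, bitscore. `col_map` remaps
#' column positions for other layouts (e.g. the classic 12-column tabular
#' format, where coverage is absent: pass `NA` and coverage is recorded as
#' missing).
#'
#' @param path File path; an empty file yields an empty hit table.
#' @param col_map Named integer vector giving the 1-based column positions
#'   of `query_id`, `subject_id`, `percent_identity`,
#'   `percent_query_coverage`, `e_value`, `bitscore`.
#' @return A tibble with those six columns, range-validated.
#' @export
read_hits <- function(path,
                      col_map = c(query_id = 1L, subject_id = 2L,
                                  percent_identity = 3L,
                                  percent_query_coverage = 4L,
                                  e_value = 5L, bitscore = 6L)) {
  need <- c("query_id", "subject_id", "percent_identity",
            "percent_query_coverage", "e_value", "bitscore")
  stopifnot(all(need %in% names(col_map)))
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) return(empty_hits())
  get <- function(field, numeric = TRUE) {
    j <- col_map[[field]]
    if (is.na(j)) return(rep(NA_real_, nrow(raw)))
    v <- raw[[j]]
    if (numeric) suppressWarnings(as.numeric(v)) else v
  }
  hits <- tibble::tibble(
    query_id = get("query_id", numeric = FALSE),
    subject_id = get("subject_id", numeric = FALSE),
    percent_identity = get("percent_identity"),
    percent_query_coverage = get("percent_query_coverage"),
    e_value = get("e_value"),
    bitscore = get("bitscore"))
  validate_hits(hits)
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 percent_identity = double(), percent_query_coverage = double(),
                 e_value = double(), bitscore = double())
}

validate_hits <- function(hits) {
  for (f in c("percent_identity", "percent_query_coverage")) {
    bad <- which(!is.na(hits[[f]]) & (hits[[f]] < 0 | hits[[f]] > 100))
    if (length(bad)) {
      stop(f, " out of [0,100] for query '", hits$query_id[bad[1]], "': ",
           hits[[f]][bad[1]])
    }
  }
  bad <- which(!is.na(hits$e_value) & hits$e_value < 0)
  if (length(bad)) stop("negative e_value for query '", hits$query_id[bad[1]], "'")
  hits
}

#' Read a taxonomy table
#'
#' Maps OTU ids to their eukaryotic "major lineage" (the intermediate-rank
#' level of the PR2 V9 reference used as host labels), optional NCBI
#' order/class/phylum, and optional viral family for polB OTUs. Missing
#' annotation fields may be empty or `NA`; such OTUs are treated as
#' unannotated downstream.
#'
#' @param path TSV with header columns `otu_id`, `major_lineage` and
#'   optionally `ncbi_order`, `ncbi_class`, `ncbi_phylum`, `viral_family`.
#' @param lineage_vocab Optional closed vocabulary of major lineages;
#'   any non-missing lineage outside it is rejected.
#' @return A tibble with the six columns (absent optional columns filled
#'   with `NA`).
#' @export
read_taxonomy <- function(path, lineage_vocab = NULL) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  names(x)[1] <- "otu_id"
  taxonomy_table(x, lineage_vocab = lineage_vocab)
}

#' @rdname read_taxonomy
#' @param x Data frame with at least `otu_id` and `major_lineage`.
#' @export
taxonomy_table <- function(x, lineage_vocab = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot("otu_id" %in% names(x))
  for (f in c("major_lineage", "ncbi_order", "ncbi_class", "ncbi_phylum", "viral_family")) {
    if (!f %in% names(x)) x[[f]] <- NA_character_
    x[[f]][x[[f]] %in% ""] <- NA_character_
  }
  if (anyDuplicated(x$otu_id)) {
    stop("duplicate otu_id in taxonomy: ", x$otu_id[duplicated(x$otu_id)][1])
  }
  if (!is.null(lineage_vocab)) {
    bad <- setdiff(stats::na.omit(unique(x$major_lineage)), lineage_vocab)
    if (length(bad)) stop("major_lineage outside supplied vocabulary: ",
                          paste(bad, collapse = ", "))
  }
  x[, c("otu_id", "major_lineage", "ncbi_order", "ncbi_class", "ncbi_phylum", "viral_family")]
}

#' Read the reference virus-host table
#'
#' One row per known (reference virus, host major lineage) pair; a
#' reference virus with several known host lineages appears on several
#' rows.
#'
#' @param path TSV with columns `reference_virus_id`, `viral_family`,
#'   `host_major_lineage`.
#' @param lineage_vocab Optional closed lineage vocabulary.
#' @return A tibble with those three columns.
#' @export
read_reference_hosts <- function(path, lineage_vocab = NULL) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  reference_host_table(x, lineage_vocab = lineage_vocab)
}

#' @rdname read_reference_hosts
#' @param x Data frame with the reference table columns.
#' @export
reference_host_table <- function(x, lineage_vocab = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("reference_virus_id", "host_major_lineage") %in% names(x)))
  if (!"viral_family" %in% names(x)) x$viral_family <- NA_character_
  key <- paste(x$reference_virus_id, x$host_major_lineage)
  if (anyDuplicated(key)) stop("duplicate (virus, lineage) reference pair: ",
                               key[duplicated(key)][1])
  if (!is.null(lineage_vocab)) {
    bad <- setdiff(unique(x$host_major_lineage), lineage_vocab)
    if (length(bad)) stop("host lineage outside vocabulary: ", paste(bad, collapse = ", "))
  }
  x[, c("reference_virus_id", "viral_family", "host_major_lineage")]
}

#' Read an environmental meta-variable table
#'
#' @param path TSV with a `sample_id` column followed by numeric
#'   environmental variables (temperature, salinity, nutrients, ...).
#'   Missing values are kept as `NA` and handled pairwise downstream.
#' @return A tibble, first column `sample_id`.
#' @export
read_metavars <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()))
  names(x)[1] <- "sample_id"
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in meta-variable table")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
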