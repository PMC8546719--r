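#' Convert relative abundances back to read counts
#'
#' Gene-catalog relative abundances are length-normalized; network
#' inference and clr need integer-like counts. Counts are reconstructed
#' per cell as `round(rel * gene_length / read_length * scale)`, with a
#' per-sample scale standing in for library size. Zeros map to zeros.
#'
#' @param rel A `vh_abund` table with `unit = "relative"`.
#' @param lengths Data frame with columns `otu_id`, `gene_length`
#'   (nucleotides); every OTU in `rel` must be present.
#' @param read_length Assumed read length in nucleotides (default 100).
#' @param per_sample_scale Either a single number applied to every sample
#'   or a named vector over sample ids. Defaults to `1e6`; only relative
#'   magnitudes matter downstream of clr.
#' @return A `vh_abund` table with `unit = "counts"`.
#' @export
relabund_to_counts <- function(rel, lengths, read_length = 100,
                               per_sample_scale = 1e6) {
  stopifnot(abund_unit(rel) == "relative")
  lengths <- tibble::as_tibble(lengths)
  stopifnot(all(c("otu_id", "gene_length") %in% names(lengths)))
  if (any(lengths$gene_length <= 0)) stop("gene lengths must be positive")
  missing <- setdiff(rel$otu_id, lengths$otu_id)
  if (length(missing)) stop("missing gene length for otu: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  vals <- abund_values(rel)
  len <- lengths$gene_length[match(rownames(vals), lengths$otu_id)]
  scale <- rep_len(per_sample_scale, ncol(vals))
  if (!is.null(names(per_sample_scale)) && length(per_sample_scale) > 1L) {
    scale <- per_sample_scale[colnames(vals)]
    if (anyNA(scale)) stop("per_sample_scale missing a sample id")
  }
  counts <- round(vals * (len / read_length) %o% rep(1, ncol(vals)) *
                    rep(scale, each = nrow(vals)))
  out <- tibble::as_tibble(counts)
  out <- tibble::add_column(out, otu_id = rownames(vals), .before = 1)
  abundance_table(out, marker = abund_marker(rel),
                  size_fraction = abund_fraction(rel), unit = "counts")
}

#' Centered log-ratio transform of a count table
#'
#' Each sample (column) is treated as a composition over all OTUs of the
#' matrix: `clr_i = ln(x_i + pc) - mean_k ln(x_k + pc)`. A pseudocount of
#' one (default) makes zeros transformable. Per-sample clr vectors sum to
#' zero by construction, and clr is invariant to multiplying a sample's
#' shifted vector by a positive constant.
#'
#' @param m A `vh_abund` table with `unit = "counts"`.
#' @param pseudocount Positive shift added to every cell before logging.
#' @return A `vh_abund` table with `unit = "clr"`.
#' @export
clr_transform <- function(m, pseudocount = 1) {
  stopifnot(abund_unit(m) == "counts", pseudocount > 0)
  vals <- abund_values(m)
  if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty abundance matrix")
  lg <- log(vals + pseudocount)
  clr <- sweep(lg, 2, colMeans(lg))
  out <- tibble::as_tibble(clr)
  out <- tibble::add_column(out, otu_id = rownames(vals), .before = 1)
  abundance_table(out, marker = abund_marker(m),
                  size_fraction = abund_fraction(m), unit = "clr")
}

#' Quartile-based low-abundance OTU filter
#'
#' Computes a clr threshold `T` as the requested quartile of the clr values
#' at cells that were non-zero in the original count matrix (before the
#' pseudocount), then retains an OTU iff its clr abundance exceeds `T` in
#' at least `min_samples` samples. The threshold is global over the matrix
#' by default; `scope = "per_otu"` computes a separate threshold per OTU
#' from its own non-zero cells.
#'
#' @param counts The original count table (`unit = "counts"`).
#' @param clr_m Its clr transform, same OTUs and samples.
#' @param quantile_level One of `"Q1"`, `"Q2"`, `"Q3"` (lower quartile,
#'   median, upper quartile). Lower-quartile filtering is the standard
#'   trimming; upper-quartile is the rigorous variant.
#' @param min_samples Minimum number of samples above threshold (default 5).
#' @param scope `"global"` (default) or `"per_otu"`.
#' @return Character vector of retained OTU ids (in input row order).
#' @export
quartile_filter <- function(counts, clr_m,
                            quantile_level = c("Q1", "Q2", "Q3"),
                            min_samples = 5, scope = c("global", "per_otu")) {
  quantile_level <- match.arg(quantile_level)
  scope <- match.arg(scope)
  stopifnot(min_samples >= 1)
  cv <- abund_values(counts)
  zv <- abund_values(clr_m)
  if (!identical(dim(cv), dim(zv)) || !identical(rownames(cv), rownames(zv))) {
    stop("counts and clr matrices must share shape and OTU ids")
  }
  nz <- cv > 0
  if (!any(nz)) stop("no nonzero counts; cannot compute quartile threshold")
  prob <- c(Q1 = 0.25, Q2 = 0.5, Q3 = 0.75)[[quantile_level]]
  if (scope == "global") {
    thr <- stats::quantile(zv[nz], probs = prob, names = FALSE)
    above <- rowSums(zv > thr)
  } else {
    above <- vapply(seq_len(nrow(zv)), function(i) {
      if (!any(nz[i, ])) return(0L)
      ti <- stats::quantile(zv[i, nz[i, ]], probs = prob, names = FALSE)
      sum(zv[i, ] > ti)
    }, integer(1))
  }
  rownames(cv)[above >= min_samples]
}

#' Restrict two marker tables to their shared samples and stack them
#'
#' Network inference needs the viral and eukaryotic tables over the same
#' samples. Samples are intersected (sorted for determinism), the OTU rows
#' of both markers are stacked, and OTU ids are prefixed with their marker
#' so the id spaces stay disjoint.
#'
#' @param a,b `vh_abund` tables with the same unit and disjoint OTU ids
#'   after marker prefixing.
#' @param tag_marker Prefix OTU ids with `"<marker>:"` (default `TRUE`).
#' @return A `vh_abund` table over the shared samples; the size fraction
#'   label is taken from `b` (the eukaryotic fraction defines the network).
#' @export
intersect_and_merge <- function(a, b, tag_marker = TRUE) {
  stopifnot(abund_unit(a) == abund_unit(b))
  shared <- sort(intersect(abund_samples(a), abund_samples(b)))
  if (length(shared) == 0L) stop("no shared samples between the two tables")
  ta <- tibble::as_tibble(a)[, c("otu_id", shared)]
  tb <- tibble::as_tibble(b)[, c("otu_id", shared)]
  if (tag_marker) {
    ta$otu_id <- paste0(abund_marker(a), ":", ta$otu_id)
    tb$otu_id <- paste0(abund_marker(b), ":", tb$otu_id)
  }
  merged <- dplyr::bind_rows(ta, tb)
  if (anyDuplicated(merged$otu_id)) stop("OTU id spaces overlap after merge")
  out <- abundance_table(merged, marker = abund_marker(a),
                         size_fraction = abund_fraction(b),
                         unit = abund_unit(a), validate_clr_sum = FALSE)
  attr(out, "markers") <- stats::setNames(
    c(abund_marker(a), abund_marker(b)), c("a", "b"))
  out
}

#' Per-sample Shannon diversity and richness
#'
#' Shannon diversity in nats (via vegan) and richness (number of OTUs with
#' non-zero counts) per sample. All-zero samples are returned with zero
#' diversity and richness and flagged.
#'
#' @param counts A `vh_abund` table with `unit = "counts"`.
#' @return A tibble with columns `sample_id`, `shannon`, `richness`,
#'   `empty`.
#' @export
diversity_indices <- function(counts) {
  stopifnot(abund_unit(counts) == "counts")
  vals <- abund_values(counts)
  tot <- colSums(vals)
  sh <- rep(0, ncol(vals))
  ok <- tot > 0
  if (any(ok)) {
    sh[ok] <- vegan::diversity(t(vals[, ok, drop = FALSE]), index = "shannon")
  }
  tibble::tibble(
    sample_id = colnames(vals),
    shannon = sh,
    richness = as.integer(colSums(vals > 0)),
    empty = !ok)
}

#' Full preprocessing pipeline for one size fraction
#'
#' Runs the data-processing stage end to end for a viral and a eukaryotic
#' table: clr-normalize each marker separately (pseudocount 1), apply the
#' quartile filter to each, then intersect samples and stack the retained
#' OTUs. Filtering precedes merging, and the clr values are (by default)
#' the full-matrix values subset to the retained OTUs rather than
#' recomputed; `recompute_clr = TRUE` re-runs clr on the filtered counts.
#'
#' @param polb,v9 Count tables (`unit = "counts"`) for the two markers.
#' @param quantile_level,min_samples,pseudocount Filter settings (defaults:
#'   lower quartile, 5 samples, pseudocount 1).
#' @param recompute_clr Recompute clr after filtering (default `FALSE`).
#' @return A list with `merged` (clr `vh_abund` over shared samples),
#'   `retained` (list of retained OTU ids per marker) and `report`
#'   (tibble of OTU counts before/after filtering).
#' @export
preprocess_pair <- function(polb, v9, quantile_level = "Q1", min_samples = 5,
                            pseudocount = 1, recompute_clr = FALSE) {
  one <- function(m) {
    z <- clr_transform(m, pseudocount = pseudocount)
    keep <- quartile_filter(m, z, quantile_level = quantile_level,
                            min_samples = min_samples)
    mk <- abundance_table(tibble::as_tibble(m)[m$otu_id %in% keep, ],
                          marker = abund_marker(m),
                          size_fraction = abund_fraction(m), unit = "counts")
    zk <- if (recompute_clr) {
      clr_transform(mk, pseudocount = pseudocount)
    } else {
      tibble::as_tibble(z)[z$otu_id %in% keep, ] |>
        abundance_table(marker = abund_marker(m),
                        size_fraction = abund_fraction(m), unit = "clr",
                        validate_clr_sum = FALSE)
    }
    list(clr = zk, keep = keep, before = nrow(m))
  }
  pa <- one(polb)
  pb <- one(v9)
  merged <- intersect_and_merge(pa$clr, pb$clr)
  list(
    merged = merged,
    retained = list(polB = pa$keep, V9 = pb$keep),
    report = tibble::tibble(
      marker = c(abund_marker(polb), abund_marker(v9)),
      otus_before = c(pa$before, pb$before),
      otus_after = c(length(pa$keep), length(pb$keep)),
      samples_shared = length(abund_samples(merged))))
}
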