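# Small in-code fixtures shared across test files.

toy_counts <- function(marker = "polB", fraction = "pico") {
  abundance_table(
    tibble::tibble(otu_id = c("a", "b", "c"),
                   s1 = c(3, 0, 9), s2 = c(1, 5, 0), s3 = c(2, 2, 2)),
    marker = marker, size_fraction = fraction, unit = "counts")
}

toy_tree <- function(text = "((A,B),(C,D));") {
  label_tree_nodes(ape::read.tree(text = text))
}

# a deterministic merged clr-like table with known cross-marker structure
toy_merged <- function(n = 12, seed = 7) {
  set.seed(seed)
  x <- stats::rnorm(n)
  tibble::tibble(
    otu_id = c("polB:v1", "polB:v2", "V9:h1", "V9:h2"),
    !!!stats::setNames(as.data.frame(rbind(x, -x + stats::rnorm(n, sd = 0.01),
                                           x + stats::rnorm(n, sd = 0.01),
                                           stats::rnorm(n))),
                       paste0("s", seq_len(n)))) |>
    abundance_table(marker = "polB", size_fraction = "pico", unit = "clr",
                    validate_clr_sum = FALSE)
}

toy_taxonomy <- function() {
  taxonomy_table(tibble::tibble(
    otu_id = c("h1", "h2", "h3", "v1", "v2"),
    major_lineage = c("Haptophyta", "Metazoa", "Dinophyceae", NA, NA),
    viral_family = c(NA, NA, NA, "Mimiviridae", "Iridoviridae")))
}
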