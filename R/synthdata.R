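#' Parameters of the synthetic paired-community generator
#'
#' Defaults mirror the study conditions the package is designed around:
#' 88 samples per size fraction, zero-inflated lognormal abundances,
#' 12 host major lineages, and planted virus-host couplings with a target
#' Spearman correlation of 0.8 on a phylogenetically structured host
#' preference (related viruses prefer related host lineages).
#'
#' @param n_samples Number of samples (default 88).
#' @param n_hosts Number of eukaryotic (V9) OTUs (default 150).
#' @param n_viruses Number of viral (polB) OTUs (default 100).
#' @param n_lineages Number of host major lineages (default 12).
#' @param frac_coupled Fraction of viruses with a planted host
#'   (default 0.4).
#' @param coupling_strength Target Spearman correlation of a planted pair
#'   over the samples where the pair is present, in (0, 1\] (default 0.8).
#' @param occupancy Per-OTU probability of presence in a sample
#'   (default 0.5).
#' @param clade_host_fidelity Probability that a child tree node keeps its
#'   parent's preferred host lineage (default 0.9).
#' @param identity_true,identity_decoy Percent-identity ranges of true and
#'   decoy reference hits (defaults 66-95 and 30-60, straddling the 65%
#'   grouping threshold).
#' @param n_confounded Number of otherwise-uncoupled virus-host pairs
#'   driven by the temperature confounder (default 4).
#' @param log_mean,log_sd Lognormal abundance parameters (defaults 2, 1).
#' @param seed Integer seed; every artifact is reproducible from it.
#' @return A list of class `vh_synth_params`.
#' @export
synth_params <- function(n_samples = 88, n_hosts = 150, n_viruses = 100,
                         n_lineages = 12, frac_coupled = 0.4,
                         coupling_strength = 0.8, occupancy = 0.5,
                         clade_host_fidelity = 0.9,
                         identity_true = c(66, 95),
                         identity_decoy = c(30, 60),
                         n_confounded = 4,
                         log_mean = 2, log_sd = 1, seed = 1) {
  p <- list(n_samples = n_samples, n_hosts = n_hosts, n_viruses = n_viruses,
            n_lineages = n_lineages, frac_coupled = frac_coupled,
            coupling_strength = coupling_strength, occupancy = occupancy,
            clade_host_fidelity = clade_host_fidelity,
            identity_true = identity_true, identity_decoy = identity_decoy,
            n_confounded = n_confounded, log_mean = log_mean,
            log_sd = log_sd, seed = seed)
  stopifnot(p$frac_coupled >= 0, p$frac_coupled <= 1,
            p$occupancy > 0, p$occupancy <= 1,
            p$coupling_strength > 0, p$coupling_strength <= 1,
            p$clade_host_fidelity >= 0, p$clade_host_fidelity <= 1,
            identity_true[1] <= identity_true[2],
            identity_decoy[1] <= identity_decoy[2])
  if (round(p$frac_coupled * p$n_viruses) < 1) {
    stop("infeasible parameters: frac_coupled * n_viruses < 1")
  }
  class(p) <- "vh_synth_params"
  p
}

# Pearson latent correlation giving a target Spearman rho under a
# Gaussian copula: rho_pearson = 2 sin(pi rho_s / 6)
copula_latent_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic paired viral/eukaryotic data set with planted truth
#'
#' Emits every artifact the pipeline consumes: paired polB and V9 count
#' tables (zero-inflated lognormal; coupled viruses share their host's
#' presence pattern and track its abundance through a Gaussian copula at
#' the target Spearman correlation), a random bifurcating viral tree whose
#' clades inherit host-lineage preference with the configured fidelity, a
#' taxonomy table, a reference host table with one reference virus per
#' lineage, a homology hit table in which coupled viruses hit their
#' reference inside the true identity range while decoy hits stay below
#' the 65% threshold, an environmental table whose temperature column
#' confounds a few otherwise-uncoupled pairs, and the ground truth.
#'
#' @param params A [synth_params()] list.
#' @return A list with elements `polb`, `v9` (`vh_abund` count tables),
#'   `taxonomy`, `reference`, `hits`, `tree`, `metavars`, `truth`
#'   (`truth$planted`: tibble of `virus_otu`, `host_otu`, `host_lineage`;
#'   `truth$confounded`; `truth$families`; `truth$lineages`;
#'   `truth$reference_assignment`).
#' @export
synth_generate <- function(params = synth_params()) {
  stopifnot(inherits(params, "vh_synth_params"))
  set.seed(params$seed)
  p <- params
  lineages <- sprintf("Lineage%02d", seq_len(p$n_lineages))
  host_ids <- sprintf("h%03d", seq_len(p$n_hosts))
  virus_ids <- sprintf("v%03d", seq_len(p$n_viruses))
  samples <- sprintf("s%03d", seq_len(p$n_samples))
  host_lineage <- sample(rep_len(lineages, p$n_hosts))
  names(host_lineage) <- host_ids

  # viral tree with heritable host-lineage preference and family labels
  tree <- ape::rtree(p$n_viruses, tip.label = virus_ids)
  tree <- label_tree_nodes(tree)
  pref <- inherit_labels(tree, lineages, p$clade_host_fidelity)
  fams <- c("Mimiviridae", "Phycodnaviridae", "Iridoviridae",
            "Marseilleviridae", "Asfarviridae", "Poxviridae")
  family_of <- inherit_labels(tree, fams, 0.97)

  # planted couplings: infectivity is a clade trait, so coupled viruses are
  # drawn as whole clades (plus random singletons to hit the quota exactly);
  # each coupled virus picks a host from its preferred lineage
  n_coupled <- round(p$frac_coupled * p$n_viruses)
  coupled <- sort(select_coupled_clades(tree, n_coupled))
  planted <- purrr::map_dfr(coupled, function(v) {
    cands <- host_ids[host_lineage == pref[[v]]]
    if (!length(cands)) cands <- host_ids
    tibble::tibble(virus_otu = v, host_otu = sample(cands, 1))
  })
  planted$host_lineage <- unname(host_lineage[planted$host_otu])

  # abundances
  rho_g <- copula_latent_rho(p$coupling_strength)
  z_host <- matrix(stats::rnorm(p$n_hosts * p$n_samples), p$n_hosts,
                   dimnames = list(host_ids, samples))
  mask_host <- matrix(stats::runif(p$n_hosts * p$n_samples) < p$occupancy,
                      p$n_hosts, dimnames = list(host_ids, samples))
  to_counts <- function(z, mask) {
    out <- round(exp(p$log_mean + p$log_sd * z))
    out[!mask] <- 0
    out
  }
  host_counts <- to_counts(z_host, mask_host)
  z_virus <- matrix(stats::rnorm(p$n_viruses * p$n_samples), p$n_viruses,
                    dimnames = list(virus_ids, samples))
  mask_virus <- matrix(stats::runif(p$n_viruses * p$n_samples) < p$occupancy,
                       p$n_viruses, dimnames = list(virus_ids, samples))
  for (i in seq_len(nrow(planted))) {
    v <- planted$virus_otu[i]; h <- planted$host_otu[i]
    z_virus[v, ] <- rho_g * z_host[h, ] +
      sqrt(1 - rho_g^2) * stats::rnorm(p$n_samples)
    mask_virus[v, ] <- mask_host[h, ]
  }

  # temperature confounder drives a few otherwise-uncoupled pairs
  temperature <- stats::rnorm(p$n_samples, 15, 5)
  z_temp <- as.vector(scale(temperature))
  free_viruses <- setdiff(virus_ids, coupled)
  free_hosts <- setdiff(host_ids, planted$host_otu)
  n_conf <- min(p$n_confounded, length(free_viruses), length(free_hosts))
  confounded <- tibble::tibble(virus_otu = character(), host_otu = character(),
                               variable = character())
  if (n_conf > 0) {
    cv <- sample(free_viruses, n_conf)
    ch <- sample(free_hosts, n_conf)
    rho_c <- copula_latent_rho(0.9)
    for (i in seq_len(n_conf)) {
      z_virus[cv[i], ] <- rho_c * z_temp + sqrt(1 - rho_c^2) * stats::rnorm(p$n_samples)
      z_host[ch[i], ] <- rho_c * z_temp + sqrt(1 - rho_c^2) * stats::rnorm(p$n_samples)
      mask_virus[cv[i], ] <- TRUE
      mask_host[ch[i], ] <- TRUE
    }
    host_counts <- to_counts(z_host, mask_host)
    confounded <- tibble::tibble(virus_otu = cv, host_otu = ch,
                                 variable = "temperature")
  }
  virus_counts <- to_counts(z_virus, mask_virus)

  as_abund <- function(counts, marker, fraction) {
    abundance_table(
      tibble::add_column(tibble::as_tibble(counts), otu_id = rownames(counts),
                         .before = 1),
      marker = marker, size_fraction = fraction, unit = "counts")
  }
  polb <- as_abund(virus_counts, "polB", "pico")
  v9 <- as_abund(host_counts, "V9", "0.8-5")

  taxonomy <- dplyr::bind_rows(
    tibble::tibble(otu_id = host_ids, major_lineage = unname(host_lineage)),
    tibble::tibble(otu_id = virus_ids, major_lineage = NA_character_,
                   viral_family = unname(family_of[virus_ids]))) |>
    taxonomy_table()

  ref_ids <- paste0("ref_", lineages)
  reference <- tibble::tibble(
    reference_virus_id = ref_ids,
    viral_family = sample(fams, p$n_lineages, replace = TRUE),
    host_major_lineage = lineages)

  # hit table: true hits for coupled viruses, decoys for everyone
  runif_range <- function(n, r) stats::runif(n, r[1], r[2])
  true_hits <- tibble::tibble(
    query_id = coupled,
    subject_id = paste0("ref_", host_lineage[planted$host_otu[match(coupled, planted$virus_otu)]]),
    percent_identity = runif_range(n_coupled, p$identity_true),
    percent_query_coverage = runif_range(n_coupled, c(80, 100)),
    e_value = 10^stats::runif(n_coupled, -120, -60),
    bitscore = stats::runif(n_coupled, 200, 400))
  n_decoy <- p$n_viruses
  decoy_hits <- tibble::tibble(
    query_id = virus_ids,
    subject_id = sample(ref_ids, n_decoy, replace = TRUE),
    percent_identity = runif_range(n_decoy, p$identity_decoy),
    percent_query_coverage = runif_range(n_decoy, c(40, 90)),
    e_value = 10^stats::runif(n_decoy, -30, -5),
    bitscore = stats::runif(n_decoy, 50, 120))
  hits <- validate_hits(dplyr::bind_rows(true_hits, decoy_hits))

  metavars <- tibble::tibble(
    sample_id = samples,
    temperature = temperature,
    salinity = stats::rnorm(p$n_samples, 35, 1),
    nitrate = stats::rlnorm(p$n_samples, 0.5, 0.6),
    phosphate = stats::rlnorm(p$n_samples, -1, 0.5),
    silicate = stats::rlnorm(p$n_samples, 0.8, 0.7))

  truth <- list(
    planted = planted,
    confounded = confounded,
    families = tibble::tibble(otu_id = virus_ids,
                              viral_family = unname(family_of[virus_ids])),
    lineages = lineages,
    preferred_lineage = tibble::tibble(virus_otu = virus_ids,
                                       lineage = unname(pref[virus_ids])),
    reference_assignment = tibble::tibble(
      otu_id = true_hits$query_id,
      reference_virus_id = true_hits$subject_id))

  list(polb = polb, v9 = v9, taxonomy = taxonomy, reference = reference,
       hits = hits, tree = tree, metavars = metavars, truth = truth,
       params = params)
}

# Draw coupled leaves as disjoint clades (size 3..15) until the quota is
# reached, topping up with random singleton leaves. Gives exactly `quota`
# coupled leaves with phylogenetically clustered membership.
select_coupled_clades <- function(tree, quota) {
  stopifnot(quota >= 1, quota <= length(tree$tip.label))
  sets <- node_leaf_sets(tree)
  sizes <- lengths(sets)
  coupled <- character(0)
  repeat {
    remaining <- quota - length(coupled)
    if (remaining < 3) break
    ok <- vapply(sets, function(s)
      length(s) >= 3 && length(s) <= min(15, remaining) &&
        !any(s %in% coupled), logical(1))
    if (!any(ok)) break
    pick <- sample(names(sets)[ok], 1)
    coupled <- c(coupled, sets[[pick]])
  }
  remaining <- quota - length(coupled)
  if (remaining > 0) {
    coupled <- c(coupled, sample(setdiff(tree$tip.label, coupled), remaining))
  }
  coupled
}

# Per-edge probability of keeping the parent's trait: fidelity is the
# retention probability per average-length branch (switching is a Poisson
# process along the branches, so longer branches switch more often),
# falling back to flat per-edge retention on trees without branch lengths.
edge_keep_prob <- function(tree, fidelity) {
  if (is.null(tree$edge.length)) return(rep(fidelity, nrow(tree$edge)))
  len <- tree$edge.length / mean(tree$edge.length)
  fidelity^len
}

# Root-to-tip label inheritance: each node keeps its parent's label with
# the edge's retention probability, otherwise switches to a uniformly
# drawn other label. Returns labels for tips (named by tip label).
inherit_labels <- function(tree, labels, fidelity) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  keep_p <- edge_keep_prob(tree, fidelity)
  lab <- character(n_tip + tree$Nnode)
  lab[root] <- sample(labels, 1)
  ord <- preorder_edges(tree)  # parents always precede their children
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    keep <- stats::runif(1) < keep_p[e]
    lab[child] <- if (keep || length(labels) == 1L) lab[parent] else
      sample(setdiff(labels, lab[parent]), 1)
  }
  stats::setNames(lab[seq_len(n_tip)], tree$tip.label)
}

# Heritable binary trait: each node keeps its parent's state with the
# edge's retention probability, otherwise redraws it as Bernoulli(freq);
# the stationary frequency is exactly `freq`. Named logical over tips.
inherit_binary <- function(tree, freq, fidelity) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  keep_p <- edge_keep_prob(tree, fidelity)
  state <- logical(n_tip + tree$Nnode)
  state[root] <- stats::runif(1) < freq
  for (e in preorder_edges(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    state[child] <- if (stats::runif(1) < keep_p[e]) state[parent] else
      stats::runif(1) < freq
  }
  stats::setNames(state[seq_len(n_tip)], tree$tip.label)
}

# edge indices in root-first (preorder) order
preorder_edges <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children_edges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    es <- children_edges[[as.character(node)]]
    for (e in rev(es)) {
      out <- c(out, e)
      stack <- c(stack, tree$edge[e, 2])
    }
  }
  out
}

#' Confusion matrix of predictions against the planted truth
#'
#' Uses the planted (virus, host lineage) pairs of a synthetic data set
#' as the condition positives and delegates to [confusion_matrix()]; the
#' assigned-OTU set is the set of viruses with a planted host.
#'
#' @param reduced Reduced edge tibble ([reduce_best_edges()]).
#' @param truth The `truth` element of [synth_generate()] output.
#' @param universe_lineages Candidate lineages (default: all generated
#'   lineages).
#' @param sign,weight_cutoff Passed to [confusion_matrix()].
#' @return A `vh_confusion` object.
#' @export
truth_confusion <- function(reduced, truth,
                            universe_lineages = truth$lineages,
                            sign = "positive", weight_cutoff = 0) {
  positives <- tibble::tibble(otu_id = truth$planted$virus_otu,
                              major_lineage = truth$planted$host_lineage)
  confusion_matrix(reduced, positives, universe_lineages, sign = sign,
                   weight_cutoff = weight_cutoff,
                   assigned_otus = unique(truth$planted$virus_otu))
}
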