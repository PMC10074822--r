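#' Parameters for the synthetic community generator
#'
#' Describes a multi-group amplicon study: a shared baseline composition
#' drawn from a symmetric Dirichlet, optional group-specific dominance
#' effects (a designated ASV reallocated to a target relative abundance,
#' emulating e.g. a fermented-feed diet dominated by a single lactic acid
#' bacterium at ~0.9), log-normal library sizes spanning roughly
#' 1.6k-180k reads, and taxonomy with stochastically missing lower ranks.
#'
#' @param n_groups number of diet groups
#' @param samples_per_group samples per group (>= 2)
#' @param n_asvs number of ASVs (>= 10)
#' @param base_concentration symmetric Dirichlet concentration of the shared
#'   baseline composition; small values give realistically uneven communities
#' @param dominance_effects list of `list(group=, asv=, target=)` entries;
#'   within a group the targets must sum to < 1
#' @param library_size_log_mean,library_size_log_sd log-normal read depth
#'   model (defaults give median ~22k, range ~1.6k-180k)
#' @param missing_rank_prob probability an ASV's lineage is truncated at
#'   genus or family level
#' @param species_prob probability a non-truncated ASV carries a species name
#' @param theta Dirichlet concentration of the per-sample perturbation
#'   around the group composition (larger = less compositional noise)
#' @param seed master integer seed; all stages derive sub-seeds from it
#' @return a `community_sim_params` list
#' @export
community_sim_params <- function(n_groups = 2, samples_per_group = 9,
                                 n_asvs = 60, base_concentration = 0.5,
                                 dominance_effects = list(),
                                 library_size_log_mean = 10,
                                 library_size_log_sd = 1,
                                 missing_rank_prob = 0.25,
                                 species_prob = 0.15,
                                 theta = 200, seed = 1) {
  stopifnot(n_groups >= 1, samples_per_group >= 2, n_asvs >= 10,
            base_concentration > 0, theta > 0,
            missing_rank_prob >= 0, missing_rank_prob <= 1,
            species_prob >= 0, species_prob <= 1)
  for (eff in dominance_effects) {
    stopifnot(is.list(eff), !is.null(eff$group), !is.null(eff$asv),
              is.numeric(eff$target))
    if (eff$target < 0 || eff$target >= 1)
      stop("dominance target must lie in [0, 1)")
  }
  grp <- vapply(dominance_effects, function(e) as.character(e$group), "")
  for (g in unique(grp)) {
    tot <- sum(vapply(dominance_effects[grp == g],
                      function(e) e$target, 0))
    if (tot >= 1)
      stop(sprintf("dominance targets in group '%s' sum to %.3f (>= 1)", g, tot))
  }
  structure(list(n_groups = n_groups, samples_per_group = samples_per_group,
                 n_asvs = n_asvs, base_concentration = base_concentration,
                 dominance_effects = dominance_effects,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 missing_rank_prob = missing_rank_prob,
                 species_prob = species_prob,
                 theta = theta, seed = seed),
            class = "community_sim_params")
}

#' Simulate a multi-group amplicon study
#'
#' Counts are drawn per sample as Multinomial(library size, p_s) where p_s
#' is a Dirichlet perturbation (concentration `theta * p_g`) of the group
#' composition p_g. Group compositions come from a single shared baseline
#' with dominance effects applied as deterministic mass reallocation, so
#' planted effect sizes are exact in expectation. Taxonomy is generated to
#' be consistent with the phylogeny at genus level: the tree is built by
#' random binary merging within each genus first, then across genera, with
#' exponential branch lengths.
#'
#' @param params a [community_sim_params()] object
#' @return list with `counts` (samples x ASVs integer matrix), `taxonomy`
#'   (data.frame with the 7 rank columns, "" = unassigned), `tree`
#'   (rooted bifurcating `phylo` over the ASVs), `metadata` (data.frame
#'   with `group`, `sample_type`, `tank`, `run`), and `library_sizes`
#' @export
simulate_community <- function(params) {
  stopifnot(inherits(params, "community_sim_params"))
  p <- params
  asv_ids <- sprintf("ASV%03d", seq_len(p$n_asvs))
  groups <- sprintf("G%d", seq_len(p$n_groups))

  taxonomy <- .sim_taxonomy(asv_ids, p)
  tree <- .sim_tree(asv_ids, taxonomy$genus,
                    derive_seed(p$seed, "tree"))

  # shared baseline composition
  set.seed(derive_seed(p$seed, "baseline"))
  p0 <- as.numeric(rdirichlet(1, rep(p$base_concentration, p$n_asvs)))

  # group compositions: deterministic reallocation toward dominance targets
  comp <- matrix(rep(p0, p$n_groups), nrow = p$n_groups, byrow = TRUE,
                 dimnames = list(groups, asv_ids))
  for (g in groups) {
    eff <- Filter(function(e) as.character(e$group) == g, p$dominance_effects)
    if (!length(eff)) next
    tgt_asv <- vapply(eff, function(e) as.character(e$asv), "")
    if (!all(tgt_asv %in% asv_ids)) stop("dominance effect names unknown ASV")
    tgt <- vapply(eff, function(e) e$target, 0)
    others <- setdiff(asv_ids, tgt_asv)
    comp[g, tgt_asv] <- tgt
    comp[g, others] <- p0[match(others, asv_ids)] *
      (1 - sum(tgt)) / sum(p0[match(others, asv_ids)])
  }

  n_samples <- p$n_groups * p$samples_per_group
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  group_of <- rep(groups, each = p$samples_per_group)

  set.seed(derive_seed(p$seed, "depths"))
  depths <- pmax(50L, as.integer(round(stats::rlnorm(
    n_samples, p$library_size_log_mean, p$library_size_log_sd))))

  set.seed(derive_seed(p$seed, "counts"))
  counts <- matrix(0L, n_samples, p$n_asvs,
                   dimnames = list(sample_ids, asv_ids))
  for (s in seq_len(n_samples)) {
    alpha <- p$theta * comp[group_of[s], ]
    # Dirichlet components with alpha = 0 stay exactly 0
    ps <- numeric(p$n_asvs)
    pos <- alpha > 0
    ps[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
    ps <- ps / sum(ps)
    counts[s, ] <- as.integer(stats::rmultinom(1, depths[s], ps))
  }

  metadata <- data.frame(
    group = group_of,
    sample_type = "digesta",
    tank = sprintf("T%02d", as.integer(ceiling(seq_len(n_samples) / 3))),
    run = rep_len(c("run1", "run2"), n_samples),
    row.names = sample_ids, stringsAsFactors = FALSE)

  list(counts = counts, taxonomy = taxonomy, tree = tree,
       metadata = metadata, library_sizes = stats::setNames(depths, sample_ids))
}

# taxonomy over 7 ranks, genus-nested hierarchy, top-down truncation
.sim_taxonomy <- function(asv_ids, p) {
  set.seed(derive_seed(p$seed, "taxonomy"))
  n <- length(asv_ids)
  n_genera <- max(2L, ceiling(n / 4))
  genus_of <- sort(rep_len(seq_len(n_genera), n))
  fam_of_genus <- ceiling(seq_len(n_genera) / 2)
  ord_of_fam <- ceiling(seq_len(max(fam_of_genus)) / 2)
  cls_of_ord <- ceiling(seq_len(max(ord_of_fam)) / 2)
  phy_of_cls <- rep_len(1:4, max(cls_of_ord))
  phyla <- c("Firmicutes", "Proteobacteria", "Actinobacteriota",
             "Bacteroidota")
  g <- genus_of
  f <- fam_of_genus[g]
  o <- ord_of_fam[f]
  cl <- cls_of_ord[o]
  tax <- data.frame(
    domain = "Bacteria",
    phylum = phyla[phy_of_cls[cl]],
    class = sprintf("Class_%02d", cl),
    order = sprintf("Order_%02d", o),
    family = sprintf("Family_%02d", f),
    genus = sprintf("Genus_%02d", g),
    species = ifelse(stats::runif(n) < p$species_prob,
                     sprintf("Species_%s", asv_ids), ""),
    row.names = asv_ids, stringsAsFactors = FALSE)
  # lineage truncation: drop species+genus (at family) or species (at genus)
  trunc <- stats::runif(n) < p$missing_rank_prob
  at_family <- trunc & (stats::runif(n) < 0.5)
  tax$species[trunc] <- ""
  tax$genus[at_family] <- ""
  tax
}

# random rooted bifurcating tree, genus-consistent, exponential branch lengths
.sim_tree <- function(asv_ids, genus, seed) {
  set.seed(seed)
  blen <- function() round(stats::rexp(1, rate = 10) + 0.01, 4)
  merge_nodes <- function(nodes) {
    while (length(nodes) > 1L) {
      i <- sample.int(length(nodes), 2L)
      joined <- sprintf("(%s,%s):%g", nodes[[i[1L]]], nodes[[i[2L]]], blen())
      nodes <- c(nodes[-i], joined)
    }
    nodes[[1L]]
  }
  tips <- sprintf("%s:%g", asv_ids,
                  vapply(asv_ids, function(x) blen(), 0))
  clades <- vapply(split(tips, genus), merge_nodes, "")
  nwk <- if (length(clades) == 1L) clades[[1L]] else merge_nodes(clades)
  # strip the root edge length; ape wants "(...);"
  nwk <- sub(":[0-9.]+$", "", nwk)
  if (!startsWith(nwk, "(")) nwk <- sprintf("(%s);", nwk) else
    nwk <- paste0(nwk, ";")
  ape::read.tree(text = nwk)
}

#' Parameters for the synthetic GSMM collection generator
#'
#' Emulates a collection of genome-scale metabolic models keyed by taxon:
#' every model carries a core reaction set shared by all models, plus
#' Bernoulli-sampled accessory reactions; models of one designated taxon
#' include the reactions of a designated "signature" subsystem with an
#' elevated probability, planting a recoverable functional signal.
#'
#' @param n_models_per_taxon models generated per mapped taxon
#' @param n_reactions total distinct reactions
#' @param n_subsystems number of subsystems; reactions are assigned
#'   round-robin so every reaction belongs to exactly one subsystem
#' @param core_reaction_frac fraction of reactions present in every model
#' @param accessory_prob baseline inclusion probability of a non-core
#'   reaction in a model
#' @param taxon_signature_strength added inclusion probability (capped at 1)
#'   of signature-subsystem reactions in the signature taxon's models
#' @param signature_taxon taxon receiving the planted signature; default:
#'   first element of `taxa` at simulation time
#' @param signature_subsystem subsystem name carrying the signature
#' @param unmapped_taxon_frac fraction of taxa (taken from the end of the
#'   taxa list) that receive no models at all
#' @param seed integer seed
#' @return a `gsmm_sim_params` list
#' @export
gsmm_sim_params <- function(n_models_per_taxon = 10, n_reactions = 200,
                            n_subsystems = 10, core_reaction_frac = 0.3,
                            accessory_prob = 0.3,
                            taxon_signature_strength = 0,
                            signature_taxon = NULL,
                            signature_subsystem = "SS01",
                            unmapped_taxon_frac = 0, seed = 1) {
  stopifnot(n_models_per_taxon >= 1, n_reactions >= 1,
            n_subsystems >= 1, n_subsystems <= n_reactions,
            core_reaction_frac >= 0, core_reaction_frac <= 1,
            accessory_prob >= 0, accessory_prob <= 1,
            taxon_signature_strength >= 0, taxon_signature_strength <= 1,
            unmapped_taxon_frac >= 0, unmapped_taxon_frac < 1)
  structure(list(n_models_per_taxon = n_models_per_taxon,
                 n_reactions = n_reactions, n_subsystems = n_subsystems,
                 core_reaction_frac = core_reaction_frac,
                 accessory_prob = accessory_prob,
                 taxon_signature_strength = taxon_signature_strength,
                 signature_taxon = signature_taxon,
                 signature_subsystem = signature_subsystem,
                 unmapped_taxon_frac = unmapped_taxon_frac, seed = seed),
            class = "gsmm_sim_params")
}

#' Simulate a GSMM collection over a set of taxa
#'
#' @param params a [gsmm_sim_params()] object
#' @param taxa character vector of taxon names; models are labelled at the
#'   given `rank`
#' @param rank taxonomic rank of the model labels (default "genus")
#' @return a `gsmm_collection` (see [read_gsmms()] for the structure)
#' @export
simulate_gsmm_collection <- function(params, taxa, rank = "genus") {
  stopifnot(inherits(params, "gsmm_sim_params"), length(taxa) >= 1)
  taxa <- unique(as.character(taxa))
  p <- params
  sig_taxon <- p$signature_taxon %||% taxa[[1L]]

  rxn_ids <- sprintf("R%04d", seq_len(p$n_reactions))
  subsys_names <- sprintf("SS%02d", seq_len(p$n_subsystems))
  subsystems <- stats::setNames(
    subsys_names[((seq_len(p$n_reactions) - 1L) %% p$n_subsystems) + 1L],
    rxn_ids)
  if (!p$signature_subsystem %in% subsys_names)
    stop("signature_subsystem not among generated subsystems")

  n_core <- round(p$core_reaction_frac * p$n_reactions)
  core <- rxn_ids[seq_len(n_core)]
  accessory <- setdiff(rxn_ids, core)
  sig_rxns <- accessory[subsystems[accessory] == p$signature_subsystem]

  n_unmapped <- floor(p$unmapped_taxon_frac * length(taxa))
  mapped <- if (n_unmapped > 0)
    taxa[seq_len(length(taxa) - n_unmapped)] else taxa

  set.seed(derive_seed(p$seed, "gsmm"))
  models <- list()
  for (tx in mapped) {
    pr <- rep(p$accessory_prob, length(accessory))
    if (tx == sig_taxon && length(sig_rxns))
      pr[accessory %in% sig_rxns] <-
        pmin(1, p$accessory_prob + p$taxon_signature_strength)
    for (k in seq_len(p$n_models_per_taxon)) {
      keep <- accessory[stats::runif(length(accessory)) < pr]
      rxns <- c(core, keep)
      if (!length(rxns)) rxns <- rxn_ids[1L]  # model reaction sets non-empty
      models[[sprintf("%s_m%02d", tx, k)]] <-
        list(rank = rank, taxon = tx, reactions = rxns)
    }
  }
  new_gsmm_collection(models, subsystems)
}

#' Simulate an observed mock-community profile
#'
#' Applies multiplicative log-normal noise to an expected composition and
#' renormalizes, emulating the observed taxonomic profile of a sequenced
#' microbial community standard.
#'
#' @param expected_profile named numeric composition summing to 1
#' @param noise_sd standard deviation of the log-scale noise (>= 0)
#' @param seed integer seed
#' @return named numeric observed composition summing to 1
#' @export
simulate_mock <- function(expected_profile, noise_sd, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (abs(sum(expected_profile) - 1) > 1e-8)
    stop("expected_profile must sum to 1")
  set.seed(derive_seed(seed, "mock"))
  obs <- expected_profile * exp(stats::rnorm(length(expected_profile),
                                             0, noise_sd))
  obs / sum(obs)
}
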