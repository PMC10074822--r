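# One full pipeline run with (optionally) planted effects: simulate a
# 2-diet study, filter, map to a simulated GSMM collection, compute a_r,
# test reactions for the diet pair and run subsystem enrichment.
# Returns the enrichment table plus the planted (subsystem, diet) truth.
run_planted_pipeline <- function(seed, dominance = 0.9, strength = 0.9,
                                 samples_per_group = 9) {
  effects <- if (dominance > 0)
    list(list(group = "G2", asv = "ASV001", target = dominance)) else list()
  sim <- simulate_community(community_sim_params(
    n_groups = 2, samples_per_group = samples_per_group, n_asvs = 60,
    dominance_effects = effects, seed = seed))
  sig_genus <- sim$taxonomy["ASV001", "genus"]
  if (sig_genus == "") sig_genus <- "Genus_01"
  taxa <- sort(unique(sim$taxonomy$genus[sim$taxonomy$genus != ""]))
  coll <- simulate_gsmm_collection(
    gsmm_sim_params(n_models_per_taxon = 10, n_reactions = 200,
                    n_subsystems = 10, core_reaction_frac = 0.3,
                    taxon_signature_strength = strength,
                    signature_taxon = sig_genus,
                    signature_subsystem = "SS01",
                    unmapped_taxon_frac = 0.1,
                    seed = derive_seed(seed, "gsmm-pipe")),
    taxa)
  fl <- filter_asvs(sim$counts, sim$taxonomy)
  mp <- map_asvs(sim$taxonomy[colnames(fl$counts), , drop = FALSE], coll)
  E <- reaction_probabilities(mp, coll)
  ram <- reaction_abundance(fl$counts, E)$abundance
  grp <- sim$metadata[rownames(ram), "group"]
  diff <- differential_reactions(ram, grp, c("G1", "G2"))
  enr <- subsystem_enrichment(diff, coll$subsystems)
  list(enrichment = enr, planted_subsystem = "SS01", planted_diet = "G2")
}
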