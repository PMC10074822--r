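test_that("ASV-model mapping picks the lowest assigned rank with a model", {
  tax <- toy_taxonomy(
    c("a_sp", "a_gen", "a_fam", "a_ord", "a_nomod"),
    a_sp  = list(family = "Lactobacillaceae", genus = "Pediococcus",
                 species = "Pediococcus acidilactici"),
    a_gen = list(family = "Lactobacillaceae", genus = "Pediococcus"),
    a_fam = list(family = "Lactobacillaceae"),
    a_ord = list(),                              # order level only
    a_nomod = list(family = "Enterococcaceae", genus = "Enterococcus"))
  mp <- map_asvs(tax, toy_collection())
  m <- mp$mapping
  expect_equal(m$rank[m$asv_id == "a_sp"], "species")
  expect_equal(m$n_models[m$asv_id == "a_sp"], 1L)
  expect_equal(m$rank[m$asv_id == "a_gen"], "genus")
  expect_equal(m$n_models[m$asv_id == "a_gen"], 4L)
  expect_equal(m$rank[m$asv_id == "a_fam"], "family")
  un <- setNames(mp$unmapped$reason, mp$unmapped$asv_id)
  expect_equal(un[["a_ord"]], "rank above family")
  expect_equal(un[["a_nomod"]], "no model for taxon")
  # summary arithmetic: per-rank counts add up to total mapped
  expect_equal(sum(mp$summary$per_rank), mp$summary$n_mapped)
  expect_equal(mp$summary$n_mapped, 3L)
  expect_equal(mp$summary$mean_models, mean(c(1, 4, 1)))
})

test_that("an ASV with a genus name but a species-only model falls through", {
  # species rank assigned but unmatched: genus is tried next
  tax <- toy_taxonomy("a1", a1 = list(family = "Lactobacillaceae",
                                      genus = "Pediococcus",
                                      species = "Pediococcus unknownii"))
  mp <- map_asvs(tax, toy_collection())
  expect_equal(mp$mapping$rank, "genus")
})

test_that("reaction probabilities are model-set frequencies", {
  tax <- toy_taxonomy("a1", a1 = list(family = "Lactobacillaceae",
                                      genus = "Pediococcus"))
  mp <- map_asvs(tax, toy_collection())
  E <- reaction_probabilities(mp, toy_collection())
  # Pediococcus genus models: gA1..gA4
  expect_equal(E["a1", "R1"], 1)      # in 4 of 4
  expect_equal(E["a1", "R3"], 0.75)   # in 3 of 4
  expect_equal(E["a1", "R2"], 0.5)
  expect_equal(E["a1", "R5"], 0)
  # row sum over reactions = mean model size (brute force on the toy set)
  sizes <- lengths(lapply(toy_collection()$models[c("gA1", "gA2",
                                                    "gA3", "gA4")],
                          `[[`, "reactions"))
  expect_equal(sum(E["a1", ]), mean(sizes))
  # single-model ASV: E is 0/1
  tax2 <- toy_taxonomy("a2", a2 = list(family = "Lactobacillaceae"))
  E2 <- reaction_probabilities(map_asvs(tax2, toy_collection()),
                               toy_collection())
  expect_true(all(E2 %in% c(0, 1)))
})

test_that("reaction abundance: worked example and invariances", {
  E <- rbind(a1 = c(R = 0.5), a2 = c(R = 1))
  counts <- matrix(c(30L, 10L), 1, 2, dimnames = list("S1", c("a1", "a2")))
  ram <- reaction_abundance(counts, E)
  expect_equal(ram$abundance["S1", "R"], (30 * 0.5 + 10 * 1) / 40)
  # doubling counts leaves a_r unchanged
  ram2 <- reaction_abundance(counts * 2L, E)
  expect_equal(ram2$abundance, ram$abundance)
  # unmapped ASVs excluded from numerator and denominator by default
  counts3 <- cbind(counts, unmapped = 1000L)
  expect_equal(reaction_abundance(counts3, E)$abundance["S1", "R"], 0.625)
  # literal all-ASV denominator available for sensitivity analysis
  expect_equal(reaction_abundance(counts3, E, denominator = "all")
               $abundance["S1", "R"], 25 / 1040)
  expect_error(reaction_abundance(
    matrix(0L, 1, 2, dimnames = list("S1", c("a1", "a2"))), E),
    "zero mapped")
})

test_that("a_r equals the brute-force double loop on random instances", {
  set.seed(61)
  for (trial in 1:25) {
    n_asv <- sample(2:6, 1); n_rxn <- sample(2:8, 1)
    n_s <- sample(2:4, 1)
    E <- matrix(round(runif(n_asv * n_rxn), 3), n_asv, n_rxn,
                dimnames = list(sprintf("a%d", 1:n_asv),
                                sprintf("R%d", 1:n_rxn)))
    counts <- matrix(rpois(n_s * n_asv, 20) + 1L, n_s, n_asv,
                     dimnames = list(sprintf("S%d", 1:n_s), rownames(E)))
    expect_equal(reaction_abundance(counts, E)$abundance,
                 oracle_reaction_abundance(counts, E), tolerance = 1e-12)
  }
})

test_that("if every model carries a reaction, a_r is 1 everywhere", {
  coll <- toy_collection()   # R1 is in every model
  tax <- toy_taxonomy(c("a1", "a2"),
                      a1 = list(family = "Lactobacillaceae",
                                genus = "Pediococcus"),
                      a2 = list(family = "Lactobacillaceae"))
  mp <- map_asvs(tax, coll)
  E <- reaction_probabilities(mp, coll)
  counts <- matrix(c(5L, 9L, 2L, 14L), 2, 2,
                   dimnames = list(c("S1", "S2"), c("a1", "a2")))
  ram <- reaction_abundance(counts, E)$abundance
  expect_equal(unname(ram[, "R1"]), c(1, 1))
  # and a_r is bounded by the contributing E range per reaction
  for (r in colnames(ram)) {
    expect_gte(min(ram[, r]), min(E[, r]) - 1e-12)
    expect_lte(max(ram[, r]), max(E[, r]) + 1e-12)
  }
})

test_that("differential reactions: nulls, significance rule, power", {
  ram <- matrix(0.5, 8, 3,
                dimnames = list(sprintf("S%d", 1:8), c("R1", "R2", "R3")))
  ram[, "R2"] <- rep(c(0.2, 0.8), 4)   # variance but identical group means
  grp <- rep(c("FM", "SBM"), each = 4)
  res <- differential_reactions(ram, grp, c("FM", "SBM"))
  expect_equal(attr(res, "skipped"), c("R1", "R3"))
  expect_equal(res$statistic[res$reaction == "R2"], 0)
  expect_false(any(res$significant))
  expect_identical(res$significant, res$p_adj <= 0.05)
  # power: planted +0.3 shift, n = 9 vs 9, sd 0.05, 50 of 200 reactions
  hit_rate <- numeric(20)
  set.seed(92)
  for (k in seq_along(hit_rate)) {
    m <- matrix(rnorm(18 * 200, 0.4, 0.05), 18, 200,
                dimnames = list(sprintf("S%d", 1:18),
                                sprintf("R%03d", 1:200)))
    m[1:9, 1:50] <- m[1:9, 1:50] + 0.3
    d <- differential_reactions(m, rep(c("hi", "lo"), each = 9),
                                c("hi", "lo"))
    hit_rate[k] <- mean(d$significant[match(sprintf("R%03d", 1:50),
                                            d$reaction)])
  }
  expect_gte(mean(hit_rate >= 0.9), 0.9)
  expect_error(differential_reactions(ram, grp, c("FM", "none")),
               "at least 2 samples")
})

test_that("Welch flag changes the degrees of freedom, not the contract", {
  set.seed(14)
  m <- matrix(rnorm(12 * 5, 0.5, 0.1), 12, 5,
              dimnames = list(sprintf("S%d", 1:12), sprintf("R%d", 1:5)))
  grp <- rep(c("a", "b"), each = 6)
  student <- differential_reactions(m, grp, c("a", "b"))
  welch <- differential_reactions(m, grp, c("a", "b"), welch = TRUE)
  ref <- t.test(m[1:6, 1], m[7:12, 1])
  expect_equal(welch$statistic[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(welch$p[1], ref$p.value, tolerance = 1e-12)
  ref_s <- t.test(m[1:6, 1], m[7:12, 1], var.equal = TRUE)
  expect_equal(student$p[1], ref_s$p.value, tolerance = 1e-12)
})

test_that("one-sided Fisher equals the choose-product oracle", {
  expect_equal(fisher_exact_greater(3, 7, 10, 80),
               oracle_fisher_greater(3, 7, 10, 80), tolerance = 1e-14)
  expect_equal(fisher_exact_greater(3, 7, 10, 80),
               fisher.test(matrix(c(3, 10, 7, 80), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  set.seed(71)
  for (trial in 1:100) {
    cells <- rmultinom(1, sample(4:30, 1), rep(0.25, 4))
    expect_equal(fisher_exact_greater(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_greater(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("subsystem enrichment: null case, planted case, universe", {
  subsystems <- setNames(rep(c("mucin", "other"), c(10, 90)),
                         sprintf("R%03d", 1:100))
  # no significant reactions: every Fisher p is 1
  ram <- matrix(rnorm(8 * 100, 0.5, 0.05), 8, 100,
                dimnames = list(sprintf("S%d", 1:8), names(subsystems)))
  d0 <- differential_reactions(ram, rep(c("a", "b"), each = 4), c("a", "b"))
  if (!any(d0$significant)) {
    e0 <- subsystem_enrichment(d0, subsystems)
    expect_true(all(e0$p == 1))
    expect_false(any(e0$enriched))
  }
  # planted: mucin reactions shifted up in diet "a"
  ram[1:4, 1:10] <- ram[1:4, 1:10] + 0.4
  d1 <- differential_reactions(ram, rep(c("a", "b"), each = 4), c("a", "b"))
  e1 <- subsystem_enrichment(d1, subsystems)
  hit <- e1[e1$subsystem == "mucin" & e1$direction == "a", ]
  expect_true(hit$enriched)
  expect_equal(hit$a + hit$b + hit$c + hit$d, nrow(d1))
  expect_identical(e1$enriched, e1$p_adj <= 0.05)
  expect_error(subsystem_enrichment(d1, subsystems[-1]), "absent")
})

test_that("capacity report signs cells by the pair's first diet", {
  subsystems <- setNames(rep(c("mucin", "other"), c(10, 90)),
                         sprintf("R%03d", 1:100))
  set.seed(33)
  ram <- matrix(rnorm(8 * 100, 0.5, 0.05), 8, 100,
                dimnames = list(sprintf("S%d", 1:8), names(subsystems)))
  ram[1:4, 1:10] <- ram[1:4, 1:10] + 0.4
  grp <- rep(c("a", "b"), each = 4)
  e_ab <- subsystem_enrichment(
    differential_reactions(ram, grp, c("a", "b")), subsystems)
  e_ba <- subsystem_enrichment(
    differential_reactions(ram, grp, c("b", "a")), subsystems)
  rep1 <- capacity_report(list(a_vs_b = e_ab))
  rep2 <- capacity_report(list(b_vs_a = e_ba))
  expect_equal(rep1$signed["a_vs_b", "mucin"], 1)
  # relabelling the pair flips the sign
  expect_equal(rep2$signed["b_vs_a", "mucin"], -1)
  expect_equal(nrow(rep1$long), nrow(e_ab))
})
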