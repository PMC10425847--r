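test_that("simulation is reproducible and respects its planted structure", {
  cfg <- tiny_sim_config(13)
  s1 <- simulate_ciliome(cfg)
  s2 <- simulate_ciliome(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(ape::write.tree(s1$truth$tree), ape::write.tree(s2$truth$tree))
  expect_identical(s1$annotations, s2$annotations)

  # at zero noise the ciliary module is absent exactly where cilia are lost
  cil <- s1$annotations$is_ciliated
  mod_rows <- names(s1$truth$modules)
  expect_true(all(s1$matrix[mod_rows, cil] == 1L))
  expect_true(all(s1$matrix[mod_rows, !cil] == 0L))

  # prokaryotes are never ciliated
  expect_true(all(!s1$annotations$is_ciliated[
    s1$annotations$major_group == "prokaryote"]))
})

test_that("parsimony on the simulated trait recovers the planted loss count", {
  for (seed in c(3, 14, 159)) {
    sim <- simulate_ciliome(tiny_sim_config(seed))
    ann <- sim$annotations
    euk <- ann$species_id[ann$major_group != "prokaryote"]
    tr <- drop_species(sim$truth$tree, setdiff(sim$truth$tree$tip.label, euk))
    trait <- setNames(ann$is_ciliated, ann$species_id)
    rep <- count_independent_losses(tr, trait[tr$tip.label])
    expect_equal(rep$total_losses, 3L)
  }
})

test_that("motility-only losses hit ciliated lineages and the motility module", {
  cfg <- tiny_sim_config(
    21,
    modules = data.frame(name = c("core", "mot"), size = c(10L, 8L),
                         lost_with = c("cilia", "motility"),
                         stringsAsFactors = FALSE),
    motility_losses = c(opisthokonta = 1))
  sim <- simulate_ciliome(cfg)
  ann <- sim$annotations
  nonmotile_cil <- ann$is_ciliated & !ann$has_motile_cilia
  expect_gt(sum(nonmotile_cil), 0L)
  mot_rows <- names(sim$truth$modules)[sim$truth$modules == "mot"]
  expect_true(all(sim$matrix[mot_rows, nonmotile_cil] == 0L))
  core_rows <- names(sim$truth$modules)[sim$truth$modules == "core"]
  expect_true(all(sim$matrix[core_rows, nonmotile_cil] == 1L))
})

test_that("a per-group divergence multiplier raises that group's dropout", {
  base <- tiny_sim_config(61, noise = 0.1)
  fast <- tiny_sim_config(61, noise = 0.1,
                          fn_group_multiplier = c(alveolata = 5))
  s_base <- simulate_ciliome(base)
  s_fast <- simulate_ciliome(fast)
  grp <- s_fast$annotations$major_group
  bg <- grepl("^bg_", rownames(s_fast$matrix))
  miss_fast <- mean(s_fast$matrix[bg, grp == "alveolata"] == 0)
  miss_base <- mean(s_base$matrix[bg, grp == "alveolata"] == 0)
  expect_gt(miss_fast, miss_base + 0.1)
  # other groups untouched by the multiplier keep the base rate
  expect_equal(mean(s_fast$matrix[bg, grp == "opisthokonta"] == 0),
               mean(s_base$matrix[bg, grp == "opisthokonta"] == 0),
               tolerance = 0.05)
})

test_that("impossible loss requests are refused", {
  expect_error(
    simulate_ciliome(tiny_sim_config(
      5, groups = c(opisthokonta = 2, alveolata = 2), n_prokaryotes = 0,
      cilium_losses = 6)),
    "more requested losses")
})

test_that("fabricated hit tables round-trip through the reciprocal-best call", {
  for (seed in c(1, 8)) {
    sim <- simulate_ciliome(tiny_sim_config(seed, noise = 0.15))
    tabs <- fabricate_hit_tables(sim$matrix, rng_seed = seed + 1,
                                 decoy_prob = 0.4)
    m <- build_profile_matrix(rownames(sim$matrix), colnames(sim$matrix),
                              tabs$forward, tabs$reverse, tabs$gmap)
    expect_identical(m, sim$matrix)
  }
})

test_that("decoy hits are never admissible as reciprocal pairs", {
  m <- random_binary_matrix(6, 3, p = 0.3)
  tabs <- fabricate_hit_tables(m, decoy_prob = 1, rng_seed = 2)
  thr <- bbh_params()$e_threshold
  for (sp in colnames(m)) {
    fwd <- tabs$forward[[sp]]
    absent <- rownames(m)[m[, sp] == 0L]
    for (g in absent) {
      expect_equal(bbh_present(g, sp, fwd, tabs$reverse[[sp]], tabs$gmap), 0L)
    }
    # inadmissible decoys sit above the threshold
    decoyA <- fwd[fwd$bit_score == 40, ]
    if (nrow(decoyA)) expect_true(all(decoyA$e_value > thr))
  }
})
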