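# Synthetic PROTAC mimics: topology construction, Metropolis sampling,
# simulated NOE data with known ground truth.

test_that("mimic topologies follow the spec and are deterministic", {
  alkyl <- build_protac_mimic(protac_mimic_spec("alkyl", n_linker_atoms = 8))
  region <- attr(alkyl, "region")
  linker_heavy <- alkyl$elements[region == "linker" & alkyl$elements != "H"]
  expect_true(all(linker_heavy == "C"))
  peg <- build_protac_mimic(protac_mimic_spec("peg", n_linker_atoms = 9))
  linker_heavy <- peg$elements[attr(peg, "region") == "linker" &
                                 peg$elements != "H"]
  expect_equal(which(linker_heavy == "O"), c(3L, 6L, 9L))
  # same seed: bit-identical topology; alkyl/peg pair differs only in linker
  again <- build_protac_mimic(protac_mimic_spec("peg", n_linker_atoms = 9))
  expect_identical(attr(peg, "body_coords_a"), attr(again, "body_coords_a"))
  expect_identical(peg$bonds, again$bonds)
  alkyl9 <- build_protac_mimic(protac_mimic_spec("alkyl", n_linker_atoms = 9))
  differs <- which(alkyl9$elements != peg$elements)
  expect_true(all(attr(peg, "region")[differs] == "linker"))
  # each body carries at least two tagged protons
  for (side in c("body_a", "body_b")) {
    tags <- !is.na(peg$proton_labels) & attr(peg, "region") == side
    expect_gte(sum(tags), 2)
  }
  expect_error(protac_mimic_spec("alkyl", n_linker_atoms = 2), ">= 3")
  expect_error(protac_mimic_spec("alkyl", ligand_size = 3), ">= 4")
})

test_that("sampling returns n deterministic conformers with energies", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl", seed = 9))
  e1 <- sample_conformers(top, n = 40, seed = 4)
  expect_equal(n_conformers(e1), 40)
  expect_length(e1$energies, 40)
  e2 <- sample_conformers(top, n = 40, seed = 4)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$energies, e2$energies)
  e3 <- sample_conformers(top, n = 40, seed = 5)
  expect_false(identical(e1$coords, e3$coords))
  # solvent metadata is attached
  expect_equal(e1$solvent$label, "water")
  expect_equal(e1$solvent$epsilon, 80)
})

test_that("alkyl mimic collapses in the polar profile across seeds", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl"))
  wins <- 0L
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    ew <- sample_conformers(top, n = 150, solvent_profile("water"),
                            seed = s)
    ec <- sample_conformers(top, n = 150, solvent_profile("chloroform"),
                            seed = s + 500)
    rg <- function(e) mean(vapply(e$coords, radius_of_gyration, 0.0,
                                  masses = top$masses))
    if (rg(ew) < rg(ec)) wins <- wins + 1L
  }
  expect_gte(wins, n_seeds - 1L)
})

test_that("simulated NOEs: noise-free distances, ceiling, determinism", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl", seed = 2))
  pool <- sample_conformers(top, n = 12, seed = 6)
  w <- rep(1 / 12, 12)
  sim <- simulate_noes(pool, w, n_restraints = 10, noise_sd = 0, seed = 3)
  expect_s3_class(sim$restraints, "noe_table")
  # noise-free experimental distances equal the exact power-mean averages
  expect_equal(sim$restraints$d_exp, sim$truth$d_true, tolerance = 1e-12)
  expect_true(all(sim$truth$d_true <= 5.0))
  sim2 <- simulate_noes(pool, w, n_restraints = 10, noise_sd = 0, seed = 3)
  expect_identical(sim$restraints, sim2$restraints)
  # range classes reflect the topology regions
  expect_true(all(sim$restraints$range_class %in%
                    c("short", "medium", "long")))
})

test_that("long-range NOEs require folded conformers", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl"))
  big <- sample_conformers(top, n = 400, solvent_profile("water"), seed = 12)
  rg <- vapply(big$coords, radius_of_gyration, 0.0, masses = top$masses)
  folded_pool <- conformer_ensemble(top, big$coords[order(rg)[1:10]])
  extended_pool <- conformer_ensemble(top, big$coords[order(-rg)[1:10]])
  w <- rep(0.1, 10)
  sim_f <- suppressWarnings(
    simulate_noes(folded_pool, w, n_restraints = 40, seed = 2))
  expect_gte(sum(sim_f$restraints$range_class == "long"), 1)
  sim_e <- suppressWarnings(
    simulate_noes(extended_pool, w, n_restraints = 40, seed = 2))
  if (!is.null(sim_e$restraints)) {
    expect_equal(sum(sim_e$restraints$range_class == "long"), 0)
  }
})

test_that("round trip: simulated NOEs deconvolute to the generating truth", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl", seed = 4))
  big <- sample_conformers(top, n = 300, solvent_profile("water"), seed = 21)
  rg <- vapply(big$coords, radius_of_gyration, 0.0, masses = top$masses)
  # small diverse pool: folded and extended members, so inter-ligand NOEs
  # are informative
  pick <- order(rg)[round(seq(1, 300, length.out = 10))]
  pool <- conformer_ensemble(top, big$coords[pick],
                             energies = big$energies[pick])
  w <- c(0.45, 0.3, 0.15, rep(0, 6), 0.1)
  sim <- simulate_noes(pool, w, n_restraints = 15, noise_sd = 0, seed = 9)
  rep <- run_namfis_analysis(pool, sim$restraints, jackknife = FALSE,
                             seed = 2)
  expect_lt(rep$fit$ssd, 1e-8)
  expect_lt(max(abs(coef(rep$fit) - w)), 1e-3)
})
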