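# Clustering, Boltzmann populations, MEC, landscapes, congruence.

test_that("Kabsch RMSD is zero under rigid motion and symmetric", {
  set.seed(11)
  a <- matrix(stats::rnorm(24, sd = 3), ncol = 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  moved <- random_rigid_transform(a)
  expect_lt(kabsch_rmsd(a, moved), 1e-8)
  b <- a + matrix(stats::rnorm(24, sd = 0.6), ncol = 3)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-12)
  expect_error(kabsch_rmsd(a[1:2, ], b[1:2, ]), "3 atoms")
  col <- cbind(1:5, 0, 0)
  expect_error(kabsch_rmsd(col, col), "collinear")
})

test_that("Kabsch RMSD matches a numerical optimizer over rotations", {
  set.seed(11)
  a <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
  b <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
  got <- kabsch_rmsd(a, b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rmsd_at <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    sqrt(mean(rowSums((bc - ac %*% t(rz %*% ry %*% rx))^2)))
  }
  best <- Inf
  for (i in 1:20) {
    o <- stats::optim(stats::runif(3, -pi, pi), rmsd_at,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-5)
  expect_lte(got, best + 1e-8)  # closed form is never worse
})

test_that("leader clustering respects the cutoff and energy ordering", {
  top <- toy_topology()
  base <- toy_coords()
  # all identical -> one cluster
  ens <- conformer_ensemble(top, rep(list(base), 4))
  expect_equal(length(cluster_ensemble(ens)$representatives), 1)
  # cutoff 0 on distinct conformers -> one cluster each
  distinct <- lapply(c(0, 0.5, 1.0), function(s) {
    m <- base
    m[1, 2] <- s
    m
  })
  ens <- conformer_ensemble(top, distinct)
  expect_equal(length(cluster_ensemble(ens, 0)$representatives), 3)
  expect_error(cluster_ensemble(ens, -1), ">= 0")
  # two tight bundles far apart -> exactly two clusters; representatives are
  # the lowest-energy members
  bent <- base
  bent[5, ] <- c(1, 5, 0)
  bundle <- c(lapply(1:3, function(i) base + stats::rnorm(15, sd = 0.02)),
              lapply(1:3, function(i) bent + stats::rnorm(15, sd = 0.02)))
  en <- c(0.3, 0.1, 0.2, 1.3, 1.1, 1.2)
  ens <- conformer_ensemble(top, bundle, energies = en)
  cl <- cluster_ensemble(ens, rmsd_cutoff = 1.0)
  expect_equal(length(cl$representatives), 2)
  expect_setequal(cl$representatives, c(2, 5))
  # representatives pairwise farther apart than the cutoff
  r <- kabsch_rmsd(ens$coords[[cl$representatives[1]]],
                   ens$coords[[cl$representatives[2]]],
                   cl$atom_subset)
  expect_gt(r, 1.0)
})

test_that("Boltzmann populations: analytic cases and invariances", {
  expect_equal(boltzmann_populations(rep(2.5, 4)), rep(0.25, 4))
  RT <- 1.987204e-3 * 300
  expect_equal(boltzmann_populations(c(0, RT * log(2))), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  set.seed(5)
  e <- stats::rnorm(20, sd = 2)
  p <- boltzmann_populations(e)
  # brute-force unshifted formula
  expect_equal(p, exp(-e / RT) / sum(exp(-e / RT)), tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # offset invariance
  expect_lt(max(abs(boltzmann_populations(e + 7.3) - p)), 1e-12)
  # monotone: lower energy never has lower population
  expect_true(all(diff(p[order(e)]) <= 1e-15))
  # infinite-temperature limit is uniform
  expect_lt(max(abs(boltzmann_populations(e, 1e9) - 1 / 20)), 1e-6)
  expect_error(boltzmann_populations(numeric(0)), "no energies")
  expect_error(boltzmann_populations(c(0, Inf)), "non-finite")
})

test_that("low-energy subset uses a strict threshold", {
  expect_equal(low_energy_subset(c(0.5, 0.3, 0.2)), 1:3)
  expect_equal(low_energy_subset(c(0.995, 0.005)), 1L)
  expect_message(idx <- low_energy_subset(rep(0.005, 200)), "no conformer")
  expect_length(idx, 0)
})

test_that("MEC is the representative of the most populated cluster", {
  cl <- structure(list(labels = c(1, 1, 2, 2), representatives = c(1, 3),
                       rmsd_cutoff = 1), class = "cluster_result")
  got <- identify_mec(cl, c(0.35, 0.25, 0.2, 0.2))
  expect_equal(got$mec, 1)
  expect_equal(got$cluster_populations, c(0.6, 0.4))
  # exact tie resolves to the lower-energy representative
  got <- identify_mec(cl, c(0.25, 0.25, 0.3, 0.2), energies = c(5, 9, 2, 8))
  expect_equal(got$mec, 3)
  expect_error(identify_mec(cl, numeric(0)), "does not match")
})

test_that("landscapes are normalized histograms with correct masses", {
  one <- data.frame(r_gyr = 5, sa3d_psa = 100)
  g <- property_landscape(one, bins = 10)
  expect_equal(sum(g$density), 1)
  expect_equal(max(g$density), 1)
  set.seed(8)
  many <- data.frame(r_gyr = stats::runif(200, 4, 12),
                     sa3d_psa = stats::runif(200, 150, 260))
  g <- property_landscape(many, bins = c(15, 9))
  expect_equal(dim(g$density), c(15, 9))
  expect_equal(sum(g$density), 1, tolerance = 1e-9)
  expect_true(all(g$density >= 0))
  expect_error(property_landscape(many, bins = 0), ">= 1")
  # two separated bundles with weights 0.7/0.3 put those masses in place
  bundles <- data.frame(r_gyr = c(5, 5, 11, 11),
                        sa3d_psa = c(100, 100, 200, 200))
  g <- property_landscape(bundles, bins = 2,
                          weights = c(0.35, 0.35, 0.15, 0.15))
  expect_equal(g$density[1, 1], 0.7)
  expect_equal(g$density[2, 2], 0.3)
})

test_that("solvent comparison: identity, disjoint support, known centroids", {
  set.seed(13)
  a <- data.frame(r_gyr = stats::rnorm(300, 6, 0.4),
                  sa3d_psa = stats::rnorm(300, 220, 8),
                  population = NA_real_)
  cmp <- compare_solvent_ensembles(a, a)
  expect_equal(cmp$delta_r_gyr, 0)
  expect_equal(cmp$delta_sa3d_psa, 0)
  expect_equal(cmp$overlap, 1)
  expect_true(cmp$congruent)
  # disjoint landscapes overlap zero
  b <- a
  b$r_gyr <- b$r_gyr + 10
  cmp <- compare_solvent_ensembles(a, b)
  expect_equal(cmp$overlap, 0)
  expect_false(cmp$congruent)
  # centroid shift equals the analytic difference of means
  expect_equal(cmp$delta_r_gyr, mean(b$r_gyr) - mean(a$r_gyr),
               tolerance = 1e-12)
  # overlap is symmetric
  cmp_ba <- compare_solvent_ensembles(b, a)
  expect_equal(cmp_ba$overlap, cmp$overlap)
})
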