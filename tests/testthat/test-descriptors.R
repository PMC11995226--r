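# 3D descriptors: radius of gyration, Shrake-Rupley SASA and its partition,
# IMHB counting, fold classes, ETR.

test_that("radius of gyration matches analytic cases and the direct sum", {
  expect_equal(radius_of_gyration(matrix(0, 1, 3), masses = 12), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, mode = "geometric"), 1.0)

  set.seed(7)
  xyz <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
  m <- stats::runif(10, 1, 16)
  # independent direct evaluation of the defining sum
  ctr <- colSums(xyz * m) / sum(m)
  expected <- sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
  expect_equal(radius_of_gyration(xyz, m), expected, tolerance = 1e-12)

  expect_error(radius_of_gyration(matrix(0, 0, 3)), "no atoms")
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "positive")
})

test_that("radius of gyration is rigid-motion invariant", {
  set.seed(31)
  xyz <- matrix(stats::rnorm(45, sd = 4), ncol = 3)
  m <- stats::runif(15, 1, 16)
  ref <- radius_of_gyration(xyz, m)
  for (i in 1:25) {
    moved <- random_rigid_transform(xyz)
    expect_lt(abs(radius_of_gyration(moved, m) - ref) / ref, 1e-9)
  }
})

test_that("SASA of an isolated atom is the full expanded sphere", {
  area <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.70,
                             probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(area, 4 * pi * 3.10^2, tolerance = 0.005)
})

test_that("SASA handles burial, coincidence, and input validation", {
  # small atom fully inside a much larger sphere
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  areas <- shrake_rupley_sasa(coords, radii = c(6.0, 1.0), probe_radius = 0)
  expect_equal(areas[2], 0)
  # coincident atoms of identical radius both keep their full sphere
  coords <- rbind(c(0, 0, 0), c(0, 0, 0))
  areas <- shrake_rupley_sasa(coords, radii = c(1.5, 1.5))
  expect_equal(areas[1], areas[2])
  expect_equal(areas[1], 4 * pi * 2.9^2, tolerance = 0.01)
  expect_error(shrake_rupley_sasa(matrix(NaN, 1, 3), 1.5), "non-finite")
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), 1.5,
                                  n_sphere_points = 8), ">= 32")
})

test_that("two overlapping spheres match the spherical-cap solution", {
  for (case in list(c(1.7, 1.5, 2.0), c(1.7, 1.7, 1.0), c(2.0, 1.2, 2.8))) {
    coords <- rbind(c(0, 0, 0), c(case[3], 0, 0))
    got <- shrake_rupley_sasa(coords, radii = case[1:2], probe_radius = 1.4,
                              n_sphere_points = 4096)
    want <- two_sphere_sasa(case[1], case[2], case[3], probe = 1.4)
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("SASA is monotone under adding atoms", {
  set.seed(12)
  coords <- matrix(stats::rnorm(12, sd = 2), ncol = 3)
  radii <- stats::runif(4, 1.2, 2.0)
  base <- shrake_rupley_sasa(coords, radii)
  # distant atom leaves every area unchanged
  far <- rbind(coords, c(50, 0, 0))
  with_far <- shrake_rupley_sasa(far, c(radii, 1.7))
  expect_equal(with_far[1:4], base, tolerance = 1e-12)
  # overlapping atom never increases any neighbour's area
  near <- rbind(coords, coords[1, ] + c(1.0, 0, 0))
  with_near <- shrake_rupley_sasa(near, c(radii, 1.7))
  expect_true(all(with_near[1:4] <= base + 1e-9))
})

test_that("polar classification follows the scheme", {
  # methane-like: C with 4 H
  methane <- molecule_topology(c("C", rep("H", 4)),
                               bonds = cbind(1, 2:5))
  expect_false(any(classify_polar_atoms(methane)))
  # water: O and both attached H polar under the default scheme
  expect_true(all(classify_polar_atoms(water_topology())))
  # PEG fragment C-C-O-C-C-O without H: exactly the two O
  peg <- molecule_topology(c("C", "C", "O", "C", "C", "O"),
                           bonds = cbind(1:5, 2:6))
  expect_equal(classify_polar_atoms(peg),
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  # sulfur only when opted in
  thiol <- molecule_topology(c("C", "S"), bonds = rbind(c(1, 2)))
  expect_false(classify_polar_atoms(thiol)[2])
  expect_true(classify_polar_atoms(thiol,
                                   polar_scheme(include_sulfur = TRUE))[2])
  # H without bonds is an error when the attached-H rule is active
  loose <- molecule_topology(c("O", "H"))
  expect_error(classify_polar_atoms(loose), "no bond record")
})

test_that("SASA partition is exact and validated", {
  set.seed(3)
  areas <- stats::runif(20, 0, 30)
  mask <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  part <- partition_sasa(areas, mask)
  expect_equal(part$sa3d_psa, sum(areas[mask]))
  expect_equal(part$sa3d_npsa, sum(areas[!mask]))
  expect_equal(part$sa3d_psa + part$sa3d_npsa, sum(areas))
  expect_equal(partition_sasa(areas, rep(TRUE, 20))$sa3d_npsa, 0)
  expect_equal(partition_sasa(areas, rep(FALSE, 20))$sa3d_psa, 0)
  expect_error(partition_sasa(areas, mask[-1]), "mask length")
})

test_that("IMHB counting follows the geometric criterion", {
  # linear O-H...O at 2.0 A, 180 degrees, 3 bonds apart via a carbon chain
  top <- molecule_topology(c("O", "H", "C", "C", "O"),
                           bonds = rbind(c(1, 2), c(1, 3), c(3, 4), c(4, 5)))
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0, 1.4, 0), c(1.4, 2.2, 0),
               c(2.96, 0, 0))  # H...A = 2.0, angle 180
  expect_equal(count_imhb(xyz, top), 1L)
  xyz[5, ] <- c(5.46, 0, 0)    # H...A = 4.5: too far
  expect_equal(count_imhb(xyz, top), 0L)
  # no hydrogens: zero with warning
  expect_warning(n <- count_imhb(toy_coords(), toy_topology()),
                 "no hydrogens")
  expect_equal(n, 0L)
})

test_that("IMHB count matches exhaustive enumeration on random geometry", {
  set.seed(99)
  n <- 20
  elements <- c(rep(c("O", "H"), 5), rep("C", 6), rep("N", 4))
  bonds <- rbind(cbind(seq(1, 9, 2), seq(2, 10, 2)),  # O-H pairs
                 cbind(11:15, 12:16),
                 cbind(c(1, 3, 5, 7, 9, 17, 18, 19, 20),
                       c(11, 12, 13, 14, 15, 16, 15, 14, 13)))
  top <- molecule_topology(elements, bonds = bonds)
  sep <- chamscope:::.bond_separation(top, cap = 3L)
  for (rep_i in 1:5) {
    xyz <- matrix(stats::rnorm(n * 3, sd = 2.2), ncol = 3)
    # brute force: every H bonded to N/O against every other N/O
    brute <- 0L
    for (h in which(elements == "H")) {
      partners <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
      d_atom <- partners[elements[partners] %in% c("N", "O")][1]
      if (is.na(d_atom)) next
      for (a in which(elements %in% c("N", "O"))) {
        if (a == d_atom || a %in% partners || sep[h, a] < 3) next
        ha <- sqrt(sum((xyz[a, ] - xyz[h, ])^2))
        v1 <- xyz[d_atom, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if (ha <= 2.5 && ang >= 120) brute <- brute + 1L
      }
    }
    expect_equal(count_imhb(xyz, top), brute)
  }
})

test_that("fold classification applies thresholds with compact tie-breaks", {
  expect_equal(as.character(fold_class(11)), "extended")
  expect_equal(as.character(fold_class(5.5)), "folded")
  expect_equal(as.character(fold_class(8)), "semifolded")
  # boundary resolves to the more compact class
  expect_equal(as.character(fold_class(7.0)), "folded")
  expect_equal(as.character(fold_class(9.5)), "extended")
  # monotone non-decreasing in r_gyr
  rg <- sort(stats::runif(50, 3, 13))
  cls <- fold_class(rg)
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_error(fold_class(5, folded_max = 9, extended_min = 7), "<")
})

test_that("ETR is the EPSA/TPSA ratio with domain checks", {
  expect_equal(etr(100, 200), 0.5)
  expect_equal(etr(150, 150), 1.0)
  expect_equal(etr(0, 150), 0.0)
  expect_error(etr(100, 0), "tpsa")
  expect_error(etr(-1, 100), "epsa")
})

test_that("property tables satisfy the partition identity per conformer", {
  top <- build_protac_mimic(protac_mimic_spec("peg", seed = 5))
  ens <- sample_conformers(top, n = 20, seed = 8)
  props <- conformer_properties(ens)
  expect_equal(nrow(props), 20)
  expect_true(all(abs(props$sa3d_psa + props$sa3d_npsa -
                        props$sasa_total) < 1e-6))
  expect_true(all(props$r_gyr >= 0))
  expect_false(anyNA(props$imhb))
  # scheme metadata is echoed
  expect_equal(attr(props, "scheme")$polar_elements, c("N", "O"))
})
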