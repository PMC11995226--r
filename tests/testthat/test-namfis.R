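# NAMFIS-style deconvolution: averaging, distance matrices, the constrained
# fit, jackknife, and fold-class summaries.

test_that("r^-6 averaging: limits, direct formula, power-mean inequality", {
  expect_equal(noe_average_distance(3.7, 1), 3.7)
  expect_equal(noe_average_distance(rep(2.5, 5), rep(0.2, 5)), 2.5)
  # direct evaluation of the power mean
  d <- c(2, 5)
  w <- c(0.5, 0.5)
  expect_equal(noe_average_distance(d, w),
               (0.5 * 2^-6 + 0.5 * 5^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal(noe_average_distance(d, w), 2.24, tolerance = 0.01)
  expect_error(noe_average_distance(c(2, -1), w), "> 0")
  expect_error(noe_average_distance(d, c(0.7, 0.7)), "simplex")
  set.seed(41)
  for (i in 1:50) {
    d <- stats::runif(6, 1.8, 7)
    w <- stats::rgamma(6, 1)
    w <- w / sum(w)
    avg <- noe_average_distance(d, w)
    expect_lte(avg, sum(w * d) + 1e-12)
    expect_gte(avg, min(d) - 1e-12)
  }
})

test_that("distance matrices resolve labels, indices, and proton groups", {
  top <- molecule_topology(c("C", "H", "H", "H", "C", "H"),
                           bonds = rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                                         c(5, 6)),
                           proton_labels = c(Ha = 2, Hb = 6))
  xyz <- rbind(c(0, 0, 0), c(0, 3, 0), c(1, 0, 0), c(0, 0, 1),
               c(2, 0, 0), c(2, 4, 0))
  ens <- conformer_ensemble(top, list(xyz))
  rs <- noe_restraints("Ha", "Hb", 3.0)
  dm <- build_distance_matrix(ens, rs)
  expect_equal(dim(dm), c(1, 1))
  expect_equal(dm[1, 1], sqrt(sum((xyz[2, ] - xyz[6, ])^2)))
  # equivalent-proton group with all members at the same distance gives that
  # distance; here a 3-proton group against a single proton
  xyz_sym <- xyz
  xyz_sym[c(2, 3, 4), ] <- rbind(c(0, 3, 0), c(1, 3, 0), c(2, 3, 0))
  xyz_sym[6, ] <- c(1, 6, 0)
  d_members <- sqrt(rowSums(sweep(xyz_sym[c(2, 3, 4), ], 2,
                                  xyz_sym[6, ])^2))
  ens2 <- conformer_ensemble(top, list(xyz_sym))
  dm2 <- build_distance_matrix(ens2, noe_restraints("Me", "Hb", 3.0),
                               proton_groups = list(Me = c(2, 3, 4)))
  expect_equal(dm2[1, 1], mean(d_members^-6)^(-1 / 6), tolerance = 1e-12)
  expect_error(build_distance_matrix(ens, noe_restraints("Hx", "Hb", 3)),
               "Hx")
})

test_that("distance matrix matches brute-force distances on random pools", {
  top <- build_protac_mimic(protac_mimic_spec("alkyl", seed = 3))
  ens <- sample_conformers(top, n = 5, seed = 17)
  tagged <- which(!is.na(top$proton_labels))
  rs <- noe_restraints(top$proton_labels[tagged[1]],
                       top$proton_labels[tagged[4]], 4.0)
  dm <- build_distance_matrix(ens, rs)
  brute <- vapply(ens$coords, function(xyz) {
    sqrt(sum((xyz[tagged[1], ] - xyz[tagged[4], ])^2))
  }, 0.0)
  expect_equal(as.vector(dm), brute, tolerance = 1e-12)
})

test_that("single-conformer pool gets population 1 and plain residuals", {
  vals <- matrix(c(2.5, 4.0), ncol = 1)
  rs <- noe_restraints(c("a", "a"), c("b", "c"), c(2.8, 3.5))
  fit <- namfis_fit(vals, rs)
  expect_equal(unname(coef(fit)), 1.0)
  expect_equal(residuals(fit), c(2.8 - 2.5, 3.5 - 4.0))
})

test_that("noise-free forward simulation is recovered exactly", {
  set.seed(23)
  K <- 8
  nr <- 12
  vals <- matrix(stats::runif(nr * K, 2, 6), nr, K)
  w <- c(0.5, 0.3, 0.2, rep(0, K - 3))
  d_exp <- as.vector((vals^(-6) %*% w)^(-1 / 6))
  rs <- noe_restraints(paste0("p", 1:nr), paste0("q", 1:nr), d_exp)
  fit <- namfis_fit(vals, rs, seed = 2)
  expect_lt(fit$ssd, 1e-8)
  expect_lt(max(abs(coef(fit) - w)), 1e-3)
  # fitted() and predict() agree with the generating averages
  expect_equal(unname(fitted(fit)), d_exp, tolerance = 1e-3)
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
})

test_that("an infeasible restraint is reported as a large violation", {
  vals <- matrix(stats::runif(10, 8, 10), 5, 2)
  rs <- noe_restraints(paste0("p", 1:5), paste0("q", 1:5),
                       c(2.0, rep(8.5, 4)))
  fit <- namfis_fit(vals, rs, weighting = "uniform")
  expect_gte(abs(residuals(fit)[1]), 6)
  s <- summary(fit)
  expect_true("p1-q1" %in% s$violated$restraint)
})

test_that("identical seeds reproduce the fit; floor zeroes minor weights", {
  prob <- random_namfis_problem(77)
  f1 <- namfis_fit(prob$values, prob$restraints, seed = 5)
  f2 <- namfis_fit(prob$values, prob$restraints, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_true(all(coef(f1)[coef(f1) > 0] >= f1$floor))
  expect_equal(sum(coef(f1)), 1, tolerance = 1e-9)
})

test_that("degenerate pools warn about non-identifiability", {
  vals <- matrix(3.0, 4, 3)
  rs <- noe_restraints(paste0("p", 1:4), paste0("q", 1:4), rep(3, 4))
  expect_warning(namfis_fit(vals, rs), "not identifiable")
})

test_that("jackknife: perfect data gives tight ranges, k folds, corruption", {
  prob <- random_namfis_problem(31, pool_range = 6:10,
                                restraint_factor = 1.5)
  jk <- jackknife_restraints(prob$values, prob$restraints, seed = 3)
  nr <- nrow(prob$values)
  expect_equal(nrow(jk$fold_populations), nr)
  # noise-free: every fold recovers the same populations
  expect_lt(max(jk$ranges[, "max"] - jk$ranges[, "min"]), 1e-4)
  expect_error(jackknife_restraints(prob$values[1, , drop = FALSE],
                                    prob$restraints[1, ]), "at least 2")
  # corrupting one restraint makes its exclusion fold the best fit
  vals <- prob$values
  rs <- prob$restraints
  rs$d_exp[3] <- rs$d_exp[3] + 2.0
  jk <- jackknife_restraints(vals, rs, seed = 3, weighting = "uniform")
  expect_equal(which.min(jk$fold_ssd), 3L)
})

test_that("fold-class populations sum to 100 and honor the labels", {
  vals <- matrix(stats::runif(30, 2, 6), 10, 3)
  w <- c(0.54, 0.39, 0.07)
  d_exp <- as.vector((vals^(-6) %*% w)^(-1 / 6))
  rs <- noe_restraints(paste0("p", 1:10), paste0("q", 1:10), d_exp)
  fit <- namfis_fit(vals, rs, seed = 4)
  pct <- summarize_fold_populations(
    fit, c("folded", "semifolded", "extended"))
  expect_equal(sum(pct), 100, tolerance = 1e-6)
  expect_equal(unname(pct), c(54, 39, 7), tolerance = 0.5)
  pct_all <- summarize_fold_populations(fit, rep("folded", 3))
  expect_equal(unname(pct_all["folded"]), 100)
  expect_error(summarize_fold_populations(fit, c("folded", NA, "folded")),
               "missing")
  expect_error(summarize_fold_populations(fit, c("folded", "x", "folded")),
               "folded/semifolded/extended")
})
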