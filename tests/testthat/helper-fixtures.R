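# Fixtures built in code: tiny topologies and ensembles used across tests.

# water: O bonded to two H
water_topology <- function() {
  molecule_topology(c("O", "H", "H"), bonds = rbind(c(1, 2), c(1, 3)))
}

# five-atom toy chain C-C-O-C-C with no hydrogens
toy_topology <- function() {
  molecule_topology(c("C", "C", "O", "C", "C"),
                    bonds = cbind(1:4, 2:5))
}

toy_coords <- function(shift = 0) {
  cbind(seq(0, 6, length.out = 5) + shift, c(0, 1, 0, 1, 0), 0)
}

toy_ensemble <- function(n = 3, energies = NULL) {
  coords <- lapply(seq_len(n) - 1, function(s) toy_coords(shift = s * 0.1))
  conformer_ensemble(toy_topology(), coords, energies = energies)
}

# random rigid-body transform applied to an N x 3 matrix
random_rigid_transform <- function(xyz) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  rot <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3])),
    c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2])),
    c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
  xyz %*% t(rot) + matrix(stats::rnorm(3, sd = 5), nrow(xyz), 3, byrow = TRUE)
}

# analytic SASA of two overlapping spheres (spherical-cap solution):
# accessible area of each expanded sphere excludes the cap buried inside the
# other expanded sphere
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  cap <- function(RA, RB) {
    if (d >= RA + RB) return(0)              # disjoint
    if (d + RA <= RB) return(4 * pi * RA^2)  # fully buried
    h <- RA - (d^2 + RA^2 - RB^2) / (2 * d)
    2 * pi * RA * h
  }
  c(4 * pi * R1^2 - cap(R1, R2), 4 * pi * R2^2 - cap(R2, R1))
}

# Monte Carlo SASA oracle: uniform points on each expanded sphere, rejected
# when inside any other expanded sphere
mc_sasa <- function(coords, radii, probe, n_samples) {
  n <- nrow(coords)
  R <- radii + probe
  vapply(seq_len(n), function(i) {
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)[-i]) {
      dj2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      free <- free & dj2 >= R[j]^2
    }
    4 * pi * R[i]^2 * mean(free)
  }, 0.0)
}

# random NAMFIS problem with known sparse truth; n_restraints defaults to
# enough rows for identifiability of the support
random_namfis_problem <- function(seed, pool_range = 5:30, s_range = 3:5,
                                  restraint_factor = 0.6) {
  set.seed(seed)
  K <- sample(pool_range, 1)
  s <- min(sample(s_range, 1), K)
  nr <- max(2L * s, ceiling(restraint_factor * K))
  values <- matrix(stats::runif(nr * K, 2, 6), nr, K)
  w <- numeric(K)
  idx <- sample(K, s)
  ww <- stats::rgamma(s, 2)
  w[idx] <- ww / sum(ww)
  d_exp <- as.vector((values^(-6) %*% w)^(-1 / 6))
  restraints <- noe_restraints(atom_i = paste0("p", seq_len(nr)),
                               atom_j = paste0("q", seq_len(nr)),
                               d_exp = d_exp)
  list(values = values, truth = w, restraints = restraints, K = K, s = s)
}
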