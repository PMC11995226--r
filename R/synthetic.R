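# Synthetic PROTAC mimics: two rigid ligand-like bodies joined by a flexible
# linker (fully nonpolar alkyl-like, or PEG-like with every third atom
# oxygen), sampled with a deliberately physics-light pseudo-energy that
# reproduces the statistical structure the analysis assumes - hydrophobic
# collapse of the alkyl mimic in polar solvent, congruent behaviour of the
# PEG mimic - plus NOE data generated from known population mixtures.

#' Specification of a synthetic PROTAC mimic
#'
#' @param linker_type `"alkyl"` (all linker atoms nonpolar carbon) or
#'   `"peg"` (every third linker atom an oxygen). The two variants share
#'   the same seed-determined ligand bodies and linker geometry and differ
#'   only in linker-atom polarity, mirroring a CH2-to-O linker swap.
#' @param n_linker_atoms Number of linker chain atoms (>= 3; default 12).
#' @param ligand_size Heavy atoms per rigid ligand body (>= 4; default 22).
#' @param seed Integer seed controlling body geometry (default 42).
#' @return List of class `mimic_spec`.
#' @export
protac_mimic_spec <- function(linker_type = c("alkyl", "peg"),
                              n_linker_atoms = 12L, ligand_size = 22L,
                              seed = 42L) {
  linker_type <- match.arg(linker_type)
  if (n_linker_atoms < 3L) stop("n_linker_atoms must be >= 3", call. = FALSE)
  if (ligand_size < 4L) stop("ligand_size must be >= 4", call. = FALSE)
  structure(list(linker_type = linker_type,
                 n_linker_atoms = as.integer(n_linker_atoms),
                 ligand_size = as.integer(ligand_size),
                 seed = as.integer(seed)),
            class = "mimic_spec")
}

#' Solvent profile for the pseudo-energy
#'
#' Bundles a solvent label with its dielectric constant (metadata carried
#' into ensembles) and the two pseudo-energy weights. In a polar solvent
#' the hydrophobic weight is negative — burying nonpolar surface is
#' rewarded, driving hydrophobic collapse — while in an apolar solvent it
#' is near zero and the chain samples its intrinsic (clash-limited)
#' conformational space. The polar-exposure weight, which penalizes
#' burying a polar linker atom in a nonpolar pocket, is the same in every
#' preset: desolvating an ether-like oxygen costs energy in any medium, and
#' this is what frustrates hydrophobic collapse for the PEG-type linker
#' while leaving the alkyl linker free to collapse.
#'
#' @param label `"water"`, `"chloroform"`, `"membrane"`, or any custom
#'   label (then supply all parameters).
#' @param epsilon Dielectric constant; presets: water 80, chloroform 4.8,
#'   membrane interior 3.0.
#' @param hydrophobic_weight kcal/mol per unit of normalized nonpolar
#'   cross-region contact (negative rewards burial).
#' @param polar_exposure_weight kcal/mol per unit of normalized polar
#'   cross-region contact (positive penalizes burying polar atoms).
#' @return List of class `solvent_profile`.
#' @export
solvent_profile <- function(label = c("water", "chloroform", "membrane"),
                            epsilon = NULL, hydrophobic_weight = NULL,
                            polar_exposure_weight = NULL) {
  presets <- list(
    water = list(epsilon = 80, hydrophobic_weight = -100,
                 polar_exposure_weight = 300),
    chloroform = list(epsilon = 4.8, hydrophobic_weight = 0,
                      polar_exposure_weight = 300),
    membrane = list(epsilon = 3.0, hydrophobic_weight = 0,
                    polar_exposure_weight = 300))
  label <- if (length(label) > 1L) label[1] else label
  p <- presets[[label]]
  if (is.null(p)) {
    if (is.null(epsilon) || is.null(hydrophobic_weight) ||
        is.null(polar_exposure_weight)) {
      stop("custom solvent profile needs epsilon, hydrophobic_weight and ",
           "polar_exposure_weight", call. = FALSE)
    }
    p <- list(epsilon = epsilon, hydrophobic_weight = hydrophobic_weight,
              polar_exposure_weight = polar_exposure_weight)
  } else {
    if (!is.null(epsilon)) p$epsilon <- epsilon
    if (!is.null(hydrophobic_weight)) p$hydrophobic_weight <- hydrophobic_weight
    if (!is.null(polar_exposure_weight)) {
      p$polar_exposure_weight <- polar_exposure_weight
    }
  }
  structure(c(list(label = label), p), class = "solvent_profile")
}

# sample `n` points with pairwise separation >= min_sep inside a sphere,
# optionally restricted to the half-space x <= 0 (body A) or x >= 0 (body B)
.sample_blob <- function(n, radius, min_sep = 1.45, half = 0) {
  pts <- matrix(0, n, 3)  # atom 1 is the anchor at the origin
  i <- 2L
  guard <- 0L
  while (i <= n) {
    guard <- guard + 1L
    if (guard > 20000L) stop("blob sampling failed; lower ligand_size",
                             call. = FALSE)
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) > radius^2) next
    if (half > 0 && p[1] < 0.3) next
    if (half < 0 && p[1] > -0.3) next
    d2 <- rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2, p)^2)
    if (min(d2) < min_sep^2) next
    pts[i, ] <- p
    i <- i + 1L
  }
  pts
}

# spanning-tree bonds: each atom bonds to its nearest earlier atom
.blob_bonds <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  t(vapply(2:n, function(i) {
    d2 <- rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2, pts[i, ])^2)
    c(which.min(d2), i)
  }, integer(2)))
}

#' Build a synthetic PROTAC-mimic topology
#'
#' Constructs two rigid ligand-like bodies (mixed polar/nonpolar heavy
#' atoms, eight tagged NOE protons each) joined by a flexible chain of
#' `n_linker_atoms`. For `linker_type = "alkyl"` every linker atom is a
#' nonpolar carbon; for `"peg"` atoms at positions 3, 6, 9, ... are oxygen.
#' Identical seeds give bit-identical topologies, and the alkyl/PEG pair
#' built from one seed differs only in those linker elements.
#'
#' @param spec A [protac_mimic_spec()].
#' @return A [molecule_topology()] with attributes `body_coords_a`,
#'   `body_coords_b` (rigid local coordinates), `region` (per-atom factor
#'   body_a/linker/body_b) and `h_parents`, consumed by
#'   [sample_conformers()].
#' @export
build_protac_mimic <- function(spec) {
  stopifnot(inherits(spec, "mimic_spec"))
  withr_seed_eval(spec$seed, function() .build_mimic_impl(spec))
}

.build_mimic_impl <- function(spec) {
  ns <- spec$ligand_size
  nl <- spec$n_linker_atoms
  body_radius <- max(2.6, 1.05 * ns^(1 / 3) * 1.45)
  # body A occupies x <= 0 with its anchor (atom 1) at the origin;
  # body B is stored in local coordinates, anchor at origin, bulk at x >= 0
  coords_a <- .sample_blob(ns, body_radius, half = -1)
  coords_b_local <- .sample_blob(ns, body_radius, half = +1)

  body_elements <- function() {
    el <- rep("C", ns)
    el[seq(4, ns, by = 4)] <- rep(c("O", "N"), length.out = length(seq(4, ns, by = 4)))
    el
  }
  el_a <- body_elements()
  el_b <- body_elements()
  linker_el <- rep("C", nl)
  if (spec$linker_type == "peg") {
    linker_el[seq(3, nl, by = 3)] <- "O"
  }

  # proton sites: eight atoms per body at spread depths from the anchor — the
  # linker-facing side comes close to the other ligand in folded
  # conformations (inter-ligand NOEs), the outward face gives intra-ligand
  # contacts only
  pick_h_parents <- function(pts) {
    ord <- order(rowSums(pts^2))
    nn <- length(ord)
    unique(ord[pmax(2, ceiling(nn * c(0.1, 0.2, 0.35, 0.5, 0.65, 0.8,
                                      0.9, 1)))])
  }
  hp_a <- pick_h_parents(coords_a)
  hp_b <- pick_h_parents(coords_b_local)
  h_offset <- function(pts, parents) {
    ctr <- colMeans(pts)
    t(vapply(parents, function(p) {
      v <- pts[p, ] - ctr
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) v <- c(1, 0, 0) else v <- v / nv
      pts[p, ] + 1.09 * v
    }, numeric(3)))
  }
  h_a <- h_offset(coords_a, hp_a)
  h_b <- h_offset(coords_b_local, hp_b)

  nha <- length(hp_a)
  nhb <- length(hp_b)
  # tagged protons on interior linker atoms (every third, starting at the
  # second): their positions move with the chain and give the
  # conformation-sensitive medium-range linker-to-ligand NOEs
  lh_parents <- seq(2L, nl - 1L, by = 3L)
  nlh <- length(lh_parents)
  # global atom order: body A heavy | body A protons | linker | linker
  # protons | body B heavy | body B protons
  idx_a <- seq_len(ns)
  idx_ha <- ns + seq_len(nha)
  idx_l <- ns + nha + seq_len(nl)
  idx_lh <- ns + nha + nl + seq_len(nlh)
  idx_b <- ns + nha + nl + nlh + seq_len(ns)
  idx_hb <- ns + nha + nl + nlh + ns + seq_len(nhb)
  n_total <- ns * 2 + nl + nha + nlh + nhb

  elements <- character(n_total)
  elements[idx_a] <- el_a
  elements[idx_ha] <- "H"
  elements[idx_l] <- linker_el
  elements[idx_lh] <- "H"
  elements[idx_b] <- el_b
  elements[idx_hb] <- "H"

  bonds_a <- .blob_bonds(coords_a)
  bonds_b <- .blob_bonds(coords_b_local)
  bonds <- rbind(
    bonds_a,
    cbind(hp_a, idx_ha),
    cbind(idx_a[1], idx_l[1]),                      # anchor A - L1
    if (nl > 1L) cbind(idx_l[-nl], idx_l[-1]),      # chain
    cbind(idx_l[lh_parents], idx_lh),
    cbind(idx_l[nl], idx_b[1]),                     # Ln - anchor B
    bonds_b + (idx_b[1] - 1L),
    cbind(hp_b + (idx_b[1] - 1L), idx_hb))

  proton_labels <- stats::setNames(
    c(idx_ha, idx_lh, idx_hb),
    c(paste0("HA", seq_len(nha)), paste0("HL", seq_len(nlh)),
      paste0("HB", seq_len(nhb))))
  top <- molecule_topology(elements, bonds = bonds,
                           proton_labels = proton_labels)
  region <- character(n_total)
  region[c(idx_a, idx_ha)] <- "body_a"
  region[c(idx_l, idx_lh)] <- "linker"
  region[c(idx_b, idx_hb)] <- "body_b"
  attr(top, "region") <- factor(region, c("body_a", "linker", "body_b"))
  attr(top, "body_coords_a") <- cbind(rbind(coords_a, h_a))
  attr(top, "body_coords_b") <- cbind(rbind(coords_b_local, h_b))
  attr(top, "h_parents") <- list(a = hp_a, b = hp_b, linker = lh_parents)
  attr(top, "spec") <- spec
  top
}

# NeRF placement: position of D given A-B-C, bond length |CD|, angle B-C-D
# (degrees) and dihedral A-B-C-D (radians)
.nerf <- function(a, b, c, bond, angle_deg, dihedral) {
  theta <- angle_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {  # collinear reference: pick any perpendicular
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- pracma::cross(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma::cross(n, bc)
  d2 <- c(-bond * cos(theta), bond * sin(theta) * cos(dihedral),
          bond * sin(theta) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build full cartesian coordinates from a dihedral state vector
.mimic_coords <- function(top, dihedrals) {
  spec <- attr(top, "spec")
  nl <- spec$n_linker_atoms
  ca <- attr(top, "body_coords_a")
  cb <- attr(top, "body_coords_b")
  na_block <- nrow(ca)                      # body A heavy atoms + protons
  nlh <- length(attr(top, "h_parents")$linker)
  idx_l <- na_block + seq_len(nl)
  n_total <- na_block + nl + nlh + nrow(cb)

  coords <- matrix(0, n_total, 3)
  coords[seq_len(na_block), ] <- ca
  anchor_a <- ca[1, ]
  # a fixed in-body reference gives the first dihedral a defined zero
  ref_a <- ca[2, ]
  bond <- 1.53
  angle <- 112

  chain <- matrix(0, nl, 3)
  chain[1, ] <- anchor_a + c(1.50, 0, 0)
  prev2 <- ref_a
  prev1 <- anchor_a
  cur <- chain[1, ]
  for (k in 2:nl) {
    nxt <- .nerf(prev2, prev1, cur, bond, angle, dihedrals[k - 1])
    chain[k, ] <- nxt
    prev2 <- prev1
    prev1 <- cur
    cur <- nxt
  }
  coords[idx_l, ] <- chain

  # linker protons: perpendicular offsets that ride with the chain
  lh_parents <- attr(top, "h_parents")$linker
  if (length(lh_parents) > 0L) {
    idx_lh <- na_block + nl + seq_along(lh_parents)
    for (m in seq_along(lh_parents)) {
      j <- lh_parents[m]
      prev <- if (j == 1L) anchor_a else chain[j - 1L, ]
      nxt <- chain[min(j + 1L, nl), ]
      v1 <- chain[j, ] - prev
      v2 <- nxt - chain[j, ]
      perp <- pracma::cross(v1, v2)
      np <- sqrt(sum(perp^2))
      if (np < 1e-8) {
        ref <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        perp <- pracma::cross(v1, ref)
        np <- sqrt(sum(perp^2))
      }
      coords[idx_lh[m], ] <- chain[j, ] + 1.09 * perp / np
    }
  }

  # anchor of body B continues the chain with one more dihedral
  anchor_b <- .nerf(prev2, prev1, cur, 1.50, angle, dihedrals[nl])
  # orient body B: local +x maps onto the direction anchor_b -> away from Ln,
  # with a spin dihedral about that axis
  axis <- anchor_b - cur
  axis <- axis / sqrt(sum(axis^2))
  ref <- prev1 - cur
  ref <- ref - sum(ref * axis) * axis
  nref <- sqrt(sum(ref^2))
  if (nref < 1e-10) ref <- c(0, 0, 1) else ref <- ref / nref
  y0 <- ref
  z0 <- pracma::cross(axis, y0)
  spin <- dihedrals[nl + 1]
  y <- cos(spin) * y0 + sin(spin) * z0
  z <- pracma::cross(axis, y)
  rot <- cbind(axis, y, z)          # local frame -> world
  placed <- t(rot %*% t(cb)) + matrix(anchor_b, nrow(cb), 3, byrow = TRUE)
  coords[(na_block + nl + nlh + 1):n_total, ] <- placed
  coords
}

# pseudo-energy bookkeeping shared across evaluations
.mimic_energy_context <- function(top) {
  region <- attr(top, "region")
  heavy <- which(top$elements != "H")
  polar <- top$elements %in% c("N", "O")
  sep <- .bond_separation(top, cap = 3L)
  pair <- which(upper.tri(matrix(0, n_atoms(top), n_atoms(top))),
                arr.ind = TRUE)
  i <- pair[, 1]
  j <- pair[, 2]
  keep <- top$elements[i] != "H" & top$elements[j] != "H"
  i <- i[keep]
  j <- j[keep]
  bonded_near <- sep[cbind(i, j)] <= 2
  # burial contacts: pairs with one atom in the linker and one in a ligand
  # body — hydrophobic collapse in these mimics is collapse *around the
  # linker*, so body-body contact carries no hydrophobic reward. The polar
  # penalty acts on buried polar *linker* atoms: the alkyl/PEG pair differs
  # exactly in the linker (the CH2-to-O swap), so for the PEG mimic every
  # collapse mode buries oxygens roughly in proportion to its hydrophobic
  # gain, frustrating collapse structurally rather than on average.
  in_linker_i <- region[i] == "linker"
  in_linker_j <- region[j] == "linker"
  cross <- xor(in_linker_i, in_linker_j)
  linker_polar <- (in_linker_i & polar[i]) | (in_linker_j & polar[j])
  list(i = i, j = j,
       clash_pairs = !bonded_near,
       cross_nonpolar = cross & !polar[i] & !polar[j] & !bonded_near,
       cross_polar = cross & linker_polar & !bonded_near,
       n_cross_nonpolar = max(1L, sum(cross & !polar[i] & !polar[j])),
       n_cross_polar = max(1L, sum(cross & linker_polar)))
}

.mimic_energy <- function(coords, ctx, solvent, clash_d0 = 2.9,
                          clash_k = 20, contact_d = 4.5) {
  dx <- coords[ctx$i, ] - coords[ctx$j, ]
  d <- sqrt(rowSums(dx^2))
  viol <- ctx$clash_pairs & d < clash_d0
  e_clash <- clash_k * sum((clash_d0 - d[viol])^2)
  burial <- sum(ctx$cross_nonpolar & d < contact_d) / ctx$n_cross_nonpolar
  polar_burial <- sum(ctx$cross_polar & d < contact_d) / ctx$n_cross_polar
  e_clash + solvent$hydrophobic_weight * burial +
    solvent$polar_exposure_weight * polar_burial
}

#' Sample solvent-dependent conformers of a PROTAC mimic
#'
#' Metropolis sampling over the linker dihedrals (plus the ligand-B
#' placement and spin angles) under the pseudo-energy
#' `E = E_clash + hydrophobic_weight * burial + polar_exposure_weight *
#' polar_burial`, where `E_clash` is a soft-sphere repulsion over nonbonded
#' heavy-atom pairs, `burial` is the normalized count of nonpolar
#' cross-region contacts within 4.5 Angstrom, and `polar_burial` the same
#' count for contacts involving a polar atom. With the `"water"` profile
#' the alkyl mimic collapses (low R_gyr) while the PEG mimic's polar linker
#' frustrates collapse; with the `"chloroform"` profile both sample their
#' intrinsic chain statistics. Deterministic given `seed`.
#'
#' @param topology Output of [build_protac_mimic()].
#' @param n Number of conformers to return.
#' @param solvent A [solvent_profile()].
#' @param seed Integer seed.
#' @param temperature Sampling temperature in Kelvin (default 300).
#' @param burn_in Discarded leading Metropolis steps per chain (default
#'   300).
#' @param thin Record every `thin`-th step after burn-in (default 5).
#' @param chains Independent Metropolis chains; the requested `n` is split
#'   across them (default 6). Multiple chains decorrelate the ensemble:
#'   a single chain revisits one basin for long stretches.
#' @return A [conformer_ensemble()] with per-conformer pseudo-energies
#'   (kcal/mol) and the solvent attached as metadata.
#' @export
sample_conformers <- function(topology, n = 600L,
                              solvent = solvent_profile("water"),
                              seed = 1L, temperature = 300,
                              burn_in = 300L, thin = 5L, chains = 6L) {
  stopifnot(inherits(topology, "molecule_topology"))
  if (is.null(attr(topology, "spec"))) {
    stop("topology was not built by build_protac_mimic()", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  spec <- attr(topology, "spec")
  ctx <- .mimic_energy_context(topology)
  chains <- max(1L, as.integer(chains))
  per_chain <- diff(round(seq(0, n, length.out = chains + 1L)))
  pieces <- lapply(seq_len(chains), function(ch) {
    if (per_chain[ch] == 0L) return(NULL)
    .sample_chain(topology, per_chain[ch], solvent, ctx,
                  seed = (seed * 113L + ch) %% .Machine$integer.max,
                  temperature = temperature, burn_in = burn_in, thin = thin)
  })
  pieces <- Filter(Negate(is.null), pieces)
  conformer_ensemble(topology,
                     do.call(c, lapply(pieces, `[[`, "coords")),
                     energies = do.call(c, lapply(pieces, `[[`, "energy")),
                     solvent = list(label = solvent$label,
                                    epsilon = solvent$epsilon))
}

.sample_chain <- function(topology, n, solvent, ctx, seed, temperature,
                          burn_in, thin) {
  spec <- attr(topology, "spec")
  ndof <- spec$n_linker_atoms + 1L
  kT <- .R_KCAL * temperature

  withr_seed_eval(seed, function() {
    state <- stats::runif(ndof, -pi, pi)  # independent random start
    coords <- .mimic_coords(topology, state)
    e <- .mimic_energy(coords, ctx, solvent)
    # the extended start must itself be clash-acceptable; if the bodies are
    # built so densely that even it clashes badly, sampling cannot start
    if (!is.finite(e)) stop("degenerate start geometry", call. = FALSE)
    out_coords <- vector("list", n)
    out_energy <- numeric(n)
    collected <- 0L
    step <- 0L
    max_steps <- burn_in + thin * n + 10000L
    while (collected < n) {
      step <- step + 1L
      if (step > max_steps) {
        stop("move budget exhausted after ", step, " steps with ",
             collected, "/", n, " conformers collected", call. = FALSE)
      }
      prop <- state
      k <- sample.int(ndof, 1L)
      prop[k] <- if (stats::runif(1) < 0.2) {
        stats::runif(1, -pi, pi)
      } else {
        ((prop[k] + stats::rnorm(1, 0, 1.0) + pi) %% (2 * pi)) - pi
      }
      pc <- .mimic_coords(topology, prop)
      pe <- .mimic_energy(pc, ctx, solvent)
      if (pe <= e || stats::runif(1) < exp(-(pe - e) / kT)) {
        state <- prop
        coords <- pc
        e <- pe
      }
      if (step > burn_in && (step - burn_in) %% thin == 0L) {
        collected <- collected + 1L
        out_coords[[collected]] <- coords
        out_energy[collected] <- e
      }
    }
    list(coords = out_coords, energy = out_energy)
  })
}

#' Simulate NOE restraints from known conformer populations
#'
#' Enumerates all pairs of tagged protons, computes each pair's r^-6
#' population-averaged distance under `true_populations`, drops pairs whose
#' averaged distance exceeds the observability ceiling (the NOE detection
#' limit, default 5 Angstrom), adds Gaussian noise, and returns both the
#' restraint table and the generating ground truth. Pairs within one ligand
#' body are classed `short`, pairs across the two bodies `long`.
#'
#' @param ensemble A [conformer_ensemble()] whose topology carries tagged
#'   protons (e.g. from [build_protac_mimic()] + [sample_conformers()]).
#' @param true_populations Simplex weights over the ensemble's conformers.
#' @param n_restraints Restraints to return (at most the number of
#'   observable pairs; fewer triggers a warning).
#' @param noise_sd Gaussian noise on the averaged distances, Angstrom.
#' @param seed Integer seed (noise and pair subsampling).
#' @param ceiling Observability ceiling in Angstrom (default 5.0).
#' @param exponent Averaging exponent (default 6).
#' @return List: `restraints` (a `noe_table`), `truth` (populations,
#'   noise-free distances, selected pair labels).
#' @export
simulate_noes <- function(ensemble, true_populations, n_restraints = 20L,
                          noise_sd = 0, seed = 1L, ceiling = 5.0,
                          exponent = 6) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  top <- ensemble$topology
  tagged <- which(!is.na(top$proton_labels))
  if (length(tagged) < 2L) stop("topology has no tagged protons",
                                call. = FALSE)
  w <- true_populations
  if (length(w) != n_conformers(ensemble) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9) {
    stop("true_populations must be simplex weights over the ensemble",
         call. = FALSE)
  }
  labels <- top$proton_labels[tagged]
  pairs <- t(utils::combn(seq_along(tagged), 2))
  d_true <- apply(pairs, 1, function(p) {
    di <- vapply(ensemble$coords, function(xyz) {
      sqrt(sum((xyz[tagged[p[1]], ] - xyz[tagged[p[2]], ])^2))
    }, 0.0)
    sum(w * di^(-exponent))^(-1 / exponent)
  })
  observable <- which(d_true <= ceiling)
  if (length(observable) == 0L) {
    warning("no proton pair falls under the observability ceiling",
            call. = FALSE)
    return(list(restraints = NULL,
                truth = list(populations = w, pairs = NULL, d_true = NULL)))
  }
  region <- attr(top, "region")
  cls <- apply(pairs, 1, function(p) {
    ri <- as.character(region[tagged[p[1]]])
    rj <- as.character(region[tagged[p[2]]])
    if (!is.null(region) && ri == rj) "short"
    else if (!is.null(region) && ri != rj &&
             all(c(ri, rj) %in% c("body_a", "body_b"))) "long"
    else "medium"
  })
  withr_seed_eval(seed, function() {
    take <- observable
    if (length(observable) > n_restraints) {
      # stratified pick spanning the range classes: long (inter-ligand)
      # first, then medium (linker-involving), then short fills the rest
      take <- integer(0)
      for (cl in c("long", "medium", "short")) {
        cand <- setdiff(observable[cls[observable] == cl], take)
        quota <- min(length(cand), ceiling(n_restraints / 3))
        if (length(cand) > 0L && quota > 0L) {
          take <- c(take, cand[sample.int(length(cand), quota)])
        }
      }
      remaining <- setdiff(observable, take)
      if (length(take) < n_restraints && length(remaining) > 0L) {
        take <- c(take, remaining[sample.int(length(remaining),
                                               min(length(remaining),
                                                   n_restraints - length(take)))])
      }
      take <- sort(take[seq_len(min(length(take), n_restraints))])
    } else if (length(observable) < n_restraints) {
      warning("only ", length(observable), " observable pairs for ",
              n_restraints, " requested restraints", call. = FALSE)
    }
    d_exp <- d_true[take] + stats::rnorm(length(take), 0, noise_sd)
    d_exp <- pmax(d_exp, 0.8)   # a physical lower bound on NOE distances
    restraints <- noe_restraints(
      atom_i = labels[pairs[take, 1]], atom_j = labels[pairs[take, 2]],
      d_exp = d_exp, range_class = cls[take])
    list(restraints = restraints,
         truth = list(populations = w,
                      pairs = cbind(labels[pairs[take, 1]],
                                    labels[pairs[take, 2]]),
                      d_true = d_true[take]))
  })
}
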