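# Per-conformer 3D size/polarity descriptors: radius of gyration,
# Shrake-Rupley SASA with a polar/nonpolar partition, intramolecular
# hydrogen-bond counts, fold classification, and the EPSA/TPSA ratio.

#' Radius of gyration
#'
#' \eqn{R_{gyr} = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}} with
#' weights \eqn{w_i} equal to atomic masses (`mode = "mass_weighted"`, the
#' molecular-dynamics convention and the default) or 1 (`"geometric"`), and
#' \eqn{\bar r} the weight-centred centroid. Invariant under rigid rotation
#' and translation.
#'
#' @param coords `N x 3` coordinate matrix (Angstrom).
#' @param masses Atomic masses (Da); required for mass weighting.
#' @param mode `"mass_weighted"` or `"geometric"`.
#' @param heavy_only Drop hydrogens before the sum (requires `elements`).
#' @param elements Element symbols, needed only when `heavy_only = TRUE`.
#' @return Radius of gyration in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), mode = "geometric")
#' @export
radius_of_gyration <- function(coords, masses = NULL,
                               mode = c("mass_weighted", "geometric"),
                               heavy_only = FALSE, elements = NULL) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("no atoms", call. = FALSE)
  if (heavy_only) {
    if (is.null(elements)) {
      stop("heavy_only = TRUE requires element symbols", call. = FALSE)
    }
    keep <- .normalize_element(elements) != "H"
    coords <- coords[keep, , drop = FALSE]
    if (!is.null(masses)) masses <- masses[keep]
    if (nrow(coords) == 0L) stop("no heavy atoms", call. = FALSE)
  }
  w <- if (mode == "mass_weighted") {
    if (is.null(masses)) stop("mass weighting requires masses", call. = FALSE)
    masses
  } else {
    rep(1, nrow(coords))
  }
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  ctr <- colSums(coords * w) / sum(w)
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the Shrake-Rupley rolling-probe method on a
#' deterministic Fibonacci sphere lattice: each atom's test sphere of radius
#' \eqn{r_i + probe} carries `n_sphere_points` lattice points, and its area
#' is \eqn{4\pi (r_i+probe)^2} times the fraction of points not buried in
#' any neighbour's expanded sphere. Deterministic: no randomness in the
#' lattice.
#'
#' @param coords `N x 3` coordinate matrix (Angstrom).
#' @param radii Van der Waals radii (Angstrom), positive.
#' @param probe_radius Solvent probe radius (Angstrom), default 1.4 (water).
#' @param n_sphere_points Lattice points per atom (>= 32); default 960.
#' @return Numeric vector of per-atom accessible areas (Angstrom^2); the
#'   total SASA is their sum.
#' @examples
#' # isolated atom: full sphere of radius r + probe
#' shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.7)
#' 4 * pi * (1.7 + 1.4)^2
#' @export
shrake_rupley_sasa <- function(coords, radii, probe_radius = 1.4,
                               n_sphere_points = 960L) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  stopifnot(length(radii) == nrow(coords))
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  if (probe_radius < 0) stop("probe_radius must be >= 0", call. = FALSE)
  if (n_sphere_points < 32L) {
    stop("n_sphere_points must be >= 32", call. = FALSE)
  }
  .sasa_shrake_rupley_cpp(coords, as.numeric(radii), probe_radius,
                          as.integer(n_sphere_points))
}

#' Polar-atom classification scheme
#'
#' A `polar_scheme` is a pure function of the topology (never of
#' coordinates): an atom is polar iff its element is in `polar_elements`,
#' or it is sulfur and `include_sulfur` is set, or it is a hydrogen bonded
#' to a polar heavy atom and `include_attached_hydrogens` is set. The
#' default (N, O plus attached H, no S) follows the common practice for 3D
#' polar surface areas; published tools differ in detail, so the scheme in
#' force is echoed into all outputs.
#'
#' @param polar_elements Character vector of polar heavy elements.
#' @param include_attached_hydrogens Count H bonded to a polar heavy atom
#'   as polar.
#' @param include_sulfur Treat S as polar.
#' @return An object of class `polar_scheme`.
#' @export
polar_scheme <- function(polar_elements = c("N", "O"),
                         include_attached_hydrogens = TRUE,
                         include_sulfur = FALSE) {
  structure(list(polar_elements = .normalize_element(polar_elements),
                 include_attached_hydrogens = include_attached_hydrogens,
                 include_sulfur = include_sulfur),
            class = "polar_scheme")
}

#' Classify atoms as polar or nonpolar
#'
#' @param topology A [molecule_topology()].
#' @param scheme A [polar_scheme()].
#' @return Logical mask, `TRUE` for polar atoms.
#' @export
classify_polar_atoms <- function(topology, scheme = polar_scheme()) {
  stopifnot(inherits(topology, "molecule_topology"),
            inherits(scheme, "polar_scheme"))
  el <- topology$elements
  polar <- el %in% scheme$polar_elements
  if (scheme$include_sulfur) polar <- polar | el == "S"
  if (scheme$include_attached_hydrogens) {
    h_idx <- which(el == "H")
    if (length(h_idx) > 0L) {
      b <- topology$bonds
      for (h in h_idx) {
        partners <- c(b[b[, 1] == h, 2], b[b[, 2] == h, 1])
        if (length(partners) == 0L) {
          stop("hydrogen atom ", h, " has no bond record; cannot apply the ",
               "attached-hydrogen polarity rule", call. = FALSE)
        }
        if (any(polar[partners])) polar[h] <- TRUE
      }
    }
  }
  polar
}

#' Partition SASA into polar and nonpolar components
#'
#' SA 3D PSA is the accessible area summed over polar atoms, SA 3D NPSA the
#' sum over the rest; the two add up to the total SASA exactly.
#'
#' @param per_atom_areas Per-atom SASA from [shrake_rupley_sasa()].
#' @param polar_mask Logical mask from [classify_polar_atoms()].
#' @return Named list with `sa3d_psa` and `sa3d_npsa` (Angstrom^2).
#' @export
partition_sasa <- function(per_atom_areas, polar_mask) {
  if (length(per_atom_areas) != length(polar_mask)) {
    stop("mask length (", length(polar_mask), ") != atom count (",
         length(per_atom_areas), ")", call. = FALSE)
  }
  list(sa3d_psa = sum(per_atom_areas[polar_mask]),
       sa3d_npsa = sum(per_atom_areas[!polar_mask]))
}

#' Count intramolecular hydrogen bonds
#'
#' Geometric criterion: donors are hydrogens bonded to N or O, acceptors are
#' N or O atoms not bonded to that hydrogen. A (D-H...A) contact counts when
#' the H...A distance is at most `donor_acceptor_cutoff` and the D-H...A
#' angle is at least `dha_angle_cutoff`, excluding pairs fewer than 3 bonds
#' apart (which cannot form a real hydrogen bond).
#'
#' @param coords `N x 3` coordinates (Angstrom).
#' @param topology A [molecule_topology()] with explicit hydrogens and bonds.
#' @param donor_acceptor_cutoff H...A distance cutoff, Angstrom (default 2.5).
#' @param dha_angle_cutoff D-H...A angle cutoff, degrees (default 120).
#' @return Integer count of intramolecular hydrogen bonds.
#' @export
count_imhb <- function(coords, topology, donor_acceptor_cutoff = 2.5,
                       dha_angle_cutoff = 120, .sep = NULL) {
  stopifnot(inherits(topology, "molecule_topology"))
  coords <- as.matrix(coords)
  el <- topology$elements
  h_idx <- which(el == "H")
  if (length(h_idx) == 0L) {
    warning("no hydrogens in topology; IMHB count is 0", call. = FALSE)
    return(0L)
  }
  b <- topology$bonds
  acceptors <- which(el %in% c("N", "O"))
  if (length(acceptors) == 0L) return(0L)
  sep <- if (is.null(.sep)) .bond_separation(topology, cap = 3L) else .sep
  count <- 0L
  for (h in h_idx) {
    partners <- c(b[b[, 1] == h, 2], b[b[, 2] == h, 1])
    donors <- partners[el[partners] %in% c("N", "O")]
    if (length(donors) == 0L) next
    d_atom <- donors[1]
    for (a in acceptors) {
      if (a == d_atom || a %in% partners) next
      if (sep[h, a] < 3) next  # covalent neighbourhood, not a hydrogen bond
      ha <- coords[a, ] - coords[h, ]
      dist_ha <- sqrt(sum(ha^2))
      if (dist_ha > donor_acceptor_cutoff) next
      hd <- coords[d_atom, ] - coords[h, ]
      cosang <- sum(ha * hd) / (dist_ha * sqrt(sum(hd^2)))
      angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (angle >= dha_angle_cutoff) count <- count + 1L
    }
  }
  count
}

#' Fold classification from the radius of gyration
#'
#' Conformations are binned into `folded`, `semifolded` and `extended` by
#' two thresholds on \eqn{R_{gyr}}. Defaults (7.0 and 9.5 Angstrom) place
#' the bands reported for PROTAC-sized molecules (folded around 5-7,
#' semifolded around 8, extended around 11 Angstrom); the bands scale with
#' molecular size, so both thresholds are configurable. A value exactly at
#' a threshold resolves to the more compact class.
#'
#' @param r_gyr Radius of gyration, Angstrom (vectorised).
#' @param folded_max Upper bound of the folded class (inclusive).
#' @param extended_min Lower bound of the extended class (inclusive).
#' @return Factor with ordered levels `folded < semifolded < extended`.
#' @export
fold_class <- function(r_gyr, folded_max = 7.0, extended_min = 9.5) {
  if (!(folded_max < extended_min)) {
    stop("folded_max must be < extended_min", call. = FALSE)
  }
  cls <- ifelse(r_gyr <= folded_max, "folded",
                ifelse(r_gyr >= extended_min, "extended", "semifolded"))
  factor(cls, levels = c("folded", "semifolded", "extended"), ordered = TRUE)
}

#' EPSA to TPSA ratio (ETR)
#'
#' Ratio of the experimental (chromatographic) polar surface area to the
#' topological polar surface area. Values well below 1 indicate that a
#' molecule shields much of its topological polarity in a nonpolar mobile
#' phase, the chameleonic signature. Both inputs are scalar 2D descriptors
#' supplied by the user.
#'
#' @param epsa Experimental polar surface area, Angstrom^2 (`>= 0`).
#' @param tpsa Topological polar surface area, Angstrom^2 (`> 0`).
#' @return Dimensionless ratio `epsa / tpsa`.
#' @export
etr <- function(epsa, tpsa) {
  if (any(tpsa <= 0)) stop("tpsa must be > 0", call. = FALSE)
  if (any(epsa < 0)) stop("epsa must be >= 0", call. = FALSE)
  epsa / tpsa
}

#' Per-conformer property table for an ensemble
#'
#' Computes, for every conformer: radius of gyration, total SASA, SA 3D PSA,
#' SA 3D NPSA, intramolecular hydrogen-bond count, and fold class; carries
#' populations through when attached to the ensemble.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param scheme A [polar_scheme()] for the SASA partition.
#' @param probe_radius,n_sphere_points Passed to [shrake_rupley_sasa()].
#' @param rgyr_mode Passed to [radius_of_gyration()] as `mode`.
#' @param folded_max,extended_min Passed to [fold_class()].
#' @param count_hbonds Set `FALSE` to skip the IMHB count (fills `NA`),
#'   e.g. for topologies without explicit hydrogens.
#' @return Data.frame of class `property_table` with one row per conformer
#'   and attribute `scheme` recording the polarity scheme and thresholds.
#' @export
conformer_properties <- function(ensemble, scheme = polar_scheme(),
                                 probe_radius = 1.4, n_sphere_points = 960L,
                                 rgyr_mode = "mass_weighted",
                                 folded_max = 7.0, extended_min = 9.5,
                                 count_hbonds = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  top <- ensemble$topology
  polar <- classify_polar_atoms(top, scheme)
  m <- n_conformers(ensemble)
  has_h <- any(top$elements == "H")
  do_imhb <- count_hbonds && has_h && nrow(top$bonds) > 0L
  sep <- if (do_imhb) .bond_separation(top, cap = 3L) else NULL
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    xyz <- ensemble$coords[[i]]
    areas <- shrake_rupley_sasa(xyz, top$radii, probe_radius, n_sphere_points)
    part <- partition_sasa(areas, polar)
    rg <- radius_of_gyration(xyz, top$masses, mode = rgyr_mode)
    imhb <- if (do_imhb) count_imhb(xyz, top, .sep = sep) else NA_integer_
    rows[[i]] <- data.frame(
      conformer_id = ensemble$conformer_ids[i], r_gyr = rg,
      sasa_total = sum(areas), sa3d_psa = part$sa3d_psa,
      sa3d_npsa = part$sa3d_npsa, imhb = imhb,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fold_class <- fold_class(out$r_gyr, folded_max, extended_min)
  out$population <- if (is.null(ensemble$populations)) NA_real_ else
    ensemble$populations
  attr(out, "scheme") <- list(
    polar_elements = scheme$polar_elements,
    include_attached_hydrogens = scheme$include_attached_hydrogens,
    include_sulfur = scheme$include_sulfur,
    probe_radius = probe_radius, n_sphere_points = n_sphere_points,
    rgyr_mode = rgyr_mode, folded_max = folded_max,
    extended_min = extended_min)
  class(out) <- c("property_table", "data.frame")
  out
}

#' Write a property table with its JSON sidecar
#'
#' Serializes the per-conformer descriptor table as tab-delimited text and
#' the polarity scheme/threshold metadata as a `.json` sidecar next to it.
#'
#' @param props A `property_table` from [conformer_properties()].
#' @param path Output path for the delimited table.
#' @export
write_property_table <- function(props, path) {
  utils::write.table(as.data.frame(props), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- attr(props, "scheme")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
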