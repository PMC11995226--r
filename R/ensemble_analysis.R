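# Clustering, Boltzmann population analysis, MEC identification, property
# landscapes and cross-solvent congruence comparison.

# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.987204e-3

#' Kabsch-superposed RMSD between two conformers
#'
#' Minimal root-mean-square deviation over all rigid superpositions: both
#' coordinate sets are centred, the optimal rotation is obtained from the
#' SVD of the covariance matrix with the determinant sign corrected to a
#' proper rotation, and the RMSD is evaluated after applying it. Symmetric
#' in its arguments.
#'
#' @param coords_a,coords_b `N x 3` coordinate matrices (Angstrom).
#' @param atom_subset Optional integer indices restricting the comparison
#'   (e.g. heavy atoms only).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b, atom_subset = NULL) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!is.null(atom_subset)) {
    a <- a[atom_subset, , drop = FALSE]
    b <- b[atom_subset, , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("atom counts differ", call. = FALSE)
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 atoms for superposition", call. = FALSE)
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  if (all(svd(a)$d[2:3] < 1e-10)) {
    stop("need at least 3 non-collinear atoms", call. = FALSE)
  }
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- b - a %*% t(rot)
  sqrt(sum(diff^2) / n)
}

#' Leader clustering of a conformer ensemble by RMSD
#'
#' Deterministic leader algorithm: conformers are visited in ascending
#' energy order (ties by id; by id when no energies are stored); each joins
#' the first existing cluster whose representative lies within `rmsd_cutoff`
#' (Kabsch RMSD on `atom_subset`, heavy atoms by default), otherwise it
#' founds a new cluster and becomes its representative. Because visiting is
#' energy-ordered, every representative is the lowest-energy member of its
#' cluster, and representatives are pairwise more than `rmsd_cutoff` apart.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param rmsd_cutoff Cluster radius in Angstrom (default 1.0).
#' @param atom_subset Optional indices for the RMSD; default all heavy atoms.
#' @return List of class `cluster_result`: `labels` (per-conformer cluster
#'   index, in the ensemble's conformer order), `representatives` (conformer
#'   index per cluster), `rmsd_cutoff`.
#' @export
cluster_ensemble <- function(ensemble, rmsd_cutoff = 1.0,
                             atom_subset = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (rmsd_cutoff < 0) stop("rmsd_cutoff must be >= 0", call. = FALSE)
  m <- n_conformers(ensemble)
  if (is.null(atom_subset)) {
    atom_subset <- which(ensemble$topology$elements != "H")
    if (length(atom_subset) < 3L) atom_subset <- seq_len(n_atoms(ensemble$topology))
  }
  ord <- if (is.null(ensemble$energies)) {
    seq_len(m)
  } else {
    order(ensemble$energies, seq_len(m))
  }
  labels <- integer(m)
  reps <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      r <- kabsch_rmsd(ensemble$coords[[i]], ensemble$coords[[reps[k]]],
                       atom_subset)
      if (r <= rmsd_cutoff) {
        labels[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      labels[i] <- length(reps)
    }
  }
  structure(list(labels = labels, representatives = reps,
                 rmsd_cutoff = rmsd_cutoff, atom_subset = atom_subset),
            class = "cluster_result")
}

#' Boltzmann populations from conformer energies
#'
#' \eqn{p_i = \exp(-(E_i - E_{min})/RT) / \sum_j \exp(-(E_j - E_{min})/RT)}
#' with \eqn{R = 1.987204 \times 10^{-3}} kcal/(mol K). The shift by the
#' minimum energy makes the exponentials numerically safe; the result is
#' exactly invariant under adding any constant to all energies.
#'
#' @param energies Conformer energies in kcal/mol (finite).
#' @param temperature Absolute temperature in Kelvin (default 300).
#' @return Simplex weights summing to 1.
#' @examples
#' boltzmann_populations(c(0, 0.5962 * log(2)))  # RT ln 2 gap -> 2/3, 1/3
#' @export
boltzmann_populations <- function(energies, temperature = 300) {
  if (length(energies) == 0L) stop("no energies supplied", call. = FALSE)
  if (any(!is.finite(energies))) stop("non-finite energies", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  x <- exp(-(energies - min(energies)) / (.R_KCAL * temperature))
  x / sum(x)
}

#' Conformers above a population threshold
#'
#' Indices of conformers whose population strictly exceeds `threshold`
#' (default 1%, the conventional reporting cut for low-energy conformations
#' after clustering and Boltzmann analysis).
#'
#' @param populations Simplex weights.
#' @param threshold Strict lower bound (default 0.01).
#' @return Integer indices (possibly empty, with a message).
#' @export
low_energy_subset <- function(populations, threshold = 0.01) {
  idx <- which(populations > threshold)
  if (length(idx) == 0L) {
    message("no conformer exceeds the population threshold of ", threshold)
  }
  idx
}

#' Minimum-energy conformation (MEC) of a clustered ensemble
#'
#' The MEC is the representative of the most-populated cluster, where a
#' cluster's population is the sum of its members' Boltzmann weights. Ties
#' resolve to the representative of lower energy, then to the lower
#' conformer index.
#'
#' @param cluster_result A [cluster_ensemble()] result.
#' @param populations Per-conformer simplex weights (same order as the
#'   ensemble used for clustering).
#' @param energies Optional per-conformer energies for tie-breaking.
#' @return List: `mec` (conformer index), `cluster` (its cluster index),
#'   `cluster_populations` (per-cluster summed weights).
#' @export
identify_mec <- function(cluster_result, populations, energies = NULL) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  labels <- cluster_result$labels
  if (length(populations) != length(labels)) {
    stop("populations length does not match clustered ensemble", call. = FALSE)
  }
  k <- length(cluster_result$representatives)
  cpop <- vapply(seq_len(k), function(c) sum(populations[labels == c]), 0.0)
  best <- which(cpop == max(cpop))
  if (length(best) > 1L) {
    reps <- cluster_result$representatives[best]
    if (!is.null(energies)) {
      best <- best[order(energies[reps], reps)]
    } else {
      best <- best[order(reps)]
    }
  }
  winner <- best[1]
  list(mec = cluster_result$representatives[winner], cluster = winner,
       cluster_populations = cpop)
}

#' Property-space landscape (weighted 2D histogram)
#'
#' Bins conformers in the (R_gyr, SA 3D PSA) plane — or any two columns of
#' a property table — into a normalized density grid. Bins are right-open
#' except the last, which is closed, so every in-range point lands in
#' exactly one cell.
#'
#' @param props A `property_table` (or data.frame with the named columns).
#' @param x,y Column names for the two axes.
#' @param bins Number of bins per axis (scalar or length-2), default 40.
#' @param weights Per-conformer weights; default uniform. Normalized
#'   internally.
#' @param x_range,y_range Optional axis ranges `c(lo, hi)`; default the data
#'   range (use a pooled range to put two ensembles on a common grid).
#' @return List of class `landscape_grid`: `x_edges`, `y_edges`, `density`
#'   (matrix, rows = x bins), summing to 1.
#' @export
property_landscape <- function(props, x = "r_gyr", y = "sa3d_psa",
                               bins = 40L, weights = NULL,
                               x_range = NULL, y_range = NULL) {
  xs <- props[[x]]
  ys <- props[[y]]
  if (is.null(xs) || is.null(ys)) {
    stop("property table lacks column '", if (is.null(xs)) x else y, "'",
         call. = FALSE)
  }
  if (any(!is.finite(xs)) || any(!is.finite(ys))) {
    stop("non-finite property values", call. = FALSE)
  }
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 1L)) stop("bins must be >= 1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(xs))
  stopifnot(length(weights) == length(xs))
  weights <- weights / sum(weights)
  pad_range <- function(r) {
    if (r[1] == r[2]) r + c(-0.5, 0.5) else r
  }
  if (is.null(x_range)) x_range <- pad_range(range(xs))
  if (is.null(y_range)) y_range <- pad_range(range(ys))
  x_edges <- seq(x_range[1], x_range[2], length.out = bins[1] + 1L)
  y_edges <- seq(y_range[1], y_range[2], length.out = bins[2] + 1L)
  bin_of <- function(v, edges) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    i[v < edges[1] | v > edges[length(edges)]] <- NA_integer_
    i
  }
  ix <- bin_of(xs, x_edges)
  iy <- bin_of(ys, y_edges)
  density <- matrix(0, bins[1], bins[2])
  keep <- !is.na(ix) & !is.na(iy)
  for (i in which(keep)) {
    density[ix[i], iy[i]] <- density[ix[i], iy[i]] + weights[i]
  }
  total <- sum(density)
  if (total > 0) density <- density / total
  structure(list(x_edges = x_edges, y_edges = y_edges, density = density),
            class = "landscape_grid")
}

#' Compare ensembles in two solvents for conformational congruence
#'
#' Quantifies molecular chameleonicity between a polar-solvent and an
#' apolar-solvent ensemble of the same molecule: population-weighted
#' centroid shifts in R_gyr and SA 3D PSA (apolar minus polar), the
#' landscape overlap coefficient \eqn{\sum \min(d_A, d_B)} on a common
#' grid, and a congruence verdict — congruent when the absolute R_gyr
#' shift is at most `max_delta_r_gyr` and the overlap is at least
#' `min_overlap`. A molecule whose apolar ensemble extends (positive R_gyr
#' shift) away from a collapsed polar ensemble is the non-congruent,
#' permeability-limited pattern.
#'
#' The comparison grid is deliberately coarser than the 40-bin landscape
#' export default: the overlap of two finite samples drawn from the same
#' distribution must read close to 1, and on a fine grid it is instead
#' dominated by multinomial sampling noise. Twelve bins per axis keep that
#' self-overlap above ~0.8 for ensembles of a few hundred conformers.
#'
#' @param props_polar,props_apolar `property_table`s from
#'   [conformer_properties()]; rows with `NA` population get uniform
#'   weights.
#' @param bins Bins per axis for the common comparison grid (default 12).
#' @param max_delta_r_gyr Congruence threshold on `|delta_r_gyr|`, Angstrom
#'   (default 1.5).
#' @param min_overlap Congruence threshold on landscape overlap (default
#'   0.5).
#' @return List of class `solvent_comparison`: `delta_r_gyr`,
#'   `delta_sa3d_psa`, `overlap`, `congruent`, `thresholds`, plus both
#'   landscape grids.
#' @export
compare_solvent_ensembles <- function(props_polar, props_apolar, bins = 12L,
                                      max_delta_r_gyr = 1.5,
                                      min_overlap = 0.5) {
  for (p in list(props_polar, props_apolar)) {
    if (nrow(p) == 0L) stop("empty property table", call. = FALSE)
  }
  wts <- function(p) {
    w <- p$population
    if (is.null(w) || all(is.na(w))) w <- rep(1, nrow(p))
    w / sum(w)
  }
  w_p <- wts(props_polar)
  w_a <- wts(props_apolar)
  centroid <- function(p, w, col) sum(w * p[[col]])
  delta_r <- centroid(props_apolar, w_a, "r_gyr") -
    centroid(props_polar, w_p, "r_gyr")
  delta_psa <- centroid(props_apolar, w_a, "sa3d_psa") -
    centroid(props_polar, w_p, "sa3d_psa")
  x_range <- range(c(props_polar$r_gyr, props_apolar$r_gyr))
  y_range <- range(c(props_polar$sa3d_psa, props_apolar$sa3d_psa))
  grid_p <- property_landscape(props_polar, bins = bins, weights = w_p,
                               x_range = x_range, y_range = y_range)
  grid_a <- property_landscape(props_apolar, bins = bins, weights = w_a,
                               x_range = x_range, y_range = y_range)
  overlap <- sum(pmin(grid_p$density, grid_a$density))
  structure(list(
    delta_r_gyr = delta_r, delta_sa3d_psa = delta_psa, overlap = overlap,
    congruent = (abs(delta_r) <= max_delta_r_gyr && overlap >= min_overlap),
    thresholds = list(max_delta_r_gyr = max_delta_r_gyr,
                      min_overlap = min_overlap, bins = bins),
    landscape_polar = grid_p, landscape_apolar = grid_a),
    class = "solvent_comparison")
}

#' @export
print.solvent_comparison <- function(x, ...) {
  cat("solvent_comparison:\n")
  cat(sprintf("  delta R_gyr (apolar - polar): %+.3f A\n", x$delta_r_gyr))
  cat(sprintf("  delta SA 3D PSA:              %+.2f A^2\n", x$delta_sa3d_psa))
  cat(sprintf("  landscape overlap:            %.3f\n", x$overlap))
  cat("  verdict:", if (x$congruent) "congruent" else "non-congruent",
      sprintf("(|dRg| <= %.2f A and overlap >= %.2f)\n",
              x$thresholds$max_delta_r_gyr, x$thresholds$min_overlap))
  invisible(x)
}
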