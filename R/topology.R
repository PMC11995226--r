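# Domain containers: MoleculeTopology and Ensemble.

# Bondi (1964) van der Waals radii, Angstrom. Elements outside this table are
# a hard error: silently defaulting a radius corrupts every SASA downstream.
.BONDI_RADII <- c(
  H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, As = 1.85, Se = 1.90,
  Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98, Xe = 2.16
)

# Standard atomic weights (Da) for the same element set.
.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Ne = 20.180, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798, Te = 127.60,
  I = 126.90, Xe = 131.29
)

.normalize_element <- function(el) {
  el <- trimws(as.character(el))
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

.element_property <- function(elements, table, what) {
  elements <- .normalize_element(elements)
  unknown <- setdiff(unique(elements), names(table))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " (no ", what, " available; extend the element table explicitly)",
         call. = FALSE)
  }
  unname(table[elements])
}

#' Van der Waals radii and masses by element
#'
#' Look up Bondi (1964) van der Waals radii or standard atomic masses for a
#' vector of element symbols. Elements missing from the internal table raise
#' an error rather than receiving a silent default.
#'
#' @param elements Character vector of element symbols (case-insensitive).
#' @return Numeric vector (Angstrom for radii, Dalton for masses).
#' @examples
#' vdw_radius(c("C", "O", "H"))
#' atomic_mass("N")
#' @export
vdw_radius <- function(elements) {
  .element_property(elements, .BONDI_RADII, "van der Waals radius")
}

#' @rdname vdw_radius
#' @export
atomic_mass <- function(elements) {
  .element_property(elements, .ATOMIC_MASSES, "atomic mass")
}

#' Construct a molecule topology
#'
#' A `molecule_topology` holds the per-atom constants shared by every
#' conformer of an ensemble: element symbols, masses, van der Waals radii,
#' a polarity flag (usually assigned later by [classify_polar_atoms()]),
#' the bond list, and optional text labels tagging NOE-active protons.
#'
#' @param elements Character vector of element symbols; atoms are indexed
#'   `1..n` in this order.
#' @param bonds Two-column integer matrix of 1-based atom indices (may have
#'   zero rows).
#' @param proton_labels Optional named character vector: `names` are labels,
#'   values are atom indices (as character or integer) of NOE-active
#'   hydrogens; or a character vector of length `n` with `NA` for untagged
#'   atoms.
#' @param is_polar Optional logical vector of length `n`; defaults to all
#'   `FALSE` (assign later with [classify_polar_atoms()]).
#' @param masses,radii Optional numeric overrides; by default derived from
#'   the element symbols.
#' @return An object of class `molecule_topology`.
#' @examples
#' top <- molecule_topology(c("O", "H", "H"),
#'                          bonds = rbind(c(1, 2), c(1, 3)))
#' top$radii
#' @export
molecule_topology <- function(elements, bonds = matrix(integer(), ncol = 2),
                              proton_labels = NULL, is_polar = NULL,
                              masses = NULL, radii = NULL) {
  elements <- .normalize_element(elements)
  n <- length(elements)
  if (n < 1L) stop("topology needs at least one atom", call. = FALSE)
  if (is.null(masses)) masses <- atomic_mass(elements)
  if (is.null(radii)) radii <- vdw_radius(elements)
  stopifnot(length(masses) == n, length(radii) == n)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (any(radii <= 0)) stop("vdw radii must be positive", call. = FALSE)

  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0L) {
    if (any(bonds < 1L | bonds > n)) {
      stop("bond references atom outside 1..", n, call. = FALSE)
    }
    if (any(bonds[, 1] == bonds[, 2])) {
      stop("bond connects an atom to itself", call. = FALSE)
    }
  }

  labels <- rep(NA_character_, n)
  if (!is.null(proton_labels)) {
    if (!is.null(names(proton_labels))) {
      idx <- as.integer(proton_labels)
      if (any(is.na(idx)) || any(idx < 1L | idx > n)) {
        stop("proton_labels indices must lie in 1..", n, call. = FALSE)
      }
      labels[idx] <- names(proton_labels)
    } else {
      stopifnot(length(proton_labels) == n)
      labels <- as.character(proton_labels)
    }
  }
  if (is.null(is_polar)) is_polar <- rep(FALSE, n)
  stopifnot(length(is_polar) == n)

  structure(
    list(elements = elements, masses = masses, radii = radii,
         is_polar = as.logical(is_polar), bonds = bonds,
         proton_labels = labels),
    class = "molecule_topology"
  )
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat("molecule_topology:", length(x$elements), "atoms,",
      nrow(x$bonds), "bonds,", sum(!is.na(x$proton_labels)),
      "tagged protons\n")
  tab <- table(x$elements)
  cat("  composition:", paste(names(tab), tab, sep = "", collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(topology) length(topology$elements)

# Bond-graph distances up to a small cap, used for IMHB / clash exclusions.
# Returns an n x n integer matrix with Inf beyond `cap` bonds.
.bond_separation <- function(topology, cap = 4L) {
  n <- n_atoms(topology)
  adj <- vector("list", n)
  b <- topology$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  for (start in seq_len(n)) {
    frontier <- start
    d <- 0L
    while (length(frontier) > 0L && d < cap) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[sep[start, nxt] > d]
      sep[start, nxt] <- d
      frontier <- nxt
    }
  }
  sep
}

#' Construct a conformer ensemble
#'
#' Bundles a shared [molecule_topology()] with `N` conformer coordinate sets,
#' optional per-conformer energies (kcal/mol), a solvent annotation (label
#' plus dielectric constant, metadata only), and optional population weights
#' on the probability simplex.
#'
#' @param topology A `molecule_topology`.
#' @param coords List of `n_atoms x 3` numeric matrices (Angstrom).
#' @param energies Optional numeric vector of conformer energies (kcal/mol).
#' @param conformer_ids Optional character/integer ids; default `1..N`.
#' @param solvent Optional list with elements `label` and `epsilon`
#'   (dielectric constant), e.g. `list(label = "chloroform", epsilon = 4.8)`.
#' @param populations Optional nonnegative weights summing to 1.
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(topology, coords, energies = NULL,
                               conformer_ids = NULL, solvent = NULL,
                               populations = NULL) {
  stopifnot(inherits(topology, "molecule_topology"))
  if (!is.list(coords) || length(coords) < 1L) {
    stop("ensemble needs at least one conformer", call. = FALSE)
  }
  n <- n_atoms(topology)
  for (i in seq_along(coords)) {
    ci <- as.matrix(coords[[i]])
    if (nrow(ci) != n || ncol(ci) != 3L) {
      stop("conformer ", i, " has ", nrow(ci), " atoms; topology has ", n,
           call. = FALSE)
    }
    if (any(!is.finite(ci))) {
      stop("conformer ", i, " contains non-finite coordinates", call. = FALSE)
    }
    coords[[i]] <- ci
  }
  m <- length(coords)
  if (!is.null(energies)) {
    stopifnot(length(energies) == m)
    if (any(!is.finite(energies))) stop("non-finite energies", call. = FALSE)
  }
  if (is.null(conformer_ids)) conformer_ids <- seq_len(m)
  stopifnot(length(conformer_ids) == m)
  if (!is.null(populations)) {
    stopifnot(length(populations) == m)
    if (any(populations < 0)) stop("populations must be >= 0", call. = FALSE)
    if (abs(sum(populations) - 1) > 1e-9) {
      stop("populations must sum to 1 (got ", format(sum(populations)), ")",
           call. = FALSE)
    }
  }
  structure(
    list(topology = topology, coords = coords, energies = energies,
         conformer_ids = conformer_ids, solvent = solvent,
         populations = populations),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", length(x$coords), "conformers x",
      n_atoms(x$topology), "atoms\n")
  if (!is.null(x$solvent)) {
    cat("  solvent:", x$solvent$label,
        sprintf("(epsilon = %.3g)\n", x$solvent$epsilon))
  }
  if (!is.null(x$energies)) {
    cat(sprintf("  energies: %.3f .. %.3f kcal/mol\n",
                min(x$energies), max(x$energies)))
  }
  if (!is.null(x$populations)) cat("  populations attached\n")
  invisible(x)
}

n_conformers <- function(ensemble) length(ensemble$coords)
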