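# Readers/writers for multi-conformer structures (multi-model PDB, SDF V2000,
# multi-frame XYZ) and NOE restraint tables.
#
# Conventions (fixed, no autodetection): coordinates in Angstrom, energies in
# kcal/mol. PDB parsing/writing delegates to bio3d; SDF parsing to ChemmineR
# (the V2000 serializer is local because ChemmineR's writer emits free-width
# atom lines that valid V2000 consumers reject); XYZ has no installed reader
# and is parsed here.

#' Read a multi-conformer ensemble from file
#'
#' Parses a multi-model PDB (`MODEL`/`ENDMDL` blocks), a multi-record SDF
#' (V2000; each record one conformer of the same molecule), or a multi-frame
#' XYZ file into a [conformer_ensemble()]. Element-derived masses and Bondi
#' van der Waals radii are assigned from the element symbols. Per-conformer
#' energies are captured from an SDF `<energy>` data field, an XYZ comment
#' line containing `energy=<value>` (kcal/mol), or a PDB
#' `REMARK ENERGY <value>` line inside the model block.
#'
#' @param path Path to the structure file.
#' @param format One of `"pdb_multimodel"`, `"sdf"`, `"xyz"`.
#' @return A [conformer_ensemble()]. Bond records are available from SDF
#'   only; PDB and XYZ yield a bondless topology.
#' @seealso [write_ensemble()]
#' @export
read_ensemble <- function(path, format = c("pdb_multimodel", "sdf", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  switch(format,
         pdb_multimodel = .read_pdb_multimodel(path),
         sdf = .read_sdf(path),
         xyz = .read_xyz(path))
}

#' Write a multi-conformer ensemble to file
#'
#' Inverse of [read_ensemble()]: the written file re-reads to the same
#' ensemble up to format coordinate precision (PDB/SDF/XYZ all serialize
#' coordinates with at least 4 decimals). Energies are serialized where the
#' format allows (SDF data field, XYZ comment, PDB REMARK).
#'
#' @inheritParams read_ensemble
#' @param ensemble A [conformer_ensemble()].
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path,
                           format = c("pdb_multimodel", "sdf", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (n_conformers(ensemble) < 1L) {
    stop("refusing to write an empty ensemble", call. = FALSE)
  }
  ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE,
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot write to path: ", path, call. = FALSE)
  switch(format,
         pdb_multimodel = .write_pdb_multimodel(ensemble, path),
         sdf = .write_sdf(ensemble, path),
         xyz = .write_xyz(ensemble, path))
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

# Pre-scan: model atom counts (to name a mismatching model in the error, which
# bio3d's reader cannot), REMARK ENERGY lines, altloc/occupancy notice.
.scan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {  # single implicit model
    model_of <- ifelse(is_atom, 1L, NA_integer_)
  } else {
    model_of <- findInterval(seq_along(lines), model_starts)
    model_of[!is_atom | model_of == 0L] <- NA_integer_
  }
  counts <- table(model_of[is_atom])
  if (length(counts) > 1L && length(unique(as.integer(counts))) > 1L) {
    ref <- as.integer(counts[1])
    bad <- names(counts)[as.integer(counts) != ref][1]
    stop("model ", bad, " has ", counts[[bad]], " atoms; model 1 has ", ref,
         call. = FALSE)
  }
  altloc <- substr(lines[is_atom], 17, 17)
  if (any(altloc != " " & altloc != "")) {
    warning("PDB altloc indicators present; ignored", call. = FALSE)
  }
  energies <- NULL
  erows <- grep("^REMARK ENERGY", lines)
  if (length(erows) > 0L) {
    energies <- as.numeric(sub("^REMARK ENERGY\\s+", "", lines[erows]))
  }
  list(n_models = max(1L, length(model_starts)), energies = energies)
}

.read_pdb_multimodel <- function(path) {
  scan <- .scan_pdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elements <- pdb$atom$elesy
  if (any(is.na(elements) | elements == "")) {
    # fall back to first character of the atom name, the pre-element PDB habit
    nm <- trimws(pdb$atom$elety)
    elements <- ifelse(is.na(elements) | elements == "",
                       substr(nm, 1, 1), elements)
  }
  top <- molecule_topology(elements)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  energies <- scan$energies
  if (!is.null(energies) && length(energies) != length(coords)) energies <- NULL
  conformer_ensemble(top, coords, energies = energies)
}

.write_pdb_multimodel <- function(ensemble, path) {
  top <- ensemble$topology
  n <- n_atoms(top)
  elety <- paste0(top$elements, seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_conformers(ensemble))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    if (!is.null(ensemble$energies)) {
      writeLines(sprintf("REMARK ENERGY %.6f", ensemble$energies[i]), con)
    }
    xyz <- ensemble$coords[[i]]
    writeLines(sprintf(
      "ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n), substr(elety, 1, 4), xyz[, 1], xyz[, 2], xyz[, 3],
      toupper(top$elements)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

# ---- SDF (V2000) ----------------------------------------------------------

.read_sdf <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  m <- length(sdfs)
  if (m < 1L) stop("no SDF records in ", path, call. = FALSE)
  first_ab <- ChemmineR::atomblock(sdfs[[1]])
  n <- nrow(first_ab)
  elements_of <- function(ab) sub("_.*$", "", rownames(ab))
  elements <- elements_of(first_ab)
  bb <- ChemmineR::bondblock(sdfs[[1]])
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(integer(), ncol = 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  if (nrow(bonds) > 0L) {
    # a bond-free counts line makes ChemmineR emit a zero row; drop any row
    # that does not reference two real atoms
    ok <- bonds[, 1] >= 1L & bonds[, 2] >= 1L & bonds[, 1] <= n &
      bonds[, 2] <= n & bonds[, 1] != bonds[, 2]
    bonds <- bonds[ok, , drop = FALSE]
  }
  top <- molecule_topology(elements, bonds = bonds)
  coords <- vector("list", m)
  energies <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    if (nrow(ab) != n) {
      stop("SDF record ", i, " has ", nrow(ab), " atoms; record 1 has ", n,
           call. = FALSE)
    }
    if (!identical(elements_of(ab), elements)) {
      stop("SDF record ", i, " atom ordering differs from record 1",
           call. = FALSE)
    }
    coords[[i]] <- unname(ab[, 1:3, drop = FALSE])
    db <- ChemmineR::datablock(sdfs[[i]])
    if ("energy" %in% names(db)) energies[i] <- as.numeric(db[["energy"]])
  }
  if (anyNA(energies)) energies <- NULL
  conformer_ensemble(top, coords, energies = energies)
}

.write_sdf <- function(ensemble, path) {
  top <- ensemble$topology
  n <- n_atoms(top)
  b <- top$bonds
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_conformers(ensemble))) {
    xyz <- ensemble$coords[[i]]
    writeLines(c(
      paste0("conf_", ensemble$conformer_ids[i]), "  chamscope", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], top$elements)), con)
    if (nrow(b) > 0L) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], 1L), con)
    }
    writeLines("M  END", con)
    if (!is.null(ensemble$energies)) {
      writeLines(c(">  <energy>", sprintf("%.6f", ensemble$energies[i]), ""),
                 con)
    }
    writeLines("$$$$", con)
  }
}

# ---- XYZ ------------------------------------------------------------------

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     c("", lines[-length(lines)]) == "")]
  pos <- 1L
  frames <- list()
  comments <- character()
  frame <- 0L
  n_ref <- NA_integer_
  elements_ref <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) {
      stop("XYZ frame ", frame, ": bad atom-count line '", lines[pos], "'",
           call. = FALSE)
    }
    if (pos + 1L + n > length(lines)) {
      stop("XYZ frame ", frame, " truncated", call. = FALSE)
    }
    if (!is.na(n_ref) && n != n_ref) {
      stop("XYZ frame ", frame, " has ", n, " atoms; frame 1 has ", n_ref,
           call. = FALSE)
    }
    n_ref <- n
    comments <- c(comments, lines[pos + 1L])
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) < 4L)) {
      stop("XYZ frame ", frame, ": atom line with fewer than 4 fields",
           call. = FALSE)
    }
    el <- vapply(fields, `[`, "", 1L)
    if (is.null(elements_ref)) {
      elements_ref <- el
    } else if (!identical(.normalize_element(el),
                          .normalize_element(elements_ref))) {
      stop("XYZ frame ", frame, " atom ordering differs from frame 1",
           call. = FALSE)
    }
    xyz <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) stop("XYZ frame ", frame, ": non-numeric coordinate",
                         call. = FALSE)
    frames[[frame]] <- xyz
    pos <- pos + 2L + n
  }
  if (frame == 0L) stop("no XYZ frames in ", path, call. = FALSE)
  energies <- suppressWarnings(
    as.numeric(sub(".*energy=([-0-9.eE+]+).*", "\\1", comments)))
  if (anyNA(energies)) energies <- NULL
  top <- molecule_topology(elements_ref)
  conformer_ensemble(top, frames, energies = energies)
}

.write_xyz <- function(ensemble, path) {
  top <- ensemble$topology
  n <- n_atoms(top)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_conformers(ensemble))) {
    comment <- paste0("conf_", ensemble$conformer_ids[i])
    if (!is.null(ensemble$energies)) {
      comment <- paste0(comment,
                        sprintf(" energy=%.6f", ensemble$energies[i]))
    }
    xyz <- ensemble$coords[[i]]
    writeLines(c(as.character(n), comment,
                 sprintf("%-3s %14.8f %14.8f %14.8f",
                         top$elements, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
}

# ---- NOE restraint tables -------------------------------------------------

#' Read an NOE restraint table
#'
#' Reads a comma- or tab-delimited text table with header columns `atom_i`,
#' `atom_j`, `distance` and optionally `tolerance` and `range_class`. Each
#' data row becomes one restraint. When the tolerance column is absent a
#' default of `default_tolerance_frac * distance` is applied (10% by
#' default, the typical NOE calibration uncertainty).
#'
#' @param path Path to the delimited file (delimiter sniffed from the
#'   header: tab if present, else comma).
#' @param default_tolerance_frac Fractional tolerance applied when the
#'   `tolerance` column is missing.
#' @param range_class_map Optional named character vector mapping atom
#'   labels to groups; when the `range_class` column is absent, a restraint
#'   is classed `"short"` if both protons map to the same group, `"long"`
#'   otherwise, and `"medium"` when either label is unmapped.
#' @return A data.frame of class `noe_table` with columns `atom_i`,
#'   `atom_j`, `d_exp`, `tolerance`, `range_class`.
#' @export
read_noe_table <- function(path, default_tolerance_frac = 0.10,
                           range_class_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("atom_i", "atom_j", "distance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("NOE table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  noe_restraints(
    atom_i = df$atom_i, atom_j = df$atom_j, d_exp = df$distance,
    tolerance = if ("tolerance" %in% names(df)) df$tolerance else NULL,
    range_class = if ("range_class" %in% names(df)) df$range_class else NULL,
    default_tolerance_frac = default_tolerance_frac,
    range_class_map = range_class_map)
}

#' Construct NOE restraints
#'
#' Validating constructor behind [read_noe_table()]; also usable directly.
#'
#' @param atom_i,atom_j Atom indices or proton group labels.
#' @param d_exp Experimental distances (Angstrom), strictly positive.
#' @param tolerance Optional tolerances (Angstrom), `>= 0`.
#' @param range_class Optional classes among `short`, `medium`, `long`.
#' @inheritParams read_noe_table
#' @return A data.frame of class `noe_table`.
#' @export
noe_restraints <- function(atom_i, atom_j, d_exp, tolerance = NULL,
                           range_class = NULL,
                           default_tolerance_frac = 0.10,
                           range_class_map = NULL) {
  n <- length(d_exp)
  stopifnot(length(atom_i) == n, length(atom_j) == n)
  bad <- which(!is.finite(d_exp) | d_exp <= 0)
  if (length(bad) > 0L) {
    stop("non-positive NOE distance in row ", bad[1], " (d = ",
         d_exp[bad[1]], ")", call. = FALSE)
  }
  same <- which(as.character(atom_i) == as.character(atom_j))
  if (length(same) > 0L) {
    stop("restraint row ", same[1], " pairs an atom with itself",
         call. = FALSE)
  }
  if (is.null(tolerance)) {
    tolerance <- default_tolerance_frac * d_exp
  } else {
    stopifnot(length(tolerance) == n)
    if (any(tolerance < 0)) stop("negative tolerance", call. = FALSE)
  }
  if (is.null(range_class)) {
    if (is.null(range_class_map)) {
      range_class <- rep("medium", n)
    } else {
      gi <- range_class_map[as.character(atom_i)]
      gj <- range_class_map[as.character(atom_j)]
      range_class <- ifelse(is.na(gi) | is.na(gj), "medium",
                            ifelse(gi == gj, "short", "long"))
    }
  } else {
    range_class <- match.arg(as.character(range_class),
                             c("short", "medium", "long"),
                             several.ok = TRUE)
    stopifnot(length(range_class) == n)
  }
  key <- apply(cbind(pmin(as.character(atom_i), as.character(atom_j)),
                     pmax(as.character(atom_i), as.character(atom_j))),
               1, paste, collapse = "|")
  if (anyDuplicated(key)) {
    warning("duplicate NOE pair(s) kept: ",
            paste(unique(key[duplicated(key)]), collapse = "; "),
            call. = FALSE)
  }
  structure(
    data.frame(atom_i = atom_i, atom_j = atom_j, d_exp = d_exp,
               tolerance = tolerance, range_class = range_class,
               stringsAsFactors = FALSE),
    class = c("noe_table", "data.frame"))
}

#' Write an NOE restraint table
#'
#' @param restraints A `noe_table` from [noe_restraints()].
#' @param path Output path (tab-delimited, with header).
#' @export
write_noe_table <- function(restraints, path) {
  df <- as.data.frame(restraints)
  names(df)[names(df) == "d_exp"] <- "distance"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
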