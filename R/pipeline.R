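# End-to-end workflows: the chameleonicity analysis (descriptors ->
# clustering -> Boltzmann populations -> MEC -> landscapes -> cross-solvent
# comparison) and the NAMFIS workflow (distance matrix -> population fit ->
# jackknife -> fold-class summary). Both are plain functions returning the
# report object and, when an output directory is given, writing tables,
# structures and a JSON report.

#' Run the full chameleonicity analysis on a polar/apolar ensemble pair
#'
#' Executes, for each solvent ensemble: per-conformer 3D descriptors,
#' RMSD leader clustering, Boltzmann population analysis of the conformer
#' energies, the strict greater-than-1% low-energy subset, MEC
#' identification, and the property-space landscape; then compares the two
#' ensembles for conformational congruence. Landscape densities and the
#' property-space centroids use uniform conformer weights — for
#' Boltzmann-sampled ensembles (Metropolis or MD frames) the sampling
#' already carries the thermodynamic weighting, so frame density is the
#' populated property space. Cluster populations, the low-energy subset and
#' the MEC use the Boltzmann weights of the stored energies.
#'
#' @param ensemble_polar,ensemble_apolar [conformer_ensemble()]s of the same
#'   molecule in the polar and apolar environment (must carry energies).
#' @param scheme [polar_scheme()] for the SASA partition.
#' @param rmsd_cutoff Leader-clustering radius, Angstrom (default 1.0).
#' @param temperature Boltzmann temperature, Kelvin (default 300).
#' @param population_threshold Strict cut for the low-energy subset
#'   (default 0.01).
#' @param bins Landscape export bins per axis (default 40).
#' @param comparison_bins Bins per axis for the congruence comparison grid
#'   (default 12; see [compare_solvent_ensembles()]).
#' @param max_delta_r_gyr,min_overlap Congruence thresholds (defaults 1.5
#'   Angstrom, 0.5).
#' @param n_sphere_points SASA lattice size (default 960).
#' @param out_dir Optional output directory: property tables, landscape
#'   matrices, MEC structures (multi-model PDB) and `report.json` are
#'   written there.
#' @return List of class `chameleonicity_report` with the per-solvent
#'   stages, the [compare_solvent_ensembles()] verdict, and every default
#'   echoed under `$config`.
#' @export
run_chameleonicity_analysis <- function(ensemble_polar, ensemble_apolar,
                                        scheme = polar_scheme(),
                                        rmsd_cutoff = 1.0,
                                        temperature = 300,
                                        population_threshold = 0.01,
                                        bins = 40L,
                                        comparison_bins = 12L,
                                        max_delta_r_gyr = 1.5,
                                        min_overlap = 0.5,
                                        n_sphere_points = 960L,
                                        out_dir = NULL) {
  stage <- function(label, ens) {
    if (is.null(ens$energies)) {
      stop("stage '", label, "': ensemble has no energies; Boltzmann ",
           "population analysis needs them", call. = FALSE)
    }
    props <- conformer_properties(ens, scheme = scheme,
                                  n_sphere_points = n_sphere_points)
    clus <- cluster_ensemble(ens, rmsd_cutoff = rmsd_cutoff)
    pop <- boltzmann_populations(ens$energies, temperature)
    mec <- identify_mec(clus, pop, ens$energies)
    subset <- low_energy_subset(mec$cluster_populations,
                                population_threshold)
    grid <- property_landscape(props, bins = bins)
    list(label = label, properties = props, clusters = clus,
         populations = pop, mec = mec, low_energy_clusters = subset,
         landscape = grid,
         mec_properties = props[mec$mec, , drop = FALSE])
  }
  polar <- stage("polar", ensemble_polar)
  apolar <- stage("apolar", ensemble_apolar)
  comparison <- compare_solvent_ensembles(
    polar$properties, apolar$properties, bins = comparison_bins,
    max_delta_r_gyr = max_delta_r_gyr, min_overlap = min_overlap)
  config <- list(
    scheme = attr(polar$properties, "scheme"), rmsd_cutoff = rmsd_cutoff,
    temperature = temperature, population_threshold = population_threshold,
    bins = bins, comparison_bins = comparison_bins,
    max_delta_r_gyr = max_delta_r_gyr,
    min_overlap = min_overlap, n_sphere_points = n_sphere_points)
  report <- structure(list(polar = polar, apolar = apolar,
                           comparison = comparison, config = config),
                      class = "chameleonicity_report")
  if (!is.null(out_dir)) .write_chameleonicity_outputs(
    report, ensemble_polar, ensemble_apolar, out_dir)
  report
}

.write_chameleonicity_outputs <- function(report, ens_p, ens_a, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("polar", "apolar")) {
    st <- report[[side]]
    write_property_table(st$properties,
                         file.path(out_dir, paste0("properties_", side,
                                                   ".tsv")))
    utils::write.table(st$landscape$density,
                       file.path(out_dir, paste0("landscape_", side, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    ens <- if (side == "polar") ens_p else ens_a
    mec_ens <- conformer_ensemble(ens$topology,
                                  ens$coords[st$mec$mec],
                                  energies = ens$energies[st$mec$mec],
                                  solvent = ens$solvent)
    write_ensemble(mec_ens, file.path(out_dir, paste0("mec_", side, ".pdb")),
                   "pdb_multimodel")
  }
  summary_of <- function(st) list(
    n_conformers = length(st$populations),
    n_clusters = length(st$clusters$representatives),
    mec_conformer = st$mec$mec,
    mec_r_gyr = st$mec_properties$r_gyr,
    mec_sa3d_psa = st$mec_properties$sa3d_psa,
    mec_sa3d_npsa = st$mec_properties$sa3d_npsa,
    mean_r_gyr = mean(st$properties$r_gyr),
    low_energy_clusters = st$low_energy_clusters)
  cmp <- report$comparison
  jsonlite::write_json(list(
    config = report$config,
    polar = summary_of(report$polar),
    apolar = summary_of(report$apolar),
    comparison = list(delta_r_gyr = cmp$delta_r_gyr,
                      delta_sa3d_psa = cmp$delta_sa3d_psa,
                      overlap = cmp$overlap, congruent = cmp$congruent,
                      thresholds = cmp$thresholds)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.chameleonicity_report <- function(x, ...) {
  cat("chameleonicity analysis\n")
  for (side in c("polar", "apolar")) {
    st <- x[[side]]
    cat(sprintf(
      "  %-6s %d conformers, %d clusters, MEC conf %d (R_gyr %.2f A, SA 3D PSA %.1f A^2)\n",
      st$label, length(st$populations),
      length(st$clusters$representatives), st$mec$mec,
      st$mec_properties$r_gyr, st$mec_properties$sa3d_psa))
  }
  print(x$comparison)
  invisible(x)
}

#' Run the NAMFIS workflow on an ensemble and an NOE table
#'
#' Builds the restraint-by-conformer distance matrix, fits populations by
#' [namfis_fit()], runs the leave-one-restraint-out jackknife, and
#' summarizes the fitted ensemble by fold class of each pool conformer.
#'
#' @param ensemble The conformer pool, a [conformer_ensemble()].
#' @param restraints A `noe_table` (e.g. from [read_noe_table()] or
#'   [simulate_noes()]).
#' @param proton_groups Optional equivalent-proton groups for
#'   [build_distance_matrix()].
#' @param fold_classes Optional per-conformer fold classes; computed from
#'   the pool's radii of gyration via [fold_class()] when omitted.
#' @param jackknife Set `FALSE` to skip the stability analysis.
#' @param out_dir Optional output directory for the population table,
#'   residual table and `report.json`.
#' @param ... Options passed to [namfis_fit()] (exponent, weighting,
#'   n_starts, floor, seed).
#' @return List of class `namfis_report`: `fit` (the `namfis` object),
#'   `jackknife`, `fold_class_populations` (percentages), `fold_classes`.
#' @export
run_namfis_analysis <- function(ensemble, restraints, proton_groups = NULL,
                                fold_classes = NULL, jackknife = TRUE,
                                out_dir = NULL, ...) {
  if (is.null(restraints) || nrow(restraints) == 0L) {
    stop("no NOE restraints supplied", call. = FALSE)
  }
  dmat <- build_distance_matrix(ensemble, restraints,
                                proton_groups = proton_groups)
  fit <- namfis_fit(dmat, restraints, ...)
  if (is.null(fold_classes)) {
    rg <- vapply(ensemble$coords, radius_of_gyration,
                 0.0, masses = ensemble$topology$masses)
    fold_classes <- fold_class(rg)
  }
  fcp <- summarize_fold_populations(fit, fold_classes)
  jk <- if (jackknife && nrow(restraints) >= 2L) {
    jackknife_restraints(dmat, restraints, ...)
  } else NULL
  report <- structure(list(fit = fit, jackknife = jk,
                           fold_class_populations = fcp,
                           fold_classes = fold_classes),
                      class = "namfis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(conformer_id = names(fit$populations),
                 population = fit$populations,
                 fold_class = as.character(fold_classes)),
      file.path(out_dir, "populations.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(restraint = rownames(fit$distance_matrix),
                 d_exp = fit$d_exp, d_calc = fit$fitted,
                 residual = fit$residuals),
      file.path(out_dir, "residuals.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    jsonlite::write_json(list(
      populations = as.list(fit$populations), ssd = fit$ssd,
      residuals = fit$residuals,
      jackknife_ranges = if (!is.null(jk)) {
        list(min = jk$ranges[, "min"], max = jk$ranges[, "max"])
      } else NULL,
      fold_class_populations = as.list(fcp),
      options = list(exponent = fit$exponent, weighting = fit$weighting,
                     floor = fit$floor, seed = fit$seed,
                     n_starts = fit$n_starts)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.namfis_report <- function(x, ...) {
  print(x$fit)
  cat("  fold-class populations (%):\n")
  pct <- x$fold_class_populations
  for (nm in names(pct)) cat(sprintf("    %-10s %5.1f\n", nm, pct[[nm]]))
  invisible(x)
}
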