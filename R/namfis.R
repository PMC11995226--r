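# NAMFIS-style deconvolution: fit conformer populations on the probability
# simplex so that r^-6 ensemble-averaged interproton distances reproduce the
# experimental NOE-derived distances.

#' Ensemble-averaged NOE distance
#'
#' Power-mean averaging of a distance over conformers:
#' \eqn{\langle d \rangle = (\sum_i w_i d_i^{-e})^{-1/e}} with exponent
#' \eqn{e = 6} by default (the rigid-molecule NOE limit; 3 is the common
#' alternative for flexible averaging). The result is bounded by the
#' smallest and largest distance and never exceeds the weighted arithmetic
#' mean (power-mean inequality); short distances dominate, as NOE
#' intensities do.
#'
#' @param distances Per-conformer distances (Angstrom, `> 0`).
#' @param weights Simplex weights (nonnegative, summing to 1).
#' @param exponent Averaging exponent (default 6).
#' @return Averaged distance in Angstrom.
#' @examples
#' noe_average_distance(c(2, 5), c(0.5, 0.5))  # ~2.24: the 2 A arm dominates
#' @export
noe_average_distance <- function(distances, weights, exponent = 6) {
  if (any(distances <= 0)) stop("distances must be > 0", call. = FALSE)
  stopifnot(length(distances) == length(weights))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be simplex weights (>= 0, summing to 1)",
         call. = FALSE)
  }
  sum(weights * distances^(-exponent))^(-1 / exponent)
}

.resolve_proton <- function(label, topology, proton_groups) {
  lab <- as.character(label)
  if (!is.null(proton_groups) && lab %in% names(proton_groups)) {
    return(as.integer(proton_groups[[lab]]))
  }
  hit <- which(topology$proton_labels == lab)
  if (length(hit) > 0L) return(hit)
  idx <- suppressWarnings(as.integer(lab))
  if (!is.na(idx) && idx >= 1L && idx <= n_atoms(topology)) return(idx)
  stop("cannot resolve proton label '", lab,
       "' to an atom index, tagged proton, or group", call. = FALSE)
}

#' Restraint-by-conformer distance matrix
#'
#' Evaluates each restraint's interproton distance in every conformer of
#' the pool. Restraint endpoints may be atom indices, tagged proton labels
#' from the topology, or names of equivalent-proton groups (e.g. methyls);
#' for groups, the distance within one conformer is the r^-6 average over
#' all cross pairs, the standard treatment of equivalent protons.
#'
#' @param ensemble A [conformer_ensemble()] (the fitting pool).
#' @param restraints A `noe_table` from [noe_restraints()].
#' @param proton_groups Optional named list mapping group labels to integer
#'   atom-index vectors.
#' @param exponent Averaging exponent for within-group pairs (default 6).
#' @return Matrix of class `distance_matrix`, `n_restraints x n_conformers`,
#'   with restraint ids as row names and conformer ids as column names.
#' @export
build_distance_matrix <- function(ensemble, restraints, proton_groups = NULL,
                                  exponent = 6) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  top <- ensemble$topology
  m <- n_conformers(ensemble)
  nr <- nrow(restraints)
  idx_i <- lapply(restraints$atom_i, .resolve_proton, top, proton_groups)
  idx_j <- lapply(restraints$atom_j, .resolve_proton, top, proton_groups)
  values <- matrix(NA_real_, nr, m)
  for (c in seq_len(m)) {
    xyz <- ensemble$coords[[c]]
    for (r in seq_len(nr)) {
      pairs <- expand.grid(i = idx_i[[r]], j = idx_j[[r]])
      d <- sqrt(rowSums((xyz[pairs$i, , drop = FALSE] -
                           xyz[pairs$j, , drop = FALSE])^2))
      if (any(d <= 0)) {
        stop("coincident protons in restraint ", r, ", conformer ", c,
             call. = FALSE)
      }
      values[r, c] <- if (length(d) == 1L) d else
        mean(d^(-exponent))^(-1 / exponent)
    }
  }
  rownames(values) <- paste(restraints$atom_i, restraints$atom_j, sep = "-")
  colnames(values) <- as.character(ensemble$conformer_ids)
  class(values) <- c("distance_matrix", class(values))
  values
}

# objective and gradient in softmax coordinates ----------------------------

.namfis_objective <- function(z, A, d_exp, lambda, exponent) {
  w <- exp(z - max(z))
  w <- w / sum(w)
  mj <- as.vector(A %*% w)                     # A[j,k] = d_jk^-e
  d_calc <- mj^(-1 / exponent)
  r <- d_exp - d_calc
  sum(lambda * r^2)
}

.namfis_gradient <- function(z, A, d_exp, lambda, exponent) {
  w <- exp(z - max(z))
  w <- w / sum(w)
  mj <- as.vector(A %*% w)
  d_calc <- mj^(-1 / exponent)
  r <- d_exp - d_calc
  # d(d_calc_j)/d(w_k) = -(1/e) m_j^{-1/e - 1} A[j,k]
  gw <- as.vector(t(A) %*% (lambda * 2 * r * (1 / exponent) *
                              mj^(-1 / exponent - 1)))
  # softmax Jacobian
  gw * w - w * sum(gw * w)
}

.fit_one_start <- function(z0, A, d_exp, lambda, exponent, maxit) {
  opt <- stats::optim(z0, .namfis_objective, .namfis_gradient,
                      A = A, d_exp = d_exp, lambda = lambda,
                      exponent = exponent, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-15))
  w <- exp(opt$par - max(opt$par))
  list(w = w / sum(w), value = opt$value)
}

.namfis_optimize <- function(values, d_exp, lambda, exponent, n_starts,
                             seed, maxit) {
  K <- ncol(values)
  A <- values^(-exponent)
  if (K == 1L) {
    return(list(w = 1.0, value = sum(lambda * (d_exp - values[, 1])^2)))
  }
  z_from_w <- function(w) log(pmax(w, 1e-10))
  starts <- list(rep(0, K))  # uniform
  # data-driven start: nonnegative least squares in r^-6 space with a soft
  # sum-to-one row, then renormalized
  scale <- max(A)
  nn <- tryCatch(
    pracma::lsqnonneg(rbind(A, rep(scale, K)), c(d_exp^(-exponent), scale))$x,
    error = function(e) NULL)
  if (!is.null(nn) && sum(nn) > 0) starts <- c(starts, list(z_from_w(nn / sum(nn))))
  # vertex starts at the best single-conformer fits
  single <- colSums(lambda * (d_exp - values)^2)
  for (k in utils::head(order(single), 3L)) {
    w <- rep(1e-4, K)
    w[k] <- 1
    starts <- c(starts, list(z_from_w(w / sum(w))))
  }
  n_random <- max(0L, n_starts - length(starts))
  if (n_random > 0L) {
    rs <- withr_seed_eval(seed, function() {
      lapply(seq_len(n_random), function(i) stats::rnorm(K))
    })
    starts <- c(starts, rs)
  }
  fits <- lapply(starts, function(z0) {
    tryCatch(.fit_one_start(z0, A, d_exp, lambda, exponent, maxit),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    stop("NAMFIS optimization failed in every start (", length(starts),
         " starts, ", K, " conformers, ", length(d_exp), " restraints)",
         call. = FALSE)
  }
  fits[[which.min(vapply(fits, `[[`, 0.0, "value"))]]
}

# evaluate with explicit seed, restoring the caller's RNG state
withr_seed_eval <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Fit conformer populations to NOE distances (NAMFIS-style)
#'
#' Minimizes the weighted sum of squared deviations
#' \eqn{\sum_j \lambda_j (d_{exp,j} - d_{calc,j}(w))^2} over the probability
#' simplex, where \eqn{d_{calc,j}(w)} is the r^-6 (configurable)
#' population-averaged distance of restraint \eqn{j} in the conformer pool
#' and \eqn{\lambda_j = 1/tol_j^2} (uniform when `weighting = "uniform"`).
#' The simplex constraint is enforced exactly through a softmax
#' reparameterization optimized by BFGS from multiple starts (uniform, a
#' nonnegative-least-squares start in transformed space, the best
#' single-conformer vertices, and seeded random points); the best objective
#' is kept. Populations below `floor` are then zeroed and the fit is
#' repeated on the surviving support (renormalized), mirroring the usual
#' reporting convention for minor conformers.
#'
#' @param distance_matrix `n_restraints x n_conformers` matrix from
#'   [build_distance_matrix()].
#' @param restraints Matching `noe_table` (supplies `d_exp` and tolerances).
#' @param exponent Averaging exponent (default 6; use 3 for flexible-limit
#'   averaging).
#' @param weighting `"tolerance"` for \eqn{\lambda_j = 1/tol_j^2} or
#'   `"uniform"`.
#' @param n_starts Number of optimization starts (default 10).
#' @param floor Reporting floor on populations (default 0.005); set 0 to
#'   disable the thresholded refit.
#' @param seed Integer seed for the random starts (default 1); identical
#'   seed gives identical results.
#' @param maxit BFGS iteration cap per start.
#' @return Object of class `namfis`: populations, `ssd` (objective),
#'   `residuals` (`d_exp - d_calc`), `fitted` (averaged distances),
#'   `selected` (conformer ids with population above the floor), plus the
#'   inputs needed by downstream summaries.
#' @seealso [jackknife_restraints()], [summarize_fold_populations()]
#' @export
namfis_fit <- function(distance_matrix, restraints,
                       exponent = 6, weighting = c("tolerance", "uniform"),
                       n_starts = 10L, floor = 0.005, seed = 1L,
                       maxit = 500L) {
  weighting <- match.arg(weighting)
  values <- unclass(distance_matrix)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (any(values <= 0)) stop("distance matrix entries must be > 0",
                             call. = FALSE)
  nr <- nrow(values)
  K <- ncol(values)
  if (nr < 1L || K < 1L) stop("empty distance matrix", call. = FALSE)
  if (nrow(restraints) != nr) {
    stop("restraint table (", nrow(restraints), " rows) does not match ",
         "distance matrix (", nr, " rows)", call. = FALSE)
  }
  d_exp <- restraints$d_exp
  lambda <- if (weighting == "tolerance") {
    tol <- restraints$tolerance
    if (any(tol <= 0)) {
      stop("tolerance weighting needs strictly positive tolerances; use ",
           "weighting = 'uniform' or supply tolerances", call. = FALSE)
    }
    1 / tol^2
  } else {
    rep(1, nr)
  }
  if (K > 1L && all(apply(values, 1, function(r) diff(range(r)) < 1e-12))) {
    warning("all conformers present identical distances; populations are ",
            "not identifiable", call. = FALSE)
  }
  best <- .namfis_optimize(values, d_exp, lambda, exponent, n_starts, seed,
                           maxit)
  w <- best$w
  # reporting floor: zero minor weights, renormalize, refit on the support
  if (floor > 0 && any(w < floor & w > 0) && any(w >= floor)) {
    support <- which(w >= floor)
    if (length(support) < K) {
      sub <- .namfis_optimize(values[, support, drop = FALSE], d_exp,
                              lambda, exponent, n_starts, seed, maxit)
      w <- numeric(K)
      w[support] <- sub$w
      best <- list(w = w, value = sub$value)
      w <- best$w
    }
  }
  mj <- as.vector(values^(-exponent) %*% w)
  d_calc <- mj^(-1 / exponent)
  if (is.null(rownames(values))) {
    rownames(values) <- if (!is.null(rownames(restraints)) &&
                            all(c("atom_i", "atom_j") %in%
                                  names(restraints))) {
      paste(restraints$atom_i, restraints$atom_j, sep = "-")
    } else {
      paste0("r", seq_len(nr))
    }
  }
  conf_ids <- colnames(values)
  if (is.null(conf_ids)) conf_ids <- as.character(seq_len(K))
  names(w) <- conf_ids
  structure(list(
    populations = w, ssd = best$value, residuals = d_exp - d_calc,
    fitted = d_calc, d_exp = d_exp, lambda = lambda,
    selected = conf_ids[w > max(floor, 0)],
    exponent = exponent, weighting = weighting, floor = floor,
    seed = seed, n_starts = n_starts,
    distance_matrix = values, restraints = restraints,
    call = match.call()),
    class = "namfis")
}

#' @export
print.namfis <- function(x, digits = 3, ...) {
  cat("NAMFIS population fit:", ncol(x$distance_matrix), "conformers,",
      length(x$d_exp), "restraints\n")
  cat(sprintf("  ssd = %.4g (weighting: %s, exponent: %g)\n",
              x$ssd, x$weighting, x$exponent))
  sel <- x$populations[x$populations > 0]
  sel <- sort(sel, decreasing = TRUE)
  cat("  populations above floor:\n")
  for (nm in names(sel)) {
    cat(sprintf("    %-10s %5.1f%%\n", nm, 100 * sel[[nm]]))
  }
  invisible(x)
}

#' @export
summary.namfis <- function(object, ...) {
  res <- object$residuals
  viol <- which(abs(res) > object$restraints$tolerance)
  out <- list(
    n_conformers = ncol(object$distance_matrix),
    n_restraints = length(object$d_exp),
    ssd = object$ssd,
    populations = sort(object$populations[object$populations > 0],
                       decreasing = TRUE),
    rmsd_distance = sqrt(mean(res^2)),
    max_abs_residual = max(abs(res)),
    violated = data.frame(
      restraint = rownames(object$distance_matrix)[viol],
      d_exp = object$d_exp[viol], d_calc = object$fitted[viol],
      residual = res[viol]))
  class(out) <- "summary.namfis"
  out
}

#' @export
print.summary.namfis <- function(x, ...) {
  cat("NAMFIS fit summary\n")
  cat(sprintf("  %d conformers, %d restraints, ssd = %.4g\n",
              x$n_conformers, x$n_restraints, x$ssd))
  cat(sprintf("  distance rmsd = %.3f A, max |residual| = %.3f A\n",
              x$rmsd_distance, x$max_abs_residual))
  cat("  populations:\n")
  print(round(100 * x$populations, 1))
  if (nrow(x$violated) > 0L) {
    cat("  restraints violated beyond tolerance:\n")
    print(x$violated, row.names = FALSE)
  } else {
    cat("  all restraints satisfied within tolerance\n")
  }
  invisible(x)
}

#' @export
coef.namfis <- function(object, ...) object$populations

#' @export
residuals.namfis <- function(object, ...) object$residuals

#' @export
fitted.namfis <- function(object, ...) object$fitted

#' Predict ensemble-averaged distances from a NAMFIS fit
#'
#' Applies the fitted populations to a (possibly new) restraint-by-conformer
#' distance matrix over the same pool.
#'
#' @param object A `namfis` fit.
#' @param newdata Optional distance matrix with the same conformer columns;
#'   defaults to the training matrix.
#' @param ... Unused.
#' @return Vector of population-averaged distances (Angstrom).
#' @export
predict.namfis <- function(object, newdata = NULL, ...) {
  values <- if (is.null(newdata)) object$distance_matrix else
    as.matrix(newdata)
  if (ncol(values) != length(object$populations)) {
    stop("newdata must have one column per pool conformer", call. = FALSE)
  }
  as.vector(values^(-object$exponent) %*% object$populations)^
    (-1 / object$exponent)
}

#' @export
plot.namfis <- function(x, ...) {
  pop <- sort(x$populations[x$populations > 0], decreasing = TRUE)
  graphics::barplot(100 * pop, ylab = "population (%)",
                    xlab = "conformer", las = 2, ...)
  invisible(x)
}

#' Leave-one-restraint-out stability of a NAMFIS fit
#'
#' Refits the populations with each restraint removed in turn and reports
#' the range each conformer's population spans across the folds — a cheap
#' gauge of how strongly any single NOE drives the deconvolution.
#'
#' @param distance_matrix,restraints As for [namfis_fit()].
#' @param ... Further options passed to [namfis_fit()].
#' @return List of class `namfis_jackknife`: `ranges` (per-conformer min /
#'   max population matrix), `fold_populations`, `fold_ssd`, and the index
#'   of any skipped fold.
#' @export
jackknife_restraints <- function(distance_matrix, restraints, ...) {
  values <- as.matrix(distance_matrix)
  nr <- nrow(values)
  if (nr < 2L) stop("jackknife needs at least 2 restraints", call. = FALSE)
  K <- ncol(values)
  pops <- matrix(NA_real_, nr, K)
  ssd <- rep(NA_real_, nr)
  skipped <- integer(0)
  for (j in seq_len(nr)) {
    fit <- tryCatch(
      namfis_fit(values[-j, , drop = FALSE], restraints[-j, , drop = FALSE],
                 ...),
      error = function(e) {
        warning("jackknife fold ", j, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) {
      skipped <- c(skipped, j)
      next
    }
    pops[j, ] <- fit$populations
    ssd[j] <- fit$ssd
  }
  ok <- setdiff(seq_len(nr), skipped)
  ranges <- cbind(min = apply(pops[ok, , drop = FALSE], 2, min),
                  max = apply(pops[ok, , drop = FALSE], 2, max))
  rownames(ranges) <- colnames(values)
  structure(list(ranges = ranges, fold_populations = pops, fold_ssd = ssd,
                 skipped = skipped),
            class = "namfis_jackknife")
}

#' Fold-class population percentages of a NAMFIS ensemble
#'
#' Sums the fitted populations within each fold class (folded, semifolded,
#' extended) and reports percentages, the format in which NMR ensemble
#' deconvolutions are typically summarized.
#'
#' @param fit A `namfis` object.
#' @param fold_classes Per-pool-conformer classes (character or factor with
#'   levels among folded/semifolded/extended), in column order of the pool.
#' @return Named numeric vector of percentages over the three classes,
#'   summing to 100.
#' @export
summarize_fold_populations <- function(fit, fold_classes) {
  stopifnot(inherits(fit, "namfis"))
  w <- fit$populations
  if (length(fold_classes) != length(w)) {
    stop("need one fold class per pool conformer", call. = FALSE)
  }
  if (anyNA(fold_classes)) stop("missing fold class", call. = FALSE)
  fold_classes <- factor(as.character(fold_classes),
                         levels = c("folded", "semifolded", "extended"))
  if (anyNA(fold_classes)) {
    stop("fold classes must be folded/semifolded/extended", call. = FALSE)
  }
  if (sum(w) <= 0) stop("empty selection: all populations are zero",
                        call. = FALSE)
  pct <- 100 * vapply(levels(fold_classes),
                      function(cl) sum(w[fold_classes == cl]), 0.0) / sum(w)
  pct
}
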