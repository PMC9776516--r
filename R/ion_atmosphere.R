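#' Fit a Poisson-Boltzmann ion-atmosphere model to a structure
#'
#' The central modelling interface of the package: solves the (non)linear
#' Poisson-Boltzmann equation for a fixed structure in a 1:1 salt,
#' Boltzmann-inverts the potential into cation and anion concentration
#' maps, and precomputes the distance-resolved statistics of the ion
#' atmosphere (total-charge, ion-excess and ionic-strength profiles).
#'
#' @param structure A [structure_model] (e.g. from [read_pqr],
#'   [make_charged_sphere] or [make_bead_protein]).
#' @param grid Fine [grid_spec]; default: cubic grid centered on the
#'   structure with a 15 Angstrom margin and 1 Angstrom spacing.
#' @param cfg A [pb_config] (form, dielectrics, ionic strength, ...).
#' @param coarse Optional coarse [grid_spec] for two-level focusing.
#' @param cutoffs Cutoff-distance ladder (Angstrom) for the profiles.
#' @param max_distance Outer analysis limit (Angstrom).
#' @return An object of class \code{ion_atmosphere}.
#' @seealso [summary.ion_atmosphere], [predict.ion_atmosphere],
#'   [simulate.ion_atmosphere]
#' @export
#' @examples
#' sph <- make_charged_sphere(radius = 5, charge = 4)
#' fit <- ion_atmosphere(sph, grid = grid_spec_centered(c(0, 0, 0), 40, 1),
#'                       cfg = pb_config(idie = 80, stern = 1.5, tol = 1e-6))
#' fit
#' head(coef(fit))
ion_atmosphere <- function(structure, grid = NULL, cfg = pb_config(),
                           coarse = NULL,
                           cutoffs = seq(0.5, 15, by = 0.5),
                           max_distance = max(cutoffs)) {
  if (is.null(grid)) {
    span <- apply(structure$positions, 2, range)
    center <- colMeans(span)
    extent <- max(span[2, ] - span[1, ]) + 2 * (max_distance + 15)
    grid <- grid_spec_centered(center, extent, 1)
  }
  maps <- pb_concentration_maps(structure, grid, cfg, coarse)
  dmap <- distance_map(grid, structure)
  Z <- total_charge(structure)
  prof <- total_charge_profile(Z, maps$cation, maps$anion, dmap, cutoffs,
                               bulk = cfg$ionic_strength, max_distance)
  iprof <- ionic_strength_profile(maps$cation, maps$anion, dmap, cutoffs,
                                  max_distance)
  structure(list(structure = structure, cfg = cfg,
                 grid = as_grid_spec(grid),
                 potential = maps$potential, cation = maps$cation,
                 anion = maps$anion, accessibility = maps$accessibility,
                 distmap = dmap, profiles = prof,
                 ionic_strength_profile = iprof,
                 cutoffs = cutoffs, max_distance = max_distance,
                 Z = Z, solver = attr(maps$potential, "solver")),
            class = "ion_atmosphere")
}

#' @export
print.ion_atmosphere <- function(x, ...) {
  cat(sprintf("Ion atmosphere model (%s, I = %g M, T = %g K)\n",
              toupper(x$solver$form), x$cfg$ionic_strength, x$cfg$temperature))
  cat(sprintf("  structure: %d atoms, Z = %+.3f e\n",
              n_atoms(x$structure), x$Z))
  cat(sprintf("  grid: %d x %d x %d nodes, spacing %g A\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$spacing[1]))
  cat(sprintf("  solver: %d iterations, residual %.2e\n",
              x$solver$iterations, x$solver$residual))
  last <- x$profiles[nrow(x$profiles), ]
  cat(sprintf("  at %g A cutoff: total charge %+.3f e, dN+ = %+.3f, dN- = %+.3f\n",
              last$cutoff, last$total_charge, last$excess_plus,
              last$excess_minus))
  invisible(x)
}

#' Profile coefficients of a fitted ion atmosphere
#'
#' @param object An \code{ion_atmosphere} fit.
#' @param ... Unused.
#' @return Named vector: solute charge \code{Z} and, at the largest
#'   cutoff, the total charge, ion excesses and local ionic strength.
#' @export
coef.ion_atmosphere <- function(object, ...) {
  last <- object$profiles[nrow(object$profiles), ]
  c(Z = object$Z, total_charge = last$total_charge,
    excess_plus = last$excess_plus, excess_minus = last$excess_minus,
    ionic_strength = object$ionic_strength_profile$ionic_strength[
      nrow(object$ionic_strength_profile)])
}

#' @export
summary.ion_atmosphere <- function(object, ...) {
  out <- list(fit = object,
              dispersion_cation = dispersion_summary(object$cation,
                                                     object$distmap,
                                                     object$max_distance),
              dispersion_anion = dispersion_summary(object$anion,
                                                    object$distmap,
                                                    object$max_distance))
  class(out) <- "summary.ion_atmosphere"
  out
}

#' @export
print.summary.ion_atmosphere <- function(x, ...) {
  print(x$fit)
  cat("\nCation concentration dispersion (<= max_distance):\n")
  print(x$dispersion_cation)
  cat("Anion concentration dispersion (<= max_distance):\n")
  print(x$dispersion_anion)
  cat("\nProfiles (first and last cutoffs):\n")
  print(x$fit$profiles[c(1, nrow(x$fit$profiles)), ], row.names = FALSE)
  invisible(x)
}

#' Predict potential or concentrations at arbitrary positions
#'
#' Trilinear interpolation of the fitted maps.
#'
#' @param object An \code{ion_atmosphere} fit.
#' @param newdata n x 3 matrix or data frame of positions (Angstrom).
#' @param type \code{"cation"}, \code{"anion"} or \code{"potential"}.
#' @param ... Unused.
#' @return Numeric vector (M, or kT/e for the potential).
#' @export
predict.ion_atmosphere <- function(object, newdata,
                                   type = c("cation", "anion", "potential"),
                                   ...) {
  type <- match.arg(type)
  grid_interpolate(object[[type]], newdata)
}

#' Plot ion-atmosphere profiles
#'
#' Total charge, ion excesses and local ionic strength versus the cutoff
#' distance from the closest structure atom.
#'
#' @param x An \code{ion_atmosphere} fit.
#' @param ... Passed to \code{matplot}.
#' @export
plot.ion_atmosphere <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p <- x$profiles
  graphics::matplot(p$cutoff, cbind(p$total_charge, p$excess_plus,
                                    p$excess_minus),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "blue", "red"),
                    xlab = "cutoff distance (A)", ylab = "charge / excess (e)",
                    ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("total charge", "dN+", "dN-"),
                   col = c("black", "blue", "red"), lty = 1, bty = "n")
  ip <- x$ionic_strength_profile
  graphics::plot(ip$cutoff, ip$ionic_strength, type = "l", lwd = 2,
                 xlab = "cutoff distance (A)", ylab = "ionic strength (M)")
  graphics::abline(h = x$cfg$ionic_strength, lty = 3)
  invisible(x)
}

#' Simulate ion configurations consistent with a fitted atmosphere
#'
#' Draws Metropolis Monte Carlo ion trajectories around the fitted
#' structure at the fit's ionic strength and temperature (see
#' [sample_ion_configurations]).
#'
#' @param object An \code{ion_atmosphere} fit.
#' @param nsim Number of independent trajectories.
#' @param seed Integer seed for the first trajectory; subsequent ones use
#'   \code{seed + 1, ...}.
#' @param box Box edge lengths (Angstrom); default: the fitted grid extent.
#' @param sweeps,n_water,... Passed to [sample_ion_configurations].
#' @return A list of [ion_trajectory] objects (length \code{nsim}).
#' @export
simulate.ion_atmosphere <- function(object, nsim = 1, seed = 1,
                                    box = NULL, sweeps = 2000,
                                    n_water = 0L, ...) {
  if (is.null(box))
    box <- (object$grid$dims - 1L) * object$grid$spacing
  lapply(seq_len(nsim) - 1L, function(k)
    sample_ion_configurations(object$structure, box = box, sweeps = sweeps,
                              n_water = n_water,
                              ionic_strength = object$cfg$ionic_strength,
                              temperature = object$cfg$temperature,
                              sdie = object$cfg$sdie,
                              seed = seed + k, ...))
}
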