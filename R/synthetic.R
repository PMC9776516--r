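#' Single charged sphere
#'
#' Oracle geometry: one atom at the origin.  Its screened-Coulomb potential
#' has a closed form ([analytic_dh_potential]) against which the grid
#' solvers are validated.
#'
#' @param radius Sphere radius (Angstrom), > 0.
#' @param charge Total charge (e).
#' @return A [structure_model] with one atom.
#' @export
make_charged_sphere <- function(radius, charge) {
  stopifnot(radius > 0)
  structure_model(matrix(0, 1, 3), charge, radius, "SPH")
}

#' Compact random bead model of a charged macromolecule
#'
#' Places \code{n_beads} non-overlapping hard beads uniformly inside a
#' sphere of radius \code{cluster_radius}, emulating a macromolecule with
#' positive and negative surface patches.  Per-bead charges are either
#' supplied directly (length \code{n_beads}) or drawn from a standard
#' normal and shifted so that they sum exactly to a requested total.
#'
#' @param n_beads Number of beads.
#' @param charges Either a length-\code{n_beads} vector of bead charges (e)
#'   or a single number interpreted as the requested total charge.
#' @param bead_radius Bead radius (Angstrom).
#' @param cluster_radius Radius of the placement sphere (Angstrom).
#' @param min_separation Minimum center-center distance between beads
#'   (Angstrom).
#' @param seed Integer seed; fixed seed gives a bit-identical structure.
#' @param max_attempts Placement attempts per bead before giving up.
#' @return A [structure_model].
#' @export
make_bead_protein <- function(n_beads, charges, bead_radius = 2,
                              cluster_radius = 10, min_separation = 2,
                              seed = NULL, max_attempts = 10000L) {
  stopifnot(n_beads >= 1, bead_radius > 0, min_separation >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_beads == 1L) # degenerate case: a single centered bead
    return(structure_model(matrix(0, 1, 3), sum(charges), bead_radius, "BD1"))
  if (length(charges) == 1L && n_beads > 1L) {
    q <- stats::rnorm(n_beads)
    q <- q - mean(q) + charges / n_beads
  } else {
    stopifnot(length(charges) == n_beads)
    q <- as.numeric(charges)
  }
  pos <- matrix(NA_real_, n_beads, 3)
  for (b in seq_len(n_beads)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(3, -cluster_radius, cluster_radius)
      if (sum(p^2) > cluster_radius^2) next
      if (b == 1L || all(sqrt(colSums((t(pos[seq_len(b - 1L), , drop = FALSE]) - p)^2))
                         >= min_separation)) {
        pos[b, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("placement error: could not place bead %d without overlap after %d attempts",
                   b, max_attempts))
  }
  structure_model(pos, q, rep(bead_radius, n_beads),
                  sprintf("BD%d", seq_len(n_beads)))
}

#' Analytic Debye-Hueckel potential of a charged sphere
#'
#' Closed form for a sphere of charge \eqn{q} and radius \eqn{a} in a
#' solvent of permittivity \eqn{\epsilon_s} with screening \eqn{\kappa}:
#' \deqn{\phi(r) = \frac{q \, \ell_B^{vac}}{\epsilon_s (1+\kappa a)}
#'   \frac{e^{-\kappa (r-a)}}{r} \quad (r \ge a),}
#' in kT/e units.  Nodes with \eqn{r < a} are filled with the \eqn{r = a}
#' value.
#'
#' @param sphere A single-atom [structure_model] (see [make_charged_sphere]).
#' @param grid A [grid_spec] or [grid_map] giving the target geometry.
#' @param ionic_strength Bulk ionic strength (M) defining \eqn{\kappa}.
#' @param temperature Temperature (K).
#' @param sdie Solvent relative permittivity.
#' @return A [grid_map] in kT/e.
#' @export
analytic_dh_potential <- function(sphere, grid, ionic_strength = 0.1,
                                  temperature = 300, sdie = 80) {
  if (n_atoms(sphere) != 1L)
    stop("analytic potential requires a single-sphere structure")
  g <- as_grid_spec(grid)
  a <- sphere$radii[1]
  q <- sphere$charges[1]
  kappa <- debye_kappa(ionic_strength, temperature, sdie)
  lB <- bjerrum_vacuum(temperature)
  co <- grid_coords(g)
  r <- sqrt(colSums((t(co) - sphere$positions[1, ])^2))
  r <- pmax(r, a) # inside the sphere: hold the surface value
  u <- q * lB * exp(-kappa * (r - a)) / (sdie * (1 + kappa * a) * r)
  grid_map(array(u, dim = g$dims), g$origin, g$spacing, units = "kT/e")
}

#' Metropolis Monte Carlo sampling of mobile ions around a fixed structure
#'
#' Equilibrates \code{n_cation} + \code{n_anion} monovalent hard-sphere
#' ions in the screened electrostatic field of the structure's beads
#' (Debye-Hueckel sphere potentials) with Yukawa ion-ion interactions, in a
#' rectangular box centered at the origin.  A uniform ideal water
#' background (\code{n_water} sites per recorded frame, placed outside the
#' beads) is co-generated for molality normalisation.  Energies are in kT;
#' single-particle displacement moves use the standard Metropolis
#' criterion, and moves leaving the box are rejected.
#'
#' When ion counts are not supplied they are chosen by the
#' neutrality-plus-ionic-strength protocol ([ion_addition]) for the
#' solvent volume of the box.
#'
#' @param structure A [structure_model] of fixed beads.
#' @param box Length-3 box edge lengths (Angstrom); must leave a margin of
#'   at least two Debye lengths around every bead.
#' @param sweeps Total Monte Carlo sweeps (one attempted move per ion each).
#' @param n_cation,n_anion Ion numbers; default from [ion_addition].
#' @param n_water Uniform water sites per recorded frame.
#' @param ionic_strength Bulk ionic strength (M); sets the screening length.
#' @param temperature Temperature (K).
#' @param sdie Solvent relative permittivity.
#' @param ion_radius Ion hard-sphere radius (Angstrom).
#' @param equil_fraction Fraction of sweeps discarded as equilibration.
#' @param stride Record one frame every \code{stride} post-equilibration
#'   sweeps.
#' @param step Maximum displacement per move (Angstrom).
#' @param interactions \code{"full"}, \code{"no-ion-ion"} (external field
#'   only) or \code{"ideal"} (hard cores against beads only).
#' @param seed Integer seed; fixed seed gives a bit-identical trajectory.
#' @return An [ion_trajectory]; attribute \code{"mc"} carries the final
#'   incrementally-updated and freshly recomputed total energies (kT) and
#'   the move acceptance rate.
#' @export
sample_ion_configurations <- function(structure, box, sweeps,
                                      n_cation = NULL, n_anion = NULL,
                                      n_water = 0L,
                                      ionic_strength = 0.1,
                                      temperature = 300, sdie = 80,
                                      ion_radius = 1.5,
                                      equil_fraction = 0.3, stride = 10L,
                                      step = 3, interactions = "full",
                                      seed = NULL) {
  box <- rep_len(as.numeric(box), 3L)
  stopifnot(sweeps >= 1, ionic_strength > 0, stride >= 1, step > 0)
  interactions <- match.arg(interactions, c("full", "no-ion-ion", "ideal"))
  kappa <- debye_kappa(ionic_strength, temperature, sdie)
  # distance from each bead surface to the nearest box face
  margin <- min(apply(abs(structure$positions), 1, function(p) min(box / 2 - p)) -
                  structure$radii)
  if (margin < 2 / kappa)
    stop(sprintf("geometry error: box margin %.2f A is below two Debye lengths (%.2f A)",
                 margin, 2 / kappa))
  if (is.null(n_cation) || is.null(n_anion)) {
    v_solv <- (prod(box) - sum(4 / 3 * pi * structure$radii^3)) * 1e-27
    add <- ion_addition(total_charge(structure), ionic_strength, v_solv)
    if (is.null(n_cation)) n_cation <- add$n_plus
    if (is.null(n_anion)) n_anion <- add$n_minus
  }
  stopifnot(n_cation >= 0, n_anion >= 0, n_cation + n_anion >= 1)
  mode <- match(interactions, c("full", "no-ion-ion", "ideal")) - 1L
  equil <- as.integer(floor(sweeps * equil_fraction))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_mc_sample(structure$positions, structure$charges,
                       structure$radii, as.integer(n_cation),
                       as.integer(n_anion), as.integer(n_water),
                       ion_radius, bjerrum_vacuum(temperature) / sdie,
                       kappa, box, as.integer(sweeps), equil,
                       as.integer(stride), step, mode)
  if (length(res$frames) == 0L)
    stop("no frames recorded: increase sweeps or reduce stride/equil_fraction")
  species <- c(rep("cation", n_cation), rep("anion", n_anion),
               rep("water", n_water))
  traj <- ion_trajectory(res$frames, species, box)
  attr(traj, "mc") <- list(energy_incremental = res$energy_incremental,
                           energy_recomputed = res$energy_recomputed,
                           acceptance = res$acceptance)
  traj
}
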