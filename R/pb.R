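#' Poisson-Boltzmann solver configuration
#'
#' @param idie Relative permittivity of the molecular interior.
#' @param sdie Relative permittivity of the solvent.
#' @param temperature Temperature (K).
#' @param ionic_strength Bulk ionic strength (M), 1:1 salt.
#' @param probe Solvent probe radius (Angstrom) defining the molecular
#'   surface.
#' @param stern Stern layer thickness (Angstrom); mobile ions are excluded
#'   within \code{atom radius + stern} of any atom.
#' @param tol Convergence tolerance on the relative residual.
#' @param maxiter Maximum solver iterations.
#' @param omega Successive over-relaxation factor for the linear solve.
#' @param damping Under-relaxation factor for the nonlinear Gauss-Seidel.
#' @param form \code{"nlpb"} (full sinh mobile-charge term) or \code{"lpb"}
#'   (linearised).
#' @return An object of class \code{pb_config}.
#' @export
pb_config <- function(idie = 4, sdie = 80, temperature = 300,
                      ionic_strength = 0.1, probe = 1.4, stern = 2.0,
                      tol = 1e-6, maxiter = 20000L, omega = 1.6,
                      damping = 0.6, form = c("nlpb", "lpb")) {
  form <- match.arg(form)
  stopifnot(idie > 0, sdie > 0, temperature > 0, ionic_strength >= 0,
            probe >= 0, stern >= 0, tol > 0, maxiter >= 1,
            omega > 0, omega < 2, damping > 0, damping <= 1)
  structure(list(idie = idie, sdie = sdie, temperature = temperature,
                 ionic_strength = ionic_strength, probe = probe,
                 stern = stern, tol = tol, maxiter = as.integer(maxiter),
                 omega = omega, damping = damping, form = form),
            class = "pb_config")
}

#' Ionic species specification
#'
#' @param valence Signed integer valence (protonic units), non-zero.
#' @param bulk Bulk concentration (M), > 0.
#' @return An object of class \code{species_spec}.
#' @export
species_spec <- function(valence, bulk) {
  stopifnot(valence == round(valence), valence != 0, bulk > 0)
  structure(list(valence = as.integer(valence), bulk = bulk),
            class = "species_spec")
}

#' Dielectric, accessibility and charge coefficient grids
#'
#' Discretises a structure onto a grid for the finite-difference PB solve:
#' \itemize{
#'   \item Interior/exterior classification by a two-pass approximation of
#'     the molecular (probe-inflated, then probe-eroded) surface: nodes
#'     within \code{atom radius + probe} of any atom center are tentatively
#'     interior; tentative nodes within \code{probe} of a definitely
#'     exterior node are reclassified exterior (approximate re-entrant
#'     surface, error bounded by one probe radius).
#'   \item Ion accessibility is 0 within \code{atom radius + stern} of any
#'     atom, 1 elsewhere.
#'   \item Atom charges are spread to the 8 surrounding nodes with
#'     trilinear weights, conserving total charge exactly.
#' }
#'
#' @param structure A [structure_model].
#' @param cfg A [pb_config].
#' @param grid A [grid_spec] or [grid_map].
#' @return An object of class \code{pb_coefficients}.
#' @export
assign_coefficients <- function(structure, cfg, grid) {
  g <- as_grid_spec(grid)
  lo <- g$origin; hi <- g$origin + (g$dims - 1L) * g$spacing
  if (any(sweep(structure$positions, 2, lo) < 0) ||
      any(sweep(structure$positions, 2, hi) > 0))
    stop("geometry error: structure extends beyond the grid")
  dsurf <- cpp_surface_distance(g$dims, g$origin, g$spacing,
                                structure$positions, structure$radii)
  tentative <- as.integer(dsurf <= cfg$probe)
  interior <- cpp_erode_interior(tentative, g$dims, g$spacing, cfg$probe)
  access <- as.integer(dsurf > cfg$stern)
  charge <- numeric(prod(g$dims))
  for (a in seq_len(n_atoms(structure))) {
    fr <- (structure$positions[a, ] - g$origin) / g$spacing
    i0 <- pmin(pmax(floor(fr), 0), g$dims - 2L)
    t <- fr - i0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) t[1] else 1 - t[1]) * (if (dy) t[2] else 1 - t[2]) *
           (if (dz) t[3] else 1 - t[3])
      id <- (i0[1] + dx) + g$dims[1] * ((i0[2] + dy) + g$dims[2] * (i0[3] + dz)) + 1
      charge[id] <- charge[id] + w * structure$charges[a]
    }
  }
  structure(list(grid = g,
                 interior = array(as.integer(interior), g$dims),
                 access = array(access, g$dims),
                 charge = array(charge, g$dims),
                 structure = structure, cfg = cfg),
            class = "pb_coefficients")
}

# Dirichlet boundary values: superposition of per-charge Debye-Hueckel
# monopoles ("mdh"), evaluated only on the six boundary faces.
pb_boundary <- function(coeffs, cfg) {
  g <- coeffs$grid
  st <- coeffs$structure
  kappa <- debye_kappa(cfg$ionic_strength, cfg$temperature, cfg$sdie)
  lB <- bjerrum_vacuum(cfg$temperature)
  u <- array(0, g$dims)
  bnd <- array(FALSE, g$dims)
  bnd[c(1, g$dims[1]), , ] <- TRUE
  bnd[, c(1, g$dims[2]), ] <- TRUE
  bnd[, , c(1, g$dims[3])] <- TRUE
  which_bnd <- which(bnd)
  co <- grid_coords(g)[which_bnd, , drop = FALSE]
  vals <- numeric(length(which_bnd))
  for (a in seq_len(n_atoms(st))) {
    r <- sqrt(colSums((t(co) - st$positions[a, ])^2))
    aR <- st$radii[a]
    r <- pmax(r, pmax(aR, 1e-6))
    vals <- vals + st$charges[a] * lB * exp(-kappa * (r - aR)) /
      (cfg$sdie * (1 + kappa * aR) * r)
  }
  u[which_bnd] <- vals
  u
}

pb_solve_internal <- function(coeffs, cfg, nonlinear, boundary = NULL) {
  g <- coeffs$grid
  h <- g$spacing
  if (max(abs(h - h[1])) > 1e-12)
    stop("PB solver requires equal spacing on all axes")
  h <- h[1]
  lB <- bjerrum_vacuum(cfg$temperature)
  kappa <- debye_kappa(cfg$ionic_strength, cfg$temperature, cfg$sdie)
  if (is.null(boundary)) boundary <- pb_boundary(coeffs, cfg)
  source <- 4 * pi * lB * coeffs$charge / h
  init <- as.numeric(boundary)
  if (nonlinear) {
    # start the damped Newton-Gauss-Seidel from the linearised solution:
    # the standard continuation, and essential with a low-dielectric
    # interior where bare point-charge potentials reach thousands of kT/e
    lin <- cpp_pb_solve(g$dims, as.integer(coeffs$interior),
                        as.integer(coeffs$access), as.numeric(source),
                        init, cfg$idie, cfg$sdie,
                        cfg$sdie * kappa^2 * h^2, FALSE, cfg$omega,
                        cfg$tol, cfg$maxiter)
    if (isTRUE(lin$converged)) init <- as.numeric(lin$u)
  }
  res <- cpp_pb_solve(g$dims, as.integer(coeffs$interior),
                      as.integer(coeffs$access), as.numeric(source),
                      init, cfg$idie, cfg$sdie,
                      cfg$sdie * kappa^2 * h^2, nonlinear,
                      if (nonlinear) cfg$damping else cfg$omega,
                      cfg$tol, cfg$maxiter)
  if (isTRUE(res$diverged))
    stop(sprintf("PB solver diverged (residual %.3g after %d iterations)",
                 res$residual, res$iterations))
  if (!isTRUE(res$converged))
    stop(sprintf("PB solver did not converge: residual %.3g after %d iterations",
                 res$residual, res$iterations))
  out <- grid_map(array(res$u, g$dims), g$origin, g$spacing, units = "kT/e")
  attr(out, "solver") <- list(iterations = res$iterations,
                              residual = res$residual,
                              form = if (nonlinear) "nlpb" else "lpb")
  out
}

#' Solve the linearised Poisson-Boltzmann equation
#'
#' 7-point finite-difference discretisation of
#' \eqn{\nabla\cdot(\epsilon\nabla\phi) - \epsilon_s \kappa^2 a(r) \phi =
#' -4\pi \ell_B^{vac} \rho}, solved by successive over-relaxation.
#' Dirichlet boundary values are the superposition of per-charge
#' Debye-Hueckel monopoles.
#'
#' @param coeffs A [pb_coefficients] object.
#' @param cfg A [pb_config]; defaults to the one stored in \code{coeffs}.
#' @return A potential [grid_map] in kT/e; attribute \code{"solver"}
#'   reports iterations and the final relative residual.
#' @export
solve_lpb <- function(coeffs, cfg = coeffs$cfg) {
  pb_solve_internal(coeffs, cfg, nonlinear = FALSE)
}

#' Solve the nonlinear Poisson-Boltzmann equation (1:1 salt)
#'
#' Same discretisation as [solve_lpb] with the full \eqn{\sinh\phi}
#' mobile-charge term, solved by damped nonlinear Gauss-Seidel (local
#' Newton updates with under-relaxation).
#'
#' @inheritParams solve_lpb
#' @return A potential [grid_map] in kT/e.
#' @export
solve_nlpb <- function(coeffs, cfg = coeffs$cfg) {
  pb_solve_internal(coeffs, cfg, nonlinear = TRUE)
}

#' Two-level focusing solve
#'
#' Solves on the fine grid with Dirichlet boundary values interpolated
#' trilinearly from a coarse-grid solution, the standard electrostatic
#' focusing technique.
#'
#' @param coarse A coarse potential [grid_map] (kT/e) enclosing the fine
#'   grid.
#' @param coeffs_fine A [pb_coefficients] object on the fine grid.
#' @param cfg A [pb_config]; \code{cfg$form} selects the solver.
#' @return A potential [grid_map] on the fine grid.
#' @export
focus <- function(coarse, coeffs_fine, cfg = coeffs_fine$cfg) {
  g <- coeffs_fine$grid
  lo <- g$origin; hi <- g$origin + (g$dims - 1L) * g$spacing
  clo <- coarse$origin
  chi <- coarse$origin + (coarse$dims - 1L) * coarse$spacing
  if (any(lo < clo - 1e-9) || any(hi > chi + 1e-9))
    stop("fine grid must lie inside the coarse grid")
  bnd <- array(FALSE, g$dims)
  bnd[c(1, g$dims[1]), , ] <- TRUE
  bnd[, c(1, g$dims[2]), ] <- TRUE
  bnd[, , c(1, g$dims[3])] <- TRUE
  u <- array(0, g$dims)
  which_bnd <- which(bnd)
  u[which_bnd] <- grid_interpolate(coarse, grid_coords(g)[which_bnd, , drop = FALSE])
  pb_solve_internal(coeffs_fine, cfg, nonlinear = (cfg$form == "nlpb"),
                    boundary = u)
}

#' Boltzmann inversion of a potential into a species concentration map
#'
#' \deqn{c_i(r) = c_i^{bulk} \exp(-z_i \phi(r))}
#' with \eqn{\phi} in kT/e, set to exactly zero wherever the ion
#' accessibility mask is zero (no mobile ions below the Stern layer).
#' The same formula applies to LPB and NLPB potentials; it is only
#' thermodynamically consistent with the nonlinear form, and feeding an
#' LPB potential reproduces the known inconsistency of that shortcut.
#'
#' @param potential A potential [grid_map] in kT/e.
#' @param species A [species_spec] (valence and bulk concentration).
#' @param accessibility A binary mask [grid_map], or \code{NULL} for full
#'   accessibility.
#' @return A concentration [grid_map] in M.
#' @export
boltzmann_concentration <- function(potential, species, accessibility = NULL) {
  if (potential$units != "kT/e")
    stop("unit error: potential must be tagged kT/e")
  conc <- species$bulk * exp(-species$valence * potential$values)
  if (!is.null(accessibility)) {
    if (accessibility$units != "mask")
      stop("unit error: accessibility must be a mask grid")
    stop_if_incommensurate(potential, accessibility)
    # assign, don't multiply: the potential inside the molecule can
    # overflow the exponential, and those nodes are ion-free by definition
    conc[accessibility$values == 0] <- 0
  }
  grid_map(conc, potential$origin, potential$spacing, units = "M")
}

#' One-call PB concentration maps for a structure
#'
#' Convenience wrapper: assigns coefficients, solves the configured PB
#' form (optionally with two-level focusing from a coarse grid) and
#' inverts the potential into cation and anion concentration maps of a 1:1
#' salt at the configured bulk ionic strength.
#'
#' @param structure A [structure_model].
#' @param grid Fine [grid_spec].
#' @param cfg A [pb_config].
#' @param coarse Optional coarse [grid_spec] for focusing.
#' @return A list with \code{potential}, \code{cation}, \code{anion}
#'   ([grid_map]s), \code{accessibility} mask and \code{coeffs}.
#' @export
pb_concentration_maps <- function(structure, grid, cfg = pb_config(),
                                  coarse = NULL) {
  coeffs <- assign_coefficients(structure, cfg, grid)
  pot <- if (is.null(coarse)) {
    pb_solve_internal(coeffs, cfg, nonlinear = (cfg$form == "nlpb"))
  } else {
    coeffs_coarse <- assign_coefficients(structure, cfg, coarse)
    focus(pb_solve_internal(coeffs_coarse, cfg,
                            nonlinear = (cfg$form == "nlpb")), coeffs, cfg)
  }
  acc <- grid_map(coeffs$access + 0, coeffs$grid$origin, coeffs$grid$spacing,
                  units = "mask")
  list(potential = pot,
       cation = boltzmann_concentration(pot, species_spec(1, cfg$ionic_strength), acc),
       anion = boltzmann_concentration(pot, species_spec(-1, cfg$ionic_strength), acc),
       accessibility = acc, coeffs = coeffs)
}
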