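#' Rigid-body superposition of trajectory frames onto a reference
#'
#' Least-squares optimal rotation + translation (Kabsch algorithm with the
#' proper-rotation correction, so the returned rotations always have
#' determinant +1) fitted on the per-frame protein coordinates and applied
#' to every particle of the frame.
#'
#' @param traj An [ion_trajectory].
#' @param reference Reference protein coordinates: a [structure_model] or
#'   an n x 3 matrix, in one-to-one atom correspondence with the per-frame
#'   protein coordinates.
#' @param protein_coords Optional list of per-frame n x 3 protein
#'   coordinate matrices; defaults to the trajectory's \code{"protein"}
#'   particles.
#' @return A list with \code{trajectory} (aligned frames) and
#'   \code{alignment}: per-frame rotations, translations and RMSD before /
#'   after fitting (Angstrom).
#' @export
align_frames <- function(traj, reference, protein_coords = NULL) {
  ref <- if (inherits(reference, "structure_model")) reference$positions
         else to_coord_matrix(reference)
  if (is.null(protein_coords)) protein_coords <- species_coords(traj, "protein")
  nf <- n_frames(traj)
  stopifnot(length(protein_coords) == nf)
  rot <- vector("list", nf); tra <- vector("list", nf)
  rmsd_before <- numeric(nf); rmsd_after <- numeric(nf)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    P <- to_coord_matrix(protein_coords[[f]])
    if (nrow(P) != nrow(ref))
      stop(sprintf("correspondence error: frame %d has %d protein atoms, reference has %d",
                   f, nrow(P), nrow(ref)))
    cp <- colMeans(P); cq <- colMeans(ref)
    H <- crossprod(sweep(P, 2, cp), sweep(ref, 2, cq))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    # x' = R (x - cp) + cq
    rot[[f]] <- R
    tra[[f]] <- as.numeric(cq - R %*% cp)
    rmsd_before[f] <- sqrt(mean(rowSums((P - ref)^2)))
    Pf <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
    rmsd_after[f] <- sqrt(mean(rowSums((Pf - ref)^2)))
    frames[[f]] <- sweep(sweep(traj$frames[[f]], 2, cp) %*% t(R), 2, cq, "+")
  }
  list(trajectory = ion_trajectory(frames, traj$species, traj$box),
       alignment = list(rotations = rot, translations = tra,
                        rmsd_before = rmsd_before, rmsd_after = rmsd_after))
}

#' Trajectory-derived ion concentration map (kernel density estimation)
#'
#' Deposits an isotropic radial triangular (cone) kernel
#' \eqn{K(d) \propto \max(0, 1 - d/h)} for every particle of the requested
#' species in every frame, renormalised on-grid so each sample contributes
#' total weight exactly 1, then converts the ensemble-averaged number
#' density to a molar concentration map.  Integrating the map over the
#' grid (times Avogadro's number and the voxel volume) recovers the mean
#' number of retained particles per frame exactly.
#'
#' @param traj An (aligned) [ion_trajectory].
#' @param species \code{"cation"}, \code{"anion"} or \code{"water"}.
#' @param grid A [grid_spec] or [grid_map] giving the target geometry.
#' @param bandwidth Kernel support radius h (Angstrom).
#' @param outside What to do with particles whose kernel has no on-grid
#'   mass: \code{"drop"} them with a warning or raise an \code{"error"}.
#' @return A [grid_map] in M; attribute \code{"retained"} gives the mean
#'   number of retained particles per frame.
#' @export
kde_concentration_map <- function(traj, species, grid, bandwidth = 2,
                                  outside = c("drop", "error")) {
  outside <- match.arg(outside)
  stopifnot(bandwidth > 0)
  g <- as_grid_spec(grid)
  coords <- species_coords(traj, species)
  nf <- length(coords)
  pts <- do.call(rbind, coords)
  if (nrow(pts) == 0L) {
    return(structure(grid_map(array(0, g$dims), g$origin, g$spacing, "M"),
                     retained = 0))
  }
  res <- cpp_kde_deposit(g$dims, g$origin, g$spacing, pts, bandwidth)
  if (res$dropped > 0) {
    msg <- sprintf("%d of %d samples fall outside the grid", res$dropped,
                   nrow(pts))
    if (outside == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  dens <- array(res$weights, dim = g$dims) / (nf * voxel_volume(g)) # A^-3
  conc <- dens / (.AVOGADRO * 1e-27)
  structure(grid_map(conc, g$origin, g$spacing, units = "M"),
            retained = (nrow(pts) - res$dropped) / nf)
}

#' Distance-to-closest-atom map
#'
#' Each node carries the minimum over atoms of the Euclidean distance from
#' the node to the atom *center* (no surface convention).
#'
#' @param grid A [grid_spec] or [grid_map].
#' @param structure A [structure_model].
#' @return A [grid_map] in Angstrom.
#' @export
distance_map <- function(grid, structure) {
  g <- as_grid_spec(grid)
  v <- cpp_distance_map(g$dims, g$origin, g$spacing, structure$positions)
  grid_map(array(v, dim = g$dims), g$origin, g$spacing, units = "A")
}

#' Region mask from a distance map
#'
#' Selects the grid nodes within \code{cutoff} of the closest structure
#' atom.  \code{max_distance} is the outer analysis limit (nodes beyond it
#' are never part of a region, and \code{cutoff} may not exceed it).
#'
#' @param distmap A distance [grid_map] (units \code{"A"}).
#' @param cutoff Distance cutoff (Angstrom).
#' @param max_distance Boundary-exclusion limit (Angstrom).
#' @return A binary mask [grid_map].
#' @export
region_mask <- function(distmap, cutoff, max_distance = Inf) {
  if (distmap$units != "A") stop("unit error: distmap must be in Angstrom")
  if (cutoff > max_distance)
    stop("cutoff exceeds the maximum analysis distance")
  m <- (distmap$values <= cutoff) * 1
  grid_map(m, distmap$origin, distmap$spacing, units = "mask")
}
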