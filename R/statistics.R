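#' Number of ions in a masked region of a concentration map
#'
#' \eqn{N_i = N_A \int_R c_i \, dr}: sum of concentration times voxel
#' volume over the masked nodes, with the \eqn{1\,\mathrm{\AA}^3 =
#' 10^{-27}} L conversion.
#'
#' @param conc A concentration [grid_map] (M).
#' @param mask A binary mask [grid_map] on the same grid, or \code{NULL}
#'   for the whole grid.
#' @return Real ion count.
#' @export
region_ion_count <- function(conc, mask = NULL) {
  if (conc$units != "M") stop("unit error: concentration map expected")
  m <- 1
  if (!is.null(mask)) {
    stop_if_incommensurate(conc, mask)
    m <- mask$values
  }
  .AVOGADRO * sum(conc$values * m) * voxel_volume(conc) * 1e-27
}

#' Volume of a masked region
#' @param mask A binary mask [grid_map].
#' @return Volume in liters.
#' @export
region_volume <- function(mask) sum(mask$values) * voxel_volume(mask) * 1e-27

#' Ion excess in a region
#'
#' Number of ions in the region minus the number an equal volume of bulk
#' would contain.
#'
#' @inheritParams region_ion_count
#' @param bulk Bulk concentration (M).
#' @return Real ion excess (may be negative).
#' @export
ion_excess <- function(conc, mask, bulk) {
  region_ion_count(conc, mask) - .AVOGADRO * bulk * region_volume(mask)
}

#' Neutrality-plus-ionic-strength ion addition
#'
#' Chooses the numbers of monovalent cations and anions that simultaneously
#' neutralise a solute of charge \eqn{Z} and give the solvent volume
#' \eqn{V} the bulk ionic strength \eqn{I}:
#' \deqn{N_+ + N_- = 2 I N_A V, \qquad Z + N_+ - N_- = 0,}
#' so that the whole-volume ion excesses are \eqn{\Delta N_\pm = \mp Z/2}.
#' The excesses are computed first (exact, including in floating point)
#' and the real ion numbers derived from them; integer counts round half
#' away from zero.
#'
#' @param Z Solute charge (e), may be non-integer.
#' @param I Bulk ionic strength (M).
#' @param V Solvent volume (L).
#' @return An object of class \code{ion_addition} with fields
#'   \code{n_plus_real}, \code{n_minus_real}, \code{n_plus},
#'   \code{n_minus} (rounded), \code{excess_plus}, \code{excess_minus}
#'   and \code{bulk_pairs} (\eqn{I N_A V}).
#' @export
ion_addition <- function(Z, I, V) {
  stopifnot(I > 0, V > 0)
  b <- I * .AVOGADRO * V
  excess_plus <- -Z / 2
  excess_minus <- +Z / 2
  n_plus_real <- b + excess_plus
  n_minus_real <- b + excess_minus
  if (n_plus_real < 0 || n_minus_real < 0)
    stop(sprintf("infeasible ion addition: |Z| = %g exceeds 2 I N_A V = %g",
                 abs(Z), 2 * b))
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  structure(list(Z = Z, I = I, V = V, bulk_pairs = b,
                 n_plus_real = n_plus_real, n_minus_real = n_minus_real,
                 n_plus = round_half_away(n_plus_real),
                 n_minus = round_half_away(n_minus_real),
                 excess_plus = excess_plus, excess_minus = excess_minus),
            class = "ion_addition")
}

#' @export
print.ion_addition <- function(x, ...) {
  cat(sprintf("<ion_addition> Z = %+g e, I = %g M, V = %g L\n", x$Z, x$I, x$V))
  cat(sprintf("  N+ = %g (%.4f), N- = %g (%.4f), dN+ = %+.4f, dN- = %+.4f\n",
              x$n_plus, x$n_plus_real, x$n_minus, x$n_minus_real,
              x$excess_plus, x$excess_minus))
  invisible(x)
}

#' Average number of ions within a cutoff of the structure (trajectory route)
#'
#' Per-frame count of species particles whose distance to the closest
#' structure atom is at most \code{cutoff}, averaged over frames.
#'
#' @param traj An [ion_trajectory].
#' @param structure A [structure_model], or a list of per-frame n x 3
#'   coordinate matrices for a moving structure.
#' @param species Species name.
#' @param cutoff Distance cutoff (Angstrom).
#' @return Mean ion count (real).
#' @export
bound_ion_count_md <- function(traj, structure, species, cutoff) {
  d <- trajectory_distances(traj, structure, species)
  mean(vapply(d, function(di) sum(di <= cutoff), 0))
}

# per-frame closest-atom distances for one species
trajectory_distances <- function(traj, structure, species) {
  coords <- species_coords(traj, species)
  if (inherits(structure, "structure_model")) {
    cpp_frame_distances(coords, structure$positions)
  } else {
    stopifnot(length(structure) == length(coords))
    mapply(function(p, a) cpp_closest_atom_distance(p, to_coord_matrix(a)),
           coords, structure, SIMPLIFY = FALSE)
  }
}

#' Total-charge and ion-excess profiles versus cutoff distance
#'
#' For each cutoff \eqn{d}: the total charge \eqn{Z + N_+(\le d) -
#' N_-(\le d)} of the solute plus enclosed ions, with companion excess
#' profiles \eqn{\Delta N_\pm(\le d)} relative to the bulk.
#'
#' @param Z Solute charge (e).
#' @param conc_plus,conc_minus Cation / anion concentration [grid_map]s (M).
#' @param distmap Distance [grid_map] (Angstrom).
#' @param cutoffs Vector of cutoffs (Angstrom).
#' @param bulk Bulk concentration (M) used for the excesses.
#' @param max_distance Outer analysis limit (Angstrom).
#' @return A data frame (class \code{profile_series}) with columns
#'   \code{cutoff}, \code{n_plus}, \code{n_minus}, \code{volume} (L),
#'   \code{total_charge}, \code{excess_plus}, \code{excess_minus}.
#' @export
total_charge_profile <- function(Z, conc_plus, conc_minus, distmap, cutoffs,
                                 bulk, max_distance = Inf) {
  rows <- lapply(cutoffs, function(d) {
    m <- region_mask(distmap, d, max_distance)
    np <- region_ion_count(conc_plus, m)
    nm <- region_ion_count(conc_minus, m)
    v <- region_volume(m)
    data.frame(cutoff = d, n_plus = np, n_minus = nm, volume = v,
               total_charge = Z + np - nm,
               excess_plus = np - .AVOGADRO * bulk * v,
               excess_minus = nm - .AVOGADRO * bulk * v)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("profile_series", "data.frame")
  out
}

#' Ionic-strength profile versus cutoff distance
#'
#' For a 1:1 salt: \eqn{I(\le d) = (N_+(\le d) + N_-(\le d)) / (2 N_A
#' V(\le d))} with \eqn{V} the masked voxel volume.
#'
#' @inheritParams total_charge_profile
#' @return A data frame (class \code{profile_series}) with columns
#'   \code{cutoff}, \code{ionic_strength} (M), \code{volume} (L).
#' @export
ionic_strength_profile <- function(conc_plus, conc_minus, distmap, cutoffs,
                                   max_distance = Inf) {
  rows <- lapply(cutoffs, function(d) {
    m <- region_mask(distmap, d, max_distance)
    v <- region_volume(m)
    i <- if (v > 0)
      (region_ion_count(conc_plus, m) + region_ion_count(conc_minus, m)) /
        (2 * .AVOGADRO * v)
    else NA_real_
    data.frame(cutoff = d, ionic_strength = i, volume = v)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("profile_series", "data.frame")
  out
}

#' Molality-based radial distribution function
#'
#' Distance-to-closest-atom RDF normalised by the local water count
#' instead of shell volumes, so it is well defined around irregular
#' shapes: with \eqn{h_i(r)} the ensemble-averaged histogram of species
#' \eqn{i} distances and \eqn{h_w(r)} the water histogram, the molality is
#' \eqn{m_i(r) = h_i(r) / (h_w(r) M_{water})} and
#' \eqn{g_i(r) = m_i(r) / m_i^{bulk}}, with the bulk molality computed
#' from the whole-box species and water counts.  Bins with no water are
#' flagged undefined (\code{NA}), not zero.  When the water model is
#' atomistic the water histogram would be the average of its three
#' atom-based histograms; the single-site waters used here are their own
#' histogram.
#'
#' @param traj An [ion_trajectory] containing water particles.
#' @param structure A [structure_model] (or per-frame coordinate list).
#' @param species \code{"cation"} or \code{"anion"}.
#' @param bin_width Histogram bin width (Angstrom).
#' @param r_max Largest distance analysed (Angstrom); defaults to the
#'   largest observed water distance.
#' @return A data frame (class \code{rdf_curve}) with columns \code{r}
#'   (bin centers), \code{h} (mean species count per frame),
#'   \code{h_water}, \code{molality} (mol/kg) and \code{g}; attributes
#'   \code{"bulk_molality"} (mol/kg) and \code{"bin_width"}.
#' @export
molality_rdf <- function(traj, structure, species, bin_width = 0.2,
                         r_max = NULL) {
  stopifnot(bin_width > 0)
  if (!any(traj$species == "water"))
    stop("molality RDF requires water particles in the trajectory")
  di <- unlist(trajectory_distances(traj, structure, species))
  dw <- unlist(trajectory_distances(traj, structure, "water"))
  if (is.null(r_max)) r_max <- max(dw)
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  nf <- n_frames(traj)
  hi <- graphics::hist(di[di <= max(breaks)], breaks = breaks, plot = FALSE)$counts / nf
  hw <- graphics::hist(dw[dw <= max(breaks)], breaks = breaks, plot = FALSE)$counts / nf
  n_i <- length(di) / nf
  n_w <- length(dw) / nf
  m_bulk <- n_i / (n_w * .M_WATER)
  m <- ifelse(hw > 0, hi / (hw * .M_WATER), NA_real_)
  g <- m / m_bulk
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    h = hi, h_water = hw, molality = m, g = g)
  class(out) <- c("rdf_curve", "data.frame")
  attr(out, "bulk_molality") <- m_bulk
  attr(out, "bin_width") <- bin_width
  out
}

#' Dispersion summary of a concentration map near the structure
#'
#' Boxplot-style summary of the node concentrations within
#' \code{max_distance} of the closest structure atom: median and
#' quartiles by linear-interpolation quantiles, whiskers at the 0.0005
#' and 0.9995 empirical quantiles (enclosing a 0.999 fraction of the
#' values), the values outside the whiskers as outliers, and the fraction
#' of exactly-zero nodes.
#'
#' @param conc A concentration [grid_map] (M).
#' @param distmap Distance [grid_map] on the same grid.
#' @param max_distance Outer analysis limit (Angstrom).
#' @return An object of class \code{dispersion_summary}.
#' @export
dispersion_summary <- function(conc, distmap, max_distance = 15) {
  stop_if_incommensurate(conc, distmap)
  v <- conc$values[distmap$values <= max_distance]
  if (length(v) == 0L) stop("no nodes within max_distance")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  w <- stats::quantile(v, c(0.0005, 0.9995), type = 7, names = FALSE)
  structure(list(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = w[1], whisker_high = w[2],
                 outliers = v[v < w[1] | v > w[2]],
                 zero_fraction = mean(v == 0)),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("<dispersion_summary> n = %d nodes\n", x$n))
  cat(sprintf("  median %.4g [Q1 %.4g, Q3 %.4g] M; whiskers [%.4g, %.4g]\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high))
  cat(sprintf("  %d outliers; zero fraction %.3f\n", length(x$outliers),
              x$zero_fraction))
  invisible(x)
}

#' Concentration-versus-distance scatter table
#'
#' One row per retained node (distance at most \code{max_distance}), no
#' aggregation.
#'
#' @inheritParams dispersion_summary
#' @return A data frame with columns \code{distance} (Angstrom) and
#'   \code{concentration} (M).
#' @export
scatter_table <- function(conc, distmap, max_distance = 15) {
  stop_if_incommensurate(conc, distmap)
  keep <- distmap$values <= max_distance
  data.frame(distance = distmap$values[keep],
             concentration = conc$values[keep])
}

#' Iso-concentration mask
#'
#' Binary mask of nodes with concentration at or above a level, suitable
#' for export as OpenDX and external contouring.
#'
#' @param conc A concentration [grid_map] (M).
#' @param level Concentration level (M), > 0.
#' @return A binary mask [grid_map].
#' @export
iso_concentration_mask <- function(conc, level) {
  stopifnot(level > 0)
  grid_map((conc$values >= level) * 1, conc$origin, conc$spacing,
           units = "mask")
}
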