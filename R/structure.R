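#' Fixed-atom structure with charges and radii
#'
#' The macromolecule (or synthetic bead model) against which all distances
#' are measured and whose partial charges source the electrostatic
#' potential.
#'
#' @param positions n x 3 matrix of atom positions (Angstrom).
#' @param charges Partial charge per atom (protonic units e).
#' @param radii Radius per atom (Angstrom), all non-negative.
#' @param labels Optional free-text atom labels.
#' @return An object of class \code{structure_model}.
#' @export
structure_model <- function(positions, charges, radii, labels = NULL) {
  positions <- to_coord_matrix(positions)
  n <- nrow(positions)
  if (n == 0L) stop("structure has zero atoms")
  charges <- as.numeric(charges); radii <- as.numeric(radii)
  stopifnot(length(charges) == n, length(radii) == n)
  if (any(!is.finite(positions)) || any(!is.finite(charges)) ||
      any(!is.finite(radii))) stop("non-finite structure fields")
  if (any(radii < 0)) stop("negative atom radius")
  if (is.null(labels)) labels <- sprintf("AT%d", seq_len(n))
  structure(list(positions = positions, charges = charges, radii = radii,
                 labels = as.character(labels)),
            class = "structure_model")
}

#' Total charge of a structure
#' @param structure A \code{structure_model}.
#' @return Sum of partial charges (e); the net charge Z of the molecule.
#' @export
total_charge <- function(structure) sum(structure$charges)

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, total charge %+.4g e\n",
              nrow(x$positions), total_charge(x)))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$positions)
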