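#' Multi-frame trajectory of mobile particles
#'
#' Frames of cation/anion/water (and optionally protein) positions in a
#' rectangular box.  Species identity and particle count are constant
#' across frames.
#'
#' @param frames List of n x 3 coordinate matrices (Angstrom), one per frame.
#' @param species Character vector, one of \code{"cation"}, \code{"anion"},
#'   \code{"water"}, \code{"protein"} per particle.
#' @param box Length-3 rectangular box edge lengths (Angstrom); the box is
#'   centered at the origin.
#' @return An object of class \code{ion_trajectory}.
#' @export
ion_trajectory <- function(frames, species, box) {
  stopifnot(is.list(frames), length(frames) >= 1L, length(box) == 3L,
            all(box > 0))
  species <- match.arg(species, c("cation", "anion", "water", "protein"),
                       several.ok = TRUE)
  n <- length(species)
  frames <- lapply(frames, to_coord_matrix)
  if (any(vapply(frames, nrow, 0L) != n))
    stop("particle count differs between frames and species vector")
  structure(list(frames = frames, species = species, box = as.numeric(box)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  tab <- table(factor(x$species, c("cation", "anion", "water", "protein")))
  cat(sprintf("<ion_trajectory> %d frames, box (%g, %g, %g) A\n",
              length(x$frames), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  %d cations, %d anions, %d waters, %d protein sites\n",
              tab["cation"], tab["anion"], tab["water"], tab["protein"]))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Extract coordinates of one species
#' @param traj An [ion_trajectory].
#' @param species Species name.
#' @return List of per-frame coordinate matrices for that species.
#' @export
species_coords <- function(traj, species) {
  sel <- traj$species == species
  lapply(traj$frames, function(f) f[sel, , drop = FALSE])
}

.XYZ_LABELS <- c(cation = "CAT", anion = "ANI", water = "WAT",
                 protein = "PRO")

#' Read an extended-XYZ trajectory
#'
#' Minimal dialect: per frame a particle-count line, a comment line
#' containing \code{box=Lx,Ly,Lz} (Angstrom), then \code{label x y z} lines
#' with labels in \code{CAT}, \code{ANI}, \code{WAT}, \code{PRO}.
#'
#' @param path Path to the file.
#' @return An [ion_trajectory].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= length(lines)]
  pos <- 1L
  frames <- list(); species0 <- NULL; box0 <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop("trajectory format error: bad particle count at line ", pos)
    if (pos + 1L + n > length(lines))
      stop("trajectory format error: truncated frame at line ", pos)
    comment <- lines[pos + 1L]
    m <- regmatches(comment,
                    regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                            comment))[[1]]
    if (length(m) != 4L)
      stop("trajectory format error: missing box=Lx,Ly,Lz at line ", pos + 1L)
    box <- as.numeric(m[2:4])
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    labs <- vapply(fields, `[`, "", 1L)
    bad <- which(!labs %in% .XYZ_LABELS)
    if (length(bad))
      stop("trajectory format error: unknown label '", labs[bad[1]],
           "' at line ", pos + 1L + bad[1])
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("trajectory format error: non-numeric coordinates near line ", pos + 2L)
    sp <- names(.XYZ_LABELS)[match(labs, .XYZ_LABELS)]
    if (is.null(species0)) {
      species0 <- sp; box0 <- box
    } else {
      if (length(sp) != length(species0) || any(sp != species0))
        stop("trajectory structure error: species/particle counts vary across frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(frames) == 0L) stop("trajectory format error: no frames in ", path)
  ion_trajectory(frames, species0, box0)
}

#' Write an extended-XYZ trajectory
#'
#' @param traj An [ion_trajectory].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path) {
  labs <- .XYZ_LABELS[traj$species]
  n <- length(labs)
  boxline <- sprintf("box=%.6f,%.6f,%.6f", traj$box[1], traj$box[2], traj$box[3])
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(c(sprintf("%d", n), boxline,
                 sprintf("%s %12.6f %12.6f %12.6f", labs, f[, 1], f[, 2], f[, 3])),
               con)
  }
  invisible(path)
}
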