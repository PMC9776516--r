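#' Read a PQR structure file
#'
#' Whitespace-delimited PQR: every \code{ATOM}/\code{HETATM} record carries
#' \code{x y z charge radius} as its last five numeric fields.  All other
#' lines are ignored.  PDB files are accepted for coordinates only via
#' \code{charge_default}/\code{radius_default}.
#'
#' @param path Path to the file.
#' @return A [structure_model].
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  pos <- matrix(0, length(idx), 3)
  q <- numeric(length(idx)); r <- numeric(length(idx))
  labs <- character(length(idx))
  for (a in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[a]]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(fields))
    nn <- which(!is.na(nums))
    last5 <- utils::tail(nn, 5)
    if (length(last5) < 5 || anyNA(nums[last5]))
      stop(sprintf("malformed PQR record at line %d of %s", idx[a], path))
    v <- nums[last5]
    pos[a, ] <- v[1:3]; q[a] <- v[4]; r[a] <- v[5]
    labs[a] <- if (length(fields) >= 3) fields[3] else fields[1]
  }
  structure_model(pos, q, r, labs)
}

#' Write a structure as PQR
#'
#' @param structure A [structure_model].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pqr <- function(structure, path) {
  n <- n_atoms(structure)
  lines <- sprintf("ATOM  %5d %-4s MOL %5d    %10.6f %10.6f %10.6f %10.6f %10.6f",
                   seq_len(n), substr(structure$labels, 1, 4), 1L,
                   structure$positions[, 1], structure$positions[, 2],
                   structure$positions[, 3], structure$charges,
                   structure$radii)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
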