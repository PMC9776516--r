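#' Read an OpenDX scalar grid (APBS dialect)
#'
#' Expects \code{object 1 class gridpositions counts nx ny nz}, an
#' \code{origin} line, three \code{delta} lines (diagonal spacing only) and
#' the data array with the last (z) axis varying fastest.
#'
#' @param path Path to the .dx file.
#' @param units Units tag to attach to the returned map.
#' @return A [grid_map].
#' @export
read_dx <- function(path, units = "1") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  num_after <- function(pattern) {
    ln <- grep(pattern, lines, value = TRUE)[1]
    if (is.na(ln)) stop("DX format error: missing '", pattern, "' in ", path)
    as.numeric(regmatches(ln, gregexpr("[-+0-9.eE]+", ln))[[1]])
  }
  counts <- num_after("gridpositions counts")
  dims <- as.integer(utils::tail(counts, 3))
  origin <- utils::tail(num_after("^origin"), 3)
  deltas <- grep("^delta", lines, value = TRUE)
  if (length(deltas) != 3L) stop("DX format error: expected 3 delta lines in ", path)
  dmat <- t(vapply(deltas, function(ln)
    utils::tail(as.numeric(regmatches(ln, gregexpr("[-+0-9.eE]+", ln))[[1]]), 3),
    numeric(3)))
  if (any(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) > 1e-12))
    stop("DX format error: non-diagonal delta (rotated grids unsupported)")
  spacing <- diag(dmat)
  start <- grep("object 3 class array", lines)[1]
  if (is.na(start)) stop("DX format error: missing data array object in ", path)
  end <- grep("^(attribute|object \"|component|end)", lines)
  end <- c(end[end > start], length(lines) + 1L)[1]
  data_lines <- lines[(start + 1L):(end - 1L)]
  vals <- as.numeric(unlist(strsplit(trimws(paste(data_lines, collapse = " ")),
                                     "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop(sprintf("DX format error: header promises %d values, found %d",
                 prod(dims), length(vals)))
  # file order: z fastest -> fill [k,j,i] then permute to [i,j,k]
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  grid_map(arr, origin, spacing, units = units)
}

#' Write a grid map as OpenDX (APBS dialect)
#'
#' @param grid A [grid_map].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar grid written by ionatmos (units: %s)", grid$units),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.9g %.9g %.9g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.9g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.9g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.9g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1))) # z fastest on disk
  n <- length(vals)
  pad <- ceiling(n / 3) * 3 - n
  m <- matrix(c(sprintf("%.7e", vals), rep("", pad)), nrow = 3)
  writeLines(trimws(apply(m, 2, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
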