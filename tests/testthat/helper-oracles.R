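# Independent brute-force oracles: plain R nested loops, deliberately naive,
# sharing no code with the package internals.

AVOGADRO <- 6.02214076e23

node_position <- function(g, i, j, k) {
  g$origin + (c(i, j, k) - 1) * g$spacing
}

bf_distance_map <- function(gspec, atoms) {
  d <- array(NA_real_, gspec$dims)
  for (k in seq_len(gspec$dims[3]))
    for (j in seq_len(gspec$dims[2]))
      for (i in seq_len(gspec$dims[1])) {
        p <- node_position(gspec, i, j, k)
        best <- Inf
        for (a in seq_len(nrow(atoms)))
          best <- min(best, sqrt(sum((p - atoms[a, ])^2)))
        d[i, j, k] <- best
      }
  d
}

bf_region_count <- function(conc_values, mask_values, voxvol) {
  total <- 0
  for (idx in seq_along(conc_values))
    if (mask_values[idx] == 1) total <- total + conc_values[idx]
  AVOGADRO * total * voxvol * 1e-27
}

# triangular-kernel density summed node by node and sample by sample, with
# per-sample on-grid renormalisation, converted to M
bf_kde_map <- function(gspec, samples, h, n_frames) {
  vox <- prod(gspec$spacing)
  acc <- array(0, gspec$dims)
  for (s in seq_len(nrow(samples))) {
    w <- array(0, gspec$dims)
    for (k in seq_len(gspec$dims[3]))
      for (j in seq_len(gspec$dims[2]))
        for (i in seq_len(gspec$dims[1])) {
          d <- sqrt(sum((node_position(gspec, i, j, k) - samples[s, ])^2))
          if (d < h) w[i, j, k] <- 1 - d / h
        }
    if (sum(w) > 0) acc <- acc + w / sum(w)
  }
  acc / (n_frames * vox) / (AVOGADRO * 1e-27)
}

bf_bound_count <- function(frames_species_coords, atoms, cutoff) {
  per_frame <- vapply(frames_species_coords, function(fr) {
    n <- 0
    for (p in seq_len(nrow(fr))) {
      best <- Inf
      for (a in seq_len(nrow(atoms)))
        best <- min(best, sqrt(sum((fr[p, ] - atoms[a, ])^2)))
      if (best <= cutoff) n <- n + 1
    }
    n
  }, 0)
  mean(per_frame)
}

bf_closest_histogram <- function(frames_species_coords, atoms, breaks) {
  counts <- rep(0, length(breaks) - 1)
  for (fr in frames_species_coords) {
    for (p in seq_len(nrow(fr))) {
      best <- Inf
      for (a in seq_len(nrow(atoms)))
        best <- min(best, sqrt(sum((fr[p, ] - atoms[a, ])^2)))
      for (b in seq_len(length(breaks) - 1))
        if (best > breaks[b] && best <= breaks[b + 1])
          counts[b] <- counts[b] + 1
    }
  }
  counts / length(frames_species_coords)
}

# small random fixture: trajectory with ions and waters uniform in a box
random_trajectory <- function(n_frames, n_cat, n_ani, n_wat, box, seed) {
  set.seed(seed)
  n <- n_cat + n_ani + n_wat
  frames <- lapply(seq_len(n_frames), function(f)
    cbind(runif(n, -box / 2, box / 2), runif(n, -box / 2, box / 2),
          runif(n, -box / 2, box / 2)))
  ion_trajectory(frames, c(rep("cation", n_cat), rep("anion", n_ani),
                           rep("water", n_wat)), rep(box, 3))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- svd(matrix(rnorm(9), 3))$u
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
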