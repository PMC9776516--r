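test_that("charged sphere is a single atom with the requested fields", {
  s <- make_charged_sphere(10, 12)
  expect_equal(nrow(s$positions), 1L)
  expect_equal(total_charge(s), 12)
  expect_equal(s$radii, 10)
  g <- grid_spec_centered(c(0, 0, 0), 40, 1)
  dm <- distance_map(g, s)
  expect_equal(grid_interpolate(dm, c(15, 0, 0)), 15) # atom-center convention
})

test_that("bead protein placement is reproducible and respects separation", {
  a <- make_bead_protein(50, 15, bead_radius = 1, cluster_radius = 12,
                         min_separation = 2, seed = 99)
  b <- make_bead_protein(50, 15, bead_radius = 1, cluster_radius = 12,
                         min_separation = 2, seed = 99)
  expect_identical(a, b)
  expect_equal(total_charge(a), 15)
  dmin <- min(dist(a$positions))
  expect_gte(dmin, 2)
  expect_identical(make_bead_protein(1, 3, bead_radius = 5, seed = 1)$positions,
                   make_charged_sphere(5, 3)$positions)
  expect_error(make_bead_protein(500, 0, bead_radius = 1, cluster_radius = 3,
                                 min_separation = 2, seed = 1,
                                 max_attempts = 50),
               "placement error")
})

test_that("analytic screened-sphere potential matches its closed form", {
  g <- grid_spec_centered(c(0, 0, 0), 40, 1)
  expect_equal(max(abs(analytic_dh_potential(make_charged_sphere(10, 0),
                                             g)$values)), 0)
  # frozen regression value from an independent evaluation of the closed form
  u <- analytic_dh_potential(make_charged_sphere(10, 12), g,
                             ionic_strength = 0.1, temperature = 300,
                             sdie = 80)
  expect_equal(grid_interpolate(u, c(15, 0, 0)), 1.6450865135478492,
               tolerance = 1e-9)
  # kappa -> 0 limit is the bare Coulomb potential in kT/e
  u0 <- analytic_dh_potential(make_charged_sphere(10, 12), g,
                              ionic_strength = 1e-16)
  lB <- 1.6710094689828735e5 / 300
  expect_equal(grid_interpolate(u0, c(15, 0, 0)), 12 * lB / (80 * 15),
               tolerance = 1e-6)
})

test_that("uncharged non-interacting ions fill the box uniformly", {
  s <- make_charged_sphere(2, 0)
  # wide stride so recorded frames are effectively independent
  tr <- sample_ion_configurations(s, box = 60, sweeps = 9000, stride = 60,
                                  n_cation = 40, n_anion = 0,
                                  interactions = "ideal", seed = 21)
  occ <- vapply(species_coords(tr, "cation"),
                function(f) sum(f[, 1] > 0), 0)
  se <- sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - 20), 3 * se + 1e-12)
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  s <- make_bead_protein(3, 2, bead_radius = 2, cluster_radius = 4, seed = 5)
  a <- sample_ion_configurations(s, box = 60, sweeps = 500, n_water = 50,
                                 seed = 17)
  b <- sample_ion_configurations(s, box = 60, sweeps = 500, n_water = 50,
                                 seed = 17)
  expect_identical(a$frames, b$frames)
})

test_that("incremental and recomputed energies agree after 1000 sweeps", {
  s <- make_bead_protein(4, 3, bead_radius = 2, cluster_radius = 5, seed = 2)
  tr <- sample_ion_configurations(s, box = 60, sweeps = 1000, seed = 4)
  mc <- attr(tr, "mc")
  expect_lt(abs(mc$energy_incremental - mc$energy_recomputed),
            1e-8 * max(1, abs(mc$energy_recomputed)))
})

test_that("too small a box is a geometry error", {
  s <- make_charged_sphere(2, 1)
  expect_error(sample_ion_configurations(s, box = 20, sweeps = 100,
                                         n_cation = 2, n_anion = 2, seed = 1),
               "geometry error|margin")
})

test_that("dilute anions around a central charge follow the Boltzmann weight", {
  # density ratio between two shells matches exp(-[u(r1)-u(r2)]) of the
  # sampler's own pair potential, within sampling error
  q <- 2; a <- 2; rion <- 1.5
  s <- make_charged_sphere(a, q)
  tr <- sample_ion_configurations(s, box = 60, sweeps = 8000, stride = 10,
                                  n_cation = 0, n_anion = 30,
                                  ion_radius = rion,
                                  interactions = "no-ion-ion", seed = 31)
  kappa <- debye_kappa(0.1, 300, 80)
  lB <- (1.6710094689828735e5 / 300) / 80
  b <- a + rion
  u <- function(r) -1 * q * lB * exp(-kappa * (r - b)) / ((1 + kappa * b) * r)
  shell_counts <- function(lo, hi) {
    vapply(species_coords(tr, "anion"), function(f)
      sum(rowSums(f^2) > lo^2 & rowSums(f^2) <= hi^2), 0)
  }
  # expected mean Boltzmann factor over each shell (numerical radial average)
  mean_w <- function(lo, hi) {
    r <- seq(lo, hi, length.out = 400)
    sum(exp(-u(r)) * r^2) / sum(r^2)
  }
  c1 <- shell_counts(4, 8);  c2 <- shell_counts(12, 16)
  v1 <- 4 / 3 * pi * (8^3 - 4^3); v2 <- 4 / 3 * pi * (16^3 - 12^3)
  obs <- mean(c1) / v1 / (mean(c2) / v2)
  expected <- mean_w(4, 8) / mean_w(12, 16)
  nf <- length(c1)
  se <- obs * sqrt(var(c1) / nf / mean(c1)^2 + var(c2) / nf / mean(c2)^2)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("the single-ion radial histogram matches the Boltzmann weight", {
  # detailed-balance surrogate: chi-squared test against the analytic
  # equilibrium profile, not rejected at alpha = 0.01, across seeds
  q <- 2; a <- 2; rion <- 1.5
  s <- make_charged_sphere(a, q)
  kappa <- debye_kappa(0.1, 300, 80)
  lB <- (1.6710094689828735e5 / 300) / 80
  b <- a + rion
  u <- function(r) -1 * q * lB * exp(-kappa * (r - b)) / ((1 + kappa * b) * r)
  breaks <- seq(4, 26, by = 2)
  for (seed in c(101, 202)) {
    tr <- sample_ion_configurations(s, box = 60, sweeps = 30000, stride = 15,
                                    equil_fraction = 0.1,
                                    n_cation = 0, n_anion = 1,
                                    ion_radius = rion,
                                    interactions = "no-ion-ion", seed = seed)
    r_obs <- vapply(species_coords(tr, "anion"),
                    function(f) sqrt(sum(f[1, ]^2)), 0)
    obs <- hist(r_obs[r_obs > 4 & r_obs <= 26], breaks = breaks,
                plot = FALSE)$counts
    w <- vapply(seq_len(length(breaks) - 1), function(j) {
      r <- seq(breaks[j], breaks[j + 1], length.out = 200)
      mean(exp(-u(r)) * r^2) * (breaks[j + 1] - breaks[j])
    }, 0)
    expected <- sum(obs) * w / sum(w)
    chi2 <- sum((obs - expected)^2 / expected)
    expect_lt(chi2, qchisq(0.99, df = length(obs) - 1))
  }
})
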