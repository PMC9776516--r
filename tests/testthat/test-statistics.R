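uniform_map <- function(value, dims = c(5, 5, 5), spacing = 1) {
  grid_map(array(value, dims), c(0, 0, 0), spacing, units = "M")
}

full_mask <- function(dims = c(5, 5, 5), spacing = 1) {
  grid_map(array(1, dims), c(0, 0, 0), spacing, units = "mask")
}

test_that("region ion counts reproduce the unit arithmetic and brute force", {
  # 0.1 M over 1000 A^3: 0.1 * N_A * 1e-24 = 0.06022 ions
  m <- uniform_map(0.1, c(10, 10, 10))
  mask <- full_mask(c(10, 10, 10))
  expect_equal(region_ion_count(m, mask), 0.1 * 6.02214076e23 * 1e-24,
               tolerance = 1e-12)
  expect_equal(region_ion_count(uniform_map(0), full_mask()), 0)
  set.seed(33)
  vals <- array(runif(125), c(5, 5, 5))
  msk <- array(rbinom(125, 1, 0.5), c(5, 5, 5))
  conc <- grid_map(vals, c(0, 0, 0), 1, units = "M")
  mask2 <- grid_map(msk, c(0, 0, 0), 1, units = "mask")
  expect_equal(region_ion_count(conc, mask2),
               bf_region_count(vals, msk, 1), tolerance = 1e-12)
})

test_that("ion excess is zero at bulk and fully depleted when empty", {
  mask <- full_mask()
  expect_equal(ion_excess(uniform_map(0.1), mask, bulk = 0.1), 0,
               tolerance = 1e-12)
  vr <- region_volume(mask)
  expect_equal(ion_excess(uniform_map(0), mask, bulk = 0.1),
               -6.02214076e23 * 0.1 * vr, tolerance = 1e-12)
  # three-node toy region, hand-summed
  vals <- array(0.1, c(2, 2, 2))
  vals[1, 1, 1] <- 0; vals[2, 1, 1] <- 0.3
  conc <- grid_map(vals, c(0, 0, 0), 1, units = "M")
  msk <- array(0, c(2, 2, 2)); msk[1:2, 1, 1] <- 1; msk[1, 2, 1] <- 1
  mask3 <- grid_map(msk, c(0, 0, 0), 1, units = "mask")
  hand <- 6.02214076e23 * 1e-27 * ((0 - 0.1) + (0.3 - 0.1) + (0.1 - 0.1))
  expect_equal(ion_excess(conc, mask3, 0.1), hand, tolerance = 1e-12)
})

test_that("ion addition solves neutrality plus ionic strength", {
  # Z = 12 with I*N_A*V = 100 pairs
  V <- 100 / (0.1 * 6.02214076e23)
  sol <- ion_addition(12, 0.1, V)
  expect_equal(sol$n_plus, 94)
  expect_equal(sol$n_minus, 106)
  expect_equal(sol$excess_plus, -6)
  expect_equal(sol$excess_minus, 6)
  # whole-box excess from the ion numbers: dN+ = (N+ - N-)/2 = -Z/2
  expect_equal((sol$n_plus_real - sol$n_minus_real) / 2, -6)
  z0 <- ion_addition(0, 0.1, V)
  expect_equal(z0$n_plus_real, z0$n_minus_real)
  expect_equal(z0$excess_plus, 0)
  expect_error(ion_addition(300, 0.1, V), "infeasible")
})

test_that("neutrality and half-charge identities are exact over a sweep", {
  set.seed(77)
  for (i in 1:1000) {
    Z <- runif(1, -30, 30)
    I <- runif(1, 0.01, 1)
    V <- 10^runif(1, -20, -18)
    s <- ion_addition(Z, I, V)
    expect_true(Z + s$excess_plus - s$excess_minus == 0)
    expect_true(s$excess_plus == -Z / 2 && s$excess_minus == Z / 2)
    expect_equal(s$n_plus_real + s$n_minus_real, 2 * I * 6.02214076e23 * V,
                 tolerance = 1e-12)
  }
})

test_that("bound-ion counts average the per-frame cutoff counts", {
  st <- structure_model(matrix(0, 1, 3), 0, 1)
  fr <- list(matrix(c(3, 0, 0), 1, 3))
  tr <- ion_trajectory(fr, "cation", c(60, 60, 60))
  expect_equal(bound_ion_count_md(tr, st, "cation", 3.5), 1)
  expect_equal(bound_ion_count_md(tr, st, "cation", 2), 0)
  fr2 <- list(matrix(c(1, 0, 0), 1, 3), matrix(c(20, 0, 0), 1, 3))
  tr2 <- ion_trajectory(fr2, "cation", c(60, 60, 60))
  expect_equal(bound_ion_count_md(tr2, st, "cation", 5), 0.5)
  # brute force on a random fixture
  set.seed(41)
  atoms <- matrix(runif(15, -3, 3), 5, 3)
  st5 <- structure_model(atoms, rep(0, 5), rep(1, 5))
  tr10 <- random_trajectory(10, 6, 4, 0, 20, seed = 6)
  for (cutoff in c(2, 5, 9))
    expect_equal(bound_ion_count_md(tr10, st5, "anion", cutoff),
                 bf_bound_count(species_coords(tr10, "anion"), atoms, cutoff))
})

test_that("profiles recover trivial limits and brute-force integration", {
  g <- grid_spec(c(-2, -2, -2), 1, c(5, 5, 5))
  st <- structure_model(matrix(0, 1, 3), 3, 1)
  dm <- distance_map(g, st)
  cp <- grid_map(array(0.1, c(5, 5, 5)), g$origin, 1, units = "M")
  cm <- grid_map(array(0.1, c(5, 5, 5)), g$origin, 1, units = "M")
  ip <- ionic_strength_profile(cp, cm, dm, cutoffs = c(1, 2, 3))
  expect_equal(ip$ionic_strength, rep(0.1, 3))
  zp <- ionic_strength_profile(grid_map(array(0, c(5, 5, 5)), g$origin, 1, "M"),
                               grid_map(array(0, c(5, 5, 5)), g$origin, 1, "M"),
                               dm, 2)
  expect_equal(zp$ionic_strength, 0)
  set.seed(55)
  vp <- grid_map(array(runif(125, 0, 0.3), c(5, 5, 5)), g$origin, 1, "M")
  vm <- grid_map(array(runif(125, 0, 0.3), c(5, 5, 5)), g$origin, 1, "M")
  prof <- total_charge_profile(3, vp, vm, dm, cutoffs = c(1.5, 2.5), bulk = 0.1)
  for (r in 1:2) {
    msk <- (dm$values <= prof$cutoff[r]) * 1
    np <- bf_region_count(vp$values, msk, 1)
    nm <- bf_region_count(vm$values, msk, 1)
    expect_equal(prof$n_plus[r], np, tolerance = 1e-12)
    expect_equal(prof$total_charge[r], 3 + np - nm, tolerance = 1e-12)
    vol <- sum(msk) * 1e-27
    expect_equal(prof$excess_minus[r], nm - 6.02214076e23 * 0.1 * vol,
                 tolerance = 1e-12)
  }
  # hand-checked ionic strength on the same toy grid
  ih <- ionic_strength_profile(vp, vm, dm, 1.5)
  msk <- (dm$values <= 1.5) * 1
  hand <- (bf_region_count(vp$values, msk, 1) +
             bf_region_count(vm$values, msk, 1)) /
    (2 * 6.02214076e23 * sum(msk) * 1e-27)
  expect_equal(ih$ionic_strength, hand, tolerance = 1e-12)
})

test_that("region ion count is monotone in the cutoff distance", {
  g <- grid_spec(c(-4, -4, -4), 1, c(9, 9, 9))
  st <- structure_model(matrix(0, 1, 3), 1, 1)
  dm <- distance_map(g, st)
  set.seed(60)
  conc <- grid_map(array(runif(729, 0, 0.4), c(9, 9, 9)), g$origin, 1, "M")
  counts <- vapply(seq(0.5, 6, 0.5), function(d)
    region_ion_count(conc, region_mask(dm, d)), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("the molality RDF normalises by local water and bulk molality", {
  # single frame: 2 ions and 30 waters hand-placed in one distance bin
  st <- structure_model(matrix(0, 1, 3), 0, 1)
  set.seed(71)
  dir <- function(n, r) {
    v <- matrix(rnorm(3 * n), n, 3)
    r * v / sqrt(rowSums(v^2))
  }
  ions <- dir(2, 5.05)
  wat <- rbind(dir(30, 5.05), dir(200, 12.05))
  fr <- list(rbind(ions, wat))
  tr <- ion_trajectory(fr, c(rep("cation", 2), rep("water", 230)),
                       c(60, 60, 60))
  rdf <- molality_rdf(tr, st, "cation", bin_width = 0.1, r_max = 15)
  M_w <- 0.01801528
  bin <- which(rdf$r > 5.0 & rdf$r <= 5.1)
  expect_equal(rdf$molality[bin], 2 / (30 * M_w), tolerance = 1e-12)
  m_bulk <- 2 / (230 * M_w)
  expect_equal(attr(rdf, "bulk_molality"), m_bulk, tolerance = 1e-12)
  expect_equal(rdf$g[bin], (2 / (30 * M_w)) / m_bulk, tolerance = 1e-12)
  # a bin with water but no ions has g = 0; a bin with no water is undefined
  bin2 <- which(rdf$r > 12.0 & rdf$r <= 12.1)
  expect_equal(rdf$g[bin2], 0)
  empty <- which(rdf$r > 8.0 & rdf$r <= 8.1)
  expect_true(is.na(rdf$g[empty]))
  expect_error(molality_rdf(ion_trajectory(list(ions), rep("cation", 2),
                                           c(60, 60, 60)), st, "cation"),
               "water")
})

test_that("uniform ions and water give g = 1 in bulk bins", {
  st <- structure_model(matrix(0, 1, 3), 0, 1)
  tr <- random_trajectory(60, 40, 0, 800, 50, seed = 13)
  rdf <- molality_rdf(tr, st, "cation", bin_width = 1, r_max = 20)
  bulkish <- rdf$g[rdf$r > 8 & rdf$r <= 20 & !is.na(rdf$g)]
  se <- sd(bulkish) / sqrt(length(bulkish))
  expect_lt(abs(mean(bulkish) - 1), 3 * se)
})

test_that("RDF histograms match a brute-force nested loop", {
  set.seed(81)
  atoms <- matrix(runif(9, -2, 2), 3, 3)
  st <- structure_model(atoms, rep(0, 3), rep(1, 3))
  tr <- random_trajectory(6, 4, 3, 50, 24, seed = 9)
  rdf <- molality_rdf(tr, st, "anion", bin_width = 2, r_max = 16)
  breaks <- seq(0, 16, by = 2)
  expect_equal(rdf$h[seq_len(8)],
               bf_closest_histogram(species_coords(tr, "anion"), atoms,
                                    breaks),
               tolerance = 1e-12)
})

test_that("dispersion summaries follow the stated quantile conventions", {
  g <- grid_spec(c(0, 0, 0), 1, c(10, 10, 10))
  dm <- grid_map(array(1, c(10, 10, 10)), c(0, 0, 0), 1, units = "A")
  const <- grid_map(array(0.07, c(10, 10, 10)), c(0, 0, 0), 1, units = "M")
  d <- dispersion_summary(const, dm, 15)
  expect_equal(c(d$whisker_low, d$q1, d$median, d$q3, d$whisker_high),
               rep(0.07, 5))
  expect_length(d$outliers, 0)
  vals <- array(as.numeric(1:1000), c(10, 10, 10))
  conc <- grid_map(vals, c(0, 0, 0), 1, units = "M")
  d2 <- dispersion_summary(conc, dm, 15)
  expect_equal(c(d2$q1, d2$median, d2$q3),
               unname(quantile(1:1000, c(0.25, 0.5, 0.75), type = 7)))
  expect_equal(d2$whisker_low, unname(quantile(1:1000, 5e-4, type = 7)))
  expect_true(all(d2$outliers < d2$whisker_low | d2$outliers > d2$whisker_high))
  zero <- grid_map(array(0, c(10, 10, 10)), c(0, 0, 0), 1, units = "M")
  expect_equal(dispersion_summary(zero, dm, 15)$zero_fraction, 1)
})

test_that("scatter tables list every retained node once", {
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  dmv <- array(c(1, 2, 3, 4, 20, 20, 20, 20), c(2, 2, 2))
  dm <- grid_map(dmv, c(0, 0, 0), 1, units = "A")
  conc <- grid_map(array(as.numeric(1:8) / 100, c(2, 2, 2)), c(0, 0, 0), 1,
                   units = "M")
  tab <- scatter_table(conc, dm, max_distance = 10)
  expect_equal(nrow(tab), 4L)
  expect_equal(sort(tab$distance), c(1, 2, 3, 4))
  expect_equal(nrow(scatter_table(conc, dm, 100)), sum(dmv <= 100))
})

test_that("iso-concentration masks threshold and nest correctly", {
  conc <- grid_map(array(c(0.1, 0.25, 0.45, rep(0.2, 5)), c(2, 2, 2)),
                   c(0, 0, 0), 1, units = "M")
  expect_equal(sum(iso_concentration_mask(conc, 1)$values), 0)
  expect_equal(sum(iso_concentration_mask(uniform_map(0.2, c(2, 2, 2)),
                                          0.2)$values), 8)
  m200 <- iso_concentration_mask(conc, 0.2)
  m400 <- iso_concentration_mask(conc, 0.4)
  expect_true(all(m400$values <= m200$values))
})
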