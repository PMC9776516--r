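test_that("charge spreading is trilinear and conservative", {
  g <- grid_spec(c(-2, -2, -2), 1, c(5, 5, 5))
  cfg <- pb_config()
  # charge exactly on a node
  st <- structure_model(matrix(0, 1, 3), 2.5, 1)
  co <- assign_coefficients(st, cfg, g)
  expect_equal(co$charge[3, 3, 3], 2.5)
  expect_equal(sum(co$charge), 2.5)
  # charge at a voxel center: 1/8 on each surrounding node
  st <- structure_model(matrix(0.5, 1, 3), 1, 1)
  co <- assign_coefficients(st, cfg, g)
  expect_equal(as.vector(co$charge[3:4, 3:4, 3:4]), rep(1 / 8, 8))
  expect_equal(sum(co$charge), 1, tolerance = 1e-12)
})

test_that("the accessibility boundary sits at atom radius + Stern", {
  a <- 6; stern <- 2
  g <- grid_spec_centered(c(0, 0, 0), 30, 1)
  cfg <- pb_config(stern = stern)
  co <- assign_coefficients(make_charged_sphere(a, 1), cfg, g)
  x <- grid_axis(g, 1)
  mid <- (g$dims[2] + 1) / 2
  access_line <- co$access[, mid, mid] # radial scan along +x through center
  boundary <- min(abs(x[access_line == 1]))
  expect_lt(abs(boundary - (a + stern)), 1 + 1e-9) # within one spacing
})

test_that("zero charges give the zero potential for both forms", {
  g <- grid_spec_centered(c(0, 0, 0), 20, 1)
  cfg <- pb_config(tol = 1e-8)
  co <- assign_coefficients(make_charged_sphere(3, 0), cfg, g)
  expect_equal(max(abs(solve_lpb(co, cfg)$values)), 0)
  expect_equal(max(abs(solve_nlpb(co, cfg)$values)), 0)
})

test_that("the LPB solution matches the analytic screened sphere", {
  sph <- make_charged_sphere(10, 12)
  cfg <- pb_config(idie = 80, sdie = 80, stern = 0, ionic_strength = 0.1,
                   tol = 1e-7, form = "lpb")
  g <- grid_spec_centered(c(0, 0, 0), 40, 1)
  u <- solve_lpb(assign_coefficients(sph, cfg, g), cfg)
  ref <- analytic_dh_potential(sph, g, 0.1, 300, 80)
  dm <- distance_map(g, sph)
  sel <- dm$values >= 12 & dm$values <= 20
  expect_lt(max(abs(u$values[sel] - ref$values[sel]) / ref$values[sel]), 0.02)
})

test_that("halving the spacing reduces the sphere-oracle error at order >= 1", {
  sph <- make_charged_sphere(10, 12)
  cfg <- pb_config(idie = 80, sdie = 80, stern = 0, tol = 1e-7, form = "lpb")
  err <- vapply(c(2, 1), function(sp) {
    g <- grid_spec_centered(c(0, 0, 0), 48, sp)
    u <- solve_lpb(assign_coefficients(sph, cfg, g), cfg)
    ref <- analytic_dh_potential(sph, g, 0.1, 300, 80)
    dm <- distance_map(g, sph)
    sel <- dm$values >= 12 & dm$values <= 24
    max(abs(u$values[sel] - ref$values[sel]) / ref$values[sel])
  }, 0)
  expect_lt(err[2], err[1] / 2) # observed order >= 1
})

test_that("NLPB agrees with LPB for weak potentials and is odd in the charges", {
  g <- grid_spec_centered(c(0, 0, 0), 36, 1)
  cfg <- pb_config(idie = 80, sdie = 80, stern = 0, tol = 1e-8)
  sph <- make_charged_sphere(10, 1)
  co <- assign_coefficients(sph, cfg, g)
  ul <- solve_lpb(co, cfg)
  un <- solve_nlpb(co, cfg)
  expect_lt(max(abs(un$values - ul$values)), 0.01 * max(abs(ul$values)))
  # charge conjugation: negating the charges negates the potential
  neg <- assign_coefficients(make_charged_sphere(10, -1), cfg, g)
  un_neg <- solve_nlpb(neg, cfg)
  expect_equal(un_neg$values, -un$values, tolerance = 1e-6)
})

test_that("focusing inherits its boundary from the coarse solution", {
  sph <- make_charged_sphere(8, 6)
  cfg <- pb_config(idie = 80, sdie = 80, stern = 0, tol = 1e-7, form = "lpb")
  gc <- grid_spec_centered(c(0, 0, 0), 72, 2)
  uc <- solve_lpb(assign_coefficients(sph, cfg, gc), cfg)
  gf <- grid_spec_centered(c(0, 0, 0), 36, 1)
  cof <- assign_coefficients(sph, cfg, gf)
  uf <- focus(uc, cof, cfg)
  # boundary nodes exactly equal the interpolated coarse values
  bnd <- uf$values[1, , ]
  co <- as.matrix(expand.grid(x = gf$origin[1], y = grid_axis(gf, 2),
                              z = grid_axis(gf, 3)))
  expect_equal(as.vector(bnd), grid_interpolate(uc, co), tolerance = 1e-12)
  # focused solve beats the coarse solution against the analytic oracle
  reff <- analytic_dh_potential(sph, gf, 0.1, 300, 80)
  dmf <- distance_map(gf, sph)
  sel <- dmf$values >= 10 & dmf$values <= 16
  err_f <- max(abs(uf$values[sel] - reff$values[sel]) / reff$values[sel])
  coarse_at_fine <- grid_interpolate(uc, grid_coords(gf)[sel, ])
  err_c <- max(abs(coarse_at_fine - reff$values[sel]) / reff$values[sel])
  expect_lte(err_f, err_c)
  # degenerate focusing: fine grid = coarse grid reproduces the solution
  same <- focus(uc, assign_coefficients(sph, cfg, gc), cfg)
  expect_equal(same$values, uc$values, tolerance = 1e-4)
})

test_that("Boltzmann inversion obeys the bulk limit and Stern exclusion", {
  g <- grid_spec(c(0, 0, 0), 1, c(3, 3, 3))
  zero_pot <- grid_map(array(0, c(3, 3, 3)), c(0, 0, 0), 1, units = "kT/e")
  cp <- boltzmann_concentration(zero_pot, species_spec(1, 0.1))
  cm <- boltzmann_concentration(zero_pot, species_spec(-1, 0.1))
  expect_true(all(cp$values == 0.1) && all(cm$values == 0.1))
  mask <- grid_map(array(c(0, rep(1, 26)), c(3, 3, 3)), c(0, 0, 0), 1,
                   units = "mask")
  cp <- boltzmann_concentration(zero_pot, species_spec(1, 0.1), mask)
  expect_equal(cp$values[1, 1, 1], 0) # no ions below the Stern layer
  expect_error(boltzmann_concentration(grid_map(array(0, c(3, 3, 3)),
                                                c(0, 0, 0), 1, units = "M"),
                                       species_spec(1, 0.1)), "unit error")
})

test_that("a 1:1 salt shows exact reciprocal symmetry between the species", {
  # c+/I = I/c-: a bin with c- = 200 mM at I = 100 mM has c+ = 50 mM
  u <- grid_map(array(log(2), c(2, 2, 2)), c(0, 0, 0), 1, units = "kT/e")
  cm <- boltzmann_concentration(u, species_spec(-1, 0.1))
  cp <- boltzmann_concentration(u, species_spec(+1, 0.1))
  expect_equal(cm$values[1, 1, 1], 0.2, tolerance = 1e-12)
  expect_equal(cp$values[1, 1, 1], 0.05, tolerance = 1e-12)
  # and the product identity on a real NLPB map
  g <- grid_spec_centered(c(0, 0, 0), 30, 1)
  cfg <- pb_config(tol = 1e-6)
  maps <- pb_concentration_maps(make_charged_sphere(5, 8), g, cfg)
  sel <- maps$accessibility$values == 1
  prod_err <- abs(maps$cation$values[sel] * maps$anion$values[sel] - 0.1^2)
  expect_lt(max(prod_err) / 0.01, 1e-9)
  ratio <- maps$cation$values[sel] / 0.1 - 0.1 / maps$anion$values[sel]
  expect_lt(max(abs(ratio)), 1e-12)
})

test_that("swapping the sign of all charges swaps the species maps", {
  g <- grid_spec_centered(c(0, 0, 0), 30, 1)
  cfg <- pb_config(tol = 1e-7)
  plus <- pb_concentration_maps(make_charged_sphere(5, 6), g, cfg)
  minus <- pb_concentration_maps(make_charged_sphere(5, -6), g, cfg)
  expect_equal(plus$cation$values, minus$anion$values, tolerance = 1e-6)
  expect_equal(plus$anion$values, minus$cation$values, tolerance = 1e-6)
})
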