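test_that("nucleation and severing rates follow their kinetic laws", {
  p <- kinetic_params()
  expect_equal(nucleation_rate(0, 500, p), 0)
  expect_equal(nucleation_rate(20, 100, p), 0.0153 * 20 * 0.02 * 100)
  expect_equal(nucleation_rate(20, 200, p), 2 * nucleation_rate(20, 100, p))
  expect_equal(severing_rate(0, 100, p), 0)
  # Hill half-saturation at C = k_n^(1/n)
  Chalf <- p$k_n^(1 / p$n)
  expect_equal(severing_rate(Chalf, 100, p),
               p$k_sev * p$Psi1 * 100 / 2, tolerance = 1e-12)
  # saturated Hill approaches k_sev * Psi1 * B
  expect_equal(severing_rate(40, 100, p), p$k_sev * p$Psi1 * 100,
               tolerance = 0.01)
})

test_that("influx masks satisfy their geometric predicates", {
  lat <- spine_lattice()
  g <- lat$grid
  geom <- build_influx_masks(lat$mesh, g, lat$dist)
  expect_gt(geom$n_basal, 0)
  expect_true(all(lat$dist$ds[geom$basal_mask] < 0))
  expect_true(all(lat$dist$ds[geom$stimulus_mask] < 0))
  expect_true(all(lat$dist$ds[geom$stimulus_mask] >= -(g$spacing + 1e-9)))
  z <- geom$z
  expect_true(all(z[geom$stimulus_mask] >= 0.7 - 1e-9))
  expect_true(all(z[geom$stimulus_mask] <= 1.0 + 1e-9))
  expect_equal(geom$head_scale, 1)
  expect_error(build_influx_masks(lat$mesh, g, lat$dist,
                                  z_window = c(5, 6)), "empty stimulus")
})

make_ctx <- function(lat, kin, z_absorb = -Inf, freeze = Inf) {
  spinesim:::transport_context(lat$dist, lat$grid, kin, potential_params(),
                               z_absorb = z_absorb, freeze_band = freeze)
}

test_that("with only efflux active, total B decays as the closed form", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params(nu = 0, eta = 0, I_beta = 0, IS_beta = 0, I_A = 0,
                        IS_A = 0, I_C = 0, IS_C = 0, k_nuc = 0, k_sev = 0)
  ctx <- make_ctx(lat, kin)
  f <- species_fields(lat$grid, B = 10, A = 5, C = 2)
  f2 <- f
  for (i in 1:12) f2 <- step_fields(f2, ctx, geom, 0, 5)
  expect_lt(abs(sum(f2$B) / (sum(f$B) * exp(-kin$k_beta * 60)) - 1), 1e-6)
  expect_lt(abs(sum(f2$A) / (sum(f$A) * exp(-kin$k_A * 60)) - 1), 1e-6)
})

test_that("with every source, sink and transport off, fields are conserved", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin0 <- kinetic_params(nu = 0, eta = 0, k_beta = 0, k_A = 0, k_C = 0,
                         I_beta = 0, IS_beta = 0, I_A = 0, IS_A = 0,
                         I_C = 0, IS_C = 0, k_nuc = 0, k_sev = 0)
  ctx <- make_ctx(lat, kin0)
  f <- species_fields(lat$grid, B = 10, A = 5, C = 2)
  f2 <- step_fields(f, ctx, geom, 0, 1)
  expect_identical(f2$B, f$B)
  expect_identical(f2$A, f$A)
  expect_identical(f2$C, f$C)
})

test_that("reaction terms are stoichiometrically consistent", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params(nu = 0, eta = 0, k_beta = 0, k_A = 0, k_C = 0,
                        I_beta = 0, IS_beta = 0, I_A = 0, IS_A = 0,
                        I_C = 0, IS_C = 0)
  f <- species_fields(lat$grid, B = 100, A = 20, C = 40)
  d <- species_rhs(f, lat$dist, geom, 0, kin, FALSE)
  fnuc <- nucleation_rate(f$A, f$B, kin)
  fsev <- severing_rate(f$C, f$B, kin)
  # B gains Psi0*(fnuc+fsev); A loses fnuc; C loses fsev, pointwise
  expect_equal(d$B, kin$Psi0 * (fnuc + fsev), tolerance = 1e-12)
  expect_equal(d$A, -fnuc, tolerance = 1e-12)
  expect_equal(d$C, -fsev, tolerance = 1e-12)
})

test_that("homogeneous reaction-on A decays faster than pure degradation", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params(nu = 0, eta = 0, I_beta = 0, IS_beta = 0, I_A = 0,
                        IS_A = 0, I_C = 0, IS_C = 0)
  ctx <- make_ctx(lat, kin)
  f <- species_fields(lat$grid, B = 100, A = 20, C = 40)
  f2 <- f
  for (i in 1:6) f2 <- step_fields(f2, ctx, geom, 0, 5)
  pure <- sum(f$A) * exp(-kin$k_A * 30)
  expect_lt(sum(f2$A), pure)
})

test_that("zero fields give zero derivatives except influxes on the masks", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params()
  f <- species_fields(lat$grid, B = 0, A = 0, C = 0)
  d <- species_rhs(f, lat$dist, geom, 0, kin, stimulus_on = TRUE)
  on_b <- geom$basal_mask
  on_s <- geom$stimulus_mask
  expect_true(all(d$B[!on_b & !on_s] == 0))
  expect_equal(d$B[on_b & !on_s],
               rep(kin$Psi0 * kin$I_beta / geom$n_basal, sum(on_b & !on_s)))
  expect_equal(d$A[!on_b & on_s],
               rep(kin$IS_A / geom$n_basal, sum(!on_b & on_s)))
})

test_that("advection moves a bump along the direction field, conserving mass", {
  # constant unit +z direction field, nu = 0.2: pure upwind advection
  g <- lattice_grid(c(0, 0, 0), 0.05, c(11, 11, 41))
  pts <- grid_points(g)
  one <- array(0, g$shape)
  fld <- structure(list(ds = array(-1, g$shape),
                        dir = list(x = one, y = one,
                                   z = array(1, g$shape)),
                        grid = g),
                   class = "distance_field")
  kin <- kinetic_params(nu = 0.2, eta = 0, k_beta = 0, k_A = 0, k_C = 0,
                        I_beta = 0, IS_beta = 0, I_A = 0, IS_A = 0,
                        I_C = 0, IS_C = 0, k_nuc = 0, k_sev = 0)
  ctx <- spinesim:::transport_context(fld, g, kin, potential_params(),
                                      z_absorb = -Inf, freeze_band = Inf)
  z <- array(pts[, 3], g$shape)
  B0 <- exp(-((z - 0.6) / 0.15)^2)
  f <- species_fields(g, B = B0)
  geom <- list(basal_mask = array(FALSE, g$shape),
               stimulus_mask = array(FALSE, g$shape), n_basal = 1,
               head_scale = 1)
  for (i in 1:10) f <- step_fields(f, ctx, geom, 0, 0.25)
  # after t = 2.5 s at nu = 0.2 the bump center moved to z = 1.1
  prof <- apply(f$B, 3, max)
  zax <- spinesim:::grid_axis(g, 3)
  expect_lt(abs(zax[which.max(prof)] - 1.1), 0.1)
  expect_lt(abs(sum(f$B) - sum(B0)) / sum(B0), 0.01)
})

test_that("compiled transport kernel matches the R reference stencil", {
  set.seed(21)
  lat <- spine_lattice()
  g <- lat$grid
  geom <- build_influx_masks(lat$mesh, g, lat$dist)
  kin <- kinetic_params(nu = 0.01, eta = 0, k_beta = 0, k_A = 0, k_C = 0,
                        I_beta = 0, IS_beta = 0, I_A = 0, IS_A = 0,
                        I_C = 0, IS_C = 0, k_nuc = 0, k_sev = 0)
  B <- array(runif(prod(g$shape)), dim = g$shape)
  f <- species_fields(g, B = B)
  d <- species_rhs(f, lat$dist, geom, 0, kin, FALSE)
  ctx <- make_ctx(lat, kin)
  ref <- -spinesim:::upwind_advect(B, kin$nu * ctx$dir$x, kin$nu * ctx$dir$y,
                                   kin$nu * ctx$dir$z, g$spacing) -
    B * kin$nu * ctx$div_d
  expect_equal(d$B, ref, tolerance = 1e-12)
  expect_true(all(d$A == 0))
})

test_that("CFL violations are rejected with a suggested step", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params(nu = 0.5)
  ctx <- make_ctx(lat, kin)
  f <- species_fields(lat$grid, B = 1)
  expect_error(step_fields(f, ctx, geom, 0, 10), "CFL")
})

test_that("negative undershoot is clipped and logged", {
  lat <- spine_lattice()
  geom <- build_influx_masks(lat$mesh, lat$grid, lat$dist)
  kin <- kinetic_params(nu = 0, eta = 0, k_beta = 0, k_A = 0, k_C = 0,
                        I_beta = 0, IS_beta = 0, I_A = 0, IS_A = 0,
                        I_C = 0, IS_C = 0, k_nuc = 0, k_sev = 0)
  ctx <- make_ctx(lat, kin, z_absorb = 0.3)
  f <- species_fields(lat$grid, B = 1)
  f2 <- step_fields(f, ctx, geom, 0, 1)
  # absorbing boundary zeroes everything below z_absorb
  expect_true(all(f2$B[ctx$absorb] == 0))
  expect_true(all(f2$B >= 0))
})
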