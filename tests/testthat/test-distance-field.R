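test_that("signed distance matches a brute-force oracle on random points", {
  set.seed(7)
  m <- icosphere(0.8, 2)
  m$vertices[, 3] <- m$vertices[, 3] * 1.4  # break symmetry
  pts <- matrix(runif(600, -1.4, 1.4), ncol = 3)
  fld <- signed_distance_field(pts, m, accelerate = TRUE)
  # magnitude against the independent R oracle
  idx <- sample(nrow(pts), 60)
  for (q in idx) {
    expect_lt(abs(abs(fld$ds[q]) - oracle_distance(pts[q, ], m)), 1e-10)
  }
  # sign against the generalized winding number
  wn <- winding_number(pts, m)
  expect_identical(sign(fld$ds), ifelse(wn > 0.5, -1, 1))
})

test_that("accelerated query is identical to exhaustive search", {
  set.seed(8)
  m <- small_spine()
  pts <- matrix(c(runif(300, -0.3, 0.3), runif(300, -0.3, 0.3),
                  runif(300, 0, 1.2)), ncol = 3)
  fa <- signed_distance_field(pts, m, accelerate = TRUE)
  fb <- signed_distance_field(pts, m, accelerate = FALSE)
  expect_identical(fa$ds, fb$ds)
  expect_identical(fa$face, fb$face)
  expect_identical(fa$closest, fb$closest)
})

test_that("special points: sphere center, on-surface vertex, direction norm", {
  s <- icosphere(1, 3)
  f0 <- signed_distance_field(matrix(0, 1, 3), s)
  expect_lt(abs(f0$ds - (-1)), 0.01)
  fv <- signed_distance_field(s$vertices[17, , drop = FALSE], s)
  expect_equal(fv$ds, 0)
  expect_equal(fv$feature, "vertex")
  set.seed(9)
  pts <- matrix(runif(300, -1.5, 1.5), ncol = 3)
  fa <- signed_distance_field(pts, s)
  expect_equal(max(abs(sqrt(rowSums(fa$dir^2)) - 1)), 0, tolerance = 1e-12)
})

test_that("repulsive potential follows alpha*tanh(beta*ds)/2", {
  p <- potential_params(alpha = 3e4, beta = 40)
  expect_equal(repulsive_potential(0, p), 0)
  expect_lt(abs(repulsive_potential(100, p) - p$alpha / 2), 1e-6)
  expect_equal(repulsive_potential(1 / p$beta, p), p$alpha * tanh(1) / 2)
  # odd and bounded
  ds <- seq(-0.5, 0.5, by = 0.01)
  psi <- repulsive_potential(ds, p)
  expect_equal(psi + 0, -rev(psi) + 0, tolerance = 1e-12)  # +0 drops -0
  expect_true(all(abs(psi) <= p$alpha / 2))
})

test_that("force density is antiparallel to d with maximum on the membrane", {
  p <- potential_params()
  lat <- spine_lattice()
  fu <- force_density(lat$dist, p)
  expect_equal(max(fu$mag), p$alpha * p$beta / 2, tolerance = 1e-6)
  # f_u . d < 0 off the surface
  dotp <- fu$x * lat$dist$dir$x + fu$y * lat$dist$dir$y +
    fu$z * lat$dist$dir$z
  off <- abs(lat$dist$ds) > 1e-9
  expect_true(all(dotp[off] < 0))
})

test_that("analytic force density matches finite differences of psi", {
  # gentle potential on a sphere so central differences resolve the profile
  p <- potential_params(alpha = 100, beta = 4)
  m <- icosphere(0.8, 3)
  g <- grid_for_mesh(m, 0.05)
  fld <- signed_distance_field(g, m)
  psi <- repulsive_potential(fld, p)
  fu <- force_density(fld, p)
  num <- list(x = -spinesim:::diff_axis(psi, 1, g$spacing),
              y = -spinesim:::diff_axis(psi, 2, g$spacing),
              z = -spinesim:::diff_axis(psi, 3, g$spacing))
  interior <- array(FALSE, dim = g$shape)
  interior[3:(g$shape[1] - 2), 3:(g$shape[2] - 2), 3:(g$shape[3] - 2)] <- TRUE
  # away from the medial axis (center) where the SDF is not smooth
  pts <- grid_points(g)
  r <- array(sqrt(rowSums(pts^2)), dim = g$shape)
  sel <- interior & r > 0.3
  scale <- max(fu$mag)
  for (comp in c("x", "y", "z")) {
    err <- abs(num[[comp]][sel] - fu[[comp]][sel]) / scale
    expect_lt(stats::quantile(err, 0.95), (p$beta * g$spacing)^2)
  }
})

test_that("divergence of direction matches the analytic radial field", {
  # exact SDF of a sphere: d = r_hat, div d = 2/r
  g <- lattice_grid(c(-1, -1, -1), 0.05, c(41, 41, 41))
  pts <- grid_points(g)
  r <- sqrt(rowSums(pts^2))
  fld <- list(ds = array(r - 0.7, dim = g$shape),
              dir = list(x = array(ifelse(r > 0, pts[, 1] / r, 0), g$shape),
                         y = array(ifelse(r > 0, pts[, 2] / r, 0), g$shape),
                         z = array(ifelse(r > 0, pts[, 3] / r, 0), g$shape)),
              grid = g)
  class(fld) <- "distance_field"
  dv <- divergence_of_direction(fld, g)
  sel <- r > 0.3 & r < 0.9
  expect_lt(max(abs(dv[sel] - 2 / r[sel]) / (2 / r[sel])), 0.05)
  # planar half-space SDF has divergence zero
  fldp <- fld
  fldp$dir <- list(x = array(0, g$shape), y = array(0, g$shape),
                   z = array(1, g$shape))
  expect_lt(max(abs(divergence_of_direction(fldp, g))), 1e-6)
})

test_that("fields are equivariant under rigid translation of mesh and grid", {
  set.seed(12)
  m <- icosphere(0.5, 2)
  m$vertices <- m$vertices * (1 + 0.04 * matrix(stats::rnorm(length(m$vertices)),
                                                ncol = 3))  # kill symmetry ties
  g <- grid_for_mesh(m, 0.1)
  f1 <- signed_distance_field(g, m)
  shift <- c(0.5, -0.25, 1)
  m2 <- m
  m2$vertices <- sweep(m2$vertices, 2, shift, "+")
  g2 <- lattice_grid(g$origin + shift, g$spacing, g$shape)
  f2 <- signed_distance_field(g2, m2)
  expect_lt(max(abs(f2$ds - f1$ds)), 1e-12)
  expect_lt(max(abs(f2$dir$x - f1$dir$x)), 1e-9)
})

test_that("grid containment is enforced", {
  m <- icosphere(1, 2)
  g <- lattice_grid(c(-0.5, -0.5, -0.5), 0.1, c(5, 5, 5))
  expect_error(signed_distance_field(g, m), "does not contain")
})
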