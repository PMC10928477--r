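test_that("actin force vanishes for empty barbed-end fields", {
  lat <- spine_lattice()
  fa <- actin_force(array(0, lat$grid$shape), lat$dist, lat$mesh)
  expect_true(all(fa$forces == 0))
  expect_equal(fa$energy, 0)
})

test_that("a single lattice point pushes its closest face outward", {
  # one interior point with B = 1 near a face: per-vertex forces sum to
  # dx^3 * (alpha*beta/2) * sech(beta*ds)^2 along the outward direction
  m <- icosphere(0.5, 2)
  g <- grid_for_mesh(m, 0.1)
  dist <- signed_distance_field(g, m)
  ds <- as.numeric(dist$ds)
  cand <- which(ds < -0.02 & ds > -0.08 & dist$feature == "face")
  q <- cand[1]
  B <- array(0, g$shape)
  B[q] <- 1
  p <- potential_params()
  fa <- actin_force(B, dist, m, p)
  net <- colSums(fa$forces)
  expected_mag <- g$spacing^3 * (p$alpha * p$beta / 2) /
    cosh(p$beta * ds[q])^2
  expect_lt(abs(sqrt(sum(net^2)) - expected_mag) / expected_mag, 1e-6)
  # direction: outward (same as the stored direction of increasing ds)
  d <- dist$dir
  dvec <- c(as.numeric(d$x)[q], as.numeric(d$y)[q], as.numeric(d$z)[q])
  expect_gt(sum(net * dvec) / sqrt(sum(net^2)), 1 - 1e-9)
  # only the three vertices of the closest face carry force
  loaded <- which(rowSums(abs(fa$forces)) > 0)
  expect_setequal(loaded, m$faces[dist$face[q], ])
})

test_that("actin force matches finite differences of the discrete energy", {
  set.seed(3)
  m <- icosphere(0.5, 2)
  m$vertices <- m$vertices * (1 + 0.04 * matrix(stats::rnorm(length(m$vertices)),
                                                ncol = 3))  # kill symmetry ties
  g <- grid_for_mesh(m, 0.1)
  dist <- signed_distance_field(g, m)
  B <- array(runif(prod(g$shape)) * 100, dim = g$shape)
  B[abs(dist$ds) < 0.05] <- 0  # smooth band: see comment in the module test
  fa <- actin_force(B, dist, m)
  EB <- function(mm) {
    d2 <- signed_distance_field(g, mm)
    idx <- d2$ds < 0 & B > 0
    sum(repulsive_potential(d2$ds[idx]) * B[idx]) * g$spacing^3
  }
  h <- 1e-6
  scale <- max(abs(fa$forces))
  for (k in 1:15) {
    vi <- sample(nrow(m$vertices), 1)
    ci <- sample(3, 1)
    mp <- m; mp$vertices[vi, ci] <- mp$vertices[vi, ci] + h
    mm2 <- m; mm2$vertices[vi, ci] <- mm2$vertices[vi, ci] - h
    fd <- (EB(mp) - EB(mm2)) / (2 * h)
    expect_lt(abs(-fd - fa$forces[vi, ci]) / scale, 1e-3)
  }
})

test_that("membrane advances by dt/omega times the total force", {
  m <- icosphere(1, 2)
  mech <- mechanics_params(omega = 1e5)
  # uniform outward normal force of 10 pN per vertex
  vn <- m$vertices / sqrt(rowSums(m$vertices^2))
  F0 <- structure(list(forces = 10 * vn, energy = 0, tag = "actin"),
                  class = "vertex_forces")
  m2 <- advance_membrane(m, NULL, F0, mech, dt = 1)
  disp <- m2$vertices - m$vertices
  expect_equal(disp, (1 / 1e5) * 10 * vn, tolerance = 1e-10)
  # zero force leaves the mesh bitwise unchanged
  Z <- structure(list(forces = 0 * vn, energy = 0, tag = "actin"),
                 class = "vertex_forces")
  m3 <- advance_membrane(m, NULL, Z, mech, dt = 1)
  expect_identical(m3$vertices, m$vertices)
})

test_that("fixed vertices never move under any force", {
  m <- small_spine()
  F0 <- structure(list(forces = matrix(1e4, nrow(m$vertices), 3),
                       energy = 0, tag = "actin"), class = "vertex_forces")
  m2 <- advance_membrane(m, NULL, F0, mechanics_params(), dt = 1,
                         max_disp = Inf)
  expect_identical(m2$vertices[m2$fixed, ], m$vertices[m$fixed, ])
  # and through remeshing
  r <- remesh_isotropic(m, 0.08)
  old <- m$vertices[m$fixed, ]
  new <- r$vertices[r$fixed, ]
  expect_equal(nrow(new), nrow(old))
  expect_equal(new[order(new[, 1], new[, 2]), ],
               old[order(old[, 1], old[, 2]), ], tolerance = 0)
})

test_that("oversized membrane steps are rejected", {
  m <- icosphere(1, 2)
  F0 <- structure(list(forces = matrix(1e6, nrow(m$vertices), 3),
                       energy = 0, tag = "actin"), class = "vertex_forces")
  expect_error(advance_membrane(m, NULL, F0, mechanics_params(), dt = 1),
               "step-size")
})

test_that("protrusion velocity clamps negative displacements at zero", {
  m <- icosphere(1, 2)
  tr <- protrusion_tracker(m, c(1, 0, 0))
  m2 <- m
  m2$vertices[tr$vid, 1] <- m2$vertices[tr$vid, 1] + 0.001
  tr2 <- protrusion_velocity(tr, m2, dt = 0.01)
  expect_equal(tr2$nu_mp, 0.1)
  m3 <- m2
  m3$vertices[tr$vid, 1] <- m3$vertices[tr$vid, 1] - 0.002
  tr3 <- protrusion_velocity(tr2, m3, dt = 0.01)
  expect_equal(tr3$nu_mp, 0)
  tr4 <- protrusion_velocity(tr3, m3, dt = 0.01)
  expect_equal(tr4$nu_mp, 0)
})

test_that("trackers rebind to the nearest vertex after remeshing", {
  m <- small_spine()
  tr <- protrusion_tracker(m, c(0.25, 0, 0.85))
  r <- remesh_isotropic(m, 0.08)
  tr2 <- rebind_tracker(tr, r)
  expect_lt(sqrt(sum((tr2$position - tr$position)^2)), 0.08)
  tr$position <- tr$position + c(0.03, 0.03, 0)  # now off every vertex
  expect_error(rebind_tracker(tr, r, max_dist = 1e-12), "lost")
})

test_that("stale distance fields are rejected by the actin force", {
  lat <- spine_lattice()
  m2 <- lat$mesh
  m2$vertices <- m2$vertices * 1.5
  B <- array(1, lat$grid$shape)
  expect_error(actin_force(B, lat$dist, m2), "stale")
})
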