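test_that("volume and area match analytic values on spheres and cubes", {
  s <- icosphere(1, 3)
  expect_lt(abs(mesh_volume(s) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  expect_lt(abs(mesh_area(s) - 4 * pi) / (4 * pi), 0.01)
  b <- box_mesh()
  expect_equal(mesh_volume(b), 1.0)
  expect_equal(mesh_area(b), 6.0)
  # rigid translation leaves volume unchanged
  s2 <- s
  s2$vertices <- sweep(s2$vertices, 2, c(2.3, -1.1, 0.7), "+")
  expect_lt(abs(mesh_volume(s2) - mesh_volume(s)) / mesh_volume(s), 1e-10)
  expect_lt(abs(mesh_area(s2) - mesh_area(s)) / mesh_area(s), 1e-10)
  # area scaling law
  s4 <- s
  s4$vertices <- s4$vertices * 2
  expect_lt(abs(mesh_area(s4) / mesh_area(s) - 4), 1e-10)
})

test_that("volume errors on non-watertight meshes name the open edges", {
  b <- box_mesh()
  b$faces <- b$faces[-1, ]
  expect_error(mesh_volume(b), "open edges")
})

test_that("initial spine matches analytic volume and flags the base fixed", {
  m <- build_initial_spine(0.25, 0.85, 0.1, 0.6, 0.05)
  # analytic: cylinder up to the sphere junction + spherical segment above
  zj <- 0.85 - sqrt(0.25^2 - 0.1^2)
  seg <- function(z) pi * (0.25^2 * z - (z - 0.85)^3 / 3)
  v_true <- pi * 0.1^2 * zj + (seg(0.85 + 0.25) - seg(zj))
  expect_lt(abs(mesh_volume(m) - v_true) / v_true, 0.05)
  expect_gt(mesh_volume(m), 0)
  expect_equal(nrow(open_edges <- spinesim:::open_edges(m)), 0)
  # base vertices fixed, at z = 0
  expect_gt(length(m$fixed), 3)
  expect_true(all(abs(m$vertices[m$fixed, 3]) < 1e-9))
  # edge lengths concentrated around the target
  el <- spinesim:::edge_lengths(m)
  expect_gte(mean(el >= 0.04 & el <= 0.0667), 0.95)
})

test_that("degenerate spine geometry is rejected", {
  expect_error(build_initial_spine(neck_radius = 0.3, head_radius = 0.25),
               "neck_radius")
  expect_error(build_initial_spine(target_edge = 0.2), "target_edge")
})

make_cylinder <- function(radius = 0.1, height = 0.4, n = 96, layers = 5) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  zs <- seq(0, height, length.out = layers)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  rings <- lapply(seq_len(layers) - 1, function(k) k * n + seq_len(n))
  faces <- do.call(rbind, lapply(seq_len(layers - 1), function(k)
    spinesim:::zip_rings(rings[[k]], rings[[k + 1]])))
  bot <- nrow(verts) + 1L
  top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, height))
  r1 <- rings[[1]]
  rl <- rings[[layers]]
  faces <- rbind(faces,
                 cbind(r1[c(2:n, 1)], r1, bot),
                 cbind(rl, rl[c(2:n, 1)], top))
  spine_mesh(verts, faces)
}

test_that("cross-section radius matches cylinders and spheres", {
  cyl <- make_cylinder()
  expect_lt(abs(cross_section_radius(cyl, 0.2) - 0.1) / 0.1, 0.01)
  m <- build_initial_spine(0.25, 0.85, 0.1, 0.6, 0.05)
  expect_lt(abs(cross_section_radius(m, 0.3) - 0.1) / 0.1, 0.04)
  s <- icosphere(1, 3)
  expect_lt(abs(cross_section_radius(s, 0) - 1), 0.01)
  h <- 0.62
  expect_lt(abs(cross_section_radius(s, h) - sqrt(1 - h^2)) / sqrt(1 - h^2),
            0.01)
  expect_error(cross_section_radius(s, 3), "intersect")
})

test_that("mesh I/O round-trips through OFF and PLY", {
  m <- small_spine()
  f_off <- tempfile(fileext = ".off")
  f_ply <- tempfile(fileext = ".ply")
  write_off(m, f_off)
  write_ply(m, f_ply)
  m2 <- read_off(f_off, fixed = m$fixed)
  m3 <- read_ply(f_ply, fixed = m$fixed)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(m2$faces, m$faces)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-12)
  vtk <- tempfile(fileext = ".vtk")
  write_vtk_polydata(m, vtk, point_data = list(z = m$vertices[, 3]))
  expect_true(file.exists(vtk))
})
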