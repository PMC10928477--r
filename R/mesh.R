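#' Triangulated spine membrane
#'
#' A `spine_mesh` is a watertight, consistently outward-oriented triangle
#' mesh representing the spine membrane, closed at the dendrite by a base
#' disc in the x-y plane.  Vertices flagged as fixed (the dendrite base)
#' are never displaced by any dynamics operation.
#'
#' @param vertices numeric matrix, one row per vertex (micrometres).
#' @param faces integer matrix, one row per triangle (1-based vertex ids),
#'   oriented so face normals point outward (signed volume > 0).
#' @param fixed integer vector of vertex ids held immobile.
#' @param validate check watertightness, orientation and face areas.
#' @return an object of class `spine_mesh` with elements `vertices`,
#'   `faces`, `fixed`.
#' @export
spine_mesh <- function(vertices, faces, fixed = integer(0), validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  mesh <- structure(list(vertices = vertices, faces = faces,
                         fixed = as.integer(fixed)),
                    class = "spine_mesh")
  if (validate) {
    open <- open_edges(mesh)
    if (nrow(open) > 0)
      stop("mesh is not watertight; open edges: ",
           paste(apply(utils::head(open, 5), 1, paste, collapse = "-"),
                 collapse = ", "))
    areas <- face_areas(mesh)
    if (any(areas <= 1e-12))
      stop("mesh has ", sum(areas <= 1e-12), " zero-area face(s)")
    if (mesh_volume(mesh) <= 0)
      stop("mesh orientation is inward (signed volume <= 0)")
  }
  mesh
}

#' @export
print.spine_mesh <- function(x, ...) {
  cat(sprintf("spine_mesh: %d vertices, %d faces, %d fixed\n",
              nrow(x$vertices), nrow(x$faces), length(x$fixed)))
  cat(sprintf("  volume %.4f um^3, area %.4f um^2\n",
              mesh_volume(x), mesh_area(x)))
  invisible(x)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_lengths <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                mesh$vertices[e[, 2], , drop = FALSE])^2))
}

open_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2]
  if (length(bad) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  n <- vec_cross(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  0.5 * sqrt(rowSums(n^2))
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' meshes.
#'
#' @param mesh a [spine_mesh()].
#' @return volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  open <- open_edges(mesh)
  if (nrow(open) > 0)
    stop("volume undefined: mesh has open edges ",
         paste(apply(utils::head(open, 5), 1, paste, collapse = "-"),
               collapse = ", "))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * vec_cross(b, c3))) / 6
}

#' Surface area of a mesh
#'
#' @param mesh a [spine_mesh()].
#' @return total area in square micrometres.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# Triangulate the band between two horizontal rings of vertex ids (ordered
# by angle, consistent winding) by zipping along angle.  `up` indicates the
# second ring lies above the first; orientation chosen so normals point away
# from the axis of revolution.
zip_rings <- function(lower, upper) {
  n1 <- length(lower)
  n2 <- length(upper)
  faces <- matrix(0L, 0, 3)
  i <- 0L
  j <- 0L
  # walk both rings by fractional position
  while (i < n1 || j < n2) {
    adv_lower <- (i < n1) && (j >= n2 || (i + 1) / n1 <= (j + 1) / n2)
    if (adv_lower) {
      faces <- rbind(faces, c(lower[i %% n1 + 1], lower[(i + 1) %% n1 + 1],
                              upper[j %% n2 + 1]))
      i <- i + 1L
    } else {
      faces <- rbind(faces, c(lower[i %% n1 + 1], upper[(j + 1) %% n2 + 1],
                              upper[j %% n2 + 1]))
      j <- j + 1L
    }
  }
  faces
}

#' Build the initial spine shape
#'
#' Constructs a watertight surface of revolution: a spheroid head atop a
#' cylindrical neck atop a base disc in the x-y plane.  Base-disc and rim
#' vertices are flagged fixed (the dendrite anchor).  The mesh is then
#' isotropically remeshed to the target edge length.
#'
#' @param head_radius head spheroid radius (um).
#' @param head_center_z height of the head centre (um).
#' @param neck_radius neck cylinder radius (um); must be < `head_radius`.
#' @param neck_length nominal neck length (um); the neck spans from z = 0 to
#'   where the cylinder meets the head sphere.
#' @param target_edge target mesh edge length (um).
#' @param remesh_iterations remesher iterations applied to the raw
#'   revolution mesh.
#' @return a [spine_mesh()].
#' @export
build_initial_spine <- function(head_radius = 0.25, head_center_z = 0.85,
                                neck_radius = 0.1, neck_length = 0.6,
                                target_edge = 0.05, remesh_iterations = 4) {
  stopifnot(head_radius > 0, neck_radius > 0, neck_length > 0,
            head_center_z > 0, target_edge > 0)
  if (neck_radius >= head_radius)
    stop("degenerate geometry: neck_radius (", neck_radius,
         ") must be smaller than head_radius (", head_radius, ")")
  if (target_edge >= neck_radius)
    stop("target_edge must be smaller than neck_radius")
  # z where the cylinder of radius neck_radius meets the head sphere
  z_join <- head_center_z - sqrt(head_radius^2 - neck_radius^2)
  if (z_join <= 0)
    stop("head sphere reaches below the base plane; raise head_center_z")
  z_top <- head_center_z + head_radius

  profile_r <- function(z) {
    ifelse(z <= z_join, neck_radius,
           sqrt(pmax(head_radius^2 - (z - head_center_z)^2, 0)))
  }
  # ring heights: uniform along the neck, uniform in polar angle on the head
  n_neck <- max(2L, ceiling(z_join / target_edge))
  z_neckring <- seq(0, z_join, length.out = n_neck + 1)
  ang_join <- acos((z_join - head_center_z) / head_radius)  # polar from +z
  n_head <- max(3L, ceiling(ang_join * head_radius / target_edge))
  ang <- seq(ang_join, 0, length.out = n_head + 1)
  z_headring <- head_center_z + head_radius * cos(ang)
  zs <- c(z_neckring, z_headring[-1])
  zs <- zs[zs < z_top - 1e-9]

  verts <- matrix(0, 0, 3)
  rings <- list()
  for (z in zs) {
    r <- profile_r(z)
    n <- max(6L, round(2 * pi * r / target_edge))
    th <- 2 * pi * (seq_len(n) - 1) / n
    ids <- nrow(verts) + seq_len(n)
    verts <- rbind(verts, cbind(r * cos(th), r * sin(th), z))
    rings[[length(rings) + 1]] <- ids
  }
  faces <- matrix(0L, 0, 3)
  for (k in seq_len(length(rings) - 1))
    faces <- rbind(faces, zip_rings(rings[[k]], rings[[k + 1]]))
  # apex cap
  apex <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, z_top))
  top <- rings[[length(rings)]]
  n <- length(top)
  faces <- rbind(faces, cbind(top, top[c(2:n, 1)], apex))
  # base disc: rim ring plus centre vertex (flat fan for small radii)
  centre <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, 0))
  rim <- rings[[1]]
  n <- length(rim)
  faces <- rbind(faces, cbind(rim[c(2:n, 1)], rim, centre))  # downward normals
  fixed <- c(rim, centre)

  mesh <- spine_mesh(verts, faces, fixed = fixed)
  mesh <- remesh_isotropic(mesh, target_edge, iterations = remesh_iterations)
  # remeshing may have introduced new vertices inside the flat base disc;
  # the whole disc belongs to the immobile dendrite set
  base_ids <- which(abs(mesh$vertices[, 3]) < 1e-9)
  mesh$fixed <- sort(unique(c(mesh$fixed, base_ids)))
  mesh
}

#' Isotropic remeshing
#'
#' Restores near-uniform edge lengths on an evolving mesh by edge splits,
#' collapses, flips and tangential relaxation.  Fixed vertices are preserved
#' at bitwise-identical coordinates; watertightness is preserved and the
#' enclosed volume changes by well under 1 percent in practice.
#'
#' @param mesh a [spine_mesh()].
#' @param target_edge target edge length (um).
#' @param iterations remesher sweeps.
#' @param fixed optional override of the fixed vertex ids.
#' @return a remeshed [spine_mesh()].
#' @export
remesh_isotropic <- function(mesh, target_edge, iterations = 5, fixed = NULL) {
  stopifnot(target_edge > 0)
  ids <- if (is.null(fixed)) mesh$fixed else as.integer(fixed)
  flag <- rep(FALSE, nrow(mesh$vertices))
  flag[ids] <- TRUE
  old_fixed_coords <- mesh$vertices[ids, , drop = FALSE]
  res <- cpp_remesh(mesh$vertices, mesh$faces - 1L, flag, target_edge,
                    as.integer(iterations))
  out <- spine_mesh(res$vertices, res$faces + 1L, fixed = which(res$fixed))
  new_coords <- out$vertices[out$fixed, , drop = FALSE]
  if (nrow(new_coords) != nrow(old_fixed_coords) ||
      !identical(dim(new_coords), dim(old_fixed_coords)) ||
      !isTRUE(all.equal(sort(new_coords[, 1]), sort(old_fixed_coords[, 1]),
                        tolerance = 0)))
    stop("remeshing altered fixed vertices")
  out
}

#' Equivalent-area cross-section radius at height z
#'
#' Intersects the mesh with the plane at height `z`; the intersection must
#' be a single closed polygon, whose equivalent-area radius
#' sqrt(A/pi) is returned.
#'
#' @param mesh a [spine_mesh()].
#' @param z section height (um).
#' @return radius in micrometres.
#' @export
cross_section_radius <- function(mesh, z) {
  v <- mesh$vertices
  f <- mesh$faces
  # nudge the plane off any vertex lying exactly on it, so every section
  # triangle yields a clean two-point segment
  guard <- 0
  while (any(abs(v[, 3] - z) < 1e-9) && guard < 100) {
    z <- z + 1.7e-7
    guard <- guard + 1
  }
  segs <- list()
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    d <- tri[, 3] - z
    if (all(d > 0) || all(d < 0)) next
    pts <- matrix(0, 0, 2)
    for (k in 1:3) {
      k2 <- k %% 3 + 1
      if ((d[k] > 0) != (d[k2] > 0)) {
        t <- d[k] / (d[k] - d[k2])
        p <- tri[k, 1:2] + t * (tri[k2, 1:2] - tri[k, 1:2])
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1]] <- pts
  }
  if (length(segs) == 0)
    stop("plane z = ", z, " does not intersect the mesh (0 loops)")
  # chain segments into loops by endpoint matching
  ends <- do.call(rbind, lapply(segs, function(s) c(s[1, ], s[2, ])))
  used <- rep(FALSE, length(segs))
  loops <- 0
  area <- 0
  tol <- 1e-7
  while (any(!used)) {
    start <- which(!used)[1]
    used[start] <- TRUE
    loop <- rbind(segs[[start]][1, ], segs[[start]][2, ])
    repeat {
      cur <- loop[nrow(loop), ]
      dists <- ifelse(used, Inf,
                      pmin(sqrt((ends[, 1] - cur[1])^2 + (ends[, 2] - cur[2])^2),
                           sqrt((ends[, 3] - cur[1])^2 + (ends[, 4] - cur[2])^2)))
      j <- which.min(dists)
      if (!is.finite(dists[j]) || dists[j] > tol) break
      used[j] <- TRUE
      s <- segs[[j]]
      d1 <- sqrt(sum((s[1, ] - cur)^2))
      nxt <- if (d1 <= tol) s[2, ] else s[1, ]
      loop <- rbind(loop, nxt)
    }
    loops <- loops + 1
    x <- loop[, 1]
    y <- loop[, 2]
    n <- nrow(loop)
    area <- area + abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  }
  if (loops != 1)
    stop("plane z = ", z, " intersects the mesh in ", loops,
         " loops; expected 1")
  sqrt(area / pi)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron, useful as an analytic test surface and as a
#' generic closed-mesh fixture.
#'
#' @param radius sphere radius (um).
#' @param subdivisions number of 4-to-1 subdivision rounds.
#' @param center sphere centre.
#' @return a [spine_mesh()] with no fixed vertices.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  spine_mesh(v, f)
}

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite corners.
#' @return a [spine_mesh()] of 12 triangles.
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  colnames(v) <- NULL
  # vertex order: (x,y,z) bits with x fastest
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),    # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),    # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),    # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),    # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))    # x = hi (+x)
  spine_mesh(v, f)
}
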