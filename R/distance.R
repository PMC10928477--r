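#' Cubic lattice domain
#'
#' The fixed regular grid on which species fields and the signed distance
#' field live.  Positions never change during a run.
#'
#' @param origin position of the first lattice point (um).
#' @param spacing lattice interval Delta_x (um).
#' @param shape integer triple of points per axis.
#' @return a list of class `lattice_grid`.
#' @export
lattice_grid <- function(origin, spacing, shape) {
  stopifnot(spacing > 0, length(origin) == 3, length(shape) == 3,
            all(shape >= 2))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = as.integer(shape)),
            class = "lattice_grid")
}

#' Lattice grid enclosing a mesh
#'
#' Builds a [lattice_grid()] whose extent contains the mesh bounding box
#' with at least the requested margin of cells on every side.
#'
#' @param mesh a [spine_mesh()].
#' @param spacing lattice interval (um).
#' @param margin_cells margin, in cells, beyond the mesh bounding box.
#' @return a [lattice_grid()].
#' @export
grid_for_mesh <- function(mesh, spacing, margin_cells = 3) {
  lo <- apply(mesh$vertices, 2, min) - margin_cells * spacing
  hi <- apply(mesh$vertices, 2, max) + margin_cells * spacing
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  lattice_grid(lo, spacing, shape)
}

#' Lattice point coordinates
#'
#' @param grid a [lattice_grid()].
#' @return matrix (n_points x 3) in x-fastest order, matching the array
#'   layout `dim = shape`.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + grid$spacing * (seq_len(grid$shape[d]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

grid_axis <- function(grid, d)
  grid$origin[d] + grid$spacing * (seq_len(grid$shape[d]) - 1)

#' Signed distance field from lattice to membrane
#'
#' For every lattice point, computes the signed Euclidean distance to the
#' mesh (negative inside), the closest element (face id, barycentric
#' coordinates, feature type), and the unit direction of increasing
#' distance (the polymerization direction field, reversed).  The sign comes
#' from the angle-weighted pseudonormal at the closest feature with a
#' generalized winding-number fallback for glancing queries; an exact
#' spatial-bucket search makes the query identical to exhaustive search.
#'
#' @param grid a [lattice_grid()] (or a numeric matrix of query points).
#' @param mesh a [spine_mesh()].
#' @param accelerate use the spatial bucket structure (results are
#'   identical either way).
#' @return list of class `distance_field`: arrays `ds` (signed distance),
#'   `dir` (list of three arrays), plus flat matrices `closest`, `bary`,
#'   vectors `face`, `feature`, and the query geometry.
#' @export
signed_distance_field <- function(grid, mesh, accelerate = TRUE) {
  if (is.matrix(grid)) {
    pts <- grid
    shape <- NULL
  } else {
    bb_lo <- apply(mesh$vertices, 2, min)
    bb_hi <- apply(mesh$vertices, 2, max)
    g_lo <- grid$origin
    g_hi <- grid$origin + grid$spacing * (grid$shape - 1)
    if (any(bb_lo < g_lo) || any(bb_hi > g_hi))
      stop("lattice grid does not contain the mesh bounding box")
    pts <- grid_points(grid)
    shape <- grid$shape
  }
  res <- cpp_signed_distance(mesh$vertices, mesh$faces - 1L, pts,
                             accelerate = accelerate)
  ds <- res$ds
  dir <- res$dir
  if (!is.null(shape)) {
    ds <- array(ds, dim = shape)
    dir <- list(x = array(res$dir[, 1], dim = shape),
                y = array(res$dir[, 2], dim = shape),
                z = array(res$dir[, 3], dim = shape))
  }
  structure(list(ds = ds, dir = dir, closest = res$closest,
                 bary = res$bary, face = res$face + 1L,
                 feature = c("face", "edge", "vertex")[res$feature + 1L],
                 n_fallback = res$n_fallback,
                 grid = if (is.null(shape)) NULL else grid,
                 points = pts),
            class = "distance_field")
}

#' Generalized winding number of points with respect to a mesh
#'
#' Approximately 1 for points inside a watertight mesh and 0 outside; used
#' as the robust inside/outside oracle.
#'
#' @param points numeric matrix of query points.
#' @param mesh a [spine_mesh()].
#' @return numeric vector of winding numbers.
#' @export
winding_number <- function(points, mesh) {
  cpp_winding_number(mesh$vertices, mesh$faces - 1L, as.matrix(points))
}

#' Soft repulsive membrane potential
#'
#' psi = alpha * tanh(beta * ds) / 2 (pN): odd in the signed distance,
#' bounded by alpha/2, negative inside the spine.
#'
#' @param field a [signed_distance_field()] (or a numeric vector/array of
#'   signed distances).
#' @param params a [potential_params()].
#' @return psi with the same shape as the input distances.
#' @export
repulsive_potential <- function(field, params = potential_params()) {
  ds <- if (inherits(field, "distance_field")) field$ds else field
  params$alpha * tanh(params$beta * ds) / 2
}

#' Confining force density
#'
#' f_u = -grad psi = -(alpha beta / 2) sech^2(beta ds) d: antiparallel to
#' the direction of increasing signed distance, with maximal magnitude
#' alpha*beta/2 on the membrane.  Computed analytically from the closest
#' point, not by differencing the potential.
#'
#' @param field a [signed_distance_field()] on a lattice grid.
#' @param params a [potential_params()].
#' @return list with component arrays `x`, `y`, `z` (pN/um) and the
#'   magnitude prefactor array `mag`.
#' @export
force_density <- function(field, params = potential_params()) {
  mag <- (params$alpha * params$beta / 2) / cosh(params$beta * field$ds)^2
  if (is.list(field$dir)) {
    list(x = -mag * field$dir$x, y = -mag * field$dir$y,
         z = -mag * field$dir$z, mag = mag)
  } else {
    list(xyz = -as.numeric(mag) * field$dir, mag = mag)
  }
}

# central difference along axis d with one-sided differences at the
# boundary; x is a 3D array on the grid
diff_axis <- function(x, d, h) {
  n <- dim(x)[d]
  idx_p <- c(2:n, n)
  idx_m <- c(1, 1:(n - 1))
  sel <- function(i) switch(d,
                            x[i, , , drop = FALSE],
                            x[, i, , drop = FALSE],
                            x[, , i, drop = FALSE])
  out <- (sel(idx_p) - sel(idx_m))
  dim(out) <- dim(x)
  den <- array(2 * h, dim = dim(x))
  if (d == 1) { den[1, , ] <- h; den[n, , ] <- h }
  if (d == 2) { den[, 1, ] <- h; den[, n, ] <- h }
  if (d == 3) { den[, , 1] <- h; den[, , n] <- h }
  out / den
}

#' Divergence of the direction field
#'
#' Central finite differences of the three components of the polymerization
#' direction field (one-sided at the grid boundary).
#'
#' @param field a [signed_distance_field()] on a lattice grid.
#' @param grid the [lattice_grid()] (defaults to the field's own grid).
#' @return array of div(d) values (1/um).
#' @export
divergence_of_direction <- function(field, grid = field$grid) {
  stopifnot(is.list(field$dir))
  h <- grid$spacing
  diff_axis(field$dir$x, 1, h) + diff_axis(field$dir$y, 2, h) +
    diff_axis(field$dir$z, 3, h)
}

#' Divergence of an arbitrary lattice vector field
#'
#' @param vx,vy,vz component arrays.
#' @param grid a [lattice_grid()].
#' @return array of divergence values.
#' @export
divergence_field <- function(vx, vy, vz, grid) {
  h <- grid$spacing
  diff_axis(vx, 1, h) + diff_axis(vy, 2, h) + diff_axis(vz, 3, h)
}
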