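#' Actin polymerization force on membrane vertices
#'
#' Exact gradient of the discretized barbed-end energy
#' E_B = sum_r psi(ds(r)) B(r) dx^3 over interior lattice points, taken
#' through the closest-element map of the signed distance field: each
#' interior point contributes a force of magnitude
#' dx^3 * (alpha*beta/2) * sech^2(beta*ds) * B along the outward direction,
#' distributed to the vertices of its closest face by barycentric weights.
#' Net effect: the membrane is pushed outward where barbed ends accumulate.
#'
#' @param B_field a [species_fields()] (its `B` array is used) or a bare
#'   array of barbed-end densities on the lattice.
#' @param dist a [signed_distance_field()] computed against `mesh` on the
#'   same lattice (a staleness check verifies this).
#' @param mesh the current [spine_mesh()].
#' @param params a [potential_params()].
#' @param cell_volume lattice cell volume dx^3 (um^3); defaults to the
#'   grid's spacing cubed.
#' @return a `vertex_forces` object with `forces` (n_v x 3, pN),
#'   `energy` (the discretized E_B) and `tag = "actin"`.
#' @export
actin_force <- function(B_field, dist, mesh, params = potential_params(),
                        cell_volume = NULL) {
  B <- if (inherits(B_field, "species_fields")) B_field$B else B_field
  if (is.null(cell_volume)) {
    stopifnot(!is.null(dist$grid))
    cell_volume <- dist$grid$spacing^3
  }
  nv <- nrow(mesh$vertices)
  if (max(dist$face) > nrow(mesh$faces))
    stop("stale closest-element map: face ids exceed the mesh face count")
  # staleness check: reconstruct a few closest points from the barycentric
  # map and the mesh; they must coincide with the stored closest points
  # the map may lag the mesh by a few explicit steps (sub-spacing drift);
  # reject only remesh-scale mismatches
  tol <- max(1e-8, cell_volume^(1 / 3) / 4)
  probe <- unique(round(seq(1, length(dist$ds), length.out = 5)))
  for (q in probe) {
    vid <- mesh$faces[dist$face[q], ]
    rec <- as.numeric(t(mesh$vertices[vid, , drop = FALSE]) %*% dist$bary[q, ])
    if (sqrt(sum((rec - dist$closest[q, ])^2)) > tol)
      stop("stale closest-element map: distance field was not computed ",
           "against this mesh")
  }
  ds <- as.numeric(dist$ds)
  Bv <- as.numeric(B)
  idx <- which(ds < 0 & Bv > 0)
  F <- matrix(0, nv, 3)
  energy <- 0
  if (length(idx) > 0) {
    mag <- cell_volume * (params$alpha * params$beta / 2) /
      cosh(params$beta * ds[idx])^2 * Bv[idx]
    energy <- sum(params$alpha * tanh(params$beta * ds[idx]) / 2 *
                    Bv[idx]) * cell_volume
    dirm <- if (is.list(dist$dir))
      cbind(as.numeric(dist$dir$x)[idx], as.numeric(dist$dir$y)[idx],
            as.numeric(dist$dir$z)[idx])
    else dist$dir[idx, , drop = FALSE]
    fidx <- dist$face[idx]
    for (m in 1:3) {
      vids <- mesh$faces[fidx, m]
      w <- dist$bary[idx, m] * mag
      contrib <- dirm * w
      agg <- rowsum(contrib, group = vids)
      ids <- as.integer(rownames(agg))
      F[ids, ] <- F[ids, ] + agg
    }
  }
  structure(list(forces = F, energy = energy, tag = "actin"),
            class = "vertex_forces")
}

#' Advance the membrane by the overdamped force balance
#'
#' Forward-Euler update s <- s + (dt/omega) (F_mem + F_actin) per vertex;
#' fixed vertices are never displaced.
#'
#' @param mesh a [spine_mesh()].
#' @param F_mem,F_actin `vertex_forces` (either may be NULL for zero).
#' @param mech a [mechanics_params()].
#' @param dt time step (s).
#' @param max_disp maximum allowed per-vertex displacement (um); defaults
#'   to half the mean edge length.  Exceeding it raises an error.
#' @return the displaced [spine_mesh()] (not revalidated, for speed).
#' @export
advance_membrane <- function(mesh, F_mem, F_actin, mech = mechanics_params(),
                             dt, max_disp = NULL) {
  stopifnot(dt > 0)
  nv <- nrow(mesh$vertices)
  Ftot <- matrix(0, nv, 3)
  if (!is.null(F_mem)) Ftot <- Ftot + F_mem$forces
  if (!is.null(F_actin)) Ftot <- Ftot + F_actin$forces
  disp <- (dt / mech$omega) * Ftot
  disp[mesh$fixed, ] <- 0
  dmax <- sqrt(max(rowSums(disp^2)))
  if (is.null(max_disp)) max_disp <- mean(edge_lengths(mesh)) / 2
  if (dmax > max_disp)
    stop(sprintf(
      "membrane step-size violation: max displacement %.3g um exceeds %.3g um; reduce dt",
      dmax, max_disp))
  mesh$vertices <- mesh$vertices + disp
  mesh
}

#' Relax the membrane under bending forces alone
#'
#' Gradient-flow iteration of the membrane update with F_actin = 0 until
#' the maximum per-step vertex displacement falls below `tol` or
#' `max_steps` is reached.  Used to equilibrate the constructed initial
#' shape.  The discrete bending energy is non-increasing along the flow.
#'
#' @param mesh a [spine_mesh()].
#' @param mech a [mechanics_params()].
#' @param dt time step (s).
#' @param max_steps iteration cap.
#' @param tol convergence threshold on per-step displacement (um).
#' @return the relaxed mesh, with attributes `steps`, `residual` and
#'   `energy` (trace of the bending energy).
#' @export
relax_membrane <- function(mesh, mech = mechanics_params(), dt = 0.01,
                           max_steps = 500, tol = 1e-5) {
  energies <- numeric(0)
  residual <- Inf
  steps <- 0
  for (i in seq_len(max_steps)) {
    fm <- bending_force(mesh, mech)
    energies <- c(energies, fm$energy)
    prev <- mesh$vertices
    trial <- advance_membrane(mesh, fm, NULL, mech, dt, max_disp = Inf)
    # gradient flow must descend; halve the step if the explicit update
    # overshoots the stability limit of the bending flow
    while (bending_energy(trial, mech) >
             fm$energy * (1 + 1e-9) && dt > 1e-8) {
      dt <- dt / 2
      trial <- advance_membrane(mesh, fm, NULL, mech, dt, max_disp = Inf)
    }
    mesh <- trial
    residual <- sqrt(max(rowSums((mesh$vertices - prev)^2)))
    steps <- i
    if (residual < tol) break
  }
  if (residual >= tol)
    warning(sprintf(
      "membrane relaxation did not converge in %d steps (residual %.3g um)",
      max_steps, residual))
  attr(mesh, "steps") <- steps
  attr(mesh, "residual") <- residual
  attr(mesh, "energy") <- energies
  mesh
}

#' Protrusion tracker
#'
#' Tracks one membrane vertex (chosen at the side of the spine head at
#' t = 0) and its horizontal displacement along a fixed axis; the
#' protrusion velocity nu_mp feeds the bulk-flow terms.  Negative
#' displacements give zero velocity.
#'
#' @param mesh a [spine_mesh()].
#' @param point reference position; the nearest vertex is tracked.
#' @param axis fixed unit tracking direction (default +x).
#' @return a list of class `protrusion_tracker`.
#' @export
protrusion_tracker <- function(mesh, point, axis = c(1, 0, 0)) {
  d2 <- rowSums(sweep(mesh$vertices, 2, point)^2)
  vid <- which.min(d2)
  structure(list(vid = vid, axis = axis / sqrt(sum(axis^2)),
                 position = mesh$vertices[vid, ],
                 nu_mp = 0, displacement = numeric(0)),
            class = "protrusion_tracker")
}

#' Update tracked protrusion velocity
#'
#' Computes nu_mp = max(0, displacement along the tracking axis / dt) since
#' the previous update and records the new tracked position.
#'
#' @param tracker a [protrusion_tracker()].
#' @param mesh the current [spine_mesh()].
#' @param dt elapsed time (s).
#' @return the updated tracker; its `nu_mp` field holds the velocity.
#' @export
protrusion_velocity <- function(tracker, mesh, dt) {
  stopifnot(dt > 0)
  if (tracker$vid > nrow(mesh$vertices))
    stop("tracked vertex no longer exists; rebind after remeshing")
  pos <- mesh$vertices[tracker$vid, ]
  disp <- sum((pos - tracker$position) * tracker$axis)
  tracker$nu_mp <- max(0, disp / dt)
  tracker$displacement <- c(tracker$displacement, disp)
  tracker$position <- pos
  tracker
}

#' Rebind a tracker after remeshing
#'
#' Remeshing destroys vertex identity; the tracker is rebound to the new
#' vertex nearest its last tracked position.
#'
#' @param tracker a [protrusion_tracker()].
#' @param mesh the remeshed [spine_mesh()].
#' @param max_dist furthest allowed rebinding distance (um); an error is
#'   raised if no vertex lies within it.
#' @return the rebound tracker.
#' @export
rebind_tracker <- function(tracker, mesh, max_dist = Inf) {
  d2 <- rowSums(sweep(mesh$vertices, 2, tracker$position)^2)
  vid <- which.min(d2)
  if (sqrt(d2[vid]) > max_dist)
    stop(sprintf(
      "tracked vertex lost: nearest vertex after remeshing is %.3g um away (limit %.3g)",
      sqrt(d2[vid]), max_dist))
  tracker$vid <- vid
  tracker$position <- mesh$vertices[vid, ]
  tracker
}

#' Local force at the tracked protrusion site
#'
#' Average of the three vertex forces of the face intersected by a ray from
#' the tracked vertex along the tracking axis; falls back to the faces
#' incident to the tracked vertex when no face is hit.
#'
#' @param mesh a [spine_mesh()].
#' @param forces a `vertex_forces` object.
#' @param tracker a [protrusion_tracker()].
#' @return mean force magnitude (pN).
#' @export
local_force <- function(mesh, forces, tracker) {
  o <- tracker$position + 1e-9 * tracker$axis
  dirv <- tracker$axis
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  # Moller-Trumbore, vectorized over faces
  pv <- matrix(rep(dirv, each = nrow(f)), ncol = 3)
  pvec <- vec_cross(pv, e2)
  det <- rowSums(e1 * pvec)
  tvec <- sweep(-a, 2, -o)  # o - a
  u <- rowSums(tvec * pvec) / det
  qvec <- vec_cross(tvec, e1)
  w <- (qvec %*% dirv) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- which(abs(det) > 1e-14 & u >= 0 & w >= 0 & (u + w) <= 1 & tt > 1e-9)
  mags <- sqrt(rowSums(forces$forces^2))
  if (length(hit) > 0) {
    fi <- hit[which.min(tt[hit])]
    mean(mags[f[fi, ]])
  } else {
    inc <- which(rowSums(matrix(f %in% tracker$vid, nrow(f), 3)) > 0)
    if (length(inc) == 0) return(mags[tracker$vid])
    mean(mags[unique(as.integer(f[inc, ]))])
  }
}
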