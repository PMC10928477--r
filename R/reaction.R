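#' Species fields on the lattice
#'
#' Barbed-end density B (number per cubic micrometre) and Arp2/3 (A) and
#' cofilin (C) concentrations (uM), one value per lattice point.
#'
#' @param grid a [lattice_grid()].
#' @param B,A,C initial arrays or scalars.
#' @param time simulation time (s).
#' @return a list of class `species_fields`.
#' @export
species_fields <- function(grid, B = 0, A = 0, C = 0, time = 0) {
  shape <- grid$shape
  expand <- function(x) {
    if (length(x) == 1) x <- array(x, dim = shape)
    stopifnot(identical(dim(x), as.integer(shape)), all(is.finite(x)),
              all(x >= 0))
    x
  }
  structure(list(B = expand(B), A = expand(A), C = expand(C),
                 time = time, grid = grid, clipped = c(B = 0, A = 0, C = 0)),
            class = "species_fields")
}

# neighbor shifts with replicated boundary (zero one-sided gradient there)
shift_m <- function(x, d) {
  n <- dim(x)[d]
  i <- c(1, 1:(n - 1))
  switch(d, x[i, , , drop = FALSE], x[, i, , drop = FALSE],
         x[, , i, drop = FALSE])
}
shift_p <- function(x, d) {
  n <- dim(x)[d]
  i <- c(2:n, n)
  switch(d, x[i, , , drop = FALSE], x[, i, , drop = FALSE],
         x[, , i, drop = FALSE])
}

# first-order upwind (v . grad x) for velocity component arrays vx,vy,vz
upwind_advect <- function(x, vx, vy, vz, h) {
  out <- array(0, dim = dim(x))
  comps <- list(vx, vy, vz)
  for (d in 1:3) {
    v <- comps[[d]]
    if (all(v == 0)) next
    bwd <- (x - array(shift_m(x, d), dim = dim(x))) / h
    fwd <- (array(shift_p(x, d), dim = dim(x)) - x) / h
    out <- out + pmax(v, 0) * bwd + pmin(v, 0) * fwd
  }
  out
}

#' Influx geometry
#'
#' Lattice masks for the basal protein influx (homogeneous inside the spine
#' head) and for the stimulus-triggered influx (interior points within one
#' lattice spacing of the membrane, inside a height window).  Basal and
#' stimulus influx rates are divided by the number of basal locations; the
#' stimulus influx is additionally scaled by the initial head volume
#' relative to a reference so that total delivered protein tracks the
#' initial head size.
#'
#' @param mesh a [spine_mesh()] (used for error messages only; geometry is
#'   read from `dist`).
#' @param grid a [lattice_grid()].
#' @param dist a [signed_distance_field()] computed on `grid` against the
#'   current mesh.
#' @param z_window stimulus height window (um).
#' @param head_z_min height above which interior points count as the head.
#' @param ref_head_volume reference head volume for the stimulus scaling
#'   (um^3); defaults to the current head volume, giving `head_scale = 1`.
#' @return a list of class `influx_geometry` with `basal_mask`,
#'   `stimulus_mask` (logical arrays), `n_basal`, `head_scale`.
#' @export
build_influx_masks <- function(mesh, grid, dist, z_window = c(0.7, 1.0),
                               head_z_min = 0.6, ref_head_volume = NULL) {
  shape <- grid$shape
  z <- array(rep(grid_axis(grid, 3), each = shape[1] * shape[2]), dim = shape)
  interior <- dist$ds < 0
  basal <- interior & (z >= head_z_min)
  if (!any(basal))
    stop("empty basal mask: no interior lattice points above z = ", head_z_min)
  eps <- 1e-9
  stim <- interior & (dist$ds >= -(grid$spacing + eps)) &
    (z >= z_window[1]) & (z <= z_window[2])
  if (!any(stim))
    stop("empty stimulus mask: no interior points within one spacing of the ",
         "membrane in z-window [", z_window[1], ", ", z_window[2], "]")
  v_head <- sum(basal) * grid$spacing^3
  head_scale <- if (is.null(ref_head_volume)) 1 else v_head / ref_head_volume
  structure(list(basal_mask = basal, stimulus_mask = stim,
                 n_basal = sum(basal), head_scale = head_scale,
                 head_volume = v_head, z = z),
            class = "influx_geometry")
}

# Precompute the geometry-dependent transport quantities used by the RHS so
# repeated integrator evaluations within a step do not redo them.
transport_context <- function(dist, grid, kin = kinetic_params(),
                              pot = potential_params(),
                              z_absorb = 0.3, freeze_band = 3 / pot$beta) {
  fu <- force_density(dist, pot)
  div_d <- divergence_of_direction(dist, grid)
  div_fu <- divergence_field(fu$x, fu$y, fu$z, grid)
  shape <- grid$shape
  z <- array(rep(grid_axis(grid, 3), each = shape[1] * shape[2]), dim = shape)
  list(dist = dist, grid = grid, kin = kin, pot = pot,
       dir = dist$dir, div_d = div_d, fu = fu, div_fu = div_fu,
       absorb = z < z_absorb, frozen = dist$ds > freeze_band)
}

#' Time derivatives of the species fields
#'
#' Evaluates the coupled barbed-end / Arp2/3 / cofilin right-hand sides at
#' every lattice point: polymerization transport of B along the direction
#' field at speed `nu`, the confining repulsive force-density terms scaled
#' by the filament mobility `eta`, bulk flow of A and C at speed
#' `xi * nu_mp`, first-order decay, nucleation and severing reactions
#' (stoichiometrically coupled: B gains `Psi0 * f`, A or C loses `f`), and
#' basal/stimulus influxes on their masks.
#'
#' @param fields a [species_fields()].
#' @param dist a [signed_distance_field()] for the current membrane.
#' @param geom an [build_influx_masks()] result.
#' @param nu_mp protrusion speed (um/s, >= 0).
#' @param params a [kinetic_params()].
#' @param stimulus_on logical: stimulus influx active.
#' @param pot a [potential_params()].
#' @param ctx optional precomputed [transport_context()].
#' @return list with arrays `B`, `A`, `C` of time derivatives.
#' @export
species_rhs <- function(fields, dist, geom, nu_mp, params = kinetic_params(),
                        stimulus_on = FALSE, pot = potential_params(),
                        ctx = NULL) {
  stopifnot(nu_mp >= 0)
  grid <- fields$grid
  if (is.null(ctx)) ctx <- transport_context(dist, grid, params, pot)
  shape <- grid$shape
  res <- cpp_species_rhs(
    shape, as.numeric(fields$B), as.numeric(fields$A),
    as.numeric(fields$C), as.numeric(ctx$dir$x), as.numeric(ctx$dir$y),
    as.numeric(ctx$dir$z), as.numeric(ctx$div_d), as.numeric(ctx$fu$x),
    as.numeric(ctx$fu$y), as.numeric(ctx$fu$z), as.numeric(ctx$div_fu),
    as.numeric(geom$basal_mask) / geom$n_basal,
    as.numeric(geom$stimulus_mask) * geom$head_scale / geom$n_basal,
    unclass(params), nu_mp, isTRUE(stimulus_on), grid$spacing)
  out <- list(B = array(res$B, dim = shape), A = array(res$A, dim = shape),
              C = array(res$C, dim = shape))
  for (nm in c("B", "A", "C"))
    if (!all(is.finite(out[[nm]])))
      stop("non-finite values in d", nm,
           " (reaction-transport right-hand side)")
  out
}

#' Advance the species fields by one global time step
#'
#' Integrates the reaction-transport system over `dt` with an adaptive
#' explicit Runge-Kutta 4(5) scheme (Dormand-Prince via deSolve),
#' sub-stepping as needed.  After the step, negative values are clipped to
#' zero (clipped mass is accumulated in `fields$clipped`), species are
#' zeroed below the absorbing boundary height and at lattice points far
#' outside the membrane where the repulsive potential has saturated.
#'
#' @param fields a [species_fields()].
#' @param ctx a [transport_context()]; carries the distance field, grid,
#'   kinetic and potential parameters, and boundary masks.
#' @param geom an [build_influx_masks()] result.
#' @param nu_mp protrusion speed (um/s).
#' @param dt time step (s).
#' @param stimulus_on logical.
#' @param rtol,atol integrator tolerances.
#' @return the advanced [species_fields()].
#' @export
step_fields <- function(fields, ctx, geom, nu_mp, dt, stimulus_on = FALSE,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(dt > 0)
  grid <- fields$grid
  # advective CFL guard for the explicit sub-stepping
  vmax <- max(ctx$kin$nu, ctx$kin$xi * nu_mp,
              ctx$kin$eta * max(abs(ctx$fu$mag)))
  if (vmax * dt > grid$spacing)
    stop(sprintf(
      "advective CFL violation: max speed %.3g um/s, dt %.3g s, spacing %.3g um; reduce dt below %.3g s",
      vmax, dt, grid$spacing, grid$spacing / vmax))
  npts <- prod(grid$shape)
  y0 <- c(as.numeric(fields$B), as.numeric(fields$A), as.numeric(fields$C))
  shape <- grid$shape
  deriv <- function(t, y, parms) {
    f <- fields
    f$B <- array(y[seq_len(npts)], dim = shape)
    f$A <- array(y[npts + seq_len(npts)], dim = shape)
    f$C <- array(y[2 * npts + seq_len(npts)], dim = shape)
    d <- species_rhs(f, ctx$dist, geom, nu_mp, ctx$kin,
                     stimulus_on = stimulus_on, pot = ctx$pot, ctx = ctx)
    list(c(as.numeric(d$B), as.numeric(d$A), as.numeric(d$C)))
  }
  sol <- deSolve::ode(y = y0, times = c(fields$time, fields$time + dt),
                      func = deriv, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  y1 <- sol[nrow(sol), -1]
  out <- fields
  out$time <- fields$time + dt
  kill <- ctx$absorb | ctx$frozen
  for (k in 1:3) {
    nm <- c("B", "A", "C")[k]
    v <- array(y1[(k - 1) * npts + seq_len(npts)], dim = shape)
    neg <- v < 0
    out$clipped[nm] <- out$clipped[nm] - sum(v[neg])
    v[neg] <- 0
    v[kill] <- 0
    out[[nm]] <- v
  }
  out
}

#' Totals of the species fields
#'
#' @param fields a [species_fields()].
#' @param integral multiply raw sums by the cell volume.
#' @return named vector of totals for B, A, C.
#' @export
species_totals <- function(fields, integral = FALSE) {
  s <- c(B = sum(fields$B), A = sum(fields$A), C = sum(fields$C))
  if (integral) s * fields$grid$spacing^3 else s
}
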