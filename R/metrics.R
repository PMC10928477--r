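#' Collect one record of spine observables
#'
#' Volume, surface area, neck and head cross-section radii, species totals
#' (both raw lattice sums and cell-volume integrals), force totals and the
#' protrusion velocity, at one instant.
#'
#' @param state a [species_fields()].
#' @param mesh a [spine_mesh()].
#' @param forces list with elements `membrane` and `actin`
#'   (`vertex_forces`), either may be NULL.
#' @param tracker a [protrusion_tracker()] or NULL.
#' @param grid a [lattice_grid()].
#' @param z_neck,z_head section heights for the neck and head radii (um).
#' @return one-row data.frame.
#' @export
collect_observables <- function(state, mesh, forces = list(), tracker = NULL,
                                grid = state$grid, z_neck = 0.63,
                                z_head = 0.84) {
  radius_at <- function(z) {
    r <- try(cross_section_radius(mesh, z), silent = TRUE)
    if (inherits(r, "try-error")) NA_real_ else r
  }
  fsum <- function(f) if (is.null(f)) 0 else sum(sqrt(rowSums(f$forces^2)))
  ftotsum <- if (!is.null(forces$membrane) && !is.null(forces$actin)) {
    sum(sqrt(rowSums((forces$membrane$forces + forces$actin$forces)^2)))
  } else 0
  raw <- species_totals(state, integral = FALSE)
  intg <- species_totals(state, integral = TRUE)
  data.frame(
    time = state$time,
    volume = mesh_volume(mesh),
    area = mesh_area(mesh),
    neck_radius = radius_at(z_neck),
    head_radius = radius_at(z_head),
    B_total = raw[["B"]], A_total = raw[["A"]], C_total = raw[["C"]],
    B_integral = intg[["B"]], A_integral = intg[["A"]],
    C_integral = intg[["C"]],
    F_mem = fsum(forces$membrane),
    F_actin = fsum(forces$actin),
    F_total = ftotsum,
    nu_mp = if (is.null(tracker)) NA_real_ else tracker$nu_mp,
    clipped = sum(state$clipped))
}

#' Normalize an observables series to a reference time
#'
#' Divides every quantity by its value at the sample nearest `t_ref`, and
#' adds per-volume normalized species columns (`B_per_vol` etc., species
#' totals divided by the instantaneous normalized volume).
#'
#' @param series data.frame of stacked [collect_observables()] rows.
#' @param t_ref reference time (s).
#' @return data.frame of normalized quantities.
#' @export
normalize_series <- function(series, t_ref = 0) {
  stopifnot(nrow(series) > 0)
  if (t_ref < min(series$time) || t_ref > max(series$time))
    stop("t_ref = ", t_ref, " outside the series time range")
  i0 <- which.min(abs(series$time - t_ref))
  cols <- setdiff(names(series), c("time", "nu_mp", "clipped"))
  out <- series
  for (cn in cols) {
    ref <- series[[cn]][i0]
    if (!is.finite(ref) || ref == 0)
      stop("zero or missing reference value for '", cn, "' at t_ref")
    out[[cn]] <- series[[cn]] / ref
  }
  for (sp in c("B", "A", "C"))
    out[[paste0(sp, "_per_vol")]] <- out[[paste0(sp, "_total")]] / out$volume
  out
}

#' Force-velocity pairs
#'
#' Pairs local force magnitudes with protrusion velocities; velocities are
#' clamped at zero from below upstream.
#'
#' @param force numeric vector of local force magnitudes (pN).
#' @param velocity numeric vector of protrusion velocities (um/s).
#' @return data.frame with columns `force`, `velocity`.
#' @export
force_velocity_curve <- function(force, velocity) {
  if (length(force) != length(velocity))
    stop("force and velocity histories have different lengths (",
         length(force), " vs ", length(velocity), ")")
  data.frame(force = as.numeric(force), velocity = pmax(0, velocity))
}

#' Residual variance fraction of the best affine fit
#'
#' Fraction of velocity variance left unexplained by the best straight
#' line; large values indicate a nonlinear force-velocity relation.
#'
#' @param fv a [force_velocity_curve()] data.frame.
#' @return residual sum of squares divided by total sum of squares.
#' @export
affine_fit_residual <- function(fv) {
  keep <- is.finite(fv$force) & is.finite(fv$velocity)
  fit <- stats::lm(velocity ~ force, data = fv[keep, ])
  tss <- sum((fv$velocity[keep] - mean(fv$velocity[keep]))^2)
  if (tss == 0) return(0)
  sum(stats::residuals(fit)^2) / tss
}

#' Percent change of a quantity over the stimulus window
#'
#' (value at the stimulus end / value at the last pre-stimulus sample - 1)
#' times 100.
#'
#' @param series observables data.frame.
#' @param column column name.
#' @param t_on,t_off stimulus window (s).
#' @return percent change.
#' @export
percent_change <- function(series, column, t_on, t_off) {
  pre <- series[series$time <= t_on, ]
  if (nrow(pre) == 0) stop("no samples at or before t_on")
  v0 <- pre[[column]][which.max(pre$time)]
  i1 <- which.min(abs(series$time - t_off))
  (series[[column]][i1] / v0 - 1) * 100
}
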