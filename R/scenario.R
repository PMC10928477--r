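#' Scenario configuration
#'
#' Full specification of a simulation run: kinetic/mechanical/potential
#' parameters, discretization, phase schedule and stimulus windows, and
#' perturbations scoped to the stimulus window.
#'
#' The timeline is: membrane held fixed while fields evolve
#' (`fixed_duration`), coupled evolution to pre-stimulus equilibrium
#' (`relax_duration`), then the stimulus window(s) (offsets in
#' `stim_offsets`, each of length `stim_length`, relative to the end of the
#' relaxation phase), then a post-stimulus period (`post_duration` after
#' the last window closes).
#'
#' @param name scenario name.
#' @param preset `"paper"` (dt 0.01 s, dx 0.0315 um, edge 0.05 um, 1 min
#'   fixed + 3 min coupled + 1 min stimulus + 4 min post) or `"reduced"`
#'   (dt 0.05 s, dx 0.06 um, edge 0.1 um, compressed schedule) resolution.
#' @param ... overrides of any config field (see Details in the package
#'   vignette); notable fields: `kin` ([kinetic_params()]), `mech`
#'   ([mechanics_params()]), `pot` ([potential_params()]), `dt`, `dx`,
#'   `edge`, `fixed_duration`, `relax_duration`, `stim_offsets`,
#'   `stim_length`, `post_duration`, `stim_nu_factor`, `stim_omega_factor`,
#'   `stim_eta_factor`, `remesh_every`, `sdf_every`, `output_every`,
#'   `seed`.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(name = "control", preset = c("paper", "reduced"),
                            ...) {
  preset <- match.arg(preset)
  cfg <- list(
    name = name, preset = preset, seed = 1L,
    kin = kinetic_params(), mech = mechanics_params(),
    pot = potential_params(),
    head_radius = 0.25, head_center_z = 0.85, neck_radius = 0.1,
    neck_length = 0.6,
    dt = 0.01, dx = 0.0315, edge = 0.05,
    fixed_duration = 60, relax_duration = 180,
    stim_offsets = 0, stim_length = 60, post_duration = 240,
    stim_nu_factor = 1, stim_omega_factor = 1, stim_eta_factor = 1,
    z_window = c(0.7, 1.0), head_z_min = 0.6, z_absorb = 0.3,
    z_neck = 0.63, z_head = 0.84,
    remesh_every = 0.5, sdf_every = 1L, output_every = 1,
    margin_cells = 4,
    init_relax_steps = 150, init_relax_step_size = 1e-4,
    ref_head_volume = NULL,
    rtol = 1e-6, atol = 1e-8)
  if (preset == "reduced") {
    cfg$dt <- 0.05
    cfg$dx <- 0.06
    cfg$edge <- 0.08
    cfg$fixed_duration <- 20
    cfg$relax_duration <- 40
    cfg$post_duration <- 60
    cfg$remesh_every <- 2
    cfg$sdf_every <- 40L
    cfg$output_every <- 1
    cfg$init_relax_steps <- 80
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$dt > 0, cfg$dx > 0, cfg$edge > 0)
  structure(cfg, class = "scenario_config")
}

#' Catalog of stimulus-perturbation scenarios
#'
#' Named scenario constructors: control at the default parameters;
#' knockouts of each stimulus-triggered influx; 50 percent enhancement of
#' the Arp2/3 and cofilin stimulus influx; bending-modulus sweep (+/- 25
#' percent); clutch/ECM perturbations scoped to the stimulus window
#' (filament mobility eta x 0.6, polymerization speed nu x 1.4, drag omega
#' x 0.6, and their combinations); and the repeated-stimuli protocol
#' (three 1-minute windows separated by 1-minute rests).
#'
#' @param name scenario name; omit to get the full list of names.
#' @param preset resolution preset forwarded to [scenario_config()].
#' @param ... further overrides forwarded to [scenario_config()].
#' @return a `scenario_config`, or a character vector of names.
#' @export
scenario_catalog <- function(name = NULL, preset = "paper", ...) {
  build <- list(
    control = function(...) scenario_config("control", ...),
    no_actin_stimulus = function(...)
      scenario_config("no_actin_stimulus", kin = kinetic_params(IS_beta = 0),
                      ...),
    no_arp_stimulus = function(...)
      scenario_config("no_arp_stimulus", kin = kinetic_params(IS_A = 0), ...),
    no_cofilin_stimulus = function(...)
      scenario_config("no_cofilin_stimulus", kin = kinetic_params(IS_C = 0),
                      ...),
    enhanced_abp = function(...)
      scenario_config("enhanced_abp",
                      kin = kinetic_params(IS_A = 0.0293 * 1.5,
                                           IS_C = 0.4384 * 1.5), ...),
    kappa_up = function(...)
      scenario_config("kappa_up", mech = mechanics_params(kappa = 0.18 * 1.25),
                      ...),
    kappa_down = function(...)
      scenario_config("kappa_down",
                      mech = mechanics_params(kappa = 0.18 * 0.75), ...),
    eta_down = function(...)
      scenario_config("eta_down", stim_eta_factor = 0.6, ...),
    nu_up = function(...)
      scenario_config("nu_up", stim_nu_factor = 1.4, ...),
    omega_down = function(...)
      scenario_config("omega_down", stim_omega_factor = 0.6, ...),
    nu_up_omega_down = function(...)
      scenario_config("nu_up_omega_down", stim_nu_factor = 1.4,
                      stim_omega_factor = 0.6, ...),
    nu_up_eta_down = function(...)
      scenario_config("nu_up_eta_down", stim_nu_factor = 1.4,
                      stim_eta_factor = 0.6, ...),
    repeated = function(...)
      scenario_config("repeated", stim_offsets = c(0, 120, 240),
                      margin_cells = 7, ...))
  if (is.null(name)) return(names(build))
  if (!name %in% names(build))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(build), collapse = ", "))
  build[[name]](preset = preset, ...)
}

# absolute stimulus windows of a config
config_windows <- function(cfg) {
  t0 <- cfg$fixed_duration + cfg$relax_duration
  cbind(t0 + cfg$stim_offsets, t0 + cfg$stim_offsets + cfg$stim_length)
}

#' Run a simulation scenario
#'
#' Executes the full phase schedule of a [scenario_config()]: (1) species
#' fields evolve on the lattice with the membrane held fixed, (2) coupled
#' field-membrane evolution toward pre-stimulus equilibrium, (3) stimulus
#' window(s) with the stimulus-triggered influx (and any window-scoped
#' parameter perturbations) active, (4) post-stimulus evolution.
#' Observables are recorded at `output_every` seconds; the run is
#' deterministic for a fixed configuration and seed.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; if given, writes `observables.csv`,
#'   `normalized.csv`, `force_velocity.csv`, `config.json` and the final
#'   mesh as OFF.
#' @param verbose print per-phase progress.
#' @return list with `observables` (data.frame), `normalized` (normalized
#'   to the last pre-stimulus sample), `fv` (force-velocity data.frames for
#'   membrane/actin/total force), `mesh`, `fields`, `tracker`, `config`,
#'   `windows`.
#' @export
run_scenario <- function(config = scenario_config(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- config
  set.seed(cfg$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[init] building initial spine (edge %.3g um)", cfg$edge)
  mesh <- build_initial_spine(cfg$head_radius, cfg$head_center_z,
                              cfg$neck_radius, cfg$neck_length, cfg$edge)
  mesh <- relax_membrane(mesh, cfg$mech,
                         dt = cfg$init_relax_step_size * cfg$mech$omega,
                         max_steps = cfg$init_relax_steps, tol = 1e-6)
  grid <- grid_for_mesh(mesh, cfg$dx, margin_cells = cfg$margin_cells)
  dist <- signed_distance_field(grid, mesh)
  geom <- build_influx_masks(mesh, grid, dist, z_window = cfg$z_window,
                             head_z_min = cfg$head_z_min,
                             ref_head_volume = cfg$ref_head_volume)
  basal0 <- geom$basal_mask  # basal influx locations never change
  kin <- cfg$kin
  fields <- species_fields(
    grid,
    B = kin$Psi0 * (kin$I_beta / kin$k_beta) / geom$n_basal * geom$basal_mask,
    A = (kin$I_A / kin$k_A) / geom$n_basal * geom$basal_mask,
    C = (kin$I_C / kin$k_C) / geom$n_basal * geom$basal_mask)
  tracker <- protrusion_tracker(
    mesh, c(cfg$head_radius, 0, cfg$head_center_z))

  windows <- config_windows(cfg)
  t_end <- max(windows[, 2]) + cfg$post_duration
  n_steps <- ceiling(t_end / cfg$dt)
  obs <- vector("list", floor(t_end / cfg$output_every) + 2)
  fvrec <- list(mem = numeric(0), act = numeric(0), tot = numeric(0),
                v = numeric(0))
  n_obs <- 0
  ctx <- transport_context(dist, grid, kin, cfg$pot, z_absorb = cfg$z_absorb)
  nu_mp <- 0
  drift <- 0
  stim_prev <- FALSE
  next_output <- 0
  last_remesh <- 0
  phase_of <- function(t) {
    if (t < cfg$fixed_duration) "fixed"
    else if (stimulus_active(sched_abs, t)) "stimulus"
    else if (t < cfg$fixed_duration + cfg$relax_duration) "relax"
    else "free"
  }
  sched_abs <- stimulus_schedule(split(windows, row(windows)))

  record <- function(t, Fm, Fa) {
    forces <- list(membrane = Fm, actin = Fa)
    row <- collect_observables(fields, mesh, forces, tracker, grid,
                               z_neck = cfg$z_neck, z_head = cfg$z_head)
    row$time <- t
    n_obs <<- n_obs + 1
    obs[[n_obs]] <<- row
    if (!is.null(Fm) && !is.null(Fa)) {
      tot <- Fm
      tot$forces <- Fm$forces + Fa$forces
      fvrec$mem <<- c(fvrec$mem, local_force(mesh, Fm, tracker))
      fvrec$act <<- c(fvrec$act, local_force(mesh, Fa, tracker))
      fvrec$tot <<- c(fvrec$tot, local_force(mesh, tot, tracker))
      fvrec$v <<- c(fvrec$v, tracker$nu_mp)
    }
  }

  Fm <- bending_force(mesh, cfg$mech)
  Fa <- actin_force(fields, dist, mesh, cfg$pot)
  record(0, Fm, Fa)
  next_output <- cfg$output_every

  for (step in seq_len(n_steps)) {
    t <- (step - 1) * cfg$dt
    t_next <- step * cfg$dt
    stim_on <- any(t >= windows[, 1] & t < windows[, 2])
    phase <- phase_of(t)

    # window-scoped perturbations of nu, eta (kinetics) and omega (drag)
    kin_eff <- kin
    mech_eff <- cfg$mech
    if (stim_on) {
      kin_eff$nu <- kin$nu * cfg$stim_nu_factor
      kin_eff$eta <- kin$eta * cfg$stim_eta_factor
      mech_eff$omega <- cfg$mech$omega * cfg$stim_omega_factor
    }

    if (stim_on && !stim_prev) {
      # stimulus mask is frozen at window onset from the current membrane
      geom2 <- build_influx_masks(mesh, grid, dist, z_window = cfg$z_window,
                                  head_z_min = cfg$head_z_min,
                                  ref_head_volume = cfg$ref_head_volume)
      geom$stimulus_mask <- geom2$stimulus_mask
      geom$head_scale <- geom2$head_scale
      say("[t=%.1f] stimulus on (%d stimulus points, head_scale %.3f)",
          t, sum(geom$stimulus_mask), geom$head_scale)
    }
    stim_prev <- stim_on
    ctx$kin <- kin_eff

    fields <- step_fields(fields, ctx, geom, nu_mp, cfg$dt,
                          stimulus_on = stim_on, rtol = cfg$rtol,
                          atol = cfg$atol)

    if (phase != "fixed") {
      Fm <- bending_force(mesh, mech_eff)
      Fa <- actin_force(fields, dist, mesh, cfg$pot)
      prev_verts <- mesh$vertices
      mesh <- advance_membrane(mesh, Fm, Fa, mech_eff, cfg$dt)
      drift <- drift + sqrt(max(rowSums((mesh$vertices - prev_verts)^2)))
      tracker <- protrusion_velocity(tracker, mesh, cfg$dt)
      nu_mp <- tracker$nu_mp
      if (t_next - last_remesh >= cfg$remesh_every - 1e-9) {
        mesh <- remesh_isotropic(mesh, cfg$edge, iterations = 1)
        base_ids <- which(abs(mesh$vertices[, 3]) < 1e-9)
        mesh$fixed <- sort(unique(c(mesh$fixed, base_ids)))
        tracker <- rebind_tracker(tracker, mesh)
        last_remesh <- t_next
        drift <- Inf  # force a distance-field refresh
      }
      # refresh the distance field when the membrane has moved far enough
      # for the closest-element map to go stale, or at the hard cadence
      if (drift > cfg$dx / 8 || step %% cfg$sdf_every == 0) {
        dist <- signed_distance_field(grid, mesh)
        ctx <- transport_context(dist, grid, kin_eff, cfg$pot,
                                 z_absorb = cfg$z_absorb)
        drift <- 0
      }
    }

    if (t_next >= next_output - 1e-9) {
      if (phase == "fixed") {
        Fm <- bending_force(mesh, mech_eff)
        Fa <- actin_force(fields, dist, mesh, cfg$pot)
      }
      record(t_next, Fm, Fa)
      next_output <- next_output + cfg$output_every
      if (verbose && abs(t_next - round(t_next / 30) * 30) < cfg$dt / 2)
        say("[t=%.1f s] phase %s, volume %.4f um^3, sumB %.1f",
            t_next, phase, mesh_volume(mesh), sum(fields$B))
    }
  }

  observables <- do.call(rbind, obs[seq_len(n_obs)])
  t_ref <- max(observables$time[observables$time <= windows[1, 1]])
  normalized <- normalize_series(observables, t_ref = t_ref)
  fv <- list(
    membrane = force_velocity_curve(fvrec$mem, fvrec$v),
    actin = force_velocity_curve(fvrec$act, fvrec$v),
    total = force_velocity_curve(fvrec$tot, fvrec$v))

  out <- list(observables = observables, normalized = normalized, fv = fv,
              mesh = mesh, fields = fields, tracker = tracker,
              config = cfg, windows = windows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(observables, file.path(out_dir, "observables.csv"),
                     row.names = FALSE)
    utils::write.csv(normalized, file.path(out_dir, "normalized.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(F_mem = fvrec$mem, F_actin = fvrec$act, F_total = fvrec$tot,
                 nu_mp = fvrec$v),
      file.path(out_dir, "force_velocity.csv"), row.names = FALSE)
    cfg_json <- unclass(cfg)
    cfg_json$kin <- unclass(cfg$kin)
    cfg_json$mech <- unclass(cfg$mech)
    cfg_json$pot <- unclass(cfg$pot)
    jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_off(mesh, file.path(out_dir, "final_mesh.off"))
  }
  out
}
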