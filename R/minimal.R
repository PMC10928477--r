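#' Stimulus schedule
#'
#' Disjoint, ordered stimulus windows during which the stimulus-triggered
#' influxes are active.
#'
#' @param windows list of `c(t_on, t_off)` pairs (s), or a 2-column matrix.
#' @return a list of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(windows = list(c(0, 60))) {
  if (is.matrix(windows)) windows <- split(windows, row(windows))
  w <- do.call(rbind, lapply(windows, function(x) {
    stopifnot(length(x) == 2, x[2] > x[1])
    as.numeric(x)
  }))
  if (nrow(w) > 1) {
    o <- order(w[, 1])
    w <- w[o, , drop = FALSE]
    if (any(w[-1, 1] < w[-nrow(w), 2]))
      stop("stimulus windows must be disjoint")
  }
  structure(list(windows = w), class = "stimulus_schedule")
}

#' Is the stimulus active at time t?
#'
#' @param schedule a [stimulus_schedule()].
#' @param t time (s); vectorized.
#' @return logical vector.
#' @export
stimulus_active <- function(schedule, t) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(schedule$windows)))
    out <- out | (t >= schedule$windows[i, 1] & t < schedule$windows[i, 2])
  out
}

#' Parameters of the non-spatial kinetic model
#'
#' Decay rates, stimulus influxes and steady-state concentrations of the
#' well-mixed actin / Arp2/3 / cofilin model used to constrain the spatial
#' model.  The basal influxes are defined as I = k * steady_state so the
#' normalized pre-stimulus state (1, 1, 1) is an exact fixed point.
#'
#' @param k_beta,k_A,k_C decay rates (1/s).
#' @param IS_beta,IS_A,IS_C stimulus influxes (uM/s).
#' @param beta_star,A_star,C_star steady-state concentrations (uM).
#' @return a list of class `minimal_params`.
#' @export
minimal_params <- function(k_beta = 0.0081, k_A = 0.0013, k_C = 0.0006,
                           IS_beta = 25.6684, IS_A = 0.0293, IS_C = 0.4384,
                           beta_star = 3000, A_star = 20, C_star = 40) {
  stopifnot(k_beta > 0, k_A > 0, k_C > 0, IS_beta >= 0, IS_A >= 0,
            IS_C >= 0, beta_star > 0, A_star > 0, C_star > 0)
  structure(list(k_beta = k_beta, k_A = k_A, k_C = k_C,
                 IS_beta = IS_beta, IS_A = IS_A, IS_C = IS_C,
                 beta_star = beta_star, A_star = A_star, C_star = C_star),
            class = "minimal_params")
}

#' Simulate the normalized minimal model
#'
#' Integrates db/dt = IS_beta(t)/beta* + k_beta (1 - b) (and likewise for a
#' and c) from the normalized initial state (1, 1, 1), with the stimulus
#' influxes active only inside the schedule windows.
#'
#' @param params a [minimal_params()].
#' @param schedule a [stimulus_schedule()].
#' @param times output times (s), sorted increasing.
#' @return a data.frame of class `normalized_series` with columns
#'   `time`, `b`, `a`, `c`.
#' @export
simulate_minimal <- function(params = minimal_params(),
                             schedule = stimulus_schedule(),
                             times = seq(0, 600, by = 5)) {
  stopifnot(!is.unsorted(times))
  deriv <- function(t, y, p) {
    on <- as.numeric(stimulus_active(schedule, t))
    list(c(on * p$IS_beta / p$beta_star + p$k_beta * (1 - y[1]),
           on * p$IS_A / p$A_star + p$k_A * (1 - y[2]),
           on * p$IS_C / p$C_star + p$k_C * (1 - y[3])))
  }
  # integrate piecewise so window edges are never smoothed over
  edges <- sort(unique(c(times, as.numeric(schedule$windows))))
  edges <- edges[edges >= min(times) & edges <= max(times)]
  sol <- deSolve::ode(y = c(b = 1, a = 1, c = 1), times = edges,
                      func = deriv, parms = params, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)[match(times, edges), ]
  res <- data.frame(time = times, b = out$b, a = out$a, c = out$c)
  class(res) <- c("normalized_series", "data.frame")
  res
}

#' Closed-form response of one normalized species
#'
#' For a single stimulus window starting at t = 0 with duration `t_off`:
#' during the window, x(t) = 1 + (IS/(k s*)) (1 - exp(-k t)); afterwards
#' the excess decays exponentially at rate k.  Used as the analytic oracle
#' for the integrator.
#'
#' @param t time (s), vectorized.
#' @param k decay rate (1/s).
#' @param IS stimulus influx (uM/s).
#' @param star steady-state concentration (uM).
#' @param t_off stimulus end (s).
#' @return normalized concentration.
#' @export
minimal_closed_form <- function(t, k, IS, star, t_off = 60) {
  gain <- IS / (k * star)
  peak <- 1 + gain * (1 - exp(-k * t_off))
  ifelse(t <= t_off,
         1 + gain * (1 - exp(-k * t)),
         1 + (peak - 1) * exp(-k * (t - t_off)))
}

#' Piecewise-analytic solution of the normalized minimal model
#'
#' The model is linear within each epoch (stimulus on or off), so the exact
#' solution is a chain of exponential relaxations toward 1 + IS/(k s*)
#' (stimulus on) or 1 (off).  Used by the fitter, where speed matters, and
#' as an independent cross-check of the numerical integrator.
#'
#' @inheritParams simulate_minimal
#' @return a `normalized_series` data.frame.
#' @export
minimal_solution <- function(params = minimal_params(),
                             schedule = stimulus_schedule(),
                             times = seq(0, 600, by = 5)) {
  stopifnot(!is.unsorted(times))
  t0 <- times[1]
  edges <- sort(unique(c(t0, as.numeric(schedule$windows), max(times))))
  edges <- edges[edges >= t0]
  one_species <- function(k, IS, star) {
    gain <- IS / (k * star)
    out <- numeric(length(times))
    x <- 1
    for (i in seq_len(length(edges) - 1)) {
      a <- edges[i]
      b <- edges[i + 1]
      on <- stimulus_active(schedule, (a + b) / 2)
      target <- if (on) 1 + gain else 1
      sel <- times >= a & times <= b
      out[sel] <- target + (x - target) * exp(-k * (times[sel] - a))
      x <- target + (x - target) * exp(-k * (b - a))
    }
    out[times <= t0] <- 1
    out
  }
  res <- data.frame(time = times,
                    b = one_species(params$k_beta, params$IS_beta,
                                    params$beta_star),
                    a = one_species(params$k_A, params$IS_A, params$A_star),
                    c = one_species(params$k_C, params$IS_C, params$C_star))
  class(res) <- c("normalized_series", "data.frame")
  res
}

#' Generate synthetic normalized fluorescence traces
#'
#' Emulates digitized normalized-concentration time courses: baseline 1, a
#' one-minute stimulus-driven rise, exponential relaxation, plus i.i.d.
#' additive Gaussian noise.  Deterministic for a fixed seed.
#'
#' @param params a [minimal_params()].
#' @param noise_sigma standard deviation of the additive noise.
#' @param times sample times (s).
#' @param seed RNG seed.
#' @param schedule a [stimulus_schedule()].
#' @return a `normalized_series` data.frame with columns `time`, `b`, `a`,
#'   `c`.
#' @export
generate_synthetic_series <- function(params = minimal_params(),
                                      noise_sigma = 0.05,
                                      times = seq(-60, 540, by = 30),
                                      seed = 1,
                                      schedule = stimulus_schedule()) {
  stopifnot(noise_sigma >= 0)
  t0 <- min(times, 0)
  clean <- simulate_minimal(params, schedule,
                            times = sort(unique(c(t0, times))))
  clean <- clean[match(times, clean$time), ]
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    n <- length(times)
    clean$b <- clean$b + stats::rnorm(n, 0, noise_sigma)
    clean$a <- clean$a + stats::rnorm(n, 0, noise_sigma)
    clean$c <- clean$c + stats::rnorm(n, 0, noise_sigma)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  rownames(clean) <- NULL
  clean
}

#' Fit the minimal model to normalized traces
#'
#' Bounded nonlinear least squares over {k_beta, k_A, k_C, IS_beta, IS_A,
#' IS_C} against three normalized series, with multi-start (log-uniform
#' perturbations around the initial guess) to guard the six-parameter
#' landscape.  Steady states are held at their literature values.
#'
#' @param series a `normalized_series` data.frame (columns `time`, `b`,
#'   `a`, `c`).
#' @param init_guess a [minimal_params()] used as the fit starting point.
#' @param schedule a [stimulus_schedule()].
#' @param n_starts number of multi-start perturbations (first start is the
#'   unperturbed guess).
#' @param seed RNG seed for the multi-start perturbations.
#' @return list with `params` (fitted [minimal_params()]), `residual`
#'   (squared norm of residuals), `fits` (per-start residuals).
#' @export
fit_minimal <- function(series, init_guess = minimal_params(),
                        schedule = stimulus_schedule(), n_starts = 10,
                        seed = 1) {
  stopifnot(all(c("time", "b", "a", "c") %in% names(series)))
  series <- series[order(series$time), ]
  times <- series$time
  obs <- c(series$b, series$a, series$c)
  model_resid <- function(par) {
    p <- minimal_params(k_beta = par[1], k_A = par[2], k_C = par[3],
                        IS_beta = par[4], IS_A = par[5], IS_C = par[6],
                        beta_star = init_guess$beta_star,
                        A_star = init_guess$A_star,
                        C_star = init_guess$C_star)
    sim <- minimal_solution(p, schedule, times = times)
    c(sim$b, sim$a, sim$c) - obs
  }
  p0 <- c(init_guess$k_beta, init_guess$k_A, init_guess$k_C,
          init_guess$IS_beta, init_guess$IS_A, init_guess$IS_C)
  lower <- rep(1e-8, 6)
  upper <- c(rep(1, 3), rep(1e3, 3))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  starts <- list(p0)
  for (i in seq_len(max(0, n_starts - 1)))
    starts[[i + 1]] <- pmin(pmax(p0 * exp(stats::runif(6, -1, 1)), lower),
                            upper)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  best <- NULL
  resids <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[[i]], lower = lower, upper = upper, fn = model_resid,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    resids[i] <- sum(fit$fvec^2)
    if (is.null(best) || resids[i] < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best))
    stop("minimal-model fit failed to converge from any start")
  par <- best$par
  list(params = minimal_params(k_beta = par[1], k_A = par[2], k_C = par[3],
                               IS_beta = par[4], IS_A = par[5],
                               IS_C = par[6],
                               beta_star = init_guess$beta_star,
                               A_star = init_guess$A_star,
                               C_star = init_guess$C_star),
       residual = sum(best$fvec^2),
       fits = resids)
}

#' Scale factors between barbed ends and concentrations
#'
#' From the mean dynamic filament length, the per-monomer length
#' contribution, and the minimal spacing between Arp2/3 branches:
#' monomers per filament = round(length / contribution), branches per
#' filament = round(length / spacing), and with 602.214 molecules per
#' (um^3 uM), Psi0 = 602.214 / monomers (barbed ends per um^3 per uM of
#' actin) and Psi1 = branches / 602.214 (uM um^3 per barbed end).
#'
#' @param filament_length mean dynamic F-actin length (nm).
#' @param monomer_contribution filament length per G-actin monomer (nm).
#' @param branch_spacing minimal distance between branches (nm).
#' @return list with `Psi0`, `Psi1`, `monomers_per_filament`,
#'   `branches_per_filament`.
#' @export
derive_scale_factors <- function(filament_length = 450,
                                 monomer_contribution = 2.7,
                                 branch_spacing = 37) {
  stopifnot(filament_length > 0, monomer_contribution > 0, branch_spacing > 0)
  avogadro_per_um3_uM <- 602.214
  monomers <- round(filament_length / monomer_contribution)
  branches <- round(filament_length / branch_spacing)
  list(Psi0 = avogadro_per_um3_uM / monomers,
       Psi1 = branches / avogadro_per_um3_uM,
       monomers_per_filament = monomers,
       branches_per_filament = branches)
}
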