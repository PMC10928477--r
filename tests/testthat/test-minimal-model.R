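test_that("(1,1,1) is an exact fixed point without stimulus", {
  p <- minimal_params()
  out <- simulate_minimal(p, stimulus_schedule(list(c(1e6, 1e6 + 60))),
                          times = seq(0, 300, by = 30))
  expect_lt(max(abs(out$b - 1)), 1e-10)
  expect_lt(max(abs(out$a - 1)), 1e-10)
  expect_lt(max(abs(out$c - 1)), 1e-10)
})

test_that("integrator matches the closed-form stimulus response", {
  p <- minimal_params()
  times <- seq(0, 300, by = 5)
  out <- simulate_minimal(p, stimulus_schedule(list(c(0, 60))), times)
  cf_b <- minimal_closed_form(times, p$k_beta, p$IS_beta, p$beta_star, 60)
  cf_a <- minimal_closed_form(times, p$k_A, p$IS_A, p$A_star, 60)
  cf_c <- minimal_closed_form(times, p$k_C, p$IS_C, p$C_star, 60)
  expect_lt(max(abs(out$b - cf_b)), 1e-6)
  expect_lt(max(abs(out$a - cf_a)), 1e-6)
  expect_lt(max(abs(out$c - cf_c)), 1e-6)
  # peak value at the end of a one-minute stimulus
  b60 <- 1 + p$IS_beta / (p$k_beta * p$beta_star) * (1 - exp(-p$k_beta * 60))
  expect_equal(out$b[out$time == 60], b60, tolerance = 1e-6)
  expect_equal(b60, 1.4066, tolerance = 1e-4)
  # post-stimulus relaxation is exponential at rate k
  i1 <- which(times == 120)
  decay <- (out$b[i1] - 1) / (out$b[times == 60] - 1)
  expect_equal(decay, exp(-p$k_beta * 60), tolerance = 1e-6)
})

test_that("piecewise-analytic solution agrees with the integrator", {
  p <- minimal_params()
  sched <- stimulus_schedule(list(c(0, 60), c(120, 180)))
  times <- seq(-30, 300, by = 10)
  a1 <- simulate_minimal(p, sched, times)
  a2 <- minimal_solution(p, sched, times)
  expect_lt(max(abs(a1$b - a2$b)), 1e-7)
  expect_lt(max(abs(a1$c - a2$c)), 1e-7)
})

test_that("synthetic traces are reproducible and correctly calibrated", {
  p <- minimal_params()
  s1 <- generate_synthetic_series(p, 0.05, seed = 11)
  s2 <- generate_synthetic_series(p, 0.05, seed = 11)
  expect_identical(s1, s2)
  s3 <- generate_synthetic_series(p, 0, seed = 11)
  clean <- simulate_minimal(p, stimulus_schedule(),
                            times = sort(unique(c(-60, s3$time))))
  clean <- clean[match(s3$time, clean$time), ]
  expect_equal(s3$b, clean$b, tolerance = 1e-9)
  # noise standard deviation matches sigma
  tt <- seq(-60, 540, length.out = 1000)
  noisy <- generate_synthetic_series(p, 0.05, times = tt, seed = 4)
  ref <- generate_synthetic_series(p, 0, times = tt)
  sdres <- stats::sd(noisy$b - ref$b)
  expect_gt(sdres, 0.045)
  expect_lt(sdres, 0.055)
})

test_that("noiseless fits recover the generating parameters within 1%", {
  truth <- minimal_params()
  series <- generate_synthetic_series(truth, 0,
                                      times = seq(-60, 540, by = 20))
  guess <- minimal_params(k_beta = 0.02, k_A = 0.003, k_C = 0.002,
                          IS_beta = 10, IS_A = 0.01, IS_C = 0.1)
  fit <- fit_minimal(series, guess, n_starts = 3)
  p <- fit$params
  for (nm in c("k_beta", "k_A", "k_C", "IS_beta", "IS_A", "IS_C"))
    expect_lt(abs(p[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
  expect_lt(fit$residual, 1e-10)
})

test_that("constant all-ones series drives stimulus influx estimates to zero", {
  series <- data.frame(time = seq(-60, 540, by = 30), b = 1, a = 1, c = 1)
  fit <- fit_minimal(series, minimal_params(), n_starts = 2)
  expect_lt(fit$params$IS_beta / fit$params$beta_star, 1e-6)
  expect_lt(fit$params$IS_A / fit$params$A_star, 1e-6)
  expect_lt(fit$params$IS_C / fit$params$C_star, 1e-6)
})

test_that("fit residual is invariant under time-point reordering", {
  truth <- minimal_params()
  series <- generate_synthetic_series(truth, 0.05,
                                      times = seq(-60, 540, by = 50),
                                      seed = 2)
  f1 <- fit_minimal(series, truth, n_starts = 1)
  # reorder columns by shuffling rows (times unsorted)
  perm <- sample(nrow(series))
  f2 <- fit_minimal(series[perm, ], truth, n_starts = 1)
  expect_equal(f1$residual, f2$residual, tolerance = 1e-8)
})

test_that("noisy-fit recovery error grows monotonically with noise", {
  truth <- minimal_params()
  times13 <- seq(-60, 540, length.out = 13)
  med_err <- function(sigma, seeds) {
    errs <- sapply(seeds, function(sd) {
      series <- generate_synthetic_series(truth, sigma, times13, seed = sd)
      fit <- fit_minimal(series, truth, n_starts = 1)
      p <- fit$params
      sapply(c("k_beta", "k_A", "k_C", "IS_beta", "IS_A", "IS_C"),
             function(nm) abs(p[[nm]] - truth[[nm]]) / truth[[nm]])
    })
    stats::median(errs)  # pooled over parameters and seeds
  }
  meds <- sapply(c(0, 0.02, 0.05, 0.1), med_err, seeds = 1:8)
  expect_lt(meds[1], 1e-4)
  expect_true(all(diff(meds) > 0))
})

test_that("scale factors reproduce the filament geometry conversions", {
  sf <- derive_scale_factors()
  expect_equal(sf$monomers_per_filament, 167)
  expect_equal(sf$branches_per_filament, 12)
  expect_equal(sf$Psi0, 602.214 / 167)
  expect_equal(sf$Psi0, 3.6, tolerance = 0.01)
  expect_equal(sf$Psi1, 12 / 602.214)
  expect_equal(sf$Psi1, 0.02, tolerance = 0.01)
})

test_that("stimulus schedules enforce disjoint ordered windows", {
  s <- stimulus_schedule(list(c(0, 60), c(120, 180)))
  expect_true(all(stimulus_active(s, c(10, 130))))
  expect_false(any(stimulus_active(s, c(-5, 70, 200))))
  expect_error(stimulus_schedule(list(c(0, 60), c(30, 90))), "disjoint")
})
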