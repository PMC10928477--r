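#' Kinetic parameters
#'
#' Default rate constants, influxes, scale factors and transport speeds of
#' the barbed-end/Arp2/3/cofilin system.  Units: decay rates 1/s, influxes
#' uM/s, `k_nuc` 1/(uM s), `k_sev` 1/s, `k_n` uM^n, `Psi0` #/(um^3 uM),
#' `Psi1` um^3 uM/#, `nu` um/s, `eta` um/(s pN); `xi` dimensionless in (0,1).
#'
#' @param ... named overrides of any default.
#' @return a list of class `kinetic_params`.
#' @export
kinetic_params <- function(...) {
  p <- list(
    k_beta = 0.0081, I_beta = 24.4284, IS_beta = 25.6684,
    k_A = 0.0013, I_A = 0.0255, IS_A = 0.0293,
    k_C = 0.0006, I_C = 0.0237, IS_C = 0.4384,
    k_nuc = 0.0153, k_sev = 0.0120, k_n = 0.6, n = 3.5,
    Psi0 = 3.6, Psi1 = 0.02,
    nu = 1e-5, xi = 0.1, eta = 1e-10)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0)
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(all(unlist(p) >= 0), p$xi > 0, p$xi < 1)
  structure(p, class = "kinetic_params")
}

#' Mechanical parameters of the membrane
#'
#' @param kappa bending modulus (pN um).
#' @param omega effective drag coefficient (s pN/um).
#' @return a list of class `mechanics_params`.
#' @export
mechanics_params <- function(kappa = 0.18, omega = 1e5) {
  stopifnot(kappa > 0, omega > 0)
  structure(list(kappa = kappa, omega = omega), class = "mechanics_params")
}

#' Repulsive membrane potential parameters
#'
#' The soft repulsive potential psi = alpha * tanh(beta * ds) / 2 couples
#' lattice species to the membrane through the signed distance ds.
#'
#' @param alpha amplitude (pN).
#' @param beta steepness (dimensionless).
#' @return a list of class `potential_params`.
#' @export
potential_params <- function(alpha = 3e4, beta = 40) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "potential_params")
}

#' Arp2/3-mediated nucleation rate
#'
#' Side-branching nucleation of new barbed ends, linear in both the Arp2/3
#' concentration and the barbed-end density.
#'
#' @param A_val Arp2/3 concentration (uM).
#' @param B_val barbed ends per cubic micrometre.
#' @param params a [kinetic_params()].
#' @return rate in uM/s.
#' @export
nucleation_rate <- function(A_val, B_val, params = kinetic_params()) {
  stopifnot(all(A_val >= 0), all(B_val >= 0))
  params$k_nuc * A_val * params$Psi1 * B_val
}

#' Cofilin severing rate
#'
#' Cooperative (Hill) severing of filaments by cofilin, producing new barbed
#' ends: k_sev * C^n / (k_n + C^n) * Psi1 * B.
#'
#' @param C_val cofilin concentration (uM).
#' @param B_val barbed ends per cubic micrometre.
#' @param params a [kinetic_params()].
#' @return rate in uM/s.
#' @export
severing_rate <- function(C_val, B_val, params = kinetic_params()) {
  stopifnot(all(C_val >= 0), all(B_val >= 0))
  cn <- C_val^params$n
  params$k_sev * cn / (params$k_n + cn) * params$Psi1 * B_val
}
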