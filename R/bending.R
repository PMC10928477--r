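#' Discrete Helfrich bending energy
#'
#' Cotangent-Laplacian discretization of E = (kappa/2) * integral of H^2 dA
#' with zero spontaneous curvature and the H = c1 + c2 convention, so a
#' sphere has energy 8 * pi * kappa independent of radius.
#'
#' @param mesh a [spine_mesh()].
#' @param params a [mechanics_params()].
#' @return bending energy (pN um).
#' @export
bending_energy <- function(mesh, params = mechanics_params()) {
  cpp_bending(mesh$vertices, mesh$faces - 1L, params$kappa)$energy
}

#' Bending force on membrane vertices
#'
#' The exact negative gradient of the discrete bending energy with respect
#' to vertex positions.  Forces are computed at every vertex, including
#' fixed ones; dynamics callers zero the fixed entries.
#'
#' @param mesh a [spine_mesh()].
#' @param params a [mechanics_params()].
#' @return a list of class `vertex_forces` with `forces` (n_v x 3, pN),
#'   `energy`, and `tag = "membrane"`.
#' @export
bending_force <- function(mesh, params = mechanics_params()) {
  res <- cpp_bending(mesh$vertices, mesh$faces - 1L, params$kappa)
  structure(list(forces = -res$grad, energy = res$energy, tag = "membrane"),
            class = "vertex_forces")
}

#' @export
print.vertex_forces <- function(x, ...) {
  cat(sprintf("vertex_forces [%s]: %d vertices, sum |F| = %.4g pN\n",
              x$tag, nrow(x$forces), sum(sqrt(rowSums(x$forces^2)))))
  invisible(x)
}
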