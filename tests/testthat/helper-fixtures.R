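# Shared fixtures: analytic meshes and a small relaxed spine + lattice,
# built once per test run.

fixture_env <- new.env()

small_spine <- function() {
  if (is.null(fixture_env$spine)) {
    set.seed(1)
    m <- build_initial_spine(0.25, 0.85, 0.1, 0.6, 0.08)
    fixture_env$spine <- suppressWarnings(
      relax_membrane(m, mechanics_params(), dt = 10, max_steps = 60,
                     tol = 1e-6))
  }
  fixture_env$spine
}

spine_lattice <- function(spacing = 0.07) {
  key <- paste0("grid", spacing)
  if (is.null(fixture_env[[key]])) {
    m <- small_spine()
    g <- grid_for_mesh(m, spacing)
    fixture_env[[key]] <- list(grid = g,
                               dist = signed_distance_field(g, m),
                               mesh = m)
  }
  fixture_env[[key]]
}

# R-side brute-force point-to-mesh distance oracle (vectorized over faces,
# one point at a time); independent of the C++ query path
oracle_distance <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    # closest point by projecting onto the plane then clamping to edges
    best <- min(best, oracle_tri_dist(p, a, b, c3))
  }
  best
}

oracle_tri_dist <- function(p, a, b, c3) {
  # distance to triangle = min over (plane projection if inside, edges)
  n <- pracma::cross(b - a, c3 - a)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric test of q
  v0 <- b - a; v1 <- c3 - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  w1 <- (d11 * d20 - d01 * d21) / den
  w2 <- (d00 * d21 - d01 * d20) / den
  if (w1 >= 0 && w2 >= 0 && w1 + w2 <= 1) return(sqrt(sum((p - q)^2)))
  seg <- function(s, e) {
    t <- sum((p - s) * (e - s)) / sum((e - s)^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (s + t * (e - s)))^2))
  }
  min(seg(a, b), seg(b, c3), seg(c3, a))
}
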