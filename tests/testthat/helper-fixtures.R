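## Shared fixtures: small synthetic systems and hand-built trajectories.

## a light hydrated slab for I/O and geometry tests
small_slab <- function(n_frames = 3, seed = 2, ...) {
  generate_trajectory(ldh_preset("SUC_6.5_WAT", n_formula_units = 4,
                                 n_frames = n_frames, seed = seed, dt = 10,
                                 ...))
}

## wrap a bare coordinate matrix as a frame
as_frame <- function(coords) {
  list(coordinates = coords)
}

## trajectory of free atoms (no slab) for RDF/density unit tests
gas_trajectory <- function(n, n_frames, box, role = "water_O", seed = 1) {
  set.seed(seed)
  top <- topology(rep("O", n), rep(0, n), seq_len(n), rep(role, n))
  coords <- array(stats::runif(n * 3 * n_frames), dim = c(n, 3, n_frames))
  for (j in 1:3) coords[, j, ] <- coords[, j, ] * box[j]
  trajectory(top, coords, box, dt = 1)
}

## harmonic oscillation of one atom along x at frequency nu (cm^-1)
harmonic_trajectory <- function(nu, n_frames, dt = 0.5, amp = 0.05,
                                with_velocities = TRUE) {
  top <- topology(c("C", "C"), c(0, 0), c(1L, 1L), c("other", "other"))
  om <- 2 * pi * nu * 2.99792458e-5
  t_ <- (seq_len(n_frames) - 1) * dt
  coords <- array(0, dim = c(2, 3, n_frames))
  coords[1, 1, ] <- amp * cos(om * t_)
  coords[2, , ] <- 5
  vel <- NULL
  if (with_velocities) {
    vel <- array(0, dim = c(2, 3, n_frames))
    vel[1, 1, ] <- -amp * om * sin(om * t_)
  }
  trajectory(top, coords, c(20, 20, 20), dt = dt, velocities = vel)
}
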