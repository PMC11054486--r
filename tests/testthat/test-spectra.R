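c_cmfs <- 2.99792458e-5

test_that("dipole of a two-atom +1/-1 molecule matches the hand value", {
  top <- topology(c("H", "H"), c(1, -1), c(1L, 1L), c("other", "other"))
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(1, 0, 0)
  tr <- trajectory(top, coords, c(10, 10, 10), dt = 1)
  ds <- dipole_series(tr, 1L)
  expect_equal(ds$values[1, ], c(1, 0, 0), tolerance = 1e-12)
})

test_that("net-charged anion dipole is translation invariant (COM reference)", {
  tr <- small_slab(n_frames = 4)
  mol <- tr$topology$anion_records[[1]]$molecule_id
  mu0 <- dipole_series(tr, mol)$values
  shifted <- tr
  shifted$coords <- shifted$coords + 3.7
  mu1 <- dipole_series(shifted, mol)$values
  expect_lt(max(abs(mu1 - mu0)), 1e-9)
})

test_that("|mu|, C(t) and the spectrum are rotation invariant", {
  tr <- generate_trajectory(
    synthetic_config("SUC", n_formula_units = 1, spacing_d = 11.98,
                     p_parallel = 0.5, n_frames = 4096, seed = 31))
  mol <- tr$topology$anion_records[[1]]$molecule_id
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- tr
  for (f in seq_len(n_frames(tr))) {
    rot$coords[, , f] <- tr$coords[, , f] %*% t(R)
  }
  d0 <- dipole_series(tr, mol)
  d1 <- dipole_series(rot, mol)
  n0 <- sqrt(rowSums(d0$values^2))
  n1 <- sqrt(rowSums(d1$values^2))
  expect_lt(max(abs(n1 - n0)) / max(n0), 1e-8)
  c0 <- dipole_acf(d0)$values
  c1 <- dipole_acf(d1)$values
  expect_lt(max(abs(c1 - c0)) / max(abs(c0)), 1e-8)
  ## the summed per-component AR spectrum is invariant up to fit error
  ## (Burg is nonlinear in the components), so compare shapes and peaks
  s0 <- mem_spectrum(d0, order = 200)
  s1 <- mem_spectrum(d1, order = 200)
  expect_gt(cor(log(s0$intensity), log(s1$intensity)), 0.99)
  expect_equal(find_band_gap(s1)$gap, find_band_gap(s0)$gap,
               tolerance = 0.03)
})

test_that("autocorrelation closed forms hold", {
  ## constant dipole -> C(t) = 1 at every lag
  V <- matrix(rep(c(1, 0, 0), each = 50), 50, 3)
  cf <- dipole_acf(V, dt = 1)
  expect_equal(cf$values, rep(1, 50), tolerance = 1e-12)
  ## cosine -> C(t) ~ 0.5 cos(Omega t) for large N
  n <- 20000
  Om <- 0.31
  V2 <- cbind(cos(Om * (0:(n - 1))), 0, 0)
  cf2 <- dipole_acf(V2, max_lag = 50, dt = 1)
  expect_equal(cf2$values, 0.5 * cos(Om * (0:50)), tolerance = 5e-3)
  ## normalization and error paths
  expect_error(dipole_acf(V, max_lag = 100, dt = 1), "max_lag")
  expect_equal(dipole_acf(V2, dt = 1, normalize = TRUE)$values[1], 1)
})

test_that("FFT autocorrelation equals the O(N^2) direct sum", {
  set.seed(8)
  V <- matrix(rnorm(300 * 3), 300, 3)
  cf <- dipole_acf(V, dt = 1)
  n <- nrow(V)
  direct <- vapply(0:(n - 1), function(k) {
    s <- 0
    for (m in 1:(n - k)) s <- s + sum(V[m, ] * V[m + k, ])
    s / (n - k)
  }, numeric(1))
  expect_lt(max(abs(cf$values - direct)), 1e-10)
  expect_identical(cf$values[1], mean(rowSums(V^2)))
})

test_that("MEM spectrum of a pure cosine peaks at its frequency", {
  dt <- 0.5
  n <- 8192
  nu0 <- 1500
  x <- cos(2 * pi * nu0 * c_cmfs * dt * (0:(n - 1)))
  sp <- mem_spectrum(cbind(x), order = 100, dt = dt,
                     grid = seq(800, 2000, by = 2))
  expect_lte(abs(sp$frequency[which.max(sp$intensity)] - nu0), 2)
})

test_that("white noise gives a flat low-order MEM spectrum", {
  set.seed(21)
  x <- rnorm(8192)
  sp <- mem_spectrum(cbind(x), order = 2, dt = 0.5,
                     grid = seq(800, 2000, by = 2))
  expect_lt(max(sp$intensity) / min(sp$intensity), 2)
})

test_that("MEM peak matches the closed-form AR(2) spectral maximum", {
  ## noise-driven damped oscillator == AR(2); its true PSD follows from the
  ## coefficients, giving an independent closed-form oracle for the peak
  dt <- 0.5
  nu0 <- 1450
  r <- exp(-dt / 400)
  a1 <- 2 * r * cos(2 * pi * nu0 * c_cmfs * dt)
  a2 <- -r^2
  set.seed(5)
  x <- as.numeric(stats::filter(rnorm(16384), c(a1, a2),
                                method = "recursive"))
  fine <- seq(1300, 1600, by = 0.5)
  denom <- Mod(1 - a1 * exp(-2i * pi * fine * c_cmfs * dt) -
                 a2 * exp(-4i * pi * fine * c_cmfs * dt))^2
  truth <- fine[which.min(denom)]
  sp <- mem_spectrum(cbind(x), order = 50, dt = dt,
                     grid = seq(1300, 1600, by = 1))
  peak <- sp$frequency[which.max(sp$intensity)]
  expect_lt(abs(peak - truth), 10)
})

test_that("MEM agrees with the FFT periodogram on AR signals", {
  dt <- 0.5
  set.seed(9)
  r <- exp(-dt / 300)
  a1 <- 2 * r * cos(2 * pi * 1400 * c_cmfs * dt)
  x <- as.numeric(stats::filter(rnorm(4096), c(a1, -r^2),
                                method = "recursive"))
  n <- length(x)
  ## lightly smoothed periodogram on the FFT grid, band of interest only
  pg <- stats::spec.pgram(x, spans = 11, taper = 0, plot = FALSE,
                          detrend = TRUE)
  fgrid <- pg$freq / dt / c_cmfs
  sel <- fgrid >= 800 & fgrid <= 2000
  sp <- mem_spectrum(cbind(x), order = 2, dt = dt, grid = fgrid[sel])
  expect_gt(cor(log(pg$spec[sel]), log(sp$intensity)), 0.9)
})

test_that("integrated MEM spectrum recovers the series variance", {
  dt <- 0.5
  set.seed(12)
  r <- exp(-dt / 200)
  a1 <- 2 * r * cos(2 * pi * 1200 * c_cmfs * dt)
  x <- as.numeric(stats::filter(rnorm(8192), c(a1, -r^2),
                                method = "recursive"))
  nyq <- 1 / (2 * dt) / c_cmfs
  grid <- seq(0.5, nyq, length.out = 20000)
  sp <- mem_spectrum(cbind(x), order = 30, dt = dt, grid = grid)
  integral <- sum(sp$intensity) * diff(grid[1:2])
  expect_lt(abs(integral - var(x)) / var(x), 0.05)
})

test_that("order bounds are enforced", {
  expect_error(mem_spectrum(cbind(rnorm(100)), order = 60, dt = 1),
               "below n_frames/2")
})

test_that("spectrum averaging is a pointwise mean on identical grids", {
  g <- seq(800, 2000, by = 2)
  s1 <- ldhtraj:::new_spectrum(g, rep(0, length(g)))
  x <- seq_along(g) / 100
  s2 <- ldhtraj:::new_spectrum(g, 2 * x)
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$intensity, x)
  expect_equal(average_spectra(list(s2, s2))$intensity, s2$intensity)
  s3 <- ldhtraj:::new_spectrum(seq(800, 1998, by = 2), rep(1, 600))
  expect_error(average_spectra(list(s1, s3)), "mismatched")
})

test_that("shifting translates peaks and leaves the band gap unchanged", {
  g <- seq(800, 2000, by = 2)
  lor <- function(x0, w) 1 / (1 + ((g - x0) / w)^2)
  sp <- ldhtraj:::new_spectrum(g, lor(1400, 25) + 0.8 * lor(1600, 25))
  bg0 <- find_band_gap(sp)
  expect_equal(bg0$gap, 200)
  sh <- apply_shift(sp, -200)
  expect_equal(sh$shift_applied, -200)
  expect_equal(sh$frequency[which.max(sh$intensity)],
               sp$frequency[which.max(sp$intensity)] - 200)
  bg1 <- find_band_gap(sh, s_window = c(1100, 1300),
                       as_window = c(1300, 1550))
  expect_equal(bg1$gap, bg0$gap)
  expect_equal(bg1$nu_S, bg0$nu_S - 200)
  ## zero shift is the identity
  expect_equal(apply_shift(sp, 0)$intensity, sp$intensity)
  expect_equal(apply_shift(sp, 0)$frequency, sp$frequency)
})

test_that("band maxima at 1393/1603 give the 210 band gap", {
  g <- seq(800, 2000, by = 1)
  lor <- function(x0, w) 1 / (1 + ((g - x0) / w)^2)
  sp <- ldhtraj:::new_spectrum(g, lor(1393, 20) + 0.9 * lor(1603, 20))
  bg <- find_band_gap(sp)
  expect_equal(bg$nu_S, 1393)
  expect_equal(bg$nu_AS, 1603)
  expect_equal(bg$gap, 210)
})

test_that("a flat or edge-peaked window is a no-interior-peak error", {
  g <- seq(800, 2000, by = 2)
  flat <- ldhtraj:::new_spectrum(g, rep(1, length(g)))
  expect_error(find_band_gap(flat), "no interior peak")
  ramp <- ldhtraj:::new_spectrum(g, g)
  expect_error(find_band_gap(ramp), "no interior peak")
})

test_that("velocity power spectrum locates harmonic frequencies", {
  tr <- harmonic_trajectory(1500, 4096)
  sp <- velocity_power_spectrum(tr, 1:2, order = 100)
  expect_lte(abs(sp$frequency[which.max(sp$intensity)] - 1500), 2)
  ## static atom contributes a zero spectrum
  sp2 <- velocity_power_spectrum(tr, 2, order = 50)
  expect_true(all(sp2$intensity == 0))
  expect_error(velocity_power_spectrum(tr, integer(0)), "empty")
})

test_that("two atoms at distinct frequencies give two peaks (FFT oracle)", {
  dt <- 0.5
  n <- 4096
  top <- topology(c("C", "C"), c(0, 0), c(1L, 1L), c("other", "other"))
  om1 <- 2 * pi * 1200 * c_cmfs
  om2 <- 2 * pi * 1700 * c_cmfs
  t_ <- dt * (0:(n - 1))
  vel <- array(0, dim = c(2, 3, n))
  vel[1, 1, ] <- sin(om1 * t_)
  vel[2, 2, ] <- sin(om2 * t_)
  tr <- trajectory(top, array(0, dim = c(2, 3, n)), c(10, 10, 10), dt = dt,
                   velocities = vel)
  sp <- velocity_power_spectrum(tr, 1:2, order = 80)
  ## the two local maxima sit where the periodogram of each series peaks
  pk <- function(v) {
    P <- Mod(fft(v))^2
    ((0:(n - 1)) / (n * dt) / c_cmfs)[which.max(P[1:(n / 2)])]
  }
  in_window <- function(lo, hi) {
    ii <- sp$frequency >= lo & sp$frequency <= hi
    sp$frequency[ii][which.max(sp$intensity[ii])]
  }
  ## the FFT oracle resolution is 1/(n dt) ~ 16 cm^-1 here
  expect_lt(abs(in_window(1000, 1400) - pk(vel[1, 1, ])), 17)
  expect_lt(abs(in_window(1500, 1900) - pk(vel[2, 2, ])), 17)
})

test_that("missing velocities error unless finite differences are requested", {
  tr <- harmonic_trajectory(1500, 2048, with_velocities = FALSE)
  expect_error(velocity_power_spectrum(tr, 1:2), "no velocities")
  sp <- velocity_power_spectrum(tr, 1:2, order = 80, use_finite_diff = TRUE)
  expect_lte(abs(sp$frequency[which.max(sp$intensity)] - 1500), 4)
})

test_that("all-zero charges give a warning and a zero dipole", {
  top <- topology(c("C", "C"), c(0, 0), c(1L, 1L), c("other", "other"))
  tr <- trajectory(top, array(rnorm(12), dim = c(2, 3, 2)), c(5, 5, 5),
                   dt = 1)
  expect_warning(ds <- dipole_series(tr, 1L), "all-zero")
  expect_true(all(ds$values == 0))
})
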