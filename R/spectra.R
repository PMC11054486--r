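## Infrared spectra from dipole time-correlation functions.
##
## The absorption intensity is proportional to the Fourier transform of
## <mu(0).mu(t)>; the transform is estimated by the maximum entropy method
## (an autoregressive fit by Burg recursion) rather than a raw periodogram.
## The quantum prefactor relating the classical and quantum correlation
## functions is deliberately not applied; computed carboxylate bands are
## conventionally translated by a constant shift (see apply_shift) when
## compared with experiment, which leaves band separations untouched.

#' Dipole time series of one molecule
#'
#' For each frame, `mu = sum_i q_i (r_i - r_ref)` with `r_ref` the center of
#' mass of the selected atoms in that frame.  The center-of-mass reference
#' makes the dipole of the net-charged anions translation invariant.
#'
#' @param traj A [trajectory()].
#' @param molecule_id Molecule to analyse.
#' @param fragment `"molecule"` uses all atoms of the molecule;
#'   `"carboxylate"` restricts to the carboxylate C/O atoms (anions only).
#' @return An object of class `dipole_series`: `values` (`n_frames x 3`
#'   matrix, e.angstrom), `dt` (fs), `molecule_id`.  A molecule with
#'   all-zero charges yields a zero series with a warning.
#' @export
dipole_series <- function(traj, molecule_id,
                          fragment = c("molecule", "carboxylate")) {
  fragment <- match.arg(fragment)
  top <- traj$topology
  idx <- which(top$molecule_ids == molecule_id)
  if (length(idx) == 0L) stop("no molecule with id ", molecule_id)
  if (fragment == "carboxylate") {
    idx <- idx[top$roles[idx] %in% c("carboxylate_C", "carboxylate_O")]
    if (length(idx) == 0L) {
      stop("molecule ", molecule_id, " has no carboxylate atoms")
    }
  }
  q <- top$charges[idx]
  m <- element_mass(top$elements[idx])
  nf <- n_frames(traj)
  V <- matrix(0, nf, 3)
  if (all(q == 0)) {
    warning("molecule ", molecule_id, " has all-zero charges; zero dipole")
  } else {
    R <- traj$coords[idx, , , drop = FALSE]
    Qtot <- sum(q)
    Mtot <- sum(m)
    for (j in 1:3) {
      Rj <- matrix(R[, j, ], nrow = length(idx))
      com_j <- colSums(Rj * m) / Mtot
      V[, j] <- colSums(Rj * q) - Qtot * com_j
    }
  }
  s <- list(values = V, dt = traj$dt, molecule_id = molecule_id,
            fragment = fragment)
  class(s) <- "dipole_series"
  s
}

#' @export
print.dipole_series <- function(x, ...) {
  cat("<dipole_series> molecule ", x$molecule_id, ", ", nrow(x$values),
      " frames @ ", x$dt, " fs\n", sep = "")
  invisible(x)
}

#' Dipole autocorrelation function
#'
#' `C(t_k) = (1/(N-k)) sum_n mu(n).mu(n+k)` (raw, not mean-subtracted), so
#' `C(0)` equals the mean squared dipole.  Computed via FFT; an `O(N^2)`
#' direct sum gives identical values to rounding error.
#'
#' @param series A [dipole_series()] (or a plain numeric matrix with one
#'   column per component, in which case `dt` must be given).
#' @param max_lag Largest lag in fs; defaults to the full series length.
#' @param dt Frame spacing, only for plain-matrix input.
#' @param normalize If `TRUE`, divide by `C(0)`.
#' @return An object of class `correlation_function` with `lags` (fs),
#'   `values`, and `normalization`.
#' @export
dipole_acf <- function(series, max_lag = NULL, dt = NULL, normalize = FALSE) {
  if (inherits(series, "dipole_series")) {
    V <- series$values
    dt <- series$dt
  } else {
    V <- as.matrix(series)
    if (is.null(dt)) stop("dt required for plain-matrix input")
  }
  n <- nrow(V)
  if (n < 2L) stop("need at least 2 frames")
  k_max <- if (is.null(max_lag)) n - 1L else floor(max_lag / dt + 1e-9)
  if (k_max > n - 1L) stop("max_lag exceeds the series length")
  pad <- 2^ceiling(log2(2L * n))
  sums <- numeric(k_max + 1L)
  for (j in seq_len(ncol(V))) {
    s <- stats::fft(c(V[, j], rep(0, pad - n)))
    cc <- Re(stats::fft(Mod(s)^2, inverse = TRUE)) / pad
    sums <- sums + cc[seq_len(k_max + 1L)]
  }
  vals <- sums / (n - 0:k_max)
  vals[1] <- mean(rowSums(V^2))   # C(0) exactly
  norm <- "raw"
  if (normalize) {
    vals <- vals / vals[1]
    norm <- "normalized"
  }
  cf <- list(lags = (0:k_max) * dt, values = vals, normalization = norm,
             dt = dt)
  class(cf) <- "correlation_function"
  cf
}

new_spectrum <- function(frequency, intensity, shift_applied = 0,
                         meta = list()) {
  if (is.unsorted(frequency, strictly = TRUE)) {
    stop("frequency grid must be strictly increasing")
  }
  sp <- list(frequency = frequency, intensity = intensity,
             shift_applied = shift_applied, meta = meta)
  class(sp) <- "spectrum"
  sp
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", length(x$frequency), " points, ",
      signif(min(x$frequency), 6), "-", signif(max(x$frequency), 6),
      " cm^-1, shift ", x$shift_applied, " cm^-1\n", sep = "")
  invisible(x)
}

#' Maximum-entropy (Burg) power spectrum of a dipole series
#'
#' Fits an autoregressive model of the stated order to each Cartesian
#' component by Burg recursion and evaluates the model power spectral
#' density on a wavenumber grid; the three components are summed.  The
#' intensity is normalized so that integrating the (unshifted) spectrum
#' over wavenumber recovers the series variance.  Stationarity of the
#' series is assumed, not checked.
#'
#' @param series A [dipole_series()], or a numeric vector/matrix with `dt`.
#' @param order AR order; default `min(500, n_frames/10)`.  Must be below
#'   `n_frames / 2`.
#' @param grid Wavenumber grid (cm^-1), strictly increasing; the default
#'   covers the carboxylate stretch region at 2 cm^-1 resolution.
#' @param dt Frame spacing (fs) for plain input.
#' @param prefactor Optional function of wavenumber multiplying the
#'   intensity pointwise (hook for a quantum correction; none is applied by
#'   default).
#' @return A `spectrum` object.
#' @export
mem_spectrum <- function(series, order = NULL, grid = seq(800, 2000, by = 2),
                         dt = NULL, prefactor = NULL) {
  if (inherits(series, "dipole_series")) {
    V <- series$values
    dt <- series$dt
  } else {
    V <- as.matrix(series)
    if (is.null(dt)) stop("dt required for plain input")
  }
  n <- nrow(V)
  if (is.null(order)) order <- max(2L, min(500L, floor(n / 10)))
  order <- as.integer(order)
  if (order >= n / 2) {
    stop("order (", order, ") must be below n_frames/2 (", n / 2, ")")
  }
  f <- grid * .c_cm_per_fs            # cycles per fs
  E <- exp(-2i * pi * outer(seq_len(order), f * dt))
  intensity <- numeric(length(grid))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (stats::var(v) < 1e-30) next
    fit <- tryCatch(
      stats::ar.burg(v, aic = FALSE, order.max = order, demean = TRUE),
      error = function(e) {
        stop("maximum entropy recursion numerically singular at order ",
             order, ": ", conditionMessage(e))
      })
    a <- fit$ar
    sig2 <- max(fit$var.pred, 1e-300)
    denom <- Mod(1 - colSums(a * E))^2
    intensity <- intensity + 2 * .c_cm_per_fs * dt * sig2 / denom
  }
  if (!is.null(prefactor)) intensity <- intensity * prefactor(grid)
  new_spectrum(grid, intensity, shift_applied = 0,
               meta = list(order = order, dt = dt))
}

#' Average spectra over molecules
#'
#' @param spectra List of `spectrum` objects on identical grids.
#' @return A `spectrum`: the pointwise mean.  `shift_applied` is propagated
#'   only when identical across inputs.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) == 0L) stop("no spectra to average")
  g <- spectra[[1]]$frequency
  for (sp in spectra[-1]) {
    if (length(sp$frequency) != length(g) ||
        max(abs(sp$frequency - g)) > 1e-9) {
      stop("spectra are on mismatched frequency grids")
    }
  }
  shifts <- vapply(spectra, `[[`, numeric(1), "shift_applied")
  shift <- if (length(unique(shifts)) == 1L) shifts[1] else {
    warning("mixed shift_applied values; recording NA")
    NA_real_
  }
  inten <- rowMeans(vapply(spectra, `[[`, numeric(length(g)), "intensity"))
  new_spectrum(g, inten, shift_applied = shift,
               meta = spectra[[1]]$meta)
}

#' Shift a spectrum along the wavenumber axis
#'
#' The conventional constant shift applied to computed carboxylate bands
#' when matching experiment (a force-field/classical-TCF offset); band-gap
#' type differences are invariant under it.
#'
#' @param spec A `spectrum`.
#' @param shift Shift in cm^-1 (e.g. -200).
#' @return The shifted `spectrum`, with `shift_applied` updated.
#' @export
apply_shift <- function(spec, shift) {
  new_spectrum(spec$frequency + shift, spec$intensity,
               shift_applied = spec$shift_applied + shift, meta = spec$meta)
}

#' Locate the S/AS carboxylate bands and their gap
#'
#' The symmetric and antisymmetric stretch maxima are the grid argmax within
#' their windows (no sub-grid interpolation); the band gap is their
#' difference.  A window whose maximum sits on its edge has no interior
#' peak and is an error.
#'
#' @param spec A `spectrum`.
#' @param s_window,as_window Wavenumber intervals `c(lo, hi)`; the defaults
#'   bracket the symmetric (~1400 cm^-1) and antisymmetric (~1600 cm^-1)
#'   stretch regions of the computed, unshifted spectra.
#' @return An object of class `band_gap`: `nu_S`, `nu_AS`, `gap` (cm^-1).
#' @export
find_band_gap <- function(spec, s_window = c(1300, 1500),
                          as_window = c(1500, 1750)) {
  if (s_window[1] >= s_window[2] || as_window[1] >= as_window[2]) {
    stop("windows must be increasing intervals")
  }
  if (s_window[2] > as_window[1]) stop("windows must be disjoint")
  peak_in <- function(win, label) {
    ii <- which(spec$frequency >= win[1] & spec$frequency <= win[2])
    if (length(ii) < 3L) stop("window [", win[1], ", ", win[2],
                              "] contains too few grid points")
    k <- ii[which.max(spec$intensity[ii])]
    if (k == ii[1] || k == ii[length(ii)]) {
      stop("no interior peak in the ", label, " window [",
           win[1], ", ", win[2], "] cm^-1")
    }
    spec$frequency[k]
  }
  nu_s <- peak_in(s_window, "symmetric-stretch")
  nu_as <- peak_in(as_window, "antisymmetric-stretch")
  bg <- list(nu_S = nu_s, nu_AS = nu_as, gap = nu_as - nu_s)
  class(bg) <- "band_gap"
  bg
}

#' @export
print.band_gap <- function(x, ...) {
  cat("<band_gap> nu_S = ", x$nu_S, ", nu_AS = ", x$nu_AS,
      ", gap = ", x$gap, " cm^-1\n", sep = "")
  invisible(x)
}

#' Velocity power spectrum of selected atoms
#'
#' Sums the per-component maximum-entropy spectra of the atomic velocity
#' series; used to assign bands (e.g. confirming which atoms carry the
#' carboxylate stretch intensity).  If the trajectory stores no velocities
#' they can be derived by central finite differences of the coordinates
#' (`use_finite_diff = TRUE`); otherwise missing velocities are an error.
#'
#' @param traj A [trajectory()].
#' @param atom_indices Atoms to include (non-empty).
#' @param order,grid As in [mem_spectrum()].
#' @param use_finite_diff Derive velocities from coordinates when absent.
#' @return A `spectrum`.
#' @export
velocity_power_spectrum <- function(traj, atom_indices, order = NULL,
                                    grid = seq(800, 2000, by = 2),
                                    use_finite_diff = FALSE) {
  if (length(atom_indices) == 0L) stop("empty atom selection")
  nf <- n_frames(traj)
  if (nf < 5L) stop("too few frames for a velocity spectrum")
  if (!is.null(traj$velocities)) {
    vel <- traj$velocities[atom_indices, , , drop = FALSE]
  } else if (use_finite_diff) {
    x <- traj$coords[atom_indices, , , drop = FALSE]
    vel <- array(0, dim = dim(x))
    vel[, , 2:(nf - 1)] <- (x[, , 3:nf, drop = FALSE] -
                              x[, , 1:(nf - 2), drop = FALSE]) / (2 * traj$dt)
    vel[, , 1] <- (x[, , 2] - x[, , 1]) / traj$dt
    vel[, , nf] <- (x[, , nf] - x[, , nf - 1]) / traj$dt
  } else {
    stop("trajectory has no velocities; set use_finite_diff = TRUE to ",
         "derive them from coordinates")
  }
  total <- numeric(length(grid))
  for (i in seq_along(atom_indices)) {
    V <- t(matrix(vel[i, , ], nrow = 3))
    sp <- mem_spectrum(V, order = order, grid = grid, dt = traj$dt)
    total <- total + sp$intensity
    ord <- sp$meta$order
  }
  new_spectrum(grid, total, shift_applied = 0,
               meta = list(order = ord, dt = traj$dt))
}

#' Write a spectrum or correlation function as two-column text
#'
#' @param x A `spectrum` or `correlation_function`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "spectrum")) {
    writeLines(c(
      "# ldhtraj spectrum",
      sprintf("# dt_fs %s order %s shift_applied_cm1 %s",
              format(x$meta$dt %||% NA), format(x$meta$order %||% NA),
              format(x$shift_applied)),
      "# wavenumber_cm1 intensity"), con)
    writeLines(sprintf("%.6f %.10e", x$frequency, x$intensity), con)
  } else if (inherits(x, "correlation_function")) {
    writeLines(c(
      "# ldhtraj correlation_function",
      sprintf("# dt_fs %s normalization %s", format(x$dt), x$normalization),
      "# lag_fs value"), con)
    writeLines(sprintf("%.6f %.10e", x$lags, x$values), con)
  } else {
    stop("unsupported object")
  }
  invisible(path)
}
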