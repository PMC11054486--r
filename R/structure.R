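## Geometric descriptors of the interlayer organisation: anion orientation
## relative to the layer normal, backbone conformers, number densities along
## the stacking axis, and interlayer-restricted radial distribution
## functions.

#' Orientation angle of one anion in one frame
#'
#' theta is the angle between the vector joining the two carboxylate carbons
#' and the surface normal (z), folded to `[0, 90]` degrees via `|v_z|` so the
#' label of the "first" carboxylate is immaterial: theta = 90 means the
#' anion lies parallel to the layers.
#'
#' @param frame A [get_frame()] result (or any matrix-bearing list with
#'   `coordinates`).
#' @param record An [anion_record()].
#' @return theta in degrees.
#' @export
orientation_angle <- function(frame, record) {
  cc <- record$carboxylate_carbons
  v <- frame$coordinates[cc[1], ] - frame$coordinates[cc[2], ]
  nv <- vnorm(v)
  if (nv < 1e-8) stop("degenerate geometry: coincident carboxylate carbons")
  rad2deg(acos(pmin(abs(v[3]) / nv, 1)))
}

#' Classify an orientation angle
#'
#' Parallel means theta strictly larger than the threshold (80 degrees by
#' convention); anything else, including exactly the threshold, is the
#' intermediate/perpendicular state.
#'
#' @param theta Angle(s) in degrees, in `[0, 90]`.
#' @param threshold Classification threshold in degrees.
#' @return Character vector: `"parallel"` or `"intermediate_perpendicular"`.
#' @export
classify_orientation <- function(theta, threshold = 80.0) {
  if (any(theta < 0 | theta > 90)) stop("theta must lie in [0, 90] degrees")
  ifelse(theta > threshold, "parallel", "intermediate_perpendicular")
}

#' Orientational-state populations over a trajectory
#'
#' Pools every (frame, anion) sample: the parallel population is the percent
#' of samples with theta above the threshold.
#'
#' @param traj A [trajectory()] whose topology carries anion records.
#' @param threshold Degrees; see [classify_orientation()].
#' @return An object of class `orientation_result`: `per_sample_theta`
#'   (matrix `n_frames x n_anions`), `parallel_fraction` (percent),
#'   `threshold`.
#' @export
orientation_populations <- function(traj, threshold = 80.0) {
  recs <- traj$topology$anion_records
  if (length(recs) == 0L) stop("topology has no anion records")
  nf <- n_frames(traj)
  theta <- matrix(NA_real_, nf, length(recs))
  for (a in seq_along(recs)) {
    cc <- recs[[a]]$carboxylate_carbons
    v <- traj$coords[cc[1], , ] - traj$coords[cc[2], , ]
    dim(v) <- c(3L, nf)
    nv <- sqrt(colSums(v^2))
    if (any(nv < 1e-8)) stop("degenerate geometry in anion ", a)
    theta[, a] <- rad2deg(acos(pmin(abs(v[3, ]) / nv, 1)))
  }
  res <- list(
    per_sample_theta = theta,
    parallel_fraction = 100 * mean(theta > threshold),
    threshold = threshold
  )
  class(res) <- "orientation_result"
  res
}

#' @export
print.orientation_result <- function(x, ...) {
  cat("<orientation_result> parallel ",
      signif(x$parallel_fraction, 4), "% of ",
      length(x$per_sample_theta), " samples (theta > ", x$threshold,
      " deg)\n", sep = "")
  invisible(x)
}

#' Signed torsion angle of four atoms
#'
#' Standard IUPAC convention: anti is near 180 degrees, the two gauche wells
#' near +60 and -60.  Invariant under rigid motion; reversing the quadruple
#' gives the same value.
#'
#' @param frame A frame (see [orientation_angle()]).
#' @param quadruple Four distinct atom indices, in bonded order.
#' @return Angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(frame, quadruple) {
  if (length(unique(quadruple)) != 4L) stop("need four distinct atoms")
  x <- frame$coordinates[quadruple, ]
  b1 <- x[2, ] - x[1, ]
  b2 <- x[3, ] - x[2, ]
  b3 <- x[4, ] - x[3, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) {
    stop("degenerate geometry: collinear atoms in torsion quadruple")
  }
  y <- sum(vcross(n1, n2) * (b2 / vnorm(b2)))
  ang <- rad2deg(atan2(y, sum(n1 * n2)))
  if (ang <= -180) ang + 360 else ang
}

## vectorised chi over all frames for one quadruple
dihedral_series <- function(traj, quadruple) {
  nf <- n_frames(traj)
  p <- lapply(1:4, function(k) {
    m <- traj$coords[quadruple[k], , ]
    dim(m) <- c(3L, nf)
    m
  })
  b1 <- p[[2]] - p[[1]]
  b2 <- p[[3]] - p[[2]]
  b3 <- p[[4]] - p[[3]]
  cross_cols <- function(a, b) {
    rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
          a[3, ] * b[1, ] - a[1, ] * b[3, ],
          a[1, ] * b[2, ] - a[2, ] * b[1, ])
  }
  n1 <- cross_cols(b1, b2)
  n2 <- cross_cols(b2, b3)
  b2n <- sqrt(colSums(b2^2))
  y <- colSums(cross_cols(n1, n2) * sweep(b2, 2, b2n, "/"))
  ang <- rad2deg(atan2(y, colSums(n1 * n2)))
  ifelse(ang <= -180, ang + 360, ang)
}

#' Conformer fractions over a trajectory
#'
#' Classifies the backbone torsion chi of every (frame, anion) sample:
#' anti for `|chi| > 120` (with -120 itself counted anti), gauche+ for
#' `0 < chi <= 120`, gauche- for `-120 < chi <= 0`.  The window boundaries
#' sit between the known wells at 180 and +/-60 degrees.
#'
#' @param traj A [trajectory()] with anion records.
#' @param bin_width Histogram bin width in degrees.
#' @return An object of class `conformer_result`: `chi` (matrix
#'   `n_frames x n_anions`), `chi_histogram` (data frame of bin centers and
#'   counts over `(-180, 180]`), `fractions` (percents summing to 100).
#' @export
conformer_fractions <- function(traj, bin_width = 5) {
  recs <- traj$topology$anion_records
  if (length(recs) == 0L) stop("topology has no anion records")
  nf <- n_frames(traj)
  chi <- matrix(NA_real_, nf, length(recs))
  for (a in seq_along(recs)) {
    chi[, a] <- dihedral_series(traj, recs[[a]]$dihedral)
  }
  v <- as.vector(chi)
  anti <- v > 120 | v <= -120
  gp <- v > 0 & v <= 120
  gm <- v > -120 & v <= 0
  fractions <- 100 * c(anti = mean(anti), gauche_plus = mean(gp),
                       gauche_minus = mean(gm))
  breaks <- seq(-180, 180, by = bin_width)
  counts <- as.vector(table(cut(v, breaks, include.lowest = FALSE)))
  res <- list(
    chi = chi,
    chi_histogram = data.frame(
      chi_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
      count = counts
    ),
    fractions = fractions
  )
  class(res) <- "conformer_result"
  res
}

#' @export
print.conformer_result <- function(x, ...) {
  f <- signif(x$fractions, 4)
  cat("<conformer_result> anti ", f["anti"], "%, gauche+ ",
      f["gauche_plus"], "%, gauche- ", f["gauche_minus"], "%\n", sep = "")
  invisible(x)
}

#' Number density along the surface normal
#'
#' Atoms of the requested role are assigned to their enclosing interlayer
#' region, their z re-expressed relative to that region's midplane, and the
#' histogram accumulated over frames and regions (slab analyses average over
#' all interlamellar regions).  Density is in counts per angstrom per frame,
#' so the integral times the frame count recovers the number of selected
#' atom observations inside the regions.
#'
#' @param traj A [trajectory()].
#' @param role Atom role, see [atom_roles()].
#' @param geometry A [slab_geometry()]; defaults to
#'   [detect_slab_geometry()] of `traj`.
#' @param bin_width Bin width (angstrom).
#' @param mirror Symmetrize the profile across the midplane (the two
#'   surfaces of an interlayer are equivalent).
#' @return An object of class `density_profile`: `z_centers` (angstrom,
#'   relative to the midplane), `density`, `role`, `n_frames`.
#' @export
number_density_z <- function(traj, role, geometry = NULL, bin_width = 0.1,
                             mirror = TRUE) {
  idx <- which(traj$topology$roles == role)
  if (length(idx) == 0L) stop("empty selection: no atoms with role ", role)
  if (is.null(geometry)) geometry <- detect_slab_geometry(traj)
  nf <- n_frames(traj)
  z <- traj$coords[idx, 3, , drop = FALSE]
  dim(z) <- NULL
  mids <- interlayer_midplanes(geometry)
  half <- geometry$spacing_d / 2
  rel <- rep(NA_real_, length(z))
  for (r in seq_len(nrow(geometry$interlayer_bounds))) {
    lo <- geometry$interlayer_bounds[r, 1]
    hi <- geometry$interlayer_bounds[r, 2]
    inside <- z >= lo & z < hi
    rel[inside] <- z[inside] - mids[r]
  }
  rel <- rel[!is.na(rel)]
  breaks <- seq(-half - bin_width, half + bin_width, by = bin_width)
  counts <- as.vector(table(cut(rel, breaks)))
  if (mirror) {
    counts <- (counts + rev(counts)) / 2
  }
  dp <- list(
    z_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
    density = counts / (bin_width * nf),
    role = role,
    n_frames = nf,
    bin_width = bin_width,
    mirror = mirror
  )
  class(dp) <- "density_profile"
  dp
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile> role ", x$role, ", ", length(x$z_centers),
      " bins of ", x$bin_width, " A\n", sep = "")
  invisible(x)
}

#' Radial distribution function restricted to short range
#'
#' Pair distances under the minimum-image convention, normalized by the
#' ideal-gas shell expectation at the full-box number density.  In these
#' anisotropic slab systems the RDF is meaningful only up to about one
#' interlamellar spacing (~5 angstrom), hence the default `r_max`; readings
#' beyond that are dominated by the slab geometry, not by structure.
#'
#' @param traj A [trajectory()].
#' @param roles Length-2 character vector of role tags (may be identical).
#' @param r_max Largest distance (angstrom); must not exceed half the
#'   smallest box edge.
#' @param bin_width Bin width (angstrom).
#' @return An object of class `rdf_result`: `r_centers`, `g`, `pair`,
#'   `r_max`.
#' @export
rdf <- function(traj, roles, r_max = 5.0, bin_width = 0.05) {
  stopifnot(length(roles) == 2L)
  box <- traj$box
  if (r_max > min(box) / 2) {
    stop("r_max (", r_max, ") exceeds half the smallest box edge (",
         min(box) / 2, ")")
  }
  ia <- which(traj$topology$roles == roles[1])
  ib <- which(traj$topology$roles == roles[2])
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("empty selection for role pair ", roles[1], "-", roles[2])
  }
  same <- identical(roles[1], roles[2])
  if (same && length(ia) < 2L) stop("no pairs: need at least 2 atoms")
  ## pair index lists (i < j for identical roles)
  if (same) {
    n <- length(ia)
    pi_ <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pj_ <- sequence((n - 1L):1L) + pi_
    pa <- ia[pi_]; pb <- ia[pj_]
  } else {
    pa <- rep(ia, times = length(ib))
    pb <- rep(ib, each = length(ia))
    keep <- pa != pb
    pa <- pa[keep]; pb <- pb[keep]
  }
  nf <- n_frames(traj)
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    dxyz <- xyz[pa, , drop = FALSE] - xyz[pb, , drop = FALSE]
    for (j in 1:3) {
      dxyz[, j] <- dxyz[, j] - box[j] * round(dxyz[, j] / box[j])
    }
    r <- sqrt(rowSums(dxyz^2))
    r <- r[r < r_max]
    counts <- counts + tabulate(pmin(floor(r / bin_width), nbin - 1L) + 1L,
                                nbins = nbin)
  }
  edges <- bin_width * (0:nbin)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
  V <- prod(box)
  n_pairs <- length(pa)
  ideal <- nf * n_pairs * shell / V
  res <- list(
    r_centers = (edges[-1] + edges[-(nbin + 1)]) / 2,
    g = counts / ideal,
    pair = roles,
    r_max = r_max,
    bin_width = bin_width,
    n_pairs = n_pairs
  )
  class(res) <- "rdf_result"
  res
}

#' @export
print.rdf_result <- function(x, ...) {
  cat("<rdf_result> ", x$pair[1], "-", x$pair[2], ", r <= ", x$r_max,
      " A, ", length(x$r_centers), " bins\n", sep = "")
  invisible(x)
}
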