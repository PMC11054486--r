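#' Slab geometry of a layered system
#'
#' @param layer_z_centers Mean z positions of the inorganic layers (angstrom),
#'   sorted increasing.
#' @param interlayer_bounds Matrix with one row per interlayer region and
#'   columns `lo`, `hi`: the z interval between adjacent layer centers.
#' @param spacing_d Mean interlamellar spacing (angstrom): the average
#'   difference between adjacent layer centers.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(layer_z_centers, interlayer_bounds, spacing_d) {
  if (is.unsorted(layer_z_centers)) stop("layer centers must be sorted in z")
  if (spacing_d <= 0) stop("spacing_d must be > 0")
  g <- list(
    layer_z_centers = as.numeric(layer_z_centers),
    interlayer_bounds = interlayer_bounds,
    spacing_d = as.numeric(spacing_d)
  )
  class(g) <- "slab_geometry"
  g
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat("<slab_geometry> ", length(x$layer_z_centers), " layers, d = ",
      signif(x$spacing_d, 6), " A\n", sep = "")
  invisible(x)
}

#' Detect the slab geometry from the magnesium sheets
#'
#' Locates the inorganic layers by clustering the time-averaged z coordinates
#' of the `layer_Mg` atoms (one-dimensional k-means; the cluster count is the
#' `n_layers` recorded in the topology, or else is inferred by cutting the
#' sorted z values at gaps wider than 3 angstrom).  The interlamellar spacing
#' is the mean difference between adjacent layer centers, and each interlayer
#' region spans the interval between two adjacent centers.  The Mg z
#' distribution is the conventional positional reference for these slabs.
#'
#' @param traj A [trajectory()].
#' @return A [slab_geometry()].
#' @export
detect_slab_geometry <- function(traj) {
  mg <- which(traj$topology$roles == "layer_Mg")
  if (length(mg) == 0L) stop("geometry error: no layer_Mg atoms in topology")
  z <- rowMeans(traj$coords[mg, 3, , drop = FALSE], dims = 1)
  dim(z) <- NULL
  k <- traj$topology$n_layers
  if (is.null(k)) {
    zs <- sort(z)
    k <- 1L + sum(diff(zs) > 3)
  }
  if (k < 2L) stop("geometry error: fewer than 2 layers detected")
  ## deterministic 1-D k-means: initialize at evenly spaced quantiles
  init <- stats::quantile(z, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  km <- stats::kmeans(z, centers = matrix(init, ncol = 1))
  centers <- sort(as.numeric(km$centers))
  if (min(diff(centers)) < 1e-6) {
    stop("geometry error: degenerate layer clusters")
  }
  bounds <- cbind(lo = centers[-length(centers)], hi = centers[-1])
  slab_geometry(centers, bounds, mean(diff(centers)))
}

#' Midplane z positions of the interlayer regions
#'
#' @param geometry A [slab_geometry()].
#' @return Numeric vector, one midplane per interlayer region.
#' @export
interlayer_midplanes <- function(geometry) {
  rowMeans(geometry$interlayer_bounds)
}
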