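make_rec <- function(cc = c(1L, 2L)) {
  anion_record(1L, 1:4, cc, 1:4)
}

test_that("orientation angle follows the folded arccos definition", {
  rec <- make_rec()
  fr <- function(v) as_frame(rbind(v, c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))
  expect_equal(orientation_angle(fr(c(0, 0, 3)), rec), 0)
  expect_equal(orientation_angle(fr(c(3, 0, 0)), rec), 90)
  expect_equal(orientation_angle(fr(c(1, 0, 1)), rec), 45)
  expect_equal(orientation_angle(fr(c(1, 0, -1)), rec), 45)  # |v_z| fold
  ## swapping the carbons changes nothing
  rec2 <- make_rec(c(2L, 1L))
  expect_equal(orientation_angle(fr(c(1, 0, 1)), rec2), 45)
  expect_error(orientation_angle(fr(c(0, 0, 0)), rec), "degenerate")
})

test_that("orientation classification is strict at the threshold", {
  expect_equal(classify_orientation(85), "parallel")
  expect_equal(classify_orientation(45), "intermediate_perpendicular")
  expect_equal(classify_orientation(80.0), "intermediate_perpendicular")
  expect_equal(classify_orientation(80.0001), "parallel")
  expect_error(classify_orientation(95), "\\[0, 90\\]")
})

test_that("dihedral angle matches conventions and an independent oracle", {
  ## planar trans and cis butane-like chains
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(dihedral_angle(as_frame(trans), 1:4)), 180)
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedral_angle(as_frame(cis), 1:4), 0)
  ## ideal gauche templates sit at +/-60
  tp <- anion_template("SUC", 60)
  expect_equal(dihedral_angle(as_frame(tp$coords), tp$dihedral), 60,
               tolerance = 1e-8)
  tm <- anion_template("GLU", -60)
  expect_equal(dihedral_angle(as_frame(tm$coords), tm$dihedral), -60,
               tolerance = 1e-8)
  ## reversal and rigid motion leave the value unchanged; bio3d agrees
  set.seed(33)
  for (k in 1:5) {
    x <- matrix(rnorm(12), 4, 3)
    chi <- dihedral_angle(as_frame(x), 1:4)
    expect_equal(dihedral_angle(as_frame(x[4:1, ]), 1:4), chi,
                 tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    moved <- x %*% t(R) + rep(1, 4) %o% rnorm(3)
    expect_equal(dihedral_angle(as_frame(moved), 1:4), chi,
                 tolerance = 1e-8)
    oracle <- bio3d::torsion.xyz(as.vector(t(x)), atm.inc = 4)
    expect_equal(chi, as.numeric(oracle), tolerance = 1e-6)
  }
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(as_frame(collinear), 1:4), "degenerate")
})

test_that("conformer windows use the stated boundary conventions", {
  cls <- function(chi) {
    if (chi > 120 || chi <= -120) "anti"
    else if (chi > 0) "gauche_plus" else "gauche_minus"
  }
  ## mirror of the implementation's rule, checked at the boundaries
  expect_equal(cls(120), "gauche_plus")
  expect_equal(cls(-120), "anti")
  expect_equal(cls(180), "anti")
  ## and the trajectory-level classifier agrees on forced conformers
  cfg <- synthetic_config("SUC", n_formula_units = 4, spacing_d = 11.98,
                          p_parallel = 0.3,
                          conformer_fractions = c(anti = 0,
                                                  gauche_plus = 1,
                                                  gauche_minus = 0),
                          n_frames = 20, seed = 4)
  cf <- conformer_fractions(generate_trajectory(cfg))
  expect_equal(unname(cf$fractions["gauche_plus"]), 100)
  expect_equal(sum(cf$fractions), 100, tolerance = 1e-9)
})

test_that("orientation and conformer populations recover generator settings", {
  ## binomial/multinomial oracle at a light sample size (the acceptance
  ## suite repeats this at 4000 samples)
  n <- 800
  cfg <- synthetic_config("SUC", n_formula_units = n, spacing_d = 11.98,
                          p_parallel = 0.3,
                          conformer_fractions = c(anti = 0.5,
                                                  gauche_plus = 0.25,
                                                  gauche_minus = 0.25),
                          n_frames = 1, seed = 19)
  tr <- generate_trajectory(cfg)
  or <- orientation_populations(tr)
  expect_lt(abs(or$parallel_fraction - 30), 3 * sqrt(0.3 * 0.7 / n) * 100)
  cf <- conformer_fractions(tr)
  expect_lt(abs(cf$fractions["anti"] - 50), 3 * sqrt(0.5 * 0.5 / n) * 100)
  expect_lt(abs(cf$fractions["gauche_plus"] - 25),
            3 * sqrt(0.25 * 0.75 / n) * 100)
})

test_that("descriptors are invariant under translation and z-rotation", {
  tr <- small_slab(n_frames = 6)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$coords[, , f] <- tr$coords[, , f] %*% t(R)
  }
  moved$coords <- moved$coords + 2.5
  expect_equal(orientation_populations(moved)$per_sample_theta,
               orientation_populations(tr)$per_sample_theta,
               tolerance = 1e-9)
  expect_equal(conformer_fractions(moved)$chi, conformer_fractions(tr)$chi,
               tolerance = 1e-8)
})

test_that("z-density profile localizes and conserves counts", {
  ## two Mg sheets with waters pinned at the midplane
  n_mg <- 8
  top <- topology(c(rep("Mg", n_mg), rep("O", 5)),
                  rep(0, n_mg + 5),
                  c(rep(1L, n_mg), 2:6),
                  c(rep("layer_Mg", n_mg), rep("water_O", 5)),
                  n_layers = 2)
  nf <- 4
  coords <- array(0, dim = c(n_mg + 5, 3, nf))
  coords[1:4, 3, ] <- 0
  coords[5:8, 3, ] <- 12
  coords[1:8, 1, ] <- rep(1:4 * 2, 2)
  coords[9:13, 3, ] <- 6       # exactly at the midplane
  coords[9:13, 1, ] <- 1:5
  tr <- trajectory(top, coords, c(10, 10, 24), dt = 1)
  g <- detect_slab_geometry(tr)
  expect_equal(g$spacing_d, 12)
  dp <- number_density_z(tr, "water_O", g, bin_width = 0.5)
  expect_equal(sum(dp$density) * dp$bin_width * nf, 5 * nf)
  expect_equal(dp$z_centers[which.max(dp$density)], -0.25,
               tolerance = 0.5)
  expect_true(all(dp$density[abs(dp$z_centers) > 1] == 0))
  expect_error(number_density_z(tr, "amino_N", g), "empty selection")
})

test_that("uniformly placed atoms give a flat profile within Poisson noise", {
  n_mg <- 8
  n_o <- 400
  top <- topology(c(rep("Mg", n_mg), rep("O", n_o)),
                  rep(0, n_mg + n_o),
                  c(rep(1L, n_mg), seq_len(n_o) + 1L),
                  c(rep("layer_Mg", n_mg), rep("water_O", n_o)),
                  n_layers = 2)
  nf <- 25
  set.seed(41)
  coords <- array(0, dim = c(n_mg + n_o, 3, nf))
  coords[1:4, 3, ] <- 0
  coords[5:8, 3, ] <- 10
  coords[1:8, 1, ] <- rep(1:4 * 2, 2)
  coords[(n_mg + 1):(n_mg + n_o), 3, ] <- runif(n_o * nf) * 10
  tr <- trajectory(top, coords, c(10, 10, 20), dt = 1)
  dp <- number_density_z(tr, "water_O", bin_width = 1, mirror = FALSE)
  inner <- abs(dp$z_centers) <= 4
  expected <- n_o / 10          # counts per A per frame
  sigma <- sqrt(expected / nf)  # Poisson, averaged over frames
  expect_true(all(abs(dp$density[inner] - expected) < 3.5 * sigma))
})

test_that("RDF matches a brute-force double loop bin for bin", {
  tr <- gas_trajectory(60, 3, c(11, 11, 11), seed = 6)
  r <- rdf(tr, c("water_O", "water_O"), r_max = 5, bin_width = 0.25)
  nbin <- length(r$r_centers)
  counts <- numeric(nbin)
  for (f in 1:3) {
    x <- tr$coords[, , f]
    for (i in 1:59) for (j in (i + 1):60) {
      d <- x[i, ] - x[j, ]
      d <- d - tr$box * round(d / tr$box)
      rr <- sqrt(sum(d^2))
      if (rr < 5) {
        b <- min(floor(rr / 0.25), nbin - 1) + 1
        counts[b] <- counts[b] + 1
      }
    }
  }
  edges <- 0.25 * (0:nbin)
  shell <- 4 / 3 * pi * diff(edges^3)
  g_brute <- counts / (3 * choose(60, 2) * shell / prod(tr$box))
  expect_equal(r$g, g_brute, tolerance = 1e-12)
})

test_that("two fixed atoms give a single RDF peak at their separation", {
  top <- topology(c("O", "H"), c(0, 0), c(1L, 2L), c("water_O", "water_H"))
  coords <- array(0, dim = c(2, 3, 2))
  coords[2, 1, ] <- 2.83
  tr <- trajectory(top, coords, c(12, 12, 12), dt = 1)
  r <- rdf(tr, c("water_O", "water_H"), r_max = 5, bin_width = 0.1)
  expect_equal(sum(r$g > 0), 1)
  expect_equal(r$r_centers[which.max(r$g)], 2.85)
  expect_error(rdf(tr, c("water_O", "water_O")), "at least 2")
  expect_error(rdf(tr, c("water_O", "water_H"), r_max = 7), "half the")
})
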