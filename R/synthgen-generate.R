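## Synthetic slab-trajectory generator.
##
## The generator emulates the statistical structure the analyses assume,
## not the physics: rigid brucite-like sheets at the prescribed spacing,
## rigid-geometry anions whose orientation (theta) and backbone torsion
## (chi) switch between prescribed states via Markov chains, AR(2)
## (noise-driven damped oscillator) displacements of the carboxylate
## oxygens at the two stretch frequencies, and waters placed either in a
## carboxylate hydration shell or at the interlayer midplane.

cation_spacing <- 3.1     # A, in-plane cation grid constant
oh_dz <- 1.10             # A, hydroxyl O above/below the cation plane
ohh_dz <- 2.05            # A, hydroxyl H above/below the cation plane
sheet_halfwidth <- 2.0    # A, effective half-thickness of one sheet
gap_clearance <- 0.3      # A, keep-out from the hydroxyl H plane

slab_layout <- function(config) {
  n_fu <- config$n_formula_units
  nl <- config$n_layers
  n_cat <- 6L * n_fu
  counts <- rep(n_cat %/% nl, nl)
  extra <- n_cat %% nl
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  ncols <- ceiling(sqrt(max(counts)))
  nrows <- ceiling(max(counts) / ncols)
  list(
    counts = counts,
    ncols = ncols,
    box = c(ncols * cation_spacing, nrows * cation_spacing,
            nl * config$spacing_d),
    z_centers = config$spacing_d * (seq_len(nl) - 0.5),
    ## usable half-gap for molecular centers inside one interlayer
    half_gap = (config$spacing_d - 2 * sheet_halfwidth) / 2 - gap_clearance
  )
}

site_xy <- function(m, ncols) {
  i <- seq_len(m) - 1L
  cbind((i %% ncols + 0.5) * cation_spacing,
        (i %/% ncols + 0.5) * cation_spacing)
}

waters_per_fu <- function(n_fu, X) {
  ## deterministic remainder distribution; total is round(n_fu * X)
  as.integer(diff(round((0:n_fu) * X)))
}

#' Build the topology of a synthetic LDH system
#'
#' Per formula unit `[Mg4Al2(OH)12]A^2-.XH2O`: 4 Mg and 2 Al cations with 12
#' hydroxyl O-H pairs in the sheets, one anion, and `X` waters (fractional X
#' is honoured globally: the total water count is
#' `round(n_formula_units * X)`, with the remainder spread deterministically
#' over formula units).  Atom order: sheets (site by site: cation, upper OH,
#' lower OH), then anions, then waters.
#'
#' @param config A [synthetic_config()].
#' @return A [topology()] with `n_layers` metadata and one
#'   [anion_record()] per formula unit.
#' @export
build_topology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- slab_layout(config)
  n_fu <- config$n_formula_units
  nl <- config$n_layers
  tmpl <- anion_template(config$anion_type, chi = 180)
  wat <- water_template()
  el <- character(0); q <- numeric(0); mid <- integer(0); role <- character(0)

  ## sheets: 5 atoms per cation site (cation, O up, H up, O down, H down)
  cat_idx_global <- 0L
  for (l in seq_len(nl)) {
    m <- lay$counts[l]
    is_al <- ((cat_idx_global + seq_len(m)) %% 3L) == 0L
    cat_idx_global <- cat_idx_global + m
    el <- c(el, as.vector(rbind(ifelse(is_al, "Al", "Mg"),
                                "O", "H", "O", "H")))
    q <- c(q, as.vector(rbind(ifelse(is_al, 1.55, 1.30),
                              -0.95, 0.425, -0.95, 0.425)))
    mid <- c(mid, rep(l, 5L * m))
    role <- c(role, as.vector(rbind(ifelse(is_al, "layer_Al", "layer_Mg"),
                                    "layer_OH_O", "layer_OH_H",
                                    "layer_OH_O", "layer_OH_H")))
  }
  n_layer_atoms <- length(el)

  ## anions
  n_at <- nrow(tmpl$coords)
  recs <- vector("list", n_fu)
  for (i in seq_len(n_fu)) {
    off <- length(el)
    el <- c(el, tmpl$elements)
    q <- c(q, tmpl$charges)
    mol <- nl + i
    mid <- c(mid, rep(mol, n_at))
    role <- c(role, tmpl$roles)
    recs[[i]] <- anion_record(
      molecule_id = mol,
      atoms = off + seq_len(n_at),
      carboxylate_carbons = off + tmpl$carboxylate_carbons,
      dihedral = off + tmpl$dihedral,
      amino_n = if (is.na(tmpl$amino_n)) NA_integer_ else off + tmpl$amino_n,
      carboxylate_groups = lapply(tmpl$carboxylate_groups, function(g) {
        list(C = off + g$C, O = off + g$O)
      })
    )
  }

  ## waters
  n_wat <- sum(waters_per_fu(n_fu, config$waters_per_anion_X))
  if (n_wat > 0L) {
    el <- c(el, rep(wat$elements, n_wat))
    q <- c(q, rep(wat$charges, n_wat))
    mid <- c(mid, rep(nl + n_fu + seq_len(n_wat), each = 3L))
    role <- c(role, rep(wat$roles, n_wat))
  }

  top <- topology(el, q, mid, role, anion_records = recs,
                  anion_type = config$anion_type, n_layers = nl)
  attr(top, "n_layer_atoms") <- n_layer_atoms
  top
}

## geometric segments of a Markov state chain with mean dwell `dwell`
markov_segment_lengths <- function(n_frames, dwell) {
  if (n_frames == 1L) return(1L)
  lens <- integer(0)
  tot <- 0L
  while (tot < n_frames) {
    l <- stats::rgeom(1L, 1 / dwell) + 1L
    lens <- c(lens, l)
    tot <- tot + l
  }
  lens[length(lens)] <- lens[length(lens)] - (tot - n_frames)
  lens[lens > 0L]
}

## AR(2) realisation of a noise-driven damped oscillator at nu (cm^-1),
## scaled to RMS amplitude `amp`
mode_series <- function(n, nu, dt, damping_time, amp) {
  if (n < 8L) return(stats::rnorm(n) * amp)
  phi0 <- 2 * pi * nu * .c_cm_per_fs * dt
  r <- exp(-dt / damping_time)
  x <- stats::filter(stats::rnorm(n), c(2 * r * cos(phi0), -r^2),
                     method = "recursive")
  x <- as.numeric(x)
  x / stats::sd(x) * amp
}

draw_chi <- function(state) {
  switch(state,
    anti = {
      chi <- stats::runif(1, 160, 200)
      if (chi > 180) chi - 360 else chi
    },
    gauche_plus = stats::runif(1, 45, 75),
    gauche_minus = stats::runif(1, -75, -45)
  )
}

random_rotation <- function() {
  ## uniform random rotation from a normalized quaternion
  qv <- stats::rnorm(4)
  qv <- qv / vnorm(qv)
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Generate a synthetic slab trajectory
#'
#' See the package vignette for the statistical model.  In brief: sheets are
#' rigid; each anion carries two Markov states (orientation: parallel with
#' probability `p_parallel`, theta drawn above 80 degrees, otherwise an
#' intermediate/perpendicular state with theta in the geometrically allowed
#' part of `[0, 70]` degrees; conformer per `conformer_fractions`) with mean
#' dwell `dwell_frames`; carboxylate oxygens oscillate along their C->O
#' bonds as AR(2) modes at `nu_S` (in-phase within a group) and `nu_AS`
#' (out-of-phase); waters hydrate a carboxylate oxygen on the surface side
#' or sit at the interlayer midplane; all non-layer atoms receive Gaussian
#' jitter (rigid-body for the backbone so that theta and chi keep their
#' drawn values exactly).  Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  top <- build_topology(config)
  lay <- slab_layout(config)
  nl <- config$n_layers
  n_fu <- config$n_formula_units
  nf <- config$n_frames
  d <- config$spacing_d
  h <- lay$half_gap
  if (h < 1.0) {
    stop("generation error: interlamellar gap (", signif(2 * h, 3),
         " A usable) too narrow for any intercalate; increase spacing_d")
  }
  n_inter <- nl - 1L
  anion_interlayer <- ((seq_len(n_fu) - 1L) %% n_inter) + 1L
  midplane_z <- d * seq_len(n_inter)

  coords <- array(NA_real_, dim = c(n_atoms(top), 3L, nf))

  ## sheets (static)
  a_i <- 1L
  for (l in seq_len(nl)) {
    m <- lay$counts[l]
    xy <- site_xy(m, lay$ncols)
    zc <- lay$z_centers[l]
    site_block <- function(dz) cbind(xy, zc + dz)
    block <- matrix(NA_real_, 5L * m, 3L)
    block[seq(1L, 5L * m, by = 5L), ] <- site_block(0)
    block[seq(2L, 5L * m, by = 5L), ] <- site_block(oh_dz)
    block[seq(3L, 5L * m, by = 5L), ] <- site_block(ohh_dz)
    block[seq(4L, 5L * m, by = 5L), ] <- site_block(-oh_dz)
    block[seq(5L, 5L * m, by = 5L), ] <- site_block(-ohh_dz)
    coords[a_i:(a_i + 5L * m - 1L), , ] <- block
    a_i <- a_i + 5L * m
  }

  ## named substreams from the master seed
  set.seed(config$seed)
  anion_seeds <- sample.int(.Machine$integer.max, n_fu)
  water_seed <- sample.int(.Machine$integer.max, 1L)

  conf_states <- names(config$conformer_fractions)
  conf_probs <- as.numeric(config$conformer_fractions)
  sigma <- config$thermal_sigma
  base1 <- vector("list", n_fu)   # first-segment base coords, for waters

  ramp_max <- 100L   # frames per cosine switching ramp (50 fs at 0.5 fs/frame)
  wrap180 <- function(x) ((x + 180) %% 360) - 180

  for (i in seq_len(n_fu)) {
    set.seed(anion_seeds[i])
    rec <- top$anion_records[[i]]
    idx <- rec$atoms
    mid <- midplane_z[anion_interlayer[i]]
    center_xy <- stats::runif(2) * lay$box[1:2]

    ## state chains -> combined segments
    olen <- markov_segment_lengths(nf, config$dwell_frames)
    ostates <- ifelse(stats::runif(length(olen)) < config$p_parallel,
                      "par", "other")
    clen <- markov_segment_lengths(nf, config$dwell_frames)
    cstates <- sample(conf_states, length(clen), replace = TRUE,
                      prob = conf_probs)
    o_f <- rep(ostates, olen)[seq_len(nf)]
    c_f <- rep(cstates, clen)[seq_len(nf)]
    seg <- rle(paste(o_f, c_f))
    seg_end <- cumsum(seg$lengths)
    seg_start <- c(1L, utils::head(seg_end, -1L) + 1L)

    draw_orientation <- function(ostate, tmpl_coords) {
      ## returns c(theta_deg, phi_rad, psi_rad, center_z); the spin psi is
      ## drawn first so the exact z-extent of the tilted anion is known
      psi <- stats::runif(1, 0, 2 * pi)
      xs <- cos(psi) * tmpl_coords[, 1] - sin(psi) * tmpl_coords[, 2]
      zs <- tmpl_coords[, 3]
      extent <- function(theta_deg) {
        th <- deg2rad(theta_deg)
        max(abs(cos(th) * zs - sin(th) * xs))
      }
      if (ostate == "par") {
        theta <- stats::runif(1, 80.0001, 90)
        cz <- sample(c(-1, 1), 1) * max(h - extent(theta) - 0.1, 0)
      } else {
        grid_th <- seq(0, 70, by = 0.5)
        ok <- vapply(grid_th, extent, numeric(1)) <= h
        if (!any(ok)) {
          stop("generation error: ", config$anion_type,
               " anion (z-extent ", signif(max(abs(zs)), 3),
               " A) is longer than the interlamellar gap (", signif(h, 3),
               " A half-width) allows in a tilted orientation; ",
               "increase spacing_d or set p_parallel = 1")
        }
        cand <- grid_th[ok]
        pick <- if (length(cand) == 1L) cand else sample(cand, 1)
        theta <- min(max(pick + stats::runif(1, -0.25, 0.25), 0), 70)
        cz <- 0
      }
      c(theta, stats::runif(1, 0, 2 * pi), psi, cz)
    }

    ## per-frame orientation/conformer parameters with smooth (cosine-ramp)
    ## transitions between Markov states: the dipole then evolves
    ## continuously, as in real dynamics, instead of jumping
    theta_f <- phi_f <- psi_f <- cz_f <- chi_f <- numeric(nf)
    st <- strsplit(seg$values[1], " ", fixed = TRUE)[[1]]
    chi_cur <- draw_chi(st[2])
    tmpl_cur <- anion_template(config$anion_type, chi = chi_cur)
    ori_cur <- draw_orientation(st[1], tmpl_cur$coords)
    frs1 <- seg_start[1]:seg_end[1]
    theta_f[frs1] <- ori_cur[1]; phi_f[frs1] <- ori_cur[2]
    psi_f[frs1] <- ori_cur[3]; cz_f[frs1] <- ori_cur[4]
    chi_f[frs1] <- chi_cur
    prev_state <- st
    if (length(seg$lengths) > 1L) {
      for (s in 2:length(seg$lengths)) {
        st <- strsplit(seg$values[s], " ", fixed = TRUE)[[1]]
        chi_new <- if (identical(st[2], prev_state[2])) chi_cur else
          draw_chi(st[2])
        ori_new <- if (identical(st[1], prev_state[1])) ori_cur else {
          tc <- if (chi_new == chi_cur) tmpl_cur$coords else
            anion_template(config$anion_type, chi = chi_new)$coords
          draw_orientation(st[1], tc)
        }
        frs <- seg_start[s]:seg_end[s]
        ns <- length(frs)
        Ts <- min(ramp_max, ns)
        w <- c(0.5 * (1 - cos(pi * seq_len(Ts) / Ts)), rep(1, ns - Ts))
        theta_f[frs] <- ori_cur[1] + w * (ori_new[1] - ori_cur[1])
        phi_f[frs] <- ori_cur[2] +
          w * wrap180(rad2deg(ori_new[2] - ori_cur[2])) * pi / 180
        psi_f[frs] <- ori_cur[3] +
          w * wrap180(rad2deg(ori_new[3] - ori_cur[3])) * pi / 180
        cz_f[frs] <- ori_cur[4] + w * (ori_new[4] - ori_cur[4])
        chi_f[frs] <- chi_cur + w * wrap180(chi_new - chi_cur)
        if (chi_new != chi_cur) {
          tmpl_cur <- anion_template(config$anion_type, chi = chi_new)
        }
        chi_cur <- chi_new
        ## carry the values actually reached at segment end
        ori_cur <- c(theta_f[seg_end[s]], phi_f[seg_end[s]],
                     psi_f[seg_end[s]], cz_f[seg_end[s]])
        prev_state <- st
      }
    }

    ## per-anion mode series, continuous across frames
    qs <- lapply(rec$carboxylate_groups, function(g) {
      list(S = mode_series(nf, config$nu_S, config$dt,
                           config$damping_time, config$mode_amplitude),
           AS = mode_series(nf, config$nu_AS, config$dt,
                            config$damping_time, config$mode_amplitude))
    })
    rigid_jitter <- matrix(stats::rnorm(3L * nf, sd = sigma), 3L, nf)

    ## local indices of atoms that get independent per-atom jitter
    loc_roles <- top$roles[idx]
    jit_loc <- which(!(loc_roles %in% c("carboxylate_C", "carboxylate_O")) &
                       top$elements[idx] != "C")

    ## constant-parameter runs (ramp frames are single-frame runs)
    pars <- cbind(theta_f, phi_f, psi_f, cz_f, chi_f)
    chg <- if (nf == 1L) TRUE else
      c(TRUE, rowSums(abs(diff(pars))) > 0)
    run_len <- rle(cumsum(chg))$lengths
    run_end <- cumsum(run_len)
    run_start <- c(1L, utils::head(run_end, -1L) + 1L)

    cl <- vapply(rec$carboxylate_groups, function(g) match(g$C, idx),
                 integer(1))
    ol <- lapply(rec$carboxylate_groups, function(g) match(g$O, idx))
    tmpl_chi <- chi_cur
    for (r in seq_along(run_len)) {
      frs <- run_start[r]:run_end[r]
      p <- pars[run_start[r], ]
      if (p[5] != tmpl_chi) {
        tmpl_cur <- anion_template(config$anion_type, chi = p[5])
        tmpl_chi <- p[5]
      }
      rot <- rot_z(p[2]) %*% rot_y(deg2rad(p[1])) %*% rot_z(p[3])
      base <- tmpl_cur$coords %*% t(rot)
      base <- sweep(base, 2, c(center_xy, mid + p[4]), "+")
      if (r == 1L) base1[[i]] <- base
      ns <- length(frs)
      arr <- array(base, dim = c(length(idx), 3L, ns))
      ## rigid-body thermal jitter (whole anion)
      arr <- arr + aperm(array(rigid_jitter[, frs, drop = FALSE],
                               dim = c(3L, ns, length(idx))), c(3L, 1L, 2L))
      ## independent jitter on H and N
      if (length(jit_loc)) {
        arr[jit_loc, , ] <- arr[jit_loc, , ] +
          stats::rnorm(length(jit_loc) * 3L * ns, sd = sigma)
      }
      ## carboxylate stretch modes along the local C->O bonds
      for (g_i in seq_along(rec$carboxylate_groups)) {
        qS <- qs[[g_i]]$S[frs]
        qAS <- qs[[g_i]]$AS[frs]
        for (k in 1:2) {
          o_k <- ol[[g_i]][k]
          u <- base[o_k, ] - base[cl[g_i], ]
          u <- u / vnorm(u)
          disp <- if (k == 1L) qS + qAS else qS - qAS
          arr[o_k, , ] <- arr[o_k, , ] + outer(u, disp)
        }
      }
      coords[idx, , frs] <- arr
    }
  }

  ## waters
  n_wat_fu <- waters_per_fu(n_fu, config$waters_per_anion_X)
  n_wat <- sum(n_wat_fu)
  if (n_wat > 0L) {
    set.seed(water_seed)
    wat <- water_template()
    w_fu <- rep(seq_len(n_fu), n_wat_fu)
    first_w_atom <- n_atoms(top) - 3L * n_wat + 1L
    anions_by_inter <- split(seq_len(n_fu), anion_interlayer)
    for (w in seq_len(n_wat)) {
      il <- anion_interlayer[w_fu[w]]
      mid <- midplane_z[il]
      if (stats::runif(1) < config$midplane_water_fraction) {
        pos <- c(stats::runif(2) * lay$box[1:2],
                 mid + stats::runif(1, -0.8, 0.8))
      } else {
        donor <- anions_by_inter[[as.character(il)]]
        ai <- if (length(donor) == 1L) donor else sample(donor, 1L)
        rec <- top$anion_records[[ai]]
        o_global <- unlist(lapply(rec$carboxylate_groups, `[[`, "O"))
        o_pick <- if (length(o_global) == 1L) o_global else sample(o_global, 1L)
        p <- base1[[ai]][match(o_pick, rec$atoms), ]
        s <- sign(p[3] - mid)
        if (s == 0) s <- sample(c(-1, 1), 1)
        zt <- abs(p[3] - mid) + stats::runif(1, 0.3, 1.5)
        zt <- min(max(zt, 1.8), max(h - 0.2, 1.0))
        zw <- mid + s * zt
        lat <- sqrt(max(2.85^2 - (zw - p[3])^2, 0.25))
        phi <- stats::runif(1, 0, 2 * pi)
        pos <- c(p[1] + lat * cos(phi), p[2] + lat * sin(phi), zw)
      }
      base <- wat$coords %*% t(random_rotation())
      base <- sweep(base, 2, pos, "+")
      rows <- first_w_atom + 3L * (w - 1L) + 0:2
      arr <- array(base, dim = c(3L, 3L, nf))
      coords[rows, , ] <- arr + stats::rnorm(9L * nf, sd = sigma)
    }
  }

  trajectory(top, coords, lay$box, dt = config$dt)
}
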