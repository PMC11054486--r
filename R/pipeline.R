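## Orchestration: one call from a configuration (preset, synthetic config,
## or trajectory files) to a report holding the band-gap, orientation and
## conformer tables plus profile/RDF data, with provenance.

#' Pipeline run configuration
#'
#' Exactly one input source: a preset name, a [synthetic_config()], or a
#' trajectory file plus topology file.
#'
#' @param preset Preset name (see [ldh_presets()]).
#' @param config A [synthetic_config()].
#' @param trajectory_file,topology_file Paths to an existing trajectory and
#'   its YAML topology.
#' @param analyses Character subset of `"spectra"`, `"orientation"`,
#'   `"conformers"`, `"density"`, `"rdf"`, `"velocity"`; at least one.
#' @param label System label used in report tables; defaults to the preset
#'   name or file name.
#' @param seed Seed for synthetic generation (overrides the config's).
#' @param n_frames Frames for synthetic generation (overrides the preset
#'   default).
#' @param shift Constant band shift applied to reported spectra (cm^-1).
#' @param order AR order for [mem_spectrum()] (NULL = default rule).
#' @param grid Wavenumber grid for spectra.
#' @param s_window,as_window Band windows on the unshifted grid, for
#'   [find_band_gap()].
#' @param threshold Orientation threshold (degrees).
#' @param density_roles Roles profiled along z.
#' @param rdf_pairs List of length-2 role vectors.
#' @param bin_width_z,bin_width_r Bin widths (angstrom).
#' @param r_max RDF range (angstrom).
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = NULL, config = NULL,
                       trajectory_file = NULL, topology_file = NULL,
                       analyses = c("spectra", "orientation", "conformers",
                                    "density", "rdf"),
                       label = NULL, seed = 1, n_frames = NULL,
                       shift = -200, order = NULL,
                       grid = seq(800, 2000, by = 2),
                       s_window = c(1300, 1500), as_window = c(1500, 1750),
                       threshold = 80.0,
                       density_roles = c("water_O", "amino_N"),
                       rdf_pairs = list(c("layer_OH_H", "carboxylate_O"),
                                        c("water_H", "carboxylate_O")),
                       bin_width_z = 0.1, bin_width_r = 0.05, r_max = 5.0) {
  known <- c("spectra", "orientation", "conformers", "density", "rdf",
             "velocity")
  analyses <- unique(analyses)
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (length(analyses) == 0L) stop("at least one analysis must be enabled")
  sources <- c(!is.null(preset), !is.null(config), !is.null(trajectory_file))
  if (sum(sources) != 1L) {
    stop("exactly one input source required: preset, config, or ",
         "trajectory_file (+ topology_file)")
  }
  if (!is.null(trajectory_file) && is.null(topology_file)) {
    stop("topology_file is required with trajectory_file")
  }
  if (!is.null(config)) stopifnot(inherits(config, "synthetic_config"))
  rc <- list(
    preset = preset, config = config,
    trajectory_file = trajectory_file, topology_file = topology_file,
    analyses = analyses,
    label = label %||% preset %||%
      (if (!is.null(trajectory_file)) basename(trajectory_file)
       else "synthetic"),
    seed = as.integer(seed), n_frames = n_frames,
    shift = shift, order = order, grid = grid,
    s_window = s_window, as_window = as_window,
    threshold = threshold, density_roles = density_roles,
    rdf_pairs = rdf_pairs, bin_width_z = bin_width_z,
    bin_width_r = bin_width_r, r_max = r_max
  )
  class(rc) <- "run_config"
  rc
}

resolve_trajectory <- function(rc) {
  if (!is.null(rc$trajectory_file)) {
    top <- read_topology(rc$topology_file)
    return(read_trajectory(rc$trajectory_file, top))
  }
  cfg <- rc$config %||% do.call(ldh_preset, c(
    list(name = rc$preset),
    if (!is.null(rc$n_frames)) list(n_frames = rc$n_frames)
  ))
  cfg$seed <- rc$seed
  generate_trajectory(cfg)
}

#' Run the full analysis pipeline
#'
#' Generates or reads the trajectory, runs every enabled analysis, and
#' collects the results in a report.  A failure in one analysis is recorded
#' in `report$errors` without aborting the others.  Deterministic given the
#' seed.
#'
#' @param rc A [run_config()].
#' @return An object of class `ldh_report`: tables `band_gap`,
#'   `orientation`, `conformers`; lists `density`, `rdf`; `spectrum`;
#'   `errors`; `provenance`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  traj <- resolve_trajectory(rc)
  rep_ <- list(label = rc$label, errors = list())
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rep_$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  anion_meta <- list(
    anion_type = traj$topology$anion_type,
    X = if (!is.null(rc$config)) rc$config$waters_per_anion_X
        else if (!is.null(rc$preset)) {
          ldh_preset_table()[ldh_preset_table()$name == rc$preset,
                             "waters_per_anion_X"]
        } else NULL
  )

  if ("spectra" %in% rc$analyses) {
    rep_$spectrum <- grab("spectra", {
      recs <- traj$topology$anion_records
      if (length(recs) == 0L) stop("no anions for dipole spectra")
      sps <- lapply(recs, function(r) {
        mem_spectrum(dipole_series(traj, r$molecule_id),
                     order = rc$order, grid = rc$grid)
      })
      avg <- average_spectra(sps)
      bg <- find_band_gap(avg, rc$s_window, rc$as_window)
      rep_$band_gap <- data.frame(
        system = rc$label,
        nu_S = bg$nu_S + rc$shift,
        nu_AS = bg$nu_AS + rc$shift,
        gap = bg$gap,
        shift_applied = rc$shift
      )
      apply_shift(avg, rc$shift)
    })
  }
  if ("velocity" %in% rc$analyses) {
    rep_$velocity_spectrum <- grab("velocity", {
      idx <- which(traj$topology$roles %in%
                     c("carboxylate_C", "carboxylate_O", "amino_N"))
      velocity_power_spectrum(traj, idx, order = rc$order, grid = rc$grid)
    })
  }
  if ("orientation" %in% rc$analyses) {
    rep_$orientation_result <- grab("orientation", {
      or <- orientation_populations(traj, rc$threshold)
      rep_$orientation <- data.frame(
        system = rc$label,
        parallel_pct = or$parallel_fraction,
        threshold_deg = or$threshold,
        n_samples = length(or$per_sample_theta)
      )
      or
    })
  }
  if ("conformers" %in% rc$analyses) {
    rep_$conformer_result <- grab("conformers", {
      cr <- conformer_fractions(traj)
      rep_$conformers <- data.frame(
        system = rc$label,
        anti_pct = unname(cr$fractions["anti"]),
        gauche_plus_pct = unname(cr$fractions["gauche_plus"]),
        gauche_minus_pct = unname(cr$fractions["gauche_minus"])
      )
      cr
    })
  }
  if ("density" %in% rc$analyses || "rdf" %in% rc$analyses) {
    geometry <- grab("geometry", detect_slab_geometry(traj))
  }
  if ("density" %in% rc$analyses) {
    rep_$density <- grab("density", {
      roles <- intersect(rc$density_roles, unique(traj$topology$roles))
      if (length(roles) == 0L) stop("no atoms with the requested roles")
      stats::setNames(lapply(roles, function(r) {
        number_density_z(traj, r, geometry, rc$bin_width_z)
      }), roles)
    })
  }
  if ("rdf" %in% rc$analyses) {
    rep_$rdf <- grab("rdf", {
      present <- unique(traj$topology$roles)
      pairs <- Filter(function(p) all(p %in% present), rc$rdf_pairs)
      if (length(pairs) == 0L) stop("no RDF pair has both roles present")
      ## keep the requested range inside the minimum-image sphere
      r_eff <- min(rc$r_max, min(traj$box) / 2 - rc$bin_width_r)
      r_eff <- floor(r_eff / rc$bin_width_r) * rc$bin_width_r
      stats::setNames(
        lapply(pairs, function(p) {
          rdf(traj, p, r_max = r_eff, bin_width = rc$bin_width_r)
        }),
        vapply(pairs, paste, character(1), collapse = "-"))
    })
  }

  rep_$provenance <- list(
    label = rc$label,
    seed = rc$seed,
    config_hash = rlang::hash(rc),
    anion_type = anion_meta$anion_type,
    waters_per_anion_X = anion_meta$X,
    package_version = as.character(utils::packageVersion("ldhtraj"))
  )
  class(rep_) <- "ldh_report"
  rep_
}

#' @export
print.ldh_report <- function(x, ...) {
  cat("<ldh_report> ", x$label, "\n", sep = "")
  if (!is.null(x$band_gap)) {
    cat("  band gap: ", x$band_gap$gap, " cm^-1 (nu_S ", x$band_gap$nu_S,
        ", nu_AS ", x$band_gap$nu_AS, ", shift ",
        x$band_gap$shift_applied, ")\n", sep = "")
  }
  if (!is.null(x$orientation)) {
    cat("  parallel orientation: ", signif(x$orientation$parallel_pct, 4),
        "%\n", sep = "")
  }
  if (!is.null(x$conformers)) {
    cat("  conformers: anti ", signif(x$conformers$anti_pct, 4),
        "%, g+ ", signif(x$conformers$gauche_plus_pct, 4),
        "%, g- ", signif(x$conformers$gauche_minus_pct, 4), "%\n", sep = "")
  }
  if (length(x$errors)) {
    cat("  failed analyses: ", paste(names(x$errors), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

fmt_table <- function(df) {
  ## deterministic text formatting for report files
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 10, format = "g") else
      as.character(col)
  })
  c(paste(names(df), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t")))
}

report_header <- function(report) {
  p <- report$provenance
  c("# ldhtraj report",
    sprintf("# label %s", p$label),
    sprintf("# seed %d", p$seed),
    sprintf("# config_hash %s", p$config_hash),
    sprintf("# package_version %s", p$package_version))
}

#' Write a report to a directory of delimited text files
#'
#' Every file carries a provenance header (label, seed, configuration hash,
#' package version), so any number in the output traces back to its run.
#' Output is byte-stable for a fixed seed and configuration.
#'
#' @param report An `ldh_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- report_header(report)
  put <- function(lines, name) {
    writeLines(c(hdr, lines), file.path(dir, name))
  }
  for (tab in c("band_gap", "orientation", "conformers")) {
    if (!is.null(report[[tab]])) {
      put(fmt_table(report[[tab]]), paste0(tab, ".tsv"))
    }
  }
  if (!is.null(report$spectrum)) {
    put(fmt_table(data.frame(wavenumber_cm1 = report$spectrum$frequency,
                             intensity = report$spectrum$intensity)),
        "spectrum.tsv")
  }
  if (!is.null(report$velocity_spectrum)) {
    put(fmt_table(data.frame(
      wavenumber_cm1 = report$velocity_spectrum$frequency,
      intensity = report$velocity_spectrum$intensity)),
      "velocity_spectrum.tsv")
  }
  for (r in names(report$density %||% list())) {
    dp <- report$density[[r]]
    put(fmt_table(data.frame(z_A = dp$z_centers, density = dp$density)),
        paste0("density_", r, ".tsv"))
  }
  for (p in names(report$rdf %||% list())) {
    rr <- report$rdf[[p]]
    put(fmt_table(data.frame(r_A = rr$r_centers, g = rr$g)),
        paste0("rdf_", p, ".tsv"))
  }
  if (length(report$errors)) {
    put(vapply(names(report$errors),
               function(nm) paste0(nm, "\t", report$errors[[nm]]),
               character(1)),
        "errors.tsv")
  }
  invisible(dir)
}

#' Compare systems across hydration states
#'
#' Collates band gap and parallel-orientation population against hydration
#' for a series of reports and flags, per anion, whether each quantity is
#' non-increasing with water content — the qualitative trend expected when
#' hydration relaxes the carboxylate environment.
#'
#' @param reports List of `ldh_report` objects (>= 2) from runs whose
#'   provenance carries `anion_type` and `waters_per_anion_X` (synthetic
#'   runs always do; file-based runs need labelled metadata).
#' @return A data frame sorted by anion and hydration with columns
#'   `anion_type`, `X`, `gap`, `parallel_pct` and per-anion logical flags
#'   `gap_non_increasing`.
#' @export
compare_systems <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports to compare")
  rows <- lapply(reports, function(r) {
    p <- r$provenance
    if (is.null(p$anion_type) || is.null(p$waters_per_anion_X)) {
      stop("report '", r$label, "' lacks anion_type/hydration metadata; ",
           "label file-based runs before comparing")
    }
    data.frame(
      system = r$label,
      anion_type = p$anion_type,
      X = p$waters_per_anion_X,
      gap = if (!is.null(r$band_gap)) r$band_gap$gap else NA_real_,
      parallel_pct = if (!is.null(r$orientation)) {
        r$orientation$parallel_pct
      } else NA_real_
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$anion_type, tab$X), ]
  rownames(tab) <- NULL
  flags <- vapply(split(tab, tab$anion_type), function(g) {
    gp <- g$gap[!is.na(g$gap)]
    length(gp) < 2L || all(diff(gp) <= 0)
  }, logical(1))
  tab$gap_non_increasing <- flags[tab$anion_type]
  tab
}
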