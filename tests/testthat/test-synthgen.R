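test_that("presets carry the tabulated hydration and spacing", {
  cases <- list(
    list("ASP_6.5_WAT", 6.5, 12.10),
    list("SUC_2_WAT", 2, 11.38),
    list("GLU_1_WAT", 1, 11.57),
    list("SUC_0_WAT", 0, 8.87),
    list("ASP_0_WAT", 0, 9.06)
  )
  for (cs in cases) {
    cfg <- ldh_preset(cs[[1]])
    expect_equal(cfg$waters_per_anion_X, cs[[2]], info = cs[[1]])
    expect_equal(cfg$spacing_d, cs[[3]], info = cs[[1]])
  }
  expect_error(ldh_preset("ASP_9_WAT"), "available: ")
  ## the high-hydration succinate state has no tabulated spacing
  expect_error(ldh_preset("SUC_8_WAT"), "undefined")
})

test_that("config validation catches inconsistent inputs", {
  expect_error(synthetic_config("XYZ"), "arg")
  expect_error(synthetic_config("ASP", nu_S = 1600, nu_AS = 1500), "nu_AS")
  expect_error(synthetic_config("ASP", p_parallel = 1.2), "p_parallel")
  expect_error(synthetic_config("ASP",
    conformer_fractions = c(anti = 0.6, gauche_plus = 0.3,
                            gauche_minus = 0.3)), "sum to 1")
  expect_error(synthetic_config("ASP", n_frames = 0), "positive")
})

test_that("stoichiometry is exact for every preset", {
  for (nm in ldh_presets()$name) {
    n_fu <- 3L
    cfg <- ldh_preset(nm, n_formula_units = n_fu, n_frames = 1)
    top <- build_topology(cfg)
    roles <- table(top$roles)
    expect_equal(unname(roles["layer_Mg"]), 4 * n_fu, info = nm)
    expect_equal(unname(roles["layer_Al"]), 2 * n_fu, info = nm)
    expect_equal(unname(roles["layer_OH_O"]), 12 * n_fu, info = nm)
    expect_equal(unname(roles["layer_OH_H"]), 12 * n_fu, info = nm)
    expect_length(top$anion_records, n_fu)
    n_wat <- round(n_fu * cfg$waters_per_anion_X)
    expect_equal(sum(top$roles == "water_O"), n_wat, info = nm)
    expect_equal(sum(top$roles == "water_H"), 2 * n_wat, info = nm)
  }
})

test_that("fractional hydration is rounded globally, not per formula unit", {
  cfg <- ldh_preset("ASP_6.5_WAT", n_formula_units = 2)
  top <- build_topology(cfg)
  expect_equal(sum(top$roles == "water_O"), 13)   # round(2 * 6.5)
  cfg0 <- ldh_preset("ASP_0_WAT", n_formula_units = 5)
  expect_equal(sum(build_topology(cfg0)$roles %in% c("water_O", "water_H")),
               0)
})

test_that("succinate systems have no amino nitrogen; amino acids do", {
  top_suc <- build_topology(ldh_preset("SUC_2_WAT", n_formula_units = 2))
  expect_true(all(is.na(vapply(top_suc$anion_records, `[[`, integer(1),
                               "amino_n"))))
  expect_equal(sum(top_suc$roles == "amino_N"), 0)
  top_asp <- build_topology(ldh_preset("ASP_1_WAT", n_formula_units = 2))
  expect_equal(sum(top_asp$roles == "amino_N"), 2)
})

test_that("anion charges sum to -2 and waters are neutral", {
  top <- build_topology(ldh_preset("GLU_6.5_WAT", n_formula_units = 2))
  for (rec in top$anion_records) {
    expect_equal(sum(top$charges[rec$atoms]), -2, tolerance = 1e-9)
  }
  wat_ids <- unique(top$molecule_ids[top$roles == "water_O"])
  for (w in wat_ids[1:3]) {
    expect_equal(sum(top$charges[top$molecule_ids == w]), 0,
                 tolerance = 1e-9)
  }
})

test_that("generation is bit-reproducible from the seed", {
  cfg <- ldh_preset("ASP_1_WAT", n_formula_units = 3, n_frames = 40,
                    seed = 77)
  t1 <- generate_trajectory(cfg)
  t2 <- generate_trajectory(cfg)
  expect_identical(t1$coords, t2$coords)
  cfg2 <- ldh_preset("ASP_1_WAT", n_formula_units = 3, n_frames = 40,
                     seed = 78)
  expect_false(identical(generate_trajectory(cfg2)$coords, t1$coords))
})

test_that("atom count and composition are constant across frames", {
  tr <- small_slab(n_frames = 5)
  expect_false(anyNA(tr$coords))
  expect_equal(dim(tr$coords), c(n_atoms(tr), 3L, 5L))
})

test_that("forced orientation and conformer states hold in every frame", {
  cfg <- synthetic_config("SUC", n_formula_units = 6, spacing_d = 11.98,
                          p_parallel = 1.0, n_frames = 300,
                          dwell_frames = 40, seed = 3)
  tr <- generate_trajectory(cfg)
  or <- orientation_populations(tr)
  expect_true(all(or$per_sample_theta > 80))
  expect_equal(or$parallel_fraction, 100)
  ## all-anti configuration: every per-frame chi inside the anti window
  cf <- conformer_fractions(tr)
  expect_true(all(abs(cf$chi) > 120))
  expect_equal(unname(cf$fractions["anti"]), 100)
})

test_that("an anion too long for the gallery is a generation error", {
  cfg <- synthetic_config("GLU", n_formula_units = 2, spacing_d = 7.4,
                          p_parallel = 0, n_frames = 2, seed = 1)
  expect_error(generate_trajectory(cfg), "interlamellar gap")
})

test_that("template torsion matches the requested chi exactly", {
  for (chi in c(180, 60, -60, 120.5)) {
    for (ty in c("ASP", "GLU", "SUC")) {
      tm <- anion_template(ty, chi)
      got <- dihedral_angle(as_frame(tm$coords), tm$dihedral)
      d <- ((got - chi + 180) %% 360) - 180
      expect_lt(abs(d), 1e-8)
    }
  }
})
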