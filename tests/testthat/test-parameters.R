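# parameters_and_units: unit conversion and configuration handling

test_that("concentration/copies conversion matches direct arithmetic", {
  geom <- cell_geometry(2.5e-12)
  expect_identical(concentration_to_copies(0, geom), 0)
  expect_equal(concentration_to_copies(1, geom), 1506)
  # 63 nM XIAP: 63e-9 * N_A * V = 94848.7 molecules
  expect_equal(concentration_to_copies(63, geom), 94849)
  expect_error(concentration_to_copies(-1, geom), "finite and >= 0")
  expect_error(cell_geometry(0), "positive")
})

test_that("conversion round-trips within half a molecule", {
  geom <- cell_geometry()
  for (c_nm in c(0, 0.001, 0.5, 1, 63, 120, 1000)) {
    back <- copies_to_concentration(concentration_to_copies(c_nm, geom), geom)
    expect_lt(abs(back - c_nm), 0.5 / nm_to_molecules_factor(geom) + 1e-12)
  }
})

test_that("ligand dose conversion is linear and validated", {
  expect_equal(dose_to_nm(0), 0)
  # 5 ng/mL of a 19.6 kDa monomer = 5e-6 g/L / 19600 g/mol * 1e9 nM
  expect_equal(dose_to_nm(5), 5e-6 / 19600 * 1e9)
  expect_equal(dose_to_nm(50), 10 * dose_to_nm(5))
  expect_error(dose_to_nm(-1), ">= 0")
})

test_that("default configuration is complete and self-consistent", {
  cfg <- default_cfg()
  expect_s3_class(cfg, "riposim_config")
  expect_equal(cfg$initial_nm$xiap, 63)
  expect_equal(cfg$rates$kcat_ub_min, 1.75)
  expect_equal(cfg$rates$k_basal_deg_min, 0.04)
  expect_gt(cfg$rates$kcat_ub_min, cfg$rates$k_basal_deg_min)
  expect_equal(cfg$receptors$tnfr1$count, 905)
  expect_equal(cfg$receptors$dr4$count, 769)
  expect_equal(cfg$receptors$dr5$count, 926)
  expect_equal(sum(cfg$clustering$probability), 1, tolerance = 1e-12)
  expect_true(length(cfg$metadata$placeholder_keys) > 0)
})

test_that("config validation rejects schema violations with distinct errors", {
  cfg <- default_model_config()
  bad <- cfg
  bad$initial_nm$xiap <- NULL
  expect_error(validate_model_config(bad), "xiap",
               class = "riposim_missing_key")
  bad <- cfg
  bad$rates$kcat_ub_min <- -1
  expect_error(validate_model_config(bad), class = "riposim_bad_value")
  bad <- cfg
  bad$rates$made_up_rate <- 1
  expect_error(validate_model_config(bad), "unknown",
               class = "riposim_unknown_key")
  bad <- cfg
  bad$rates$kcat_ub_min <- 0.01   # below the basal degradation rate
  expect_error(validate_model_config(bad), "kcat_ub",
               class = "riposim_bad_value")
})

test_that("config files round-trip through YAML and JSON identically", {
  cfg <- default_model_config()
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model_config(cfg, path)
    back1 <- load_model_config(path)
    back2 <- load_model_config(path)   # idempotent, side-effect free
    expect_equal(unclass(back1)[setdiff(names(back1), "metadata")],
                 unclass(cfg)[setdiff(names(cfg), "metadata")],
                 tolerance = 1e-12)
    expect_identical(back1, back2)
  }
  expect_error(load_model_config(tempfile(fileext = ".yaml")),
               "not found", class = "riposim_io")
})
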