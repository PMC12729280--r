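test_that("od_to_biomass applies the calibration product and validates input", {
  cal <- calibration_spec()
  expect_equal(suppressWarnings(od_to_biomass(0, 1, cal)), 0)
  expect_equal(od_to_biomass(0.5, 2, cal), 0.4)
  # inoculum level: OD 0.825 undiluted is out of the linear range -> warning,
  # not an error, and still converts
  expect_warning(x <- od_to_biomass(0.825, 1, cal), "linear range")
  expect_equal(x, 0.33)
  expect_silent(od_to_biomass(0.45, 3, cal))
  expect_error(od_to_biomass(-0.1, 1, cal), "non-negative")
  expect_error(od_to_biomass(0.5, 0.5, cal), ">= 1")
  expect_error(calibration_spec(k_cal = -1))
  expect_error(calibration_spec(od_range = c(0.6, 0.3)))
})

test_that("od_to_biomass is linear in od for fixed dilution", {
  cal <- calibration_spec()
  set.seed(11)
  for (i in 1:20) {
    od <- runif(1, 0, 1); a <- runif(1, 0, 5); n <- sample(1:10, 1)
    expect_equal(suppressWarnings(od_to_biomass(a * od, n, cal)),
                 a * suppressWarnings(od_to_biomass(od, n, cal)))
  }
})

test_that("volume correction is the identity when the ledger stays nominal", {
  s <- make_series(c(0, 24, 48), c(0.33, 0.5, 0.7))
  out <- apply_volume_correction(s, events = NULL, nominal_volume_L = 4,
                                 evaporation_rate_mL_per_h = 0)
  expect_equal(out$biomass_gL, out$biomass_meas_gL)
  # additions exactly cancelling evaporation also leave the series unchanged
  ev <- data.frame(time_h = c(24, 48), added_mL = c(24 * 2, 24 * 2))
  out2 <- apply_volume_correction(s, events = ev, nominal_volume_L = 4,
                                  evaporation_rate_mL_per_h = 2)
  expect_equal(out2$biomass_gL[c(1, 2, 3)], out2$biomass_meas_gL[c(1, 2, 3)])
})

test_that("volume correction rescales by V/V_nominal and conserves mass", {
  # V(100) = 4 - 0.002*100 = 3.8 L; X_meas = 2.0 -> X_corr = 1.9
  s <- make_series(c(0, 100), c(0.33, 2.0))
  out <- apply_volume_correction(s, events = NULL, nominal_volume_L = 4,
                                 evaporation_rate_mL_per_h = 2)
  expect_equal(out$volume_L[2], 3.8)
  expect_equal(out$biomass_gL[2], 1.9)
  # mass conservation: X_corr * V_nominal == X_meas * V(t) exactly
  set.seed(7)
  s2 <- make_series(seq(0, 400, by = 40), runif(11, 0.3, 3))
  ev <- data.frame(time_h = c(96, 200), added_mL = c(150, 90))
  out2 <- apply_volume_correction(s2, events = ev, nominal_volume_L = 4,
                                  evaporation_rate_mL_per_h = 1.5)
  expect_equal(out2$biomass_gL * 4, out2$biomass_meas_gL * out2$volume_L)
})

test_that("volume correction rejects an inconsistent ledger", {
  s <- make_series(c(0, 500), c(0.33, 1))
  expect_error(
    apply_volume_correction(s, events = NULL, nominal_volume_L = 0.5,
                            evaporation_rate_mL_per_h = 2),
    "inconsistent")
})

test_that("growth_series validates its invariants", {
  expect_error(growth_series(numeric(0)), "empty")
  expect_error(make_series(c(0, 10, 10), c(1, 2, 3)), "increasing")
  expect_error(make_series(c(0, 10), c(-1, 2)), "non-negative")
  expect_error(growth_series(c(0, 10)), "biomass_gL.*od750")
})

test_that("load_series parses, validates and reports malformed rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("reactor_id,time_h,od750,dilution_factor,temperature_C,added_mL",
             f)
  expect_error(load_series(f), "empty data")

  writeLines(c("reactor_id,time_h,od750,dilution_factor,temperature_C,added_mL",
               "PBR1,0,0.41,2,26.0,0",
               "PBR1,24,0.45,2,26.5,100"), f)
  s <- load_series(f)
  expect_s3_class(s, "growth_series")
  expect_equal(nrow(s), 2L)
  expect_equal(s$biomass_gL, c(0.41, 0.45) * 0.4 * 2)
  expect_equal(attr(s, "reactor_id"), "PBR1")

  writeLines(c("reactor_id,time_h,od750", "PBR1,0,0.4"), f)
  expect_error(load_series(f), "missing required column")

  writeLines(c("reactor_id,time_h,od750,dilution_factor",
               "PBR1,24,0.4,1", "PBR1,0,0.4,1"), f)
  expect_error(load_series(f), "non-monotone")

  writeLines(c("reactor_id,time_h,od750,dilution_factor",
               "PBR1,0,0.41,1", "PBR1,24,abc,1"), f)
  expect_error(load_series(f), "line")

  # out-of-range OD row loads with one warning
  writeLines(c("reactor_id,time_h,od750,dilution_factor",
               "PBR1,0,0.41,1", "PBR1,24,0.95,1"), f)
  expect_warning(s <- load_series(f), "linear range")
  expect_equal(nrow(s), 2L)
})

test_that("write -> load round-trips the documented schema exactly", {
  sc <- campaign_scenario()
  s <- generate_reactor_series(sc, sc$reactors[[5]], seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series(s, f)
  s2 <- load_series(f)
  for (col in c("time_h", "od750", "dilution_factor", "temperature_C",
                "added_mL"))
    expect_equal(s2[[col]], s[[col]], label = col)
  # load -> write -> load is bit-identical, at the file level and in memory
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_series(s2, f2)
  expect_identical(readLines(f2), readLines(f))
  s3 <- load_series(f2)
  expect_identical(as.data.frame(s3), as.data.frame(s2))
})
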