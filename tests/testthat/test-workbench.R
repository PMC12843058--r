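test_that("units CSV round-trips and rejects missing units", {
  df <- data.frame(diameter_nm = c(10.5, 20.25), count = c(3L, 7L))
  path <- tempfile(fileext = ".csv")
  write_table_units(df, path, c("nm", ""))
  back <- read_table_units(path)
  expect_equal(back$diameter_nm, df$diameter_nm, tolerance = 1e-12)
  expect_equal(attr(back, "units"), c("nm", ""))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_table_units(bad), "units")
})

test_that("PGM images round-trip bit-identically (8- and 16-bit)", {
  set.seed(51)
  img8 <- calibrated_image(matrix(sample(0:255, 30 * 20, TRUE), 30, 20), 0.2)
  p <- tempfile(fileext = ".pgm")
  write_pgm(img8, p)
  back <- read_pgm(p)
  expect_identical(back$pixels, img8$pixels)
  expect_equal(back$pixel_size_nm, 0.2)
  img16 <- calibrated_image(matrix(sample(0:65535, 64, TRUE), 8, 8), 1.5, 16)
  write_pgm(img16, p)
  back16 <- read_pgm(p)
  expect_identical(back16$pixels, img16$pixels)
  expect_equal(back16$bit_depth, 16L)
  writeLines("P5", p)
  expect_error(read_pgm(p), "P2")
})

test_that("relaxation and calorimetry dialect readers work", {
  conc <- c(0.5, 1, 2, 4)
  g <- gen_relaxation_series(1.8, 0.5, conc, noise_sd = 0, seed = 52)
  path <- tempfile(fileext = ".csv")
  df <- data.frame(concentration = conc, rate = g$series$rate,
                   channel = "T2", field_T = 0.55)
  write_table_units(df, path, c("mg/mL", "1/s", "", "T"))
  back <- read_relaxation_csv(path)
  expect_equal(fit_relaxivity(back)$relaxivity, 1.8, tolerance = 1e-9)

  th <- thermal_spec(4000, 1000, 25)
  hc <- gen_heating_curve(1.6, th, noise_sd_K = 0, seed = 53,
                          dt_s = 10)$curve
  attr(hc, "frequency_Hz") <- 58.3e3
  p2 <- tempfile(fileext = ".csv")
  write_heating_csv(hc, p2)
  back2 <- read_heating_csv(p2)
  expect_equal(back2$temperature, hc$temperature, tolerance = 1e-9)
  expect_equal(attr(back2, "frequency_Hz"), 58.3e3)
  expect_equal(compute_sar(initial_slope(back2), th)$sar_w_g, 1.6,
               tolerance = 1e-5)
})

test_that("run configs validate keys and reject empty sweeps", {
  expect_error(validate_run_config(list(particel = list())), "unknown config block")
  expect_error(validate_run_config(list(particle = list(core_diam = 10))),
               "unknown key")
  expect_error(validate_run_config(list(study = list(diameters_nm = numeric(0)))),
               "empty diameter sweep")
  cfg <- validate_run_config(list(seed = 9))
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$particle$core_diameter_nm, 16)
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 4, medium = list(temperature_K = 300)),
                       p, auto_unbox = TRUE)
  cfg2 <- read_run_config(p)
  expect_equal(cfg2$medium$temperature_K, 300)
  expect_equal(cfg2$medium$viscosity_Pa_s, 8.9e-4)
})

test_that("end-to-end demo is reproducible and finds the joint optimum", {
  cfg1 <- validate_run_config(list(seed = 5, outdir = tempfile("run1_")))
  cfg2 <- validate_run_config(list(seed = 5, outdir = tempfile("run2_")))
  r1 <- run_end_to_end(cfg1)
  r2 <- run_end_to_end(cfg2)
  # bit-identical artifacts from identical (config, seed)
  j1 <- readLines(file.path(r1$outdir, "feasibility_report.json"))
  j2 <- readLines(file.path(r2$outdir, "feasibility_report.json"))
  expect_identical(j1, j2)
  expect_identical(readLines(file.path(r1$outdir, "stem_synthetic.pgm")),
                   readLines(file.path(r2$outdir, "stem_synthetic.pgm")))
  # demo truth co-locates r2 and SAR maxima at 22 nm
  expect_match(r1$report$overlap$verdict, "joint optimum exists")
  expect_equal(attr(r1$sar, "argmax_diameter_nm"), 22)
  expect_true(file.exists(file.path(r1$outdir, "property_table.csv")))
})

test_that("the CLI drives the main subcommands", {
  out <- tempfile(fileext = ".csv")
  suppressWarnings(spionics_cli(c("model", "power-sweep", "--out", out)))
  sw <- read_table_units(out)
  expect_true(all(c("diameter_nm", "power_w_per_m3") %in% names(sw)))
  expect_gt(nrow(sw), 50)

  dir <- tempfile("synthcli_")
  spionics_cli(c("synth", "relaxation", "--seed", "3", "--out", dir))
  fitjson <- tempfile(fileext = ".json")
  spionics_cli(c("relax", "fit", "--in",
                 file.path(dir, "relaxation_series.csv"),
                 "--out", fitjson))
  expect_true(file.exists(fitjson))
  fit <- jsonlite::fromJSON(fitjson)
  expect_true(is.finite(fit$relaxivity))

  spionics_cli(c("synth", "heating", "--seed", "4", "--sar", "1.2",
                 "--out", dir))
  sarjson <- tempfile(fileext = ".json")
  spionics_cli(c("sar", "fit", "--in", file.path(dir, "heating_curve.csv"),
                 "--out", sarjson))
  expect_equal(jsonlite::fromJSON(sarjson)$sar_w_g, 1.2, tolerance = 0.05)

  expect_error(spionics_cli(c("model", "nope")), "unknown model subcommand")
  expect_error(spionics_cli(c("frobnicate")), "unknown command")
})
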