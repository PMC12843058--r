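# Run configuration and the end-to-end demo workflow. Configs are JSON with
# one block per module; unknown keys are rejected before any computation so
# a typo cannot silently fall back to a default.

config_schema <- list(
  seed = NULL, outdir = NULL, log_level = NULL,
  particle = c("core_diameter_nm", "hydrodynamic_ratio",
               "hydrodynamic_diameter_nm", "anisotropy_kJ_per_m3",
               "Msp_kA_per_m", "tau0_s", "core_density_kg_m3"),
  medium = c("viscosity_Pa_s", "temperature_K"),
  excitation = c("frequency_kHz", "induction_mT", "H0_A_m"),
  thermal = c("specific_heat_J_kgK", "density_kg_m3", "concentration_mg_mL"),
  relax = c("diffusion_m2_s", "field_low_T", "field_high_T"),
  tem = c("median_radius", "closing_radius", "expected_diameter_nm",
          "min_marker_distance_px", "exclude_border", "bin_width_nm"),
  synth = c("n_particles", "image_size_px", "pixel_size_nm", "median_nm",
            "gsd", "touching_fraction", "noise_sd", "concentrations_mg_mL",
            "rate_noise_sd", "tau_c_s", "duration_s", "dt_s",
            "temperature_noise_K"),
  study = c("diameters_nm", "plateau_fraction", "bonferroni"),
  sweep = c("diameters_nm_min", "diameters_nm_max", "diameters_nm_step",
            "frequencies_hz")
)

#' Validate a run configuration
#'
#' Checks block and key names against the schema and fills defaults. See the
#' package vignette for the full key list; all keys carry their unit in the
#' name.
#'
#' @param config named list (typically from [read_run_config()]).
#' @return The validated config with defaults filled, class `run_config`.
#' @export
validate_run_config <- function(config) {
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), names(config_schema))) {
    allowed <- config_schema[[blk]]
    if (is.null(allowed)) next
    extra <- setdiff(names(config[[blk]]), allowed)
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ", paste(extra, collapse = ", "))
  }
  defaults <- list(
    seed = 1, outdir = tempfile("spionics_run_"), log_level = "info",
    particle = list(core_diameter_nm = 16, hydrodynamic_ratio = 1.5,
                    anisotropy_kJ_per_m3 = 21, Msp_kA_per_m = 480,
                    tau0_s = 1e-9, core_density_kg_m3 = 5180),
    medium = list(viscosity_Pa_s = 8.9e-4, temperature_K = 310),
    excitation = list(frequency_kHz = 58.3, induction_mT = 20),
    thermal = list(specific_heat_J_kgK = 4000, density_kg_m3 = 1000,
                   concentration_mg_mL = 25),
    relax = list(diffusion_m2_s = 2.3e-9, field_low_T = 0.55, field_high_T = 7),
    tem = list(median_radius = 1, closing_radius = 2,
               expected_diameter_nm = 12, min_marker_distance_px = NULL,
               exclude_border = TRUE, bin_width_nm = 1),
    synth = list(n_particles = 40, image_size_px = 900, pixel_size_nm = 0.2,
                 median_nm = 12, gsd = 1.2, touching_fraction = 0,
                 noise_sd = 8, concentrations_mg_mL = c(0.5, 1, 2, 4, 8),
                 rate_noise_sd = 0.05, tau_c_s = 1000, duration_s = 3600,
                 dt_s = 2, temperature_noise_K = 0.05),
    study = list(diameters_nm = c(10, 15, 20, 22, 25, 30),
                 plateau_fraction = 0.05, bonferroni = FALSE),
    sweep = list(diameters_nm_min = 5, diameters_nm_max = 40,
                 diameters_nm_step = 0.5,
                 frequencies_hz = 10^seq(2, 6, length.out = 201))
  )
  for (blk in names(defaults)) {
    if (!is.list(defaults[[blk]])) {
      if (is.null(config[[blk]])) config[[blk]] <- defaults[[blk]]
    } else {
      if (is.null(config[[blk]])) config[[blk]] <- list()
      for (k in names(defaults[[blk]]))
        if (!k %in% names(config[[blk]]))
          config[[blk]][k] <- list(defaults[[blk]][[k]])
    }
  }
  if (!is.null(config$study$diameters_nm) &&
      length(config$study$diameters_nm) == 0)
    stop("empty diameter sweep in 'study' block")
  class(config) <- "run_config"
  config
}

#' Read a run configuration from JSON
#'
#' @param path JSON file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

# helpers materializing spec objects from a validated config
config_particle <- function(cfg, core_diameter_nm = NULL) {
  p <- cfg$particle
  d <- if (is.null(core_diameter_nm)) p$core_diameter_nm else core_diameter_nm
  particle_spec(d * 1e-9,
                hydrodynamic_diameter_m = if (is.null(p$hydrodynamic_diameter_nm))
                  NULL else p$hydrodynamic_diameter_nm * 1e-9,
                hydrodynamic_ratio = p$hydrodynamic_ratio,
                anisotropy_J_m3 = p$anisotropy_kJ_per_m3 * 1e3,
                Msp_A_m = p$Msp_kA_per_m * 1e3, tau0_s = p$tau0_s)
}
config_medium <- function(cfg)
  medium_spec(cfg$medium$viscosity_Pa_s, cfg$medium$temperature_K)
config_excitation <- function(cfg) {
  e <- cfg$excitation
  if (!is.null(e$H0_A_m)) field_excitation(e$frequency_kHz * 1e3, H0_A_m = e$H0_A_m)
  else field_excitation(e$frequency_kHz * 1e3, B0_T = e$induction_mT * 1e-3)
}
config_thermal <- function(cfg)
  thermal_spec(cfg$thermal$specific_heat_J_kgK, cfg$thermal$density_kg_m3,
               cfg$thermal$concentration_mg_mL)
config_tem <- function(cfg)
  do.call(tem_config, cfg$tem[!vapply(cfg$tem, is.null, logical(1))])

# unimodal truth curves for the demo world: r2 and SAR co-peaked at 22 nm,
# r1 peaked at 15 nm - the qualitative structure of a feasible theranostic
# formulation
demo_truth <- function(d_nm) {
  list(r1_low  = 1.2 * exp(-(d_nm - 15)^2 / (2 * 4^2)),
       r2_low  = 9.0 * exp(-(d_nm - 22)^2 / (2 * 5^2)),
       r1_high = 0.3 * exp(-(d_nm - 15)^2 / (2 * 4^2)),
       r2_high = 11.0 * exp(-(d_nm - 22)^2 / (2 * 5^2)),
       sar_w_g = 2.0 * exp(-(d_nm - 22)^2 / (2 * 5^2)))
}

#' Run the full end-to-end demo workflow
#'
#' Composes the whole study on synthetic data: generate a particle population
#' and a STEM-like image and run the morphometry pipeline; generate
#' concentration-rate series per nominal diameter and fit relaxivities at
#' low and high field; generate heating curves and estimate SAR; assemble the
#' per-diameter property table; and produce the correlation + optimum-overlap
#' feasibility report. All intermediates are written under `config$outdir`
#' and every random draw derives from `config$seed`, so a rerun is
#' bit-identical.
#'
#' @param config a `run_config` (see [validate_run_config()]); any missing
#'   block falls back to the documented defaults.
#' @return List: `distribution`, `relaxivities` (per diameter/field/channel),
#'   `sar` (a `sar_sweep`), `report` (a `feasibility_report`), `outdir`.
#' @export
run_end_to_end <- function(config = validate_run_config(list())) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sy <- config$synth
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))

  # 1. morphometry on a synthetic STEM image
  dist <- stage("tem", {
    pop <- gen_diameters(sy$n_particles, sy$median_nm, sy$gsd, seed = seed)
    img <- gen_stem_image(pop$diameters_nm, sy$image_size_px, sy$pixel_size_nm,
                          touching_fraction = sy$touching_fraction,
                          noise_sd = sy$noise_sd, seed = seed + 1)
    write_pgm(img$image, file.path(config$outdir, "stem_synthetic.pgm"))
    res <- run_tem_pipeline(img$image, config_tem(config))
    write_table_units(res$segmentation$particles,
                      file.path(config$outdir, "particles.csv"),
                      c("", "px", "px", "px", "nm", "px"))
    res$distribution
  })

  # 2. relaxivity fits per diameter at both fields
  d_nm <- config$study$diameters_nm
  truth <- demo_truth(d_nm)
  relax <- stage("relax", {
    rows <- list()
    k <- 0
    for (i in seq_along(d_nm)) {
      for (set in list(c("T1", "low"), c("T2", "low"),
                       c("T1", "high"), c("T2", "high"))) {
        k <- k + 1
        key <- paste0(tolower(set[1]), "_", set[2])
        r_true <- truth[[sub("t", "r", key)]][i]
        fld <- if (set[2] == "low") config$relax$field_low_T else config$relax$field_high_T
        g <- gen_relaxation_series(r_true, baseline = if (set[1] == "T1") 0.4 else 0.6,
                                   concentrations = sy$concentrations_mg_mL,
                                   noise_sd = sy$rate_noise_sd,
                                   seed = seed + 10 + k,
                                   channel = set[1], field_T = fld)
        fit <- fit_relaxivity(g$series)
        rows[[k]] <- data.frame(diameter_nm = d_nm[i], channel = set[1],
                                field = set[2], field_T = fld,
                                relaxivity = fit$relaxivity,
                                se = fit$relaxivity_se,
                                baseline = fit$baseline)
      }
    }
    out <- do.call(rbind, rows)
    write_table_units(out, file.path(config$outdir, "relaxivities.csv"),
                      c("nm", "", "", "T", "1/(s mg/mL)", "1/(s mg/mL)", "1/s"))
    out
  })

  # 3. SAR per diameter from synthetic heating curves
  thermal <- config_thermal(config)
  sar <- stage("sar", {
    curves <- lapply(seq_along(d_nm), function(i)
      list(gen_heating_curve(truth$sar_w_g[i], thermal, tau_c_s = sy$tau_c_s,
                             duration_s = sy$duration_s, dt_s = sy$dt_s,
                             noise_sd_K = sy$temperature_noise_K,
                             seed = seed + 100 + i)$curve))
    sw <- sar_vs_diameter(curves, d_nm, thermal)
    write_table_units(as.data.frame(sw), file.path(config$outdir, "sar.csv"),
                      c("nm", "W/g", "W/g", ""))
    sw
  })

  # 4. property table (rows = nominal diameters) + feasibility report
  report <- stage("study", {
    pick <- function(ch, f) relax$relaxivity[relax$channel == ch & relax$field == f]
    tab <- data.frame(diameter_nm = d_nm,
                      T1_low = pick("T1", "low"), T2_low = pick("T2", "low"),
                      T1_high = pick("T1", "high"), T2_high = pick("T2", "high"),
                      power = sar$sar_w_g)
    write_table_units(tab, file.path(config$outdir, "property_table.csv"),
                      c("nm", rep("1/(s mg/mL)", 4), "W/g"))
    rep <- feasibility_report(tab,
                              curves = list(diameters_nm = d_nm,
                                            r1 = pick("T1", "low"),
                                            r2 = pick("T2", "low"),
                                            power = sar$sar_w_g),
                              plateau_fraction = config$study$plateau_fraction,
                              bonferroni = config$study$bonferroni)
    write_report_json(rep, file.path(config$outdir, "feasibility_report.json"))
    rep
  })

  jsonlite::write_json(unclass(config)[c("seed", "study", "synth")],
                       file.path(config$outdir, "run_config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  list(distribution = dist, relaxivities = relax, sar = sar, report = report,
       outdir = config$outdir)
}
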