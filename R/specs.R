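#' Describe one magnetic nanoparticle type
#'
#' Geometry and magnetic constants of a single-domain nanoparticle. The
#' hydrodynamic diameter (core plus coating and solvation layer) may be given
#' directly or as a ratio to the core diameter; a ratio of 1.5 is typical for
#' polymer-coated iron oxide particles.
#'
#' No default is supplied for the core saturation magnetization `Msp`: it is a
#' material property the user must state. For magnetite, literature values
#' are around `4.8e5` A/m (bulk), often lower for small cores.
#'
#' @param core_diameter_m core (magnetic) diameter, m.
#' @param hydrodynamic_diameter_m hydrodynamic diameter, m. Give either this
#'   or `hydrodynamic_ratio`.
#' @param hydrodynamic_ratio ratio hydrodynamic/core diameter (>= 1).
#' @param anisotropy_J_m3 effective anisotropy constant K, J/m^3.
#' @param Msp_A_m saturation magnetization of the core material, A/m.
#' @param tau0_s attempt time of the Neel process, s (default 1e-9).
#' @return A `particle_spec` object.
#' @examples
#' particle_spec(16e-9, hydrodynamic_ratio = 1.5,
#'               anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
#' @export
particle_spec <- function(core_diameter_m,
                          hydrodynamic_diameter_m = NULL,
                          hydrodynamic_ratio = NULL,
                          anisotropy_J_m3,
                          Msp_A_m,
                          tau0_s = 1e-9) {
  if (!is.numeric(core_diameter_m) || core_diameter_m <= 0)
    stop("core_diameter_m must be > 0")
  if (is.null(hydrodynamic_diameter_m)) {
    if (is.null(hydrodynamic_ratio))
      stop("give hydrodynamic_diameter_m or hydrodynamic_ratio")
    if (hydrodynamic_ratio < 1) stop("hydrodynamic_ratio must be >= 1")
    hydrodynamic_diameter_m <- hydrodynamic_ratio * core_diameter_m
  }
  if (hydrodynamic_diameter_m < core_diameter_m)
    stop("hydrodynamic diameter must be >= core diameter")
  if (anisotropy_J_m3 <= 0) stop("anisotropy_J_m3 must be > 0")
  if (Msp_A_m <= 0) stop("Msp_A_m must be > 0")
  if (tau0_s <= 0) stop("tau0_s must be > 0")
  structure(list(dm = core_diameter_m, dh = hydrodynamic_diameter_m,
                 K = anisotropy_J_m3, Msp = Msp_A_m, tau0 = tau0_s),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("Particle: core %.3g nm, hydrodynamic %.3g nm, K = %.3g kJ/m^3, Msp = %.3g kA/m, tau0 = %.3g s\n",
              x$dm * 1e9, x$dh * 1e9, x$K / 1e3, x$Msp / 1e3, x$tau0))
  invisible(x)
}

#' Describe the carrier medium
#'
#' @param viscosity_Pa_s dynamic viscosity of the carrier liquid, Pa s
#'   (water at 310 K: 8.9e-4 is a low-viscosity reference in wide use at
#'   about 25 C; at body temperature ~6.9e-4).
#' @param temperature_K absolute temperature, K.
#' @return A `medium_spec` object.
#' @examples
#' medium_spec(8.9e-4, 310)
#' @export
medium_spec <- function(viscosity_Pa_s, temperature_K) {
  if (viscosity_Pa_s <= 0) stop("viscosity must be > 0")
  if (temperature_K <= 0) stop("temperature must be > 0")
  structure(list(eta = viscosity_Pa_s, T = temperature_K),
            class = "medium_spec")
}

#' Describe the AC field excitation
#'
#' The driving field is `H(t) = H0 cos(omega t)` with `omega = 2 pi f`. The
#' amplitude may be given either as a field strength H0 (A/m) or as an
#' induction B0 (T), converted via `H0 = B0 / mu0`.
#'
#' @param frequency_Hz drive frequency f, Hz (>= 0).
#' @param H0_A_m field amplitude, A/m; give either this or `B0_T`.
#' @param B0_T induction amplitude, T.
#' @param constants a [physical_constants()] object (for the mu0 conversion).
#' @return A `field_excitation` object with fields `H0`, `f`, `omega`.
#' @examples
#' field_excitation(58.3e3, B0_T = 20e-3)
#' @export
field_excitation <- function(frequency_Hz, H0_A_m = NULL, B0_T = NULL,
                             constants = physical_constants()) {
  if (frequency_Hz < 0) stop("frequency must be >= 0")
  if (is.null(H0_A_m)) {
    if (is.null(B0_T)) stop("give H0_A_m or B0_T")
    H0_A_m <- B0_T / constants$mu0
  }
  if (H0_A_m < 0) stop("field amplitude must be >= 0")
  structure(list(H0 = H0_A_m, f = frequency_Hz, omega = 2 * pi * frequency_Hz),
            class = "field_excitation")
}

#' Describe a nanoparticle suspension
#'
#' Combines a particle type, a carrier medium, and how many particles are
#' present. Concentration may be given as a number density `Nm` (particles per
#' m^3) or a mass concentration `cn` (kg of particle cores per m^3); the two
#' are interconverted through the core mass density.
#'
#' @param particle a [particle_spec()].
#' @param medium a [medium_spec()].
#' @param number_density_m3 particles per m^3.
#' @param mass_concentration_kg_m3 core mass per m^3 of suspension
#'   (1 mg/mL = 1 kg/m^3).
#' @param core_density_kg_m3 mass density of the core material, kg/m^3;
#'   required when converting between the two concentration measures
#'   (magnetite: 5180).
#' @return A `suspension_spec` object with both `Nm` and `cn` filled in when
#'   the density is known.
#' @examples
#' p <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
#'                    anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
#' suspension_spec(p, medium_spec(8.9e-4, 310),
#'                 mass_concentration_kg_m3 = 25, core_density_kg_m3 = 5180)
#' @export
suspension_spec <- function(particle, medium,
                            number_density_m3 = NULL,
                            mass_concentration_kg_m3 = NULL,
                            core_density_kg_m3 = NULL) {
  stopifnot(inherits(particle, "particle_spec"), inherits(medium, "medium_spec"))
  m_core <- if (is.null(core_density_kg_m3)) NULL
            else core_density_kg_m3 * sphere_volume(particle$dm)
  if (is.null(number_density_m3)) {
    if (is.null(mass_concentration_kg_m3))
      stop("give number_density_m3 or mass_concentration_kg_m3")
    if (is.null(m_core))
      stop("core_density_kg_m3 is required to convert a mass concentration")
    number_density_m3 <- mass_concentration_kg_m3 / m_core
  } else if (is.null(mass_concentration_kg_m3) && !is.null(m_core)) {
    mass_concentration_kg_m3 <- number_density_m3 * m_core
  }
  if (number_density_m3 < 0) stop("number density must be >= 0")
  structure(list(particle = particle, medium = medium,
                 Nm = number_density_m3, cn = mass_concentration_kg_m3,
                 core_density = core_density_kg_m3),
            class = "suspension_spec")
}

#' Thermophysical properties of a suspension for calorimetry
#'
#' @param specific_heat_J_kgK specific heat C of the suspension, J/(kg K).
#' @param density_kg_m3 mass density rho of the suspension, kg/m^3.
#' @param concentration_kg_m3 nanoparticle concentration cn, kg/m^3 of
#'   suspension (mg/mL reads directly as kg/m^3).
#' @return A `thermal_spec` object.
#' @examples
#' thermal_spec(4000, 1000, 25)  # dilute aqueous suspension at 25 mg/mL
#' @export
thermal_spec <- function(specific_heat_J_kgK, density_kg_m3,
                         concentration_kg_m3) {
  if (specific_heat_J_kgK <= 0 || density_kg_m3 <= 0 || concentration_kg_m3 <= 0)
    stop("all thermal properties must be > 0")
  structure(list(C = specific_heat_J_kgK, rho = density_kg_m3,
                 cn = concentration_kg_m3),
            class = "thermal_spec")
}
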