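#' Neel relaxation time
#'
#' Internal reorientation of the magnetic moment over the anisotropy barrier:
#' `tauN = tau0 * exp(K V / (kB T))` with `V = pi dm^3 / 6`. The exponent grows
#' with the particle volume; beyond `exponent_cap` the particle is effectively
#' blocked (no longer superparamagnetic) and the model does not apply, so an
#' error is raised rather than returning an astronomically large number.
#'
#' @param particle a [particle_spec()].
#' @param medium a [medium_spec()] (supplies the temperature).
#' @param constants a [physical_constants()] object.
#' @param exponent_cap largest allowed `K V / (kB T)` (default 700, the
#'   double-precision overflow limit of `exp`).
#' @return Neel time, s.
#' @examples
#' p <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
#'                    anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
#' neel_time(p, medium_spec(8.9e-4, 310))
#' @export
neel_time <- function(particle, medium, constants = physical_constants(),
                      exponent_cap = 700) {
  stopifnot(inherits(particle, "particle_spec"), inherits(medium, "medium_spec"))
  sigma <- particle$K * sphere_volume(particle$dm) / (constants$kB * medium$T)
  if (sigma > exponent_cap)
    stop(sprintf(paste0("Neel exponent K*V/(kB*T) = %.3g exceeds cap %g: ",
                        "particle is blocked, outside the superparamagnetic ",
                        "regime this model assumes"), sigma, exponent_cap))
  particle$tau0 * exp(sigma)
}

#' Brownian relaxation time
#'
#' Physical rotation of the whole particle in the carrier fluid:
#' `tauB = 3 Vh eta / (kB T)` with hydrodynamic volume `Vh = pi dh^3 / 6`.
#'
#' @inheritParams neel_time
#' @return Brownian time, s.
#' @export
brown_time <- function(particle, medium, constants = physical_constants()) {
  stopifnot(inherits(particle, "particle_spec"), inherits(medium, "medium_spec"))
  if (particle$dh <= 0 || medium$eta <= 0)
    stop("hydrodynamic diameter and viscosity must be > 0")
  3 * sphere_volume(particle$dh) * medium$eta / (constants$kB * medium$T)
}

#' Effective relaxation time
#'
#' Parallel combination of the Neel and Brownian channels,
#' `tau = tauN tauB / (tauN + tauB)`; the faster mechanism dominates.
#' Either argument may be `Inf` (channel switched off).
#'
#' @param tauN,tauB relaxation times, s.
#' @return Effective time, s; never exceeds `min(tauN, tauB)`.
#' @export
effective_time <- function(tauN, tauB) {
  if (!is.numeric(tauN) || !is.numeric(tauB) || tauN <= 0 || tauB <= 0)
    stop("relaxation times must be positive")
  if (is.infinite(tauN) && is.infinite(tauB))
    stop("at least one relaxation time must be finite")
  if (is.infinite(tauN)) return(tauB)
  if (is.infinite(tauB)) return(tauN)
  tauN * tauB / (tauN + tauB)
}

# Langevin function L(x) = coth(x) - 1/x, series below the switch point to
# avoid catastrophic cancellation.
langevin <- function(xi, switch_point = 1e-4) {
  out <- numeric(length(xi))
  small <- abs(xi) < switch_point
  out[small] <- xi[small] / 3 - xi[small]^3 / 45
  xb <- xi[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  out
}

# Langevin argument xi = mu0 * H * Msp * Vm / (kB T)
langevin_xi <- function(H, suspension, constants = physical_constants()) {
  p <- suspension$particle
  constants$mu0 * H * p$Msp * sphere_volume(p$dm) /
    (constants$kB * suspension$medium$T)
}

#' Equilibrium (Langevin) magnetization of a suspension
#'
#' `M(H) = Ms * (coth(xi) - 1/xi)` with `xi = mu0 H Msp Vm / (kB T)` and sample
#' saturation `Ms = Nm Msp Vm` (`Vm = pi dm^3/6`). Odd in H, saturating at
#' `|M| -> Ms`; evaluated by series below `|xi| < 1e-4` for stability.
#'
#' @param H field strength, A/m (any sign, vectorised).
#' @param suspension a [suspension_spec()].
#' @param constants a [physical_constants()] object.
#' @return Magnetization, A/m.
#' @export
langevin_magnetization <- function(H, suspension,
                                   constants = physical_constants()) {
  stopifnot(inherits(suspension, "suspension_spec"))
  p <- suspension$particle
  Ms <- suspension$Nm * p$Msp * sphere_volume(p$dm)
  Ms * langevin(langevin_xi(H, suspension, constants))
}

#' Equilibrium magnetic susceptibility
#'
#' Small-field slope of the Langevin magnetization law:
#' `chi0 = mu0 Nm (Msp Vm)^2 / (3 kB T)`. This is the per-sample form
#' consistent with the Langevin magnetization used here (the per-particle
#' textbook form `mu0 Ms^2 V/(3 kB T)` coincides after substituting the
#' sample-level quantities; see the methods vignette).
#'
#' @inheritParams langevin_magnetization
#' @return Dimensionless susceptibility chi0.
#' @export
equilibrium_susceptibility <- function(suspension,
                                       constants = physical_constants()) {
  stopifnot(inherits(suspension, "suspension_spec"))
  p <- suspension$particle
  mVm <- p$Msp * sphere_volume(p$dm)
  constants$mu0 * suspension$Nm * mVm^2 / (3 * constants$kB * suspension$medium$T)
}

#' Complex AC susceptibility spectrum (Debye model)
#'
#' For a suspension with effective relaxation time tau (parallel Neel +
#' Brownian), the linear-response susceptibility is
#' `chi'(w) = chi0 / (1 + (tau w)^2)` and
#' `chi''(w) = tau w chi0 / (1 + (tau w)^2)`.
#'
#' @param suspension a [suspension_spec()].
#' @param frequencies_Hz drive frequencies, Hz (nonnegative; sorted
#'   internally).
#' @param constants a [physical_constants()] object.
#' @return A `susceptibility_spectrum` object: data frame with columns
#'   `frequency_hz`, `chi_real`, `chi_imag` plus attributes `chi0` and `tau`.
#' @examples
#' p <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
#'                    anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
#' s <- suspension_spec(p, medium_spec(8.9e-4, 310), number_density_m3 = 1e20)
#' susceptibility_spectrum(s, 10^seq(2, 6, length.out = 9))
#' @export
susceptibility_spectrum <- function(suspension, frequencies_Hz,
                                    constants = physical_constants()) {
  stopifnot(inherits(suspension, "suspension_spec"))
  if (any(frequencies_Hz < 0)) stop("frequencies must be >= 0")
  f <- sort(frequencies_Hz)
  tau <- effective_time(neel_time(suspension$particle, suspension$medium, constants),
                        brown_time(suspension$particle, suspension$medium, constants))
  chi0 <- equilibrium_susceptibility(suspension, constants)
  tw <- tau * 2 * pi * f
  out <- data.frame(frequency_hz = f,
                    chi_real = chi0 / (1 + tw^2),
                    chi_imag = tw * chi0 / (1 + tw^2))
  attr(out, "chi0") <- chi0
  attr(out, "tau") <- tau
  class(out) <- c("susceptibility_spectrum", "data.frame")
  out
}

#' Volumetric heating power in the linear-response regime
#'
#' `P = f pi mu0 H0^2 chi''`: the per-cycle hysteresis loss of a Debye
#' susceptibility times the cycle rate.
#'
#' @param excitation a [field_excitation()].
#' @param chi_imag imaginary susceptibility chi'' at the drive frequency
#'   (dimensionless, >= 0).
#' @param constants a [physical_constants()] object.
#' @return Power density, W/m^3.
#' @export
heating_power <- function(excitation, chi_imag,
                          constants = physical_constants()) {
  stopifnot(inherits(excitation, "field_excitation"))
  if (any(chi_imag < 0)) stop("chi'' must be >= 0")
  excitation$f * pi * constants$mu0 * excitation$H0^2 * chi_imag
}

#' Hysteresis loop energy by numerical cyclic integration
#'
#' Computes `-mu0 * contour integral of M dH` over exactly one drive period by
#' cyclic trapezoidal quadrature. Serves as the brute-force oracle for the
#' closed-form linear-response loss `DeltaU = pi mu0 H0^2 chi''`.
#'
#' @param M_series magnetization samples over one period, A/m.
#' @param H_series field samples on the same uniform time grid, A/m.
#' @param constants a [physical_constants()] object.
#' @return Energy density released per cycle, J/m^3.
#' @export
hysteresis_energy_numeric <- function(M_series, H_series,
                                      constants = physical_constants()) {
  n <- length(M_series)
  if (n != length(H_series)) stop("M and H series must have equal length")
  if (n < 8) stop("too few samples for a cyclic integral")
  # cyclic trapezoid: sum over edges (i, i+1 mod n) of mean(M) * dH
  ip1 <- c(2:n, 1)
  dH <- H_series[ip1] - H_series
  -constants$mu0 * sum(0.5 * (M_series + M_series[ip1]) * dH)
}

#' Linear-response magnetization over one drive cycle
#'
#' `M(t) = H0 (chi' cos(w t) + chi'' sin(w t))`, the steady-state response to
#' `H(t) = H0 cos(w t)`. Used to build loop-integration fixtures.
#'
#' @param excitation a [field_excitation()].
#' @param chi_real,chi_imag susceptibility components at the drive frequency.
#' @param n_samples samples per period (default 1e4).
#' @return A data frame with columns `time_s`, `H_A_m`, `M_A_m`.
#' @export
linear_response_cycle <- function(excitation, chi_real, chi_imag,
                                  n_samples = 1e4) {
  stopifnot(inherits(excitation, "field_excitation"))
  if (excitation$f <= 0) stop("needs a positive drive frequency")
  t <- seq(0, 1 / excitation$f, length.out = n_samples + 1)[seq_len(n_samples)]
  wt <- excitation$omega * t
  data.frame(time_s = t,
             H_A_m = excitation$H0 * cos(wt),
             M_A_m = excitation$H0 * (chi_real * cos(wt) + chi_imag * sin(wt)))
}

#' Heating power versus core diameter
#'
#' Sweeps the core diameter at a fixed hydrodynamic ratio and evaluates the
#' full chain Neel time -> Brownian time -> effective time -> chi0 -> chi'' at
#' the drive frequency -> volumetric power. Emits a warning when the Langevin
#' argument `xi(H0)` exceeds `xi_warn` anywhere in the sweep, since the
#' linear-response formulas assume small fields.
#'
#' @details How the equilibrium susceptibility is scaled across the sweep is
#' not fixed by the underlying theory and changes the curve's shape, so it is
#' explicit:
#' * `"chi0"` (default): unit equilibrium susceptibility at every diameter, so
#'   the curve shows the pure Debye loss factor
#'   `tau w / (1 + (tau w)^2)` - the size dependence of the relaxation
#'   dynamics alone. This is the normalization under which the sweep is
#'   unimodal with an interior maximum where `tau(d) w = 1`.
#' * `"mass"`: fixed nanoparticle mass concentration
#'   (`Nm = cn / (rho_core Vm)`), the situation of a dilution series measured
#'   at constant mg/mL; `chi0` then grows like `d^3` and the loss curve
#'   saturates toward a Brownian-limited plateau.
#' * `"number"`: fixed particle number density; `chi0` grows like `d^6`.
#'
#' @param template a [particle_spec()] providing K, Msp, tau0.
#' @param medium a [medium_spec()].
#' @param excitation a [field_excitation()].
#' @param diameters_m core diameters to evaluate, m (sorted ascending).
#' @param hydrodynamic_ratio hydrodynamic/core diameter ratio (default 1.5).
#' @param normalization `"chi0"`, `"mass"` or `"number"`; see Details.
#' @param mass_concentration_kg_m3,core_density_kg_m3 used by the `"mass"`
#'   normalization (defaults 1 kg/m^3 and magnetite's 5180 kg/m^3).
#' @param number_density_m3 used by the `"number"` normalization.
#' @param constants a [physical_constants()] object.
#' @param xi_warn linear-response warning threshold on xi(H0) (default 0.5).
#' @return A `power_sweep` object: data frame with `diameter_nm`, `tau_s`,
#'   `chi_imag`, `power_w_per_m3`; attributes `argmax_diameter_m` and
#'   `interior_maximum` (FALSE when the maximum sits on the grid boundary).
#' @export
power_vs_diameter <- function(template, medium, excitation, diameters_m,
                              hydrodynamic_ratio = 1.5,
                              normalization = c("chi0", "mass", "number"),
                              mass_concentration_kg_m3 = 1,
                              core_density_kg_m3 = 5180,
                              number_density_m3 = 1,
                              constants = physical_constants(),
                              xi_warn = 0.5) {
  stopifnot(inherits(template, "particle_spec"))
  normalization <- match.arg(normalization)
  if (length(diameters_m) == 0) stop("empty diameter list")
  if (is.unsorted(diameters_m, strictly = TRUE))
    stop("diameters must be sorted strictly ascending")
  rows <- lapply(diameters_m, function(d) {
    p <- particle_spec(d, hydrodynamic_ratio = hydrodynamic_ratio,
                       anisotropy_J_m3 = template$K, Msp_A_m = template$Msp,
                       tau0_s = template$tau0)
    Nm <- switch(normalization,
                 chi0 = 1,
                 mass = mass_concentration_kg_m3 /
                   (core_density_kg_m3 * sphere_volume(d)),
                 number = number_density_m3)
    s <- suspension_spec(p, medium, number_density_m3 = Nm)
    tau <- effective_time(neel_time(p, medium, constants),
                          brown_time(p, medium, constants))
    chi0 <- if (normalization == "chi0") 1
            else equilibrium_susceptibility(s, constants)
    tw <- tau * excitation$omega
    chi2 <- tw * chi0 / (1 + tw^2)
    c(tau = tau, chi_imag = chi2,
      power = heating_power(excitation, chi2, constants),
      xi = abs(langevin_xi(excitation$H0, s, constants)))
  })
  m <- do.call(rbind, rows)
  if (max(m[, "xi"]) > xi_warn)
    warning(sprintf(paste0("xi(H0) reaches %.2f (> %.2f): beyond the ",
                           "linear-response regime the Debye loss formulas ",
                           "assume"), max(m[, "xi"]), xi_warn))
  out <- data.frame(diameter_nm = diameters_m * 1e9, tau_s = m[, "tau"],
                    chi_imag = m[, "chi_imag"], power_w_per_m3 = m[, "power"])
  i <- which.max(out$power_w_per_m3)
  attr(out, "argmax_diameter_m") <- diameters_m[i]
  attr(out, "interior_maximum") <- length(diameters_m) >= 3 &&
    i > 1 && i < length(diameters_m)
  class(out) <- c("power_sweep", "data.frame")
  out
}
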