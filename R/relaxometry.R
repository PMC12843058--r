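#' Translational diffusion correlation time
#'
#' Time for a water molecule to diffuse past a particle of radius R:
#' `tauD = R^2 / D`.
#'
#' @param R_m particle radius, m.
#' @param D_m2_s water self-diffusion constant, m^2/s (~2.3e-9 at 25 C,
#'   ~3.0e-9 at 37 C; never assumed, always supplied).
#' @return tauD, s.
#' @export
diffusion_time <- function(R_m, D_m2_s) {
  if (any(R_m <= 0) || any(D_m2_s <= 0)) stop("R and D must be > 0")
  R_m^2 / D_m2_s
}

#' Ayant spectral density JA
#'
#' Rational spectral density for proton diffusion through the dipolar field of
#' a fixed moment:
#' `JA(z) = (1 + 5z/8 + z^2/8) / (1 + z + z^2/2 + z^3/6 + 4z^4/81 + z^5/81 + z^6/648)`.
#' `JA(0) = 1` and `JA -> 0` as `z -> Inf`.
#'
#' @param z nonnegative dimensionless argument (vectorised). For use in the
#'   large-crystal rates the conventional argument is `sqrt(2 omegaI tauD)`;
#'   see [rates_large_crystal()].
#' @return Spectral density in (0, 1].
#' @export
spectral_density_JA <- function(z) {
  if (any(z < 0)) stop("z must be >= 0")
  (1 + 5 * z / 8 + z^2 / 8) /
    (1 + z + z^2 / 2 + z^3 / 6 + 4 * z^4 / 81 + z^5 / 81 + z^6 / 648)
}

# shared rational form of the Freed density in sqrt(Omega); principal branch
freed_kernel <- function(Omega) {
  s <- sqrt(Omega)  # principal branch of the complex square root
  Re((1 + s / 4) / (1 + s + 4 * Omega / 9 + s * Omega / 9))
}

#' Freed spectral density JF (fluctuating moment)
#'
#' Accounts for both proton diffusion (tauD) and fluctuation of the particle
#' moment (Neel time tauN):
#' `JF = Re[(1 + sqrt(Omega)/4) / (1 + sqrt(Omega) + 4 Omega/9 + Omega^{3/2}/9)]`
#' with `Omega = (i omega + 1/tauN) tauD` (principal branch).
#' As `tauN -> Inf` this reduces to the rigid-moment Freed function
#' [spectral_density_J()].
#'
#' @param omega angular frequency, rad/s (vectorised).
#' @param tauD diffusion time, s.
#' @param tauN Neel time, s (may be `Inf`).
#' @return Spectral density value(s).
#' @export
spectral_density_JF <- function(omega, tauD, tauN) {
  if (tauD <= 0) stop("tauD must be > 0")
  if (tauN <= 0) stop("tauN must be > 0")
  rate <- if (is.infinite(tauN)) 0 else 1 / tauN
  freed_kernel((1i * omega + rate) * tauD)
}

#' Freed spectral density J (rigid moment)
#'
#' `J(x) = Re[(1 + sqrt(i x)/4) / (1 + sqrt(i x) + 4 i x/9 + (i x)^{3/2}/9)]`
#' where the argument is the dimensionless product `x = omega tauD`.
#' `J(0) = 1`.
#'
#' @param x dimensionless `omega * tauD` (vectorised, >= 0).
#' @return Spectral density value(s).
#' @export
spectral_density_J <- function(x) {
  if (any(x < 0)) stop("x must be >= 0")
  freed_kernel(1i * x)
}

#' Outer-sphere context for the relaxation-rate formulas
#'
#' Bundles everything the two rate formulations need. The spin statistics
#' (`Sz_mean`, `Sz_var`) of a superparamagnetic particle, and the particle
#' moment, are inputs: the theory does not fix them. The moment may be given
#' directly (`mu_A_m2`) or through an effective spin quantum number `S`
#' (`mu^2 = gammaS^2 hbar^2 S (S+1)`).
#'
#' @param radius_m particle radius R, m.
#' @param D_m2_s water diffusion constant, m^2/s.
#' @param C_mol_L particle concentration, mol/L.
#' @param B0_T static field, T (sets the proton/electron Larmor frequencies).
#' @param mu_A_m2 particle magnetic moment, A m^2 (optional if `S` given).
#' @param S effective spin quantum number (optional if `mu_A_m2` given).
#' @param tauN_s Neel time, s (default `Inf`: rigid moment).
#' @param Sz_mean,Sz_var mean and variance of the z spin projection, in units
#'   of the effective spin (used by [rates_large_crystal()]).
#' @param constants a [physical_constants()] object.
#' @return An `outer_sphere_context` object.
#' @export
outer_sphere_context <- function(radius_m, D_m2_s, C_mol_L, B0_T,
                                 mu_A_m2 = NULL, S = NULL, tauN_s = Inf,
                                 Sz_mean = 0, Sz_var = 0,
                                 constants = physical_constants()) {
  if (radius_m <= 0 || D_m2_s <= 0) stop("radius and D must be > 0")
  if (C_mol_L < 0) stop("concentration must be >= 0")
  if (Sz_var < 0) stop("Sz variance must be >= 0")
  if (is.null(mu_A_m2)) {
    if (is.null(S)) stop("give mu_A_m2 or S")
    mu_A_m2 <- constants$gammaS * constants$hbar * sqrt(S * (S + 1))
  }
  structure(list(R = radius_m, D = D_m2_s, tauD = radius_m^2 / D_m2_s,
                 C = C_mol_L, B0 = B0_T,
                 omegaI = constants$gammaI * B0_T,
                 omegaS = constants$gammaS * B0_T,
                 mu = mu_A_m2, tauN = tauN_s,
                 Sz_mean = Sz_mean, Sz_var = Sz_var,
                 constants = constants),
            class = "outer_sphere_context")
}

#' Relaxation rates, large-crystal formulation
#'
#' Rates for protons diffusing past large magnetic crystals whose moment has
#' mean `<Sz>` and variance `DeltaSz^2` along the field:
#' \deqn{1/T1 = P [3 JF(\omega_I) \Delta S_z^2 + 3 J_A(a) \langle S_z\rangle^2]}
#' \deqn{1/T2 = P [ (3/2 JF(\omega_I) + 2 JF(0)) \Delta S_z^2 +
#'                 (3/2 J_A(a) + 2 J_A(0)) \langle S_z\rangle^2 ]}
#' with prefactor `P = 32 pi hbar^2 gammaI^2 gammaS^2 NA C / (135000 R D)`.
#' The JA argument `a` is `sqrt(2 omegaI tauD)` by default
#' (`JA_argument = "sqrt"`), or `2 omegaI tauD` verbatim
#' (`JA_argument = "identity"`).
#'
#' @param ctx an [outer_sphere_context()] (uses `Sz_mean`, `Sz_var`).
#' @param JA_argument `"sqrt"` (default) or `"identity"`; see Details.
#' @return Named vector `c(R1 = 1/T1, R2 = 1/T2)`, 1/s.
#' @export
rates_large_crystal <- function(ctx, JA_argument = c("sqrt", "identity")) {
  stopifnot(inherits(ctx, "outer_sphere_context"))
  JA_argument <- match.arg(JA_argument)
  pc <- ctx$constants
  pref <- 32 * pi * pc$hbar^2 * pc$gammaI^2 * pc$gammaS^2 * pc$NA_ * ctx$C /
    (135000 * ctx$R * ctx$D)
  a <- 2 * ctx$omegaI * ctx$tauD
  if (JA_argument == "sqrt") a <- sqrt(a)
  JFw <- spectral_density_JF(ctx$omegaI, ctx$tauD, ctx$tauN)
  JF0 <- spectral_density_JF(0, ctx$tauD, ctx$tauN)
  JAa <- spectral_density_JA(a)
  JA0 <- spectral_density_JA(0)
  R1 <- pref * (3 * JFw * ctx$Sz_var + 3 * JAa * ctx$Sz_mean^2)
  R2 <- pref * ((1.5 * JFw + 2 * JF0) * ctx$Sz_var +
                (1.5 * JAa + 2 * JA0) * ctx$Sz_mean^2)
  c(R1 = R1, R2 = R2)
}

#' Relaxation rates, microscopic outer-sphere formulation
#'
#' Freed-model rates in terms of the particle moment mu:
#' \deqn{1/T1 = Q [7 J(\tau_D \omega_S) + 3 J(\tau_D \omega_I)]}
#' \deqn{1/T2 = Q [6.5 J(\tau_D \omega_S) + 1.5 J(\tau_D \omega_I) + 2 J(0)]}
#' with `Q = 32 pi gammaI^2 mu^2 NA C / (405000 R D)`. The coefficient sums
#' are equal (7+3 = 6.5+1.5+2), so `R2/R1 -> 1` as the field goes to zero.
#'
#' @param ctx an [outer_sphere_context()] (uses `mu`).
#' @return Named vector `c(R1, R2)`, 1/s.
#' @export
rates_outer_sphere <- function(ctx) {
  stopifnot(inherits(ctx, "outer_sphere_context"))
  pc <- ctx$constants
  pref <- 32 * pi * pc$gammaI^2 * ctx$mu^2 * pc$NA_ * ctx$C /
    (405000 * ctx$R * ctx$D)
  JS <- spectral_density_J(ctx$tauD * ctx$omegaS)
  JI <- spectral_density_J(ctx$tauD * ctx$omegaI)
  J0 <- spectral_density_J(0)
  c(R1 = pref * (7 * JS + 3 * JI),
    R2 = pref * (6.5 * JS + 1.5 * JI + 2 * J0))
}

#' Assemble a concentration-vs-rate series
#'
#' @param concentrations nanoparticle concentrations (any consistent unit;
#'   strictly increasing, >= 3 points).
#' @param rates relaxation rates 1/T1 or 1/T2, 1/s (> 0).
#' @param channel `"T1"` or `"T2"`.
#' @param field_T static field, T.
#' @param concentration_unit unit label carried into reports
#'   (default `"mg/mL"`).
#' @return A `relaxation_series` object (data frame + metadata attributes).
#' @export
relaxation_series <- function(concentrations, rates,
                              channel = c("T1", "T2"), field_T,
                              concentration_unit = "mg/mL") {
  channel <- match.arg(channel)
  if (length(concentrations) != length(rates)) stop("length mismatch")
  if (length(concentrations) < 3) stop("need >= 3 points")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(rates <= 0)) stop("rates must be > 0")
  out <- data.frame(concentration = concentrations, rate = rates)
  attr(out, "channel") <- channel
  attr(out, "field_T") <- field_T
  attr(out, "concentration_unit") <- concentration_unit
  class(out) <- c("relaxation_series", "data.frame")
  out
}

#' Fit a relaxivity coefficient from a concentration series
#'
#' Ordinary least squares through `rate = baseline + r * concentration`
#' (`1/Ti = 1/Ti,water + ri * C`): the intercept is the carrier-water rate and
#' the slope is the relaxivity.
#'
#' @param series a [relaxation_series()].
#' @param conf_level confidence level for the slope interval (default 0.95).
#' @return A `relaxivity_result` list: `baseline`, `relaxivity`,
#'   `baseline_se`, `relaxivity_se`, `conf_int` (slope), `r_squared`, `n`,
#'   `channel`, `field_T`, `concentration_unit`.
#' @export
fit_relaxivity <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "relaxation_series"))
  if (diff(range(series$concentration)) == 0)
    stop("zero spread in concentrations")
  fit <- stats::lm(rate ~ concentration, data = series)
  sm <- quiet_perfect_fit(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tq <- stats::qt((1 + conf_level) / 2, df = nrow(series) - 2)
  ci <- matrix(c(slope - tq * se, slope + tq * se), 1)
  structure(list(baseline = unname(stats::coef(fit)[1]),
                 relaxivity = unname(stats::coef(fit)[2]),
                 baseline_se = sm$coefficients[1, 2],
                 relaxivity_se = sm$coefficients[2, 2],
                 conf_int = unname(ci[1, ]),
                 conf_level = conf_level,
                 r_squared = sm$r.squared,
                 n = nrow(series),
                 channel = attr(series, "channel"),
                 field_T = attr(series, "field_T"),
                 concentration_unit = attr(series, "concentration_unit")),
            class = "relaxivity_result")
}

#' @export
print.relaxivity_result <- function(x, ...) {
  cat(sprintf("Relaxivity fit (%s, %.3g T): r = %.4g +/- %.2g 1/(s %s), baseline %.4g 1/s, R^2 = %.4f, n = %d\n",
              x$channel, x$field_T, x$relaxivity, x$relaxivity_se,
              x$concentration_unit, x$baseline, x$r_squared, x$n))
  invisible(x)
}

#' Theoretical relaxivity versus core diameter
#'
#' Evaluates the microscopic outer-sphere rates across a diameter sweep at
#' fixed field, with the particle moment scaling as `mu = Msp * Vm`
#' (`Vm = pi d^3/6`) and `tauD = (d/2)^2 / D`, then normalizes by the molar
#' concentration to give relaxivities per mmol/L.
#'
#' @param diameters_m core diameters, m (sorted ascending).
#' @param D_m2_s water diffusion constant, m^2/s.
#' @param B0_T static field, T.
#' @param Msp_A_m core saturation magnetization, A/m.
#' @param constants a [physical_constants()] object.
#' @return A `relaxivity_sweep` data frame with `diameter_nm`, `r1_per_mM_s`,
#'   `r2_per_mM_s`; attributes `argmax_r1_m`, `argmax_r2_m`.
#' @export
relaxivity_vs_diameter <- function(diameters_m, D_m2_s, B0_T, Msp_A_m,
                                   constants = physical_constants()) {
  if (length(diameters_m) == 0) stop("empty diameter sweep")
  if (is.unsorted(diameters_m, strictly = TRUE))
    stop("diameters must be sorted strictly ascending")
  C_ref <- 1e-3  # 1 mmol particles / L; rates are exactly linear in C
  rows <- vapply(diameters_m, function(d) {
    mu <- Msp_A_m * sphere_volume(d)
    ctx <- outer_sphere_context(radius_m = d / 2, D_m2_s = D_m2_s,
                                C_mol_L = C_ref, B0_T = B0_T, mu_A_m2 = mu,
                                constants = constants)
    rates_outer_sphere(ctx)
  }, numeric(2))
  out <- data.frame(diameter_nm = diameters_m * 1e9,
                    r1_per_mM_s = rows["R1", ],
                    r2_per_mM_s = rows["R2", ])
  attr(out, "argmax_r1_m") <- diameters_m[which.max(out$r1_per_mM_s)]
  attr(out, "argmax_r2_m") <- diameters_m[which.max(out$r2_per_mM_s)]
  class(out) <- c("relaxivity_sweep", "data.frame")
  out
}
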