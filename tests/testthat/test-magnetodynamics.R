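pc <- physical_constants()

test_that("neel_time matches direct evaluation and its limits", {
  med <- medium_spec(8.9e-4, 310)
  p16 <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
                       anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
  # frozen high-precision evaluation of tau0*exp(K*V/(kB*T))
  expect_equal(neel_time(p16, med), 3.73387478263462e-05, tolerance = 1e-12)
  # K -> 0 limit: exponent vanishes, tauN -> tau0
  p0 <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
                      anisotropy_J_m3 = 1e-12, Msp_A_m = 4.8e5)
  expect_equal(neel_time(p0, med), 1e-9, tolerance = 1e-9)
  # strict monotonicity in diameter
  taus <- vapply(seq(8, 24, by = 2) * 1e-9, function(d)
    neel_time(particle_spec(d, hydrodynamic_ratio = 1.5,
                            anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5), med),
    numeric(1))
  expect_true(all(diff(taus) > 0))
  # blocked regime raises, with diagnostic
  pbig <- particle_spec(80e-9, hydrodynamic_ratio = 1.5,
                        anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
  expect_error(neel_time(pbig, med), "superparamagnetic")
})

test_that("brown_time scales linearly in viscosity and cubically in dh", {
  p <- particle_spec(16e-9, hydrodynamic_diameter_m = 24e-9,
                     anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
  expect_equal(brown_time(p, medium_spec(8.9e-4, 310)),
               4.51754854961086e-06, tolerance = 1e-12)
  expect_equal(brown_time(p, medium_spec(2 * 8.9e-4, 310)),
               2 * brown_time(p, medium_spec(8.9e-4, 310)))
  p2 <- particle_spec(16e-9, hydrodynamic_diameter_m = 48e-9,
                      anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
  expect_equal(brown_time(p2, medium_spec(8.9e-4, 310)),
               8 * brown_time(p, medium_spec(8.9e-4, 310)))
})

test_that("effective_time is the harmonic combination", {
  expect_equal(effective_time(2e-6, 2e-6), 1e-6)
  expect_equal(effective_time(Inf, 3e-6), 3e-6)
  expect_equal(effective_time(3e-6, Inf), 3e-6)
  expect_equal(effective_time(1e-5, 1e-6), 9.09090909090909e-07,
               tolerance = 1e-12)
  expect_equal(effective_time(1e-5, 1e-6), effective_time(1e-6, 1e-5))
  expect_lte(effective_time(1e-5, 1e-6), 1e-6)
  expect_error(effective_time(Inf, Inf), "finite")
})

test_that("langevin_magnetization is odd, bounded, saturating, stable", {
  s <- fixture_suspension()
  expect_equal(langevin_magnetization(0, s), 0)
  Ms <- s$Nm * s$particle$Msp * pi * s$particle$dm^3 / 6
  # xi = 1 via a field chosen to make the argument exactly one
  H1 <- pc$kB * s$medium$T / (pc$mu0 * s$particle$Msp * pi * s$particle$dm^3 / 6)
  expect_equal(langevin_magnetization(H1, s) / Ms, 0.313035285499331,
               tolerance = 1e-12)
  expect_equal(langevin_magnetization(1e4 * H1, s) / Ms, 1, tolerance = 1e-3)
  expect_equal(langevin_magnetization(-H1, s), -langevin_magnetization(H1, s))
  expect_true(all(abs(langevin_magnetization(c(-1e9, 1e9), s)) < Ms))
  # continuity across the series switch point
  Hs <- H1 * c(0.9999e-4, 1.0001e-4)
  M <- langevin_magnetization(Hs, s)
  expect_equal(M[1] / M[2], Hs[1] / Hs[2], tolerance = 1e-6)
})

test_that("equilibrium susceptibility is the Langevin slope at the origin", {
  s0 <- fixture_suspension(Nm = 0)
  expect_equal(equilibrium_susceptibility(s0), 0)
  # Curie scaling
  sA <- fixture_suspension(Temp = 300)
  sB <- fixture_suspension(Temp = 600)
  expect_equal(equilibrium_susceptibility(sA),
               2 * equilibrium_susceptibility(sB))
  # finite-difference oracle across random suspensions
  set.seed(11)
  for (i in 1:50) {
    s <- fixture_suspension(dm = runif(1, 8, 25) * 1e-9,
                            Msp = runif(1, 2e5, 6e5),
                            Nm = 10^runif(1, 18, 22),
                            Temp = runif(1, 280, 330))
    h <- 1e-6 * pc$kB * s$medium$T /
      (pc$mu0 * s$particle$Msp * pi * s$particle$dm^3 / 6)
    slope <- (langevin_magnetization(h, s) - langevin_magnetization(-h, s)) / (2 * h)
    expect_equal(equilibrium_susceptibility(s), slope, tolerance = 1e-3)
  }
})

test_that("susceptibility spectrum obeys the Debye algebra", {
  s <- fixture_suspension()
  tauN <- neel_time(s$particle, s$medium)
  tauB <- brown_time(s$particle, s$medium)
  tau <- effective_time(tauN, tauB)
  chi0 <- equilibrium_susceptibility(s)
  # exact points: omega*tau = 0, 1, 3
  f <- c(0, 1, 3) / (2 * pi * tau)
  sp <- susceptibility_spectrum(s, f)
  expect_equal(attr(sp, "tau"), tau)
  expect_equal(sp$chi_real[1], chi0)
  expect_equal(sp$chi_imag[1], 0)
  expect_equal(sp$chi_real[2], chi0 / 2)
  expect_equal(sp$chi_imag[2], chi0 / 2)
  expect_equal(sp$chi_imag[3], 0.3 * chi0, tolerance = 1e-12)
  expect_equal(sp$chi_real[3], 0.1 * chi0, tolerance = 1e-12)
  # invariants on a broad grid + algebraic identity to machine precision
  sp <- susceptibility_spectrum(s, 10^seq(0, 8, length.out = 200))
  tw <- 2 * pi * sp$frequency_hz * tau
  expect_true(all(sp$chi_imag >= 0))
  expect_true(all(sp$chi_real <= chi0 + 1e-15))
  expect_true(all(diff(sp$chi_real) <= 0))
  expect_equal(sp$chi_real * (1 + tw^2), rep(chi0, 200), tolerance = 1e-14)
  expect_equal(sp$chi_imag * (1 + tw^2), tw * chi0, tolerance = 1e-14)
})

test_that("heating power follows P = f pi mu0 H0^2 chi''", {
  ex <- field_excitation(58.3e3, B0_T = 20e-3)
  expect_equal(heating_power(ex, 0), 0)
  # frozen hand evaluation with H0 = B0/mu0
  expect_equal(heating_power(ex, 0.1), 5828316.68112283, tolerance = 1e-12)
  ex2 <- field_excitation(58.3e3, H0_A_m = 2 * ex$H0)
  expect_equal(heating_power(ex2, 0.1), 4 * heating_power(ex, 0.1))
})

test_that("numeric hysteresis loop equals the closed-form ellipse area", {
  ex <- field_excitation(1e5, H0_A_m = 3e3)
  # in-phase response: zero enclosed area
  cyc <- linear_response_cycle(ex, chi_real = 0.4, chi_imag = 0, n_samples = 1e4)
  dU0 <- hysteresis_energy_numeric(cyc$M_A_m, cyc$H_A_m)
  expect_lt(abs(dU0), 1e-6 * pc$mu0 * ex$H0^2)
  # lossy response: pi mu0 H0^2 chi'' within 0.1%
  cyc <- linear_response_cycle(ex, chi_real = 0.4, chi_imag = 0.15, n_samples = 1e4)
  expect_equal(hysteresis_energy_numeric(cyc$M_A_m, cyc$H_A_m),
               pi * pc$mu0 * ex$H0^2 * 0.15, tolerance = 1e-3)
  # quadratic amplitude scaling
  ex2 <- field_excitation(1e5, H0_A_m = 6e3)
  cyc2 <- linear_response_cycle(ex2, 0.4, 0.15, 1e4)
  expect_equal(hysteresis_energy_numeric(cyc2$M_A_m, cyc2$H_A_m),
               4 * hysteresis_energy_numeric(cyc$M_A_m, cyc$H_A_m),
               tolerance = 1e-6)
  expect_error(hysteresis_energy_numeric(cyc$M_A_m, cyc$H_A_m[-1]), "length")
})

test_that("power_vs_diameter finds a single interior optimum", {
  tmpl <- particle_spec(16e-9, hydrodynamic_ratio = 1.5,
                        anisotropy_J_m3 = 21e3, Msp_A_m = 4.8e5)
  med <- medium_spec(8.9e-4, 310)
  ex <- field_excitation(58.3e3, B0_T = 20e-3)
  one <- suppressWarnings(
    power_vs_diameter(tmpl, med, ex, 16e-9))
  expect_equal(attr(one, "argmax_diameter_m"), 16e-9)
  # 20 mT at 58.3 kHz is beyond linear response: warning expected
  expect_warning(
    sw <- power_vs_diameter(tmpl, med, ex, seq(5, 40, 0.5) * 1e-9),
    "linear-response")
  expect_true(attr(sw, "interior_maximum"))
  sgn <- sign(diff(sw$power_w_per_m3))
  expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)  # unimodal: one sign change
  # Debye regime (tau*omega << 1 throughout): monotone increasing power
  ex_lo <- field_excitation(100, H0_A_m = 10)
  sw_lo <- power_vs_diameter(tmpl, med, ex_lo, seq(5, 12, 0.5) * 1e-9)
  expect_true(all(2 * pi * ex_lo$f * sw_lo$tau_s < 0.1))
  expect_true(all(diff(sw_lo$power_w_per_m3) > 0))
  expect_error(power_vs_diameter(tmpl, med, ex, numeric(0)), "empty")
})
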