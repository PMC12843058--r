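pc <- physical_constants()

test_that("diffusion_time is R^2/D", {
  expect_equal(diffusion_time(10e-9, 2.3e-9), 4.34782608695652e-08,
               tolerance = 1e-12)
  expect_equal(diffusion_time(20e-9, 2.3e-9), 4 * diffusion_time(10e-9, 2.3e-9))
  expect_lt(diffusion_time(10e-9, 1e6), 1e-19)
  expect_error(diffusion_time(-1e-9, 2.3e-9), "> 0")
})

test_that("spectral densities hit their anchors and limits", {
  expect_identical(spectral_density_JA(0), 1)
  # exact rational value at z = 1, built from integer fractions
  ja1 <- (1 + 5 / 8 + 1 / 8) /
    (1 + 1 + 1 / 2 + 1 / 6 + 4 / 81 + 1 / 81 + 1 / 648)
  expect_equal(spectral_density_JA(1), ja1, tolerance = 1e-15)
  # asymptotic decay ~ 81/z^4
  z <- 1e5
  expect_equal(spectral_density_JA(z) * z^4 / 81, 1, tolerance = 1e-2)
  expect_error(spectral_density_JA(-1), ">= 0")

  expect_equal(spectral_density_JF(0, 1e-8, Inf), 1)
  expect_identical(spectral_density_J(0), 1)
  expect_lt(spectral_density_JF(1e12, 1e-6, 1e-9), 1e-3)
  # rigid-moment reduction: JF(w, tauD, Inf) == J(w tauD) on a log grid
  tauD <- 4.35e-8
  x <- 10^seq(-4, 4, length.out = 81)
  expect_equal(spectral_density_JF(x / tauD, tauD, Inf),
               spectral_density_J(x), tolerance = 1e-12)
})

test_that("large-crystal rates reproduce the printed coefficient structure", {
  ctx0 <- outer_sphere_context(10e-9, 2.3e-9, 0, 0.55, S = 1e3,
                               Sz_mean = 1, Sz_var = 0.5)
  expect_equal(unname(rates_large_crystal(ctx0)), c(0, 0))
  ctx1 <- outer_sphere_context(10e-9, 2.3e-9, 1e-3, 0.55, S = 1e3,
                               Sz_mean = 1, Sz_var = 0.5)
  ctx2 <- outer_sphere_context(10e-9, 2.3e-9, 2e-3, 0.55, S = 1e3,
                               Sz_mean = 1, Sz_var = 0.5)
  expect_equal(rates_large_crystal(ctx2), 2 * rates_large_crystal(ctx1))
  # omegaI -> 0 with zero variance: R2/R1 = (3/2 + 2)/3 = 7/6 exactly
  ctx <- outer_sphere_context(10e-9, 2.3e-9, 1e-3, 0, S = 1e3,
                              Sz_mean = 1, Sz_var = 0)
  r <- rates_large_crystal(ctx)
  expect_equal(unname(r["R2"] / r["R1"]), 7 / 6, tolerance = 1e-12)
  # both argument conventions are available and differ at finite field
  ra <- rates_large_crystal(ctx1, JA_argument = "sqrt")
  rb <- rates_large_crystal(ctx1, JA_argument = "identity")
  expect_false(isTRUE(all.equal(ra, rb)))
})

test_that("outer-sphere rates: zero-field identity, secular limit, mu^2", {
  mk <- function(B0, mu = 1e-19, R = 10e-9)
    outer_sphere_context(R, 2.3e-9, 1e-3, B0, mu_A_m2 = mu)
  # R2/R1 -> 1 as field -> 0 (7+3 = 6.5+1.5+2); J deviates like sqrt(w tauD),
  # so the field must be truly tiny for 1e-9 agreement
  r <- rates_outer_sphere(mk(1e-22))
  expect_equal(unname(r["R2"] / r["R1"]), 1, tolerance = 1e-9)
  # high field: R1 collapses, R2 -> secular 2 J(0) share
  rhi <- rates_outer_sphere(mk(1e4))
  expect_lt(rhi[["R1"]] / rhi[["R2"]], 1e-3)
  pref <- 32 * pi * pc$gammaI^2 * (1e-19)^2 * pc$NA_ * 1e-3 /
    (405000 * 10e-9 * 2.3e-9)
  expect_equal(rhi[["R2"]], pref * 2, tolerance = 1e-3)
  # quadratic in the moment
  expect_equal(unname(rates_outer_sphere(mk(0.55, mu = 2e-19))),
               unname(4 * rates_outer_sphere(mk(0.55, mu = 1e-19))))
})

test_that("fit_relaxivity recovers exact and noisy lines", {
  conc <- c(0.5, 1, 2, 4, 8)
  s <- relaxation_series(conc, 0.4 + 2.0 * conc, channel = "T2", field_T = 0.55)
  fit <- fit_relaxivity(s)
  expect_equal(fit$relaxivity, 2.0, tolerance = 1e-12)
  expect_equal(fit$baseline, 0.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant rates: zero slope
  s0 <- relaxation_series(conc, rep(0.7, 5), channel = "T1", field_T = 7)
  expect_equal(fit_relaxivity(s0)$relaxivity, 0, tolerance = 1e-12)
  # noisy: slope within 3 SE of truth for most seeds (the SE is t-distributed
  # with 3 df here, so ~94% coverage is the theoretical expectation)
  inside <- vapply(1:100, function(seed) {
    g <- gen_relaxation_series(2.0, 0.4, conc, noise_sd = 0.05, seed = seed)
    f <- fit_relaxivity(g$series)
    abs(f$relaxivity - 2.0) < 3 * f$relaxivity_se
  }, logical(1))
  expect_gte(mean(inside), 0.88)
  expect_error(relaxation_series(c(1, 2), c(1, 2), field_T = 1), ">= 3")
  expect_error(fit_relaxivity(
    structure(data.frame(concentration = c(1, 1, 1), rate = 1:3),
              class = c("relaxation_series", "data.frame"))), "spread")
})

test_that("relaxivity_vs_diameter shows the documented size/field trends", {
  one <- relaxivity_vs_diameter(20e-9, 2.3e-9, 0.55, 4.8e5)
  expect_equal(attr(one, "argmax_r2_m"), 20e-9)
  # fixed moment, growing radius: r2 eventually decreases (regime rollover)
  mu <- 1e-19
  r2 <- vapply(seq(5, 200, 5) * 1e-9, function(R)
    rates_outer_sphere(outer_sphere_context(R, 2.3e-9, 1e-3, 0.55,
                                            mu_A_m2 = mu))[["R2"]],
    numeric(1))
  expect_true(any(diff(r2) < 0))
  # r1 at high field well below r1 at low field, same particles
  d <- seq(5, 40, 1) * 1e-9
  lo <- relaxivity_vs_diameter(d, 2.3e-9, 0.55, 4.8e5)
  hi <- relaxivity_vs_diameter(d, 2.3e-9, 7, 4.8e5)
  expect_true(all(hi$r1_per_mM_s < lo$r1_per_mM_s))
  expect_error(relaxivity_vs_diameter(numeric(0), 2.3e-9, 0.55, 4.8e5), "empty")
})
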