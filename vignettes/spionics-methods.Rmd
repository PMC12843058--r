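---
title: "Models and methods behind spionics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spionics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spionics)
```

`spionics` asks a practical nanomedicine question: is there a nanoparticle
core diameter at which one superparamagnetic iron oxide formulation is
simultaneously a good T2 MRI contrast agent and a good magnetic-hyperthermia
heat source? This vignette documents the models, their assumptions, the
tunable parameters, what the synthetic-data generators do and do not emulate,
and the numerical and design choices that were genuinely open.

## 1. Magnetic relaxation and heating

A single-domain nanoparticle relaxes its magnetization by two parallel
channels. The **Néel** channel flips the moment inside the crystal over the
anisotropy barrier $KV$:

$$\tau_N = \tau_0 \exp\!\left(\frac{K V}{k_B T}\right), \qquad V = \frac{\pi d_m^3}{6},$$

with attempt time $\tau_0 \approx 10^{-9}$ s (the package default). The
**Brownian** channel rotates the whole particle in the carrier fluid:

$$\tau_B = \frac{3 V_h \eta}{k_B T}, \qquad V_h = \frac{\pi d_h^3}{6},$$

where $d_h$ is the hydrodynamic diameter (core + coating + solvation; a
ratio $d_h/d_m = 1.5$ is the package's sweep default, typical of thin polymer
coatings). The effective time is the parallel combination
$\tau = \tau_N \tau_B/(\tau_N + \tau_B)$ — always dominated by the faster
channel.

Because $\tau_N$ grows exponentially with volume, double precision overflows
for large cores. The exponent is capped at 700 and a particle beyond the cap
raises an error: that particle is magnetically *blocked* and outside the
superparamagnetic model's domain, so returning a number would be worse than
refusing.

The equilibrium magnetization follows the Langevin law
$M = M_s\,(\coth\xi - 1/\xi)$ with
$\xi = \mu_0 H M_{SP} V_m / (k_B T)$ and sample saturation
$M_s = N_m M_{SP} V_m$. Below $|\xi| < 10^{-4}$ the closed form suffers
catastrophic cancellation and the implementation switches to the series
$\xi/3 - \xi^3/45$ (the two branches agree to better than $10^{-10}$ at the
switch point).

**A note on the equilibrium susceptibility.** The textbook per-particle form
$\chi_0 = \mu_0 M_s^2 V / (3 k_B T)$ mixes a per-particle volume with a
sample-level magnetization and is dimensionally ambiguous when read against
the Langevin law above. `spionics` defines $\chi_0$ as what it must be for
internal consistency — the exact small-field slope of the implemented
magnetization law:

$$\chi_0 = \frac{\mu_0 N_m (M_{SP} V_m)^2}{3 k_B T}.$$

A property test verifies this against a finite-difference slope of
`langevin_magnetization()` to 0.1%.

In the **linear-response regime** the AC response at drive
$H(t) = H_0\cos\omega t$ is a Debye susceptibility

$$\chi'(\omega) = \frac{\chi_0}{1+(\tau\omega)^2}, \qquad
  \chi''(\omega) = \frac{\tau\omega\,\chi_0}{1+(\tau\omega)^2},$$

and the dissipated power density is $P = f \pi \mu_0 H_0^2 \chi''$. The
package carries an independent oracle for this: `hysteresis_energy_numeric()`
integrates $-\mu_0 \oint M\,dH$ over one cycle by cyclic trapezoidal
quadrature ($10^4$ samples/period by default) and agrees with
$\pi\mu_0 H_0^2 \chi''$ to 0.1%.

Linearity is policed, not assumed silently: whenever $\xi(H_0) > 0.5$
(configurable) a warning states that the Debye formulas are being used
outside their small-field domain. At the hyperthermia operating point used
throughout (58.3 kHz, 20 mT) $\xi$ reaches tens, so power sweeps at that
drive are qualitative size-dependence curves, not calibrated predictions.

### Normalizing the power-versus-diameter sweep

How $\chi_0$ scales across a diameter sweep is *not* fixed by the theory, and
it changes the answer:

* fixed particle **number** density: $\chi_0 \propto d^6$;
* fixed **mass** concentration (a dilution series at constant mg/mL):
  $\chi_0 \propto d^3$ — the loss curve then rises to a Brownian-limited
  plateau and never turns over within 5–40 nm;
* fixed **$\chi_0$** (default): the sweep shows the pure Debye factor
  $\tau\omega/(1+(\tau\omega)^2)$, which is unimodal with one interior
  maximum where $\tau(d)\,\omega = 1$.

The source material for this analysis presents such sweeps without stating
the normalization, and only the $\chi_0$-normalized form reproduces the
reported unimodal shape; `power_vs_diameter()` therefore defaults to
`normalization = "chi0"` and exposes the other two explicitly. This was the
most consequential open design decision in the package.

## 2. Outer-sphere relaxometry

Water protons diffusing past a magnetized particle of radius $R$ lose phase
coherence on the diffusion time $\tau_D = R^2/D$. The water self-diffusion
constant $D$ is a **required input** (≈ 2.3×10⁻⁹ m²/s at 25 °C,
≈ 3.0×10⁻⁹ at 37 °C): the package never assumes it.

Two spectral densities drive the rates: the rational Ayant density
$J_A(z)$ with $J_A(0)=1$, and the Freed density

$$J_F(\omega, \tau_D, \tau_N) =
  \mathrm{Re}\left[\frac{1+\Omega^{1/2}/4}
  {1+\Omega^{1/2}+4\Omega/9+\Omega^{3/2}/9}\right],
  \qquad \Omega = \left(i\omega + \tau_N^{-1}\right)\tau_D,$$

using the principal branch of the complex square root, real part taken last.
With a rigid moment ($\tau_N \to \infty$) $J_F$ reduces exactly to the
one-argument Freed function $J(\omega\tau_D)$; a test asserts this to
$10^{-12}$ over eight decades.

Two rate formulations are provided. The *large-crystal* form takes the spin
projection statistics $\langle S_z\rangle$, $\Delta S_z^2$ as inputs — the
theory defines only their relation, and no closed form for a
superparamagnetic particle is asserted, so the package does not invent one.
The *microscopic outer-sphere* form takes the particle moment $\mu$ and uses
the coefficient sets $7/3$ (for $1/T_1$) and $6.5/1.5/2$ (for $1/T_2$); the
equal coefficient sums make $r_2/r_1 \to 1$ at zero field, which is tested to
$10^{-9}$.

Three printed-source ambiguities were resolved as follows (each documented in
the decisions ledger):

1. the prefactors are parsed as $C/(135000\,R D)$ and $C/(405000\,R D)$,
   the standard concentration-over-$RD$ scaling of outer-sphere theory;
2. the $\hbar^2$ that appears in one printed $1/T_2$ but not in the matching
   $1/T_1$ after the $\mu^2$ substitution is treated as a typographical
   remnant ($\hbar^2$ is already absorbed into $\mu^2$);
3. the Ayant argument printed as "$2\omega_I\tau_D$" is interpreted as
   $\sqrt{2\omega_I\tau_D}$ by default (the source theory's variable), with
   the verbatim reading available via `JA_argument = "identity"`.

Empirical relaxivity is ordinary least squares on
$\text{rate} = \text{baseline} + r\cdot C$; with the usual 5-point
concentration series the slope CI is $t$-based with 3 degrees of freedom,
and seeded simulations confirm 95% CIs cover the truth 92–98% of the time.

## 3. TEM morphometry

The pipeline mirrors standard practice for STEM images of dark particles on
a bright support: invert, median-filter (radius 1 px default), Otsu
threshold (foreground strictly above; ties broken toward the lowest
threshold), morphological closing (disk radius 2 px default) to fill
interior holes, Euclidean distance transform, marker watershed
(8-connectivity, deterministic FIFO tie-break), and per-label
minimum-enclosing-circle measurement (Welzl's algorithm, verified against an
$O(n^3)$ all-pairs/all-triples oracle to $10^{-9}$ px). Markers are distance
maxima suppressed below a minimum separation, defaulting to half the
expected particle diameter — the source procedure names the steps but no
marker rule, so this is the package's choice. Particles touching the image
border are excluded by default (their enclosing circles would be clipped).

**Measurement convention and its bias.** A label's diameter is
$2 r_{\mathrm{mec}} + 1$ px, where $r_{\mathrm{mec}}$ is the enclosing-circle
radius over pixel *centres* and the +1 px pad represents pixel extent (it
also keeps a single-pixel region from measuring zero). Because a rendered
disk of true radius $r$ includes pixel centres out to distance $\approx r$,
this convention systematically over-measures by about one pixel. That is a
known, deterministic property, not noise: at 0.2 nm/px a 12-nm particle is
60 px across and the bias is ≈ 1.7%; at 0.25 nm/px it would already be
≈ 2.1%. The synthetic-image default of 0.2 nm/px (realistic for high-
magnification STEM) keeps the recovery error inside the 2% acceptance bound
*including* this convention bias.

Histograms use 1-nm bins centred on integer nanometres. On the reference
synthetic population (lognormal, median 12 nm, geometric SD 1.2 — chosen to
mirror a nominally 10-nm commercial sample whose measured distribution peaks
near 12 nm with a long right tail) the true mode is 11.6 nm, which straddles
the 11- and 12-centred bins; tests therefore assert the peak within one bin
of 12 nm, the honest reading of "approximately 12 nm". No de-aggregation
correction is applied: clusters merged beyond what watershed separates are
reported as measured.

## 4. Calorimetry

The SAR formula $\mathrm{SAR} = C\,(\rho/c_n)\,dT/dt|_{t=0}$ needs the
initial slope, and the estimator matters because hour-long exposures are far
outside the linear regime. The default fits the Newtonian balance
$T(t) = T_0 + \Delta T_\infty (1 - e^{-t/\tau_c})$ (via `nls` with
`scaleOffset = 1`, which keeps convergence well-defined on noiseless
synthetic curves) and returns the analytic slope
$\Delta T_\infty/\tau_c$ with a delta-method standard error. The windowed
linear fit is also provided; on a saturating curve it underestimates the
slope by the factor $1 - w/(2\tau_c) + O((w/\tau_c)^2)$, which a test checks
against a continuous-OLS oracle. If the exponential fit fails, the linear
window is used and flagged (`fallback = TRUE`), never silently.

Units: temperatures may arrive in °C or K (slopes are invariant);
concentration in mg/mL is read as kg/m³ of suspension, and SAR is reported
per gram of nanoparticles. With $C = 4000$ J/(kg K), $\rho/c_n = 40$
(25 mg/mL aqueous) and slope 0.01 K/s, SAR = 1.6 W/g.

The synthetic heating-curve generator inverts the same formula, so
noiseless round trips are exact to $10^{-6}$ — a construction identity, and
deliberately so: it validates unit plumbing, not physics. The single
exponential is the minimal model with a well-defined initial slope; real
calorimeters add baseline drift and non-exponential losses the generator
does not emulate, so a green SAR test establishes estimator correctness, not
instrument realism.

## 5. Study synthesis

The cross-modality table (rows = nominal diameters; columns = T1/T2 at low
and high field, heating power) is analyzed with Pearson correlations —
the analysis this package mirrors reports plain "correlation coefficients",
and Pearson is the default reading — with two-sided p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$. Labels follow p < 0.05 (significant) and
0.05 ≤ p < 0.1 (trend). With the study's five diameters, significance
requires $|r| > 0.8783$, the $t$-distribution boundary, which the tests
verify in closed form. No multiple-testing correction is applied by default
(matching how such tables are usually presented); a Bonferroni toggle
exists.

The optimum-overlap report defines each curve's "maximum range" as all grid
diameters within 5% of its peak (the plateau fraction is configurable; the
source gives ranges like 20–25 nm without stating a rule) and intersects the
$r_2$ and heating-power ranges. The demo world is constructed with $r_2$ and
SAR maxima co-located at 22 nm and $r_1$ peaking at 15 nm, so the end-to-end
pipeline should — and does — conclude "joint optimum exists".

## 6. What the generators do not emulate

Synthetic STEM images are anti-aliased disks with Gaussian pixel noise:
no electron-optics point-spread, no astigmatism, no amorphous-carbon
texture, no aggregation beyond pairwise contact. Heating curves are single
exponentials; relaxation series are exactly linear plus i.i.d. noise; the
study table is affinely-mapped multivariate normal (affine maps preserve
Pearson correlations exactly, which is why the generator can hit a target
correlation matrix). Green tests therefore establish that the *algorithms
recover known ground truth under the stated noise model* — they do not
certify performance on instrument data with structured artifacts.

## 7. Reproducibility and formats

Every generator is a pure function of (specification, integer seed) and
restores the caller's RNG state. Tables are CSV with a mandatory second
header line carrying units; images are ASCII PGM (P2) with the pixel size in
a comment — plain-text formats chosen so that every artifact in the
repository is human-readable. Configs are JSON with unknown keys rejected
before any computation. The constants $k_B = 1.38\times10^{-23}$ J/K and
$\mu_0 = 1.257\times10^{-6}$ H/m default to the rounded values conventional
in this literature and can be switched to CODATA values
(`physical_constants(codata = TRUE)`).

## 8. Known limitations

* Linear response only: no stochastic Landau–Lifshitz dynamics, no
  field-dependent anisotropy, no polydispersity averaging inside the sweep
  (average over a diameter sample yourself if needed).
* Outer-sphere relaxation only; no inner-sphere or Curie-spin terms, no
  echo-time-dependent $r_2$.
* $M_{SP}$, core density, $D$, and the spin statistics of the large-crystal
  formulation are user inputs; magnetite literature values are suggested in
  the documentation but never silently assumed.
* The watershed marker rule and all kernel radii are defaults, not measured
  properties; heavily aggregated samples will under-count regardless.
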