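# Seeded generators emulating every measured input of the study. Each
# generator is a pure function of (spec, seed): it saves and restores the
# caller's RNG state, so identical calls give identical output regardless of
# surrounding code.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1) stop("seed must be one integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a core-diameter population
#'
#' Draws particle core diameters from a lognormal (default) or truncated
#' normal population. A lognormal with geometric sd around 1.2 reproduces the
#' right-skewed, long-tailed shape of measured core-diameter distributions.
#'
#' @param n number of particles (>= 1).
#' @param median_nm population median diameter, nm.
#' @param gsd geometric standard deviation (>= 1; 1 gives a monodisperse
#'   population). For the truncated-normal family the arithmetic sd is
#'   `median_nm * (gsd - 1)`.
#' @param family `"lognormal"` or `"normal-truncated"`.
#' @param seed integer seed.
#' @return List with `diameters_nm` and `ground_truth` (spec echo + seed).
#' @export
gen_diameters <- function(n, median_nm = 12, gsd = 1.2,
                          family = c("lognormal", "normal-truncated"),
                          seed = 1) {
  family <- match.arg(family)
  if (n < 1) stop("n must be >= 1")
  if (median_nm <= 0) stop("median must be > 0")
  if (gsd < 1) stop("gsd must be >= 1")
  d <- with_seed(seed, {
    if (family == "lognormal") {
      stats::rlnorm(n, meanlog = log(median_nm), sdlog = log(gsd))
    } else {
      sd <- median_nm * (gsd - 1)
      x <- stats::rnorm(n, median_nm, sd)
      while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), median_nm, sd)
      x
    }
  })
  list(diameters_nm = d,
       ground_truth = list(family = family, median_nm = median_nm, gsd = gsd,
                           n = n, seed = seed))
}

#' Render a synthetic STEM-like image
#'
#' Places anti-aliased dark disks on a bright background (the acquisition
#' contrast; the analysis pipeline's inversion step is thereby exercised),
#' optionally with a controlled fraction of particles arranged as touching
#' pairs, plus additive Gaussian pixel noise. Disk placement keeps every
#' particle fully inside the image with a margin, so border exclusion in the
#' pipeline does not remove generated particles.
#'
#' @param diameters_nm true core diameters, nm.
#' @param image_size_px image side length, px.
#' @param pixel_size_nm nm per pixel (default 0.2, typical of high-mag STEM).
#' @param touching_fraction fraction of particles placed as touching pairs
#'   (in \[0, 1\]).
#' @param noise_sd Gaussian pixel-noise sd in grey levels.
#' @param seed integer seed.
#' @param background,foreground grey levels of background and particle
#'   interior (8-bit).
#' @param max_tries placement retries per particle before giving up.
#' @return List with `image` (a [calibrated_image()]) and `ground_truth`
#'   (data frame: center_row, center_col, radius_px, diameter_nm, pair_id).
#' @export
gen_stem_image <- function(diameters_nm, image_size_px = 2000,
                           pixel_size_nm = 0.2, touching_fraction = 0,
                           noise_sd = 8, seed = 1,
                           background = 200, foreground = 60,
                           max_tries = 5000) {
  if (touching_fraction < 0 || touching_fraction > 1)
    stop("touching_fraction must be in [0, 1]")
  n <- length(diameters_nm)
  radii <- diameters_nm / (2 * pixel_size_nm)
  if (any(2 * radii + 8 > image_size_px))
    stop("a particle does not fit in the image")
  res <- with_seed(seed, {
    n_pairs <- floor(touching_fraction * n / 2)
    ord <- order(-radii)            # place large particles first
    pair_id <- integer(n)
    if (n_pairs > 0) pair_id[ord[seq_len(2 * n_pairs)]] <-
      rep(seq_len(n_pairs), each = 2)
    cy <- cx <- rep(NA_real_, n)
    gap <- 2
    ok_at <- function(y, x, r, exclude_pair = 0L) {
      placed <- which(!is.na(cy))
      if (exclude_pair > 0)
        placed <- placed[pair_id[placed] != exclude_pair]
      if (!length(placed)) return(TRUE)
      all((cy[placed] - y)^2 + (cx[placed] - x)^2 >=
            (radii[placed] + r + gap)^2)
    }
    for (pid in seq_len(max(1, n_pairs))) {
      if (n_pairs == 0) break
      mem <- which(pair_id == pid)
      r1 <- radii[mem[1]]; r2 <- radii[mem[2]]
      margin1 <- r1 + r2 * 2 + 6
      done <- FALSE
      for (try in seq_len(max_tries)) {
        y1 <- stats::runif(1, margin1, image_size_px - margin1)
        x1 <- stats::runif(1, margin1, image_size_px - margin1)
        if (!ok_at(y1, x1, r1)) next
        th <- stats::runif(1, 0, 2 * pi)
        # slight overlap so the binary mask fuses across the contact point
        dcc <- r1 + r2 - 0.5
        y2 <- y1 + dcc * sin(th); x2 <- x1 + dcc * cos(th)
        m2 <- r2 + 4
        if (y2 < m2 || y2 > image_size_px - m2 ||
            x2 < m2 || x2 > image_size_px - m2) next
        if (!ok_at(y2, x2, r2, exclude_pair = pid)) next
        cy[mem] <- c(y1, y2); cx[mem] <- c(x1, x2)
        done <- TRUE
        break
      }
      if (!done) stop("overcrowded placement: could not place a touching pair")
    }
    for (i in ord) {
      if (!is.na(cy[i])) next
      r <- radii[i]
      margin <- r + 4
      done <- FALSE
      for (try in seq_len(max_tries)) {
        y <- stats::runif(1, margin, image_size_px - margin)
        x <- stats::runif(1, margin, image_size_px - margin)
        if (ok_at(y, x, r)) { cy[i] <- y; cx[i] <- x; done <- TRUE; break }
      }
      if (!done) stop("overcrowded placement: could not place all particles")
    }
    img <- matrix(background + 0.0, image_size_px, image_size_px)
    for (i in seq_len(n)) {
      r <- radii[i]
      i0 <- max(1, floor(cy[i] - r - 2)); i1 <- min(image_size_px, ceiling(cy[i] + r + 2))
      j0 <- max(1, floor(cx[i] - r - 2)); j1 <- min(image_size_px, ceiling(cx[i] + r + 2))
      rows <- i0:i1; cols <- j0:j1
      dy <- rows - cy[i]; dx <- cols - cx[i]
      dist <- sqrt(outer(dy^2, dx^2, "+"))
      cov <- pmin(pmax(r + 0.5 - dist, 0), 1)  # 1-px anti-alias ramp
      blk <- img[rows, cols]
      img[rows, cols] <- pmin(blk, background * (1 - cov) + foreground * cov)
    }
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    list(img = pmin(pmax(round(img), 0), 255),
         truth = data.frame(center_row = cy, center_col = cx,
                            radius_px = radii, diameter_nm = diameters_nm,
                            pair_id = pair_id))
  })
  list(image = calibrated_image(res$img, pixel_size_nm, 8,
                                sprintf("synthetic STEM seed=%d", seed)),
       ground_truth = res$truth)
}

#' Generate a synthetic calorimetric heating curve
#'
#' Single-exponential Newtonian heating
#' `T(t) = T0 + dTinf (1 - exp(-t/tauc))` whose initial slope is set by
#' inverting the SAR formula: `slope = SAR * 1000 * cn / (C * rho)` (SAR in
#' W/g), so the calorimetry module applied to the output recovers `true_sar`.
#'
#' @param true_sar_w_g ground-truth SAR, W/g.
#' @param thermal a [thermal_spec()].
#' @param tau_c_s thermal equilibration time constant, s.
#' @param duration_s exposure duration, s.
#' @param dt_s sampling interval, s.
#' @param noise_sd_K additive Gaussian temperature noise, K.
#' @param T0_C starting temperature, degrees C.
#' @param seed integer seed.
#' @return List with `curve` (a [heating_curve()], unit C) and
#'   `ground_truth` (true SAR, slope, dTinf, tauc, seed).
#' @export
gen_heating_curve <- function(true_sar_w_g, thermal, tau_c_s = 1000,
                              duration_s = 3600, dt_s = 1,
                              noise_sd_K = 0.05, T0_C = 20, seed = 1) {
  stopifnot(inherits(thermal, "thermal_spec"))
  if (tau_c_s <= 0 || duration_s <= 0 || dt_s <= 0) stop("positive parameters required")
  slope <- true_sar_w_g * 1000 * thermal$cn / (thermal$C * thermal$rho)
  dTinf <- slope * tau_c_s
  t <- seq(0, duration_s, by = dt_s)
  temp <- with_seed(seed, {
    y <- T0_C + dTinf * (1 - exp(-t / tau_c_s))
    if (noise_sd_K > 0) y <- y + stats::rnorm(length(y), 0, noise_sd_K)
    y
  })
  list(curve = heating_curve(t, temp, unit = "C",
                             concentration_kg_m3 = thermal$cn),
       ground_truth = list(sar_w_g = true_sar_w_g, slope_K_s = slope,
                           dTinf_K = dTinf, tauc_s = tau_c_s, seed = seed))
}

#' Generate a linear concentration-vs-rate series
#'
#' `rate = baseline + r_true * concentration + noise`.
#'
#' @param r_true true relaxivity (rate units per concentration unit).
#' @param baseline carrier-water rate, 1/s.
#' @param concentrations strictly increasing concentrations (>= 3).
#' @param noise_sd Gaussian rate noise, 1/s.
#' @param seed integer seed.
#' @param channel,field_T metadata passed to [relaxation_series()].
#' @return List with `series` (a [relaxation_series()]) and `ground_truth`.
#' @export
gen_relaxation_series <- function(r_true, baseline, concentrations,
                                  noise_sd = 0, seed = 1,
                                  channel = "T2", field_T = 0.55) {
  rates <- with_seed(seed, {
    y <- baseline + r_true * concentrations
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    y
  })
  if (any(rates <= 0))
    stop("generated rates fell below zero; reduce noise_sd or raise baseline")
  list(series = relaxation_series(concentrations, rates, channel = channel,
                                  field_T = field_T),
       ground_truth = list(r_true = r_true, baseline = baseline,
                           noise_sd = noise_sd, seed = seed))
}

#' Generate a multi-modality property table with known correlation structure
#'
#' Draws rows from a multivariate normal with the requested correlation
#' matrix (eigen factorization, so exactly singular targets such as a
#' duplicated column are allowed) and maps each column affinely onto a
#' positive property scale. Affine maps leave Pearson correlations unchanged,
#' so the empirical correlation matrix converges to `correlation` as
#' `n_samples` grows.
#'
#' @param n_samples number of rows (nominal diameters / samples).
#' @param correlation target correlation matrix (symmetric PSD, unit
#'   diagonal); defaults to the 5x5 identity.
#' @param means,sds positive property scales per column (defaults keep all
#'   values comfortably positive).
#' @param seed integer seed.
#' @param diameters_nm optional row diameters (default an even grid
#'   over 10-30 nm).
#' @return List with `table` (data frame: diameter_nm + property columns)
#'   and `ground_truth`.
#' @export
gen_study_table <- function(n_samples, correlation = diag(5),
                            means = c(1.2, 8.0, 0.4, 9.0, 2.0),
                            sds = means / 8, seed = 1,
                            diameters_nm = NULL) {
  k <- nrow(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))))
    stop("correlation must be symmetric")
  ev <- eigen(correlation, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("correlation must be positive semidefinite")
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  X <- with_seed(seed, matrix(stats::rnorm(n_samples * k), n_samples, k) %*% t(A))
  Y <- sweep(sweep(X, 2, sds, "*"), 2, means, "+")
  cols <- c("T1_low", "T2_low", "T1_high", "T2_high", "power")
  colnames(Y) <- if (k == 5) cols else paste0("prop", seq_len(k))
  if (is.null(diameters_nm))
    diameters_nm <- seq(10, 30, length.out = n_samples)
  out <- data.frame(diameter_nm = diameters_nm, Y, check.names = FALSE)
  list(table = out,
       ground_truth = list(correlation = correlation, means = means,
                           sds = sds, n = n_samples, seed = seed))
}
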