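# Independent brute-force oracles used against the package implementations.
# These deliberately share no code with the functions they check.

# O(n^3) minimum enclosing circle: try every pair (diameter circle) and every
# triple (circumcircle), keep the smallest circle containing all points.
mec_bruteforce <- function(pts) {
  n <- nrow(pts)
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  contains_all <- function(cx, cy, r) {
    all((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= r^2 + 1e-9)
  }
  best <- NULL
  consider <- function(cx, cy, r) {
    if (contains_all(cx, cy, r) && (is.null(best) || r < best$radius))
      best <<- list(center = c(cx, cy), radius = r)
  }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cx <- (pts[i, 1] + pts[j, 1]) / 2
    cy <- (pts[i, 2] + pts[j, 2]) / 2
    consider(cx, cy, sqrt((pts[i, 1] - cx)^2 + (pts[i, 2] - cy)^2))
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- pts[i, 1]; ay <- pts[i, 2]
      bx <- pts[j, 1]; by <- pts[j, 2]
      cx <- pts[k, 1]; cy <- pts[k, 2]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
      ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
      uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
      consider(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
    }
  }
  best
}

# Brute-force Otsu: scan every candidate threshold, maximize between-class
# variance directly from the two class means.
otsu_bruteforce <- function(values, maxval) {
  best_t <- NA
  best_v <- -Inf
  for (t in 0:(maxval - 1)) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# hand-computed Pearson r from raw sums (the Sigma formula)
pearson_sums <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# a small particle/suspension fixture used across tests
fixture_suspension <- function(dm = 16e-9, ratio = 1.5, K = 21e3,
                               Msp = 4.8e5, Nm = 1e20,
                               eta = 8.9e-4, Temp = 310) {
  suspension_spec(
    particle_spec(dm, hydrodynamic_ratio = ratio, anisotropy_J_m3 = K,
                  Msp_A_m = Msp),
    medium_spec(eta, Temp),
    number_density_m3 = Nm)
}

# disk mask fixture: TRUE where pixel center within radius of (cy, cx)
disk_mask <- function(size, cy, cx, r) {
  m <- matrix(FALSE, size, size)
  for (j in 1:size) {
    dy2 <- (1:size - cy)^2
    m[, j] <- dy2 + (j - cx)^2 <= r^2
  }
  m
}
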