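#' A calibrated grayscale electron-microscopy image
#'
#' @param pixels integer matrix of grey levels, rows = image rows (origin
#'   top-left).
#' @param pixel_size_nm physical size of one pixel, nm.
#' @param bit_depth 8 or 16.
#' @param provenance free-text provenance tag.
#' @return A `calibrated_image` object.
#' @export
calibrated_image <- function(pixels, pixel_size_nm, bit_depth = 8,
                             provenance = "unknown") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxv <- 2^bit_depth - 1
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (any(px < 0) || any(px > maxv))
    stop("intensities outside the bit-depth range")
  structure(list(pixels = px, pixel_size_nm = pixel_size_nm,
                 bit_depth = as.integer(bit_depth), provenance = provenance),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("Calibrated image %d x %d px, %g nm/px, %d-bit (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$bit_depth,
              x$provenance))
  invisible(x)
}

#' Invert and median-filter an image
#'
#' First stage of the morphometry pipeline: grayscale inversion
#' (`max_value - v`, so particles acquired dark on a bright background become
#' bright on dark), then a median filter to suppress shot noise while keeping
#' edges.
#'
#' @param image a [calibrated_image()].
#' @param median_radius half-width of the square median window, px (>= 1).
#' @return A [calibrated_image()] of the same shape and bit depth.
#' @export
preprocess <- function(image, median_radius = 1) {
  stopifnot(inherits(image, "calibrated_image"))
  if (median_radius < 1) stop("median_radius must be >= 1")
  maxv <- 2L^image$bit_depth - 1L
  inv <- maxv - image$pixels
  out <- cpp_median_filter(inv, as.integer(median_radius))
  calibrated_image(out, image$pixel_size_nm, image$bit_depth,
                   paste0(image$provenance, " | inverted+median"))
}

#' Otsu's threshold
#'
#' Picks the grey level that maximizes the between-class variance of the
#' intensity histogram. Foreground is everything *strictly above* the
#' returned threshold. Ties are broken toward the lowest threshold.
#'
#' @param image a [calibrated_image()] with at least two distinct grey levels.
#' @return The threshold grey level (integer).
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  v <- as.vector(image$pixels)
  maxv <- 2L^image$bit_depth - 1L
  if (length(unique(v)) < 2) stop("constant image: no separable classes")
  h <- tabulate(v + 1L, nbins = maxv + 1L)
  n <- length(v)
  p <- h / n
  lev <- 0:maxv
  w0 <- cumsum(p)                 # P(class <= t)
  mu_t <- cumsum(p * lev)         # partial mean
  mu_T <- mu_t[length(mu_t)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(lev))
  sigma_b[valid] <- (mu_T * w0[valid] - mu_t[valid])^2 / (w0[valid] * w1[valid])
  lev[which.max(sigma_b)]         # which.max takes the first (lowest) maximum
}

#' Threshold and morphologically close a mask
#'
#' `mask = image > threshold`, then closing (dilation followed by erosion)
#' with a disk structuring element, filling holes smaller than the disk and
#' bridging 1-px gaps in particle interiors.
#'
#' @param image a [calibrated_image()].
#' @param threshold grey level; foreground strictly above.
#' @param closing_radius disk radius, px (0 disables closing).
#' @return Logical matrix mask.
#' @export
binarize_and_close <- function(image, threshold, closing_radius = 2) {
  stopifnot(inherits(image, "calibrated_image"))
  mask <- image$pixels > threshold
  if (closing_radius >= 1) {
    mask <- cpp_morph_disk(mask, as.integer(closing_radius), TRUE)
    mask <- cpp_morph_disk(mask, as.integer(closing_radius), FALSE)
  }
  mask
}

#' Separate touching particles by marker watershed
#'
#' Computes the exact Euclidean distance transform of the mask, places
#' markers at its local maxima (suppressing maxima closer together than
#' `min_marker_distance`), and floods the negated distance map from the
#' markers (8-connectivity). Touching particles split along the distance
#' ridge between their centres.
#'
#' @param mask logical matrix (foreground TRUE).
#' @param min_marker_distance minimum marker separation, px; a good default
#'   is half the expected particle diameter.
#' @return Integer label matrix (0 = background, labels contiguous 1..N).
#'   Empty mask gives an all-zero matrix.
#' @export
separate_particles <- function(mask, min_marker_distance) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("mask must be a logical matrix")
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (min_marker_distance < 1) stop("min_marker_distance must be >= 1")
  dist <- cpp_distance_transform(mask)
  r <- as.integer(ceiling(min_marker_distance))
  wmax <- cpp_window_max(dist, r)
  cand <- which(mask & dist == wmax & dist > 0)
  nr <- nrow(mask)
  ci <- (cand - 1L) %% nr + 1L
  cj <- (cand - 1L) %/% nr + 1L
  ord <- order(-dist[cand], cand)   # strongest first, raster tie-break
  ci <- ci[ord]; cj <- cj[ord]
  keep_i <- numeric(0); keep_j <- numeric(0)
  md2 <- min_marker_distance^2
  for (k in seq_along(ci)) {
    if (length(keep_i) == 0 ||
        all((keep_i - ci[k])^2 + (keep_j - cj[k])^2 >= md2)) {
      keep_i <- c(keep_i, ci[k]); keep_j <- c(keep_j, cj[k])
    }
  }
  markers <- matrix(0L, nr, ncol(mask))
  markers[cbind(keep_i, keep_j)] <- seq_along(keep_i)
  cpp_watershed(-dist, markers, mask)
}

#' Minimum enclosing circle of a 2-D point set
#'
#' Welzl's move-to-front algorithm (expected linear time).
#'
#' @param points two-column matrix of (x, y) coordinates.
#' @return List with `center` (x, y) and `radius`.
#' @export
min_enclosing_circle <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns")
  v <- cpp_min_enclosing_circle(points)
  list(center = c(v[1], v[2]), radius = v[3])
}

#' Measure per-particle diameters from a label image
#'
#' For each label, the minimum enclosing circle of its pixel centres is
#' computed; the reported diameter is `2 * radius + 1` px (the +1 px pad
#' accounts for pixel extent and keeps single-pixel regions from measuring
#' zero), converted to nm through the pixel size.
#'
#' @param labels integer label matrix from [separate_particles()].
#' @param pixel_size_nm nm per pixel.
#' @param bin_width_nm histogram bin width (default 1 nm, bins centred on
#'   integer multiples of the width).
#' @return A `diameter_distribution` object: list with `particles` (data
#'   frame: label, center_row, center_col, diameter_px, diameter_nm,
#'   area_px), `diameters_nm`, `histogram` (edges + counts), and `summary`
#'   (mean, median, mode bin centre, sd, n).
#' @export
measure_diameters <- function(labels, pixel_size_nm, bin_width_nm = 1) {
  if (!any(labels > 0)) stop("no labelled particles")
  labs <- sort(unique(labels[labels > 0]))
  recs <- lapply(labs, function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    # (x, y) = (col, row); pure convention, the circle is symmetric
    mec <- cpp_min_enclosing_circle(cbind(idx[, 2], idx[, 1]))
    d_px <- 2 * mec[3] + 1
    data.frame(label = l, center_row = mec[2], center_col = mec[1],
               diameter_px = d_px, diameter_nm = d_px * pixel_size_nm,
               area_px = nrow(idx))
  })
  particles <- do.call(rbind, recs)
  d <- particles$diameter_nm
  edges <- seq(floor(min(d) / bin_width_nm) * bin_width_nm - bin_width_nm / 2,
               ceiling(max(d) / bin_width_nm) * bin_width_nm + bin_width_nm / 2,
               by = bin_width_nm)
  counts <- as.integer(table(cut(d, edges, right = FALSE)))
  mode_center <- edges[which.max(counts)] + bin_width_nm / 2
  structure(list(particles = particles, diameters_nm = d,
                 histogram = list(edges_nm = edges, counts = counts),
                 summary = list(mean_nm = mean(d), median_nm = stats::median(d),
                                mode_nm = mode_center, sd_nm = stats::sd(d),
                                n = length(d))),
            class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Diameter distribution: n = %d, mean %.2f nm, median %.2f nm, mode %.1f nm, sd %.2f nm\n",
              s$n, s$mean_nm, s$median_nm, s$mode_nm, s$sd_nm))
  invisible(x)
}

#' Default morphometry pipeline configuration
#'
#' @param median_radius median window half-width, px.
#' @param closing_radius closing disk radius, px.
#' @param expected_diameter_nm expected particle diameter; the marker
#'   suppression distance defaults to half of it (in px).
#' @param min_marker_distance_px explicit marker distance override, px.
#' @param exclude_border drop particles touching the image edge
#'   (their enclosing circles would be clipped).
#' @param bin_width_nm histogram bin width.
#' @return A named list of settings.
#' @export
tem_config <- function(median_radius = 1, closing_radius = 2,
                       expected_diameter_nm = 12,
                       min_marker_distance_px = NULL,
                       exclude_border = TRUE, bin_width_nm = 1) {
  list(median_radius = median_radius, closing_radius = closing_radius,
       expected_diameter_nm = expected_diameter_nm,
       min_marker_distance_px = min_marker_distance_px,
       exclude_border = exclude_border, bin_width_nm = bin_width_nm)
}

#' Run the full morphometry pipeline
#'
#' Composes the five stages in acquisition order: inversion + median filter,
#' Otsu threshold, closing, distance-transform/watershed separation, and
#' minimum-enclosing-circle measurement.
#'
#' @param image a [calibrated_image()] (particles dark on bright, as
#'   acquired).
#' @param config a [tem_config()] list.
#' @param debug when TRUE, attach per-stage intermediates
#'   (`preprocessed`, `threshold`, `mask`) to the result.
#' @return A list with `segmentation` (list: mask, labels, particles) and
#'   `distribution` (a `diameter_distribution`).
#' @export
run_tem_pipeline <- function(image, config = tem_config(), debug = FALSE) {
  stopifnot(inherits(image, "calibrated_image"))
  pre <- preprocess(image, config$median_radius)
  thr <- otsu_threshold(pre)
  mask <- binarize_and_close(pre, thr, config$closing_radius)
  md <- config$min_marker_distance_px
  if (is.null(md))
    md <- max(2, 0.5 * config$expected_diameter_nm / image$pixel_size_nm)
  labels <- separate_particles(mask, md)
  if (config$exclude_border && any(labels > 0)) {
    nr <- nrow(labels); nc <- ncol(labels)
    border <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
    border <- border[border > 0]
    if (length(border)) labels[labels %in% border] <- 0L
    # re-densify labels to 1..N
    old <- sort(unique(labels[labels > 0]))
    if (length(old)) {
      map <- integer(max(old)); map[old] <- seq_along(old)
      pos <- labels > 0
      labels[pos] <- map[labels[pos]]
    }
  }
  if (!any(labels > 0))
    stop("no particles survived segmentation")
  dist <- measure_diameters(labels, image$pixel_size_nm, config$bin_width_nm)
  seg <- list(mask = mask, labels = labels, particles = dist$particles)
  out <- list(segmentation = seg, distribution = dist)
  if (debug) out$debug <- list(preprocessed = pre, threshold = thr, mask = mask)
  out
}
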