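# Format dialects. Columns carry units in their names (time_s, diameter_nm,
# ...) and every table file has a second header line repeating the units, so
# a file can never silently drift to other units. Images travel as ASCII PGM
# (P2), a plain-text raster format with explicit maximum grey value.

#' Write / read a units-annotated CSV table
#'
#' Two header lines: column names, then a `# units:` line. Reading a file
#' without the units line is an explicit parse error.
#'
#' @param x data frame to write.
#' @param path file path.
#' @param units character vector of unit strings, one per column.
#' @return `read_table_units()` returns the data frame with a `units`
#'   attribute; `write_table_units()` returns `path` invisibly.
#' @export
write_table_units <- function(x, path, units) {
  if (length(units) != ncol(x)) stop("one unit string per column required")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = ","), con)
  writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_table_units
#' @export
read_table_units <- function(path) {
  lines <- readLines(path, n = 2)
  if (length(lines) < 2 || !startsWith(lines[2], "# units:"))
    stop("parse error at line 2 of ", path, ": missing '# units:' row")
  units <- strsplit(sub("^# units: ?", "", lines[2]), ",")[[1]]
  out <- utils::read.csv(path, header = TRUE, comment.char = "#")
  # strsplit drops trailing empty fields (unitless last columns)
  units <- c(units, rep("", max(0, ncol(out) - length(units))))
  attr(out, "units") <- units
  out
}

#' Write / read a grayscale image as ASCII PGM (P2)
#'
#' @param image a [calibrated_image()] (the pixel size is stored in a PGM
#'   comment line and recovered on read).
#' @param path file path.
#' @return `read_pgm()` returns a [calibrated_image()]; `write_pgm()` returns
#'   `path` invisibly.
#' @export
write_pgm <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  maxv <- 2L^image$bit_depth - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  writeLines(sprintf("# pixel_size_nm %.10g", image$pixel_size_nm), con)
  writeLines(sprintf("%d %d", ncol(image$pixels), nrow(image$pixels)), con)
  writeLines(sprintf("%d", maxv), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(image$pixels, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4 || trimws(lines[1]) != "P2")
    stop("parse error at line 1 of ", path, ": not an ASCII PGM (P2) file")
  px_size <- 1
  i <- 2
  while (startsWith(lines[i], "#")) {
    m <- regmatches(lines[i], regexec("# pixel_size_nm ([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2) px_size <- as.numeric(m[2])
    i <- i + 1
  }
  dims <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
  maxv <- as.integer(trimws(lines[i + 1]))
  depth <- if (maxv > 255) 16L else 8L
  vals <- as.integer(unlist(strsplit(trimws(lines[(i + 2):length(lines)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2])
    stop("parse error in ", path, ": expected ", dims[1] * dims[2],
         " pixels, found ", length(vals))
  px <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  calibrated_image(px, px_size, depth, provenance = path)
}

#' Read a concentration-rate table
#'
#' Expects the units-annotated CSV dialect with columns `concentration`,
#' `rate`, `channel`, `field_T` (one channel/field per file or filtered by
#' the arguments).
#'
#' @param path CSV path.
#' @param channel,field_T optional filters when the file mixes series.
#' @return A [relaxation_series()].
#' @export
read_relaxation_csv <- function(path, channel = NULL, field_T = NULL) {
  tab <- read_table_units(path)
  need <- c("concentration", "rate", "channel", "field_T")
  if (!all(need %in% names(tab)))
    stop("parse error in ", path, ": need columns ", paste(need, collapse = ", "))
  if (!is.null(channel)) tab <- tab[tab$channel == channel, ]
  if (!is.null(field_T)) tab <- tab[tab$field_T == field_T, ]
  if (length(unique(tab$channel)) != 1 || length(unique(tab$field_T)) != 1)
    stop("file mixes channels/fields; pass channel= and field_T= filters")
  ord <- order(tab$concentration)
  relaxation_series(tab$concentration[ord], tab$rate[ord],
                    channel = tab$channel[1], field_T = tab$field_T[1],
                    concentration_unit = attr(tab, "units")[1])
}

#' Read a calorimetry log
#'
#' Units-annotated CSV with columns `time_s`, `temperature_C` and optional
#' metadata comment lines `# meta: key value` (frequency_Hz, induction_T,
#' concentration_kg_m3).
#'
#' @param path CSV path.
#' @return A [heating_curve()].
#' @export
read_heating_csv <- function(path) {
  lines <- readLines(path)
  meta <- list(frequency_Hz = NA_real_, induction_T = NA_real_,
               concentration_kg_m3 = NA_real_)
  for (l in grep("^# meta:", lines, value = TRUE)) {
    kv <- strsplit(sub("^# meta: ?", "", l), "\\s+")[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  tab <- read_table_units(path)
  if (!all(c("time_s", "temperature_C") %in% names(tab)))
    stop("parse error in ", path, ": need columns time_s, temperature_C")
  heating_curve(tab$time_s, tab$temperature_C, unit = "C",
                frequency_Hz = meta$frequency_Hz,
                induction_T = meta$induction_T,
                concentration_kg_m3 = meta$concentration_kg_m3)
}

#' Write a heating curve in the calorimetry-log dialect
#'
#' @param curve a [heating_curve()].
#' @param path file path.
#' @export
write_heating_csv <- function(curve, path) {
  stopifnot(inherits(curve, "heating_curve"))
  con <- file(path, "w")
  writeLines("time_s,temperature_C", con)
  writeLines("# units: s,C", con)
  for (k in c("frequency_Hz", "induction_T", "concentration_kg_m3")) {
    v <- attr(curve, k)
    if (!is.na(v)) writeLines(sprintf("# meta: %s %.10g", k, v), con)
  }
  temp <- curve$temperature
  if (attr(curve, "unit") == "K") temp <- temp - 273.15
  utils::write.table(data.frame(curve$time_s, temp), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x a report object (e.g. [feasibility_report()]) or plain list.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "feasibility_report")) x <- report_as_list(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
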