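#' Pairwise Pearson correlation matrix with significance labels
#'
#' Pearson correlations between all property columns, with two-sided p-values
#' from the t statistic `t = r sqrt((n-2)/(1-r^2))` on `n-2` degrees of
#' freedom. Labels follow the conventional thresholds: `significant` for
#' p < 0.05, `trend` for 0.05 <= p < 0.1, `ns` otherwise. A zero-variance
#' column yields `NA` correlations with a warning. An optional Bonferroni
#' correction (off by default, matching the usual presentation of such
#' tables) multiplies p-values by the number of distinct pairs.
#'
#' @param table data frame of numeric property columns (a `diameter_nm`
#'   column, if present, is treated as a row identifier and dropped);
#'   >= 3 rows.
#' @param bonferroni apply Bonferroni correction to p-values.
#' @return A `correlation_report` list: `r` (matrix), `p` (matrix), `labels`
#'   (character matrix), `n`, `method`, `bonferroni`.
#' @export
pearson_matrix <- function(table, bonferroni = FALSE) {
  tab <- as.data.frame(table)
  if ("diameter_nm" %in% names(tab))
    tab <- tab[setdiff(names(tab), "diameter_nm")]
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("all property columns must be numeric")
  n <- nrow(tab)
  if (n < 3) stop("need >= 3 complete rows")
  if (anyNA(tab)) stop("missing cells are not supported")
  k <- ncol(tab)
  zerovar <- vapply(tab, function(x) stats::var(x) == 0, logical(1))
  if (any(zerovar))
    warning("zero-variance column(s): ", paste(names(tab)[zerovar], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(tab))
  diag(r) <- ifelse(zerovar, NA_real_, 1)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0  # |r| = 1: t is infinite, p exactly 0
  diag(p) <- NA_real_
  if (bonferroni) p <- pmin(p * k * (k - 1) / 2, 1)
  labels <- matrix("ns", k, k, dimnames = dimnames(r))
  labels[!is.na(p) & p < 0.1] <- "trend"
  labels[!is.na(p) & p < 0.05] <- "significant"
  diag(labels) <- ""
  labels[is.na(r)] <- "undefined"
  structure(list(r = r, p = p, labels = labels, n = n,
                 method = "pearson", bonferroni = bonferroni),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation matrix (n = %d%s):\n", x$n,
              if (x$bonferroni) ", Bonferroni-corrected" else ""))
  print(round(x$r, digits))
  cat("labels (p < 0.05 significant, 0.05 <= p < 0.1 trend):\n")
  print(x$labels, quote = FALSE)
  invisible(x)
}

# indices of grid points within `fraction` of the curve maximum
plateau_range <- function(values, fraction) {
  which(values >= (1 - fraction) * max(values))
}

#' Optimum-diameter overlap of relaxivity and heating curves
#'
#' Finds, for each curve, the "maximum range": all grid diameters whose value
#' is within `plateau_fraction` of the curve's peak. The joint optimum is the
#' intersection of the r2 and heating-power maximum ranges - the diameter
#' window in which one formulation would be near-best for both T2 contrast
#' and hyperthermia.
#'
#' @param diameters_nm common diameter grid.
#' @param r1,r2,power curve values on that grid.
#' @param plateau_fraction relative drop from the peak still counted as
#'   "maximum" (default 0.05).
#' @return An `overlap_report` list: per-curve `argmax_nm` and `range_nm`
#'   (min/max of the plateau), `overlap_nm` (NULL when empty), `verdict`.
#' @export
optimum_overlap <- function(diameters_nm, r1, r2, power,
                            plateau_fraction = 0.05) {
  n <- length(diameters_nm)
  if (length(r1) != n || length(r2) != n || length(power) != n)
    stop("curves must share the diameter grid")
  cur <- list(r1 = r1, r2 = r2, power = power)
  res <- lapply(cur, function(v) {
    idx <- plateau_range(v, plateau_fraction)
    list(argmax_nm = diameters_nm[which.max(v)],
         range_nm = range(diameters_nm[idx]), idx = idx)
  })
  joint <- intersect(res$r2$idx, res$power$idx)
  overlap <- if (length(joint)) range(diameters_nm[joint]) else NULL
  verdict <- if (length(joint))
    sprintf(paste0("joint optimum exists: diameters %.3g-%.3g nm are within ",
                   "%.0f%% of both the r2 and the heating-power maxima"),
            overlap[1], overlap[2], 100 * plateau_fraction)
  else "no joint optimum: the r2 and heating-power maximum ranges are disjoint"
  structure(list(r1 = res$r1[1:2], r2 = res$r2[1:2], power = res$power[1:2],
                 overlap_nm = overlap, verdict = verdict,
                 plateau_fraction = plateau_fraction,
                 diameters_nm = diameters_nm),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Optimum-diameter overlap:\n")
  for (nm in c("r1", "r2", "power"))
    cat(sprintf("  %-5s argmax %.3g nm, maximum range %.3g-%.3g nm\n", nm,
                x[[nm]]$argmax_nm, x[[nm]]$range_nm[1], x[[nm]]$range_nm[2]))
  cat(" ", x$verdict, "\n")
  invisible(x)
}

#' Cross-modality feasibility report
#'
#' Bundles the correlation analysis of a property table with the
#' optimum-diameter overlap of model or measured curves into one structured
#' report (suitable for JSON serialization and a human-readable summary).
#'
#' @param property_table data frame for [pearson_matrix()]; a `power` column
#'   is optional - when absent the correlation section covers the remaining
#'   columns and a warning is recorded.
#' @param curves optional list with `diameters_nm`, `r1`, `r2`, `power`
#'   vectors for [optimum_overlap()].
#' @param plateau_fraction passed to [optimum_overlap()].
#' @param bonferroni passed to [pearson_matrix()].
#' @return A `feasibility_report` list: `correlations`, `overlap` (or NULL),
#'   `warnings`, `parameters`.
#' @export
feasibility_report <- function(property_table, curves = NULL,
                               plateau_fraction = 0.05, bonferroni = FALSE) {
  warns <- character(0)
  if (!("power" %in% names(property_table))) {
    warns <- c(warns, "no 'power' column: power correlations omitted")
    warning("no 'power' column: power correlations omitted")
  }
  if (nrow(property_table) <= 3)
    warns <- c(warns, "very few rows: confidence in correlations is low (wide CIs)")
  corr <- pearson_matrix(property_table, bonferroni = bonferroni)
  ovl <- NULL
  if (!is.null(curves)) {
    ovl <- optimum_overlap(curves$diameters_nm, curves$r1, curves$r2,
                           curves$power, plateau_fraction)
  }
  structure(list(correlations = corr, overlap = ovl, warnings = warns,
                 parameters = list(plateau_fraction = plateau_fraction,
                                   bonferroni = bonferroni,
                                   correlation_method = "pearson")),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("=== Feasibility report ===\n")
  print(x$correlations)
  if (!is.null(x$overlap)) print(x$overlap)
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

# plain-list view of a feasibility report for JSON output
report_as_list <- function(x) {
  stopifnot(inherits(x, "feasibility_report"))
  out <- list(
    correlation = list(method = x$correlations$method,
                       n = x$correlations$n,
                       variables = colnames(x$correlations$r),
                       r = x$correlations$r,
                       p = x$correlations$p,
                       labels = x$correlations$labels),
    parameters = x$parameters,
    warnings = x$warnings)
  if (!is.null(x$overlap)) {
    ov <- x$overlap
    out$overlap <- list(
      r1 = ov$r1, r2 = ov$r2, power = ov$power,
      overlap_nm = if (is.null(ov$overlap_nm)) NULL else ov$overlap_nm,
      verdict = ov$verdict)
  }
  out
}
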