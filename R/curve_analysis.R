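# Force-elongation curve I/O and the summary statistics reported for
# tensile tests of capture threads: radial peak / post-radial peak forces,
# strain at break, sawtooth drop events, plus the vertical-test geometry
# (Pythagoras on hook travel) and the microbalance weight-to-force
# conversion.

#' Force-elongation curve container
#'
#' @param strain Strictly increasing numeric vector (dimensionless).
#' @param force Numeric vector of the same length; finite, in mN for
#'   empirical data or relative units for simulations.
#' @param units Units tag for the force column (`"mN"`, `"relative"`, ...).
#' @param gauge_length Optional gauge length in mm (metadata only).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(strain, force, units = "relative",
                        gauge_length = NULL) {
  if (length(strain) != length(force))
    stop("strain and force must have equal length")
  if (length(strain) == 0) stop("empty curve")
  if (any(!is.finite(force)))
    stop("non-finite force at row ", which(!is.finite(force))[1])
  if (is.unsorted(strain, strictly = TRUE)) {
    bad <- which(diff(strain) <= 0)[1] + 1L
    stop("strain must be strictly increasing (violated at row ", bad, ")")
  }
  structure(list(strain = as.numeric(strain), force = as.numeric(force),
                 units = units, gauge_length = gauge_length),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points, strain [%g, %g], peak force %g %s\n",
              length(x$strain), min(x$strain), max(x$strain), max(x$force),
              x$units))
  invisible(x)
}

#' Read / write force-elongation curves as CSV
#'
#' Two-column CSV with header `strain,force`; metadata (units tag, optional
#' gauge length in mm) is carried in leading `# key: value` comment lines.
#' Simulation curves written by [write_simulation()] use the same format.
#'
#' @param path File path.
#' @param curve A [force_curve()].
#' @return `read_curve()`: a `force_curve`. `write_curve()`: the path,
#'   invisibly.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  units <- "relative"
  gauge <- NULL
  for (m in meta_lines) {
    kv <- regmatches(m, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", m))[[1]]
    if (length(kv) == 3) {
      if (kv[2] == "units") units <- trimws(kv[3])
      if (kv[2] == "gauge_length_mm") gauge <- as.numeric(kv[3])
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("strain", "force") %in% names(df)))
    stop("curve CSV must have columns `strain` and `force`: ", path)
  force_curve(df$strain, df$force, units = units, gauge_length = gauge)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", curve$units), con)
  if (!is.null(curve$gauge_length))
    writeLines(paste0("# gauge_length_mm: ", format(curve$gauge_length)), con)
  utils::write.csv(data.frame(strain = curve$strain, force = curve$force),
                   con, row.names = FALSE)
  invisible(path)
}

#' Detect sawtooth force drops in a curve
#'
#' Scans the curve for maximal strictly decreasing runs; each run whose
#' relative drop `1 - force_after / force_before` is at least `min_rel_drop`
#' becomes one drop event. This recovers the sawtooth teeth caused by loop
#' openings and element failures, provided the failing element carries a
#' non-negligible share of the total force.
#'
#' @param curve A [force_curve()].
#' @param min_rel_drop Minimum relative drop in `(0, 1)` for a run to count.
#' @return A data.frame with columns `strain` (where the drop ends),
#'   `force_before`, `force_after`.
#' @export
detect_drops <- function(curve, min_rel_drop = 0.05) {
  stopifnot(inherits(curve, "force_curve"),
            min_rel_drop > 0, min_rel_drop < 1)
  f <- curve$force
  n <- length(f)
  out <- list()
  i <- 1L
  while (i < n) {
    if (f[i + 1L] < f[i]) {
      j <- i + 1L
      while (j < n && f[j + 1L] < f[j]) j <- j + 1L
      if (f[i] > 0 && (1 - f[j] / f[i]) >= min_rel_drop)
        out[[length(out) + 1L]] <- data.frame(
          strain = curve$strain[j], force_before = f[i], force_after = f[j])
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(strain = numeric(), force_before = numeric(),
                      force_after = numeric()))
  do.call(rbind, out)
}

#' Summarize a force-elongation curve
#'
#' Computes the tensile summary reported for capture-thread tests:
#' \describe{
#'   \item{radial_peak_force}{the global force maximum — in a full axial test
#'     the stiff radial line dominates every later force, so its failure peak
#'     is the global maximum (assumption; see `radial`)}
#'   \item{strain_at_radial_peak}{strain of that maximum}
#'   \item{post_radial_peak_force}{largest force at strains beyond the radial
#'     peak (the "peak force before break" of the unravelling bands)}
#'   \item{strain_at_break}{largest strain with force above `noise_floor`
#'     times the global maximum}
#'   \item{drops}{sawtooth drop events from [detect_drops()]}
#' }
#' For curves without a radial carrier (e.g. vertical tension tests on the
#' band alone) set `radial = FALSE`: only the overall peak and the break
#' strain are reported and the radial fields are `NA`.
#'
#' @param curve A [force_curve()] with at least one positive force.
#' @param noise_floor Fraction of the global maximum force below which the
#'   thread is considered broken (default 1%).
#' @param radial Does the curve include a radial carrier failure peak?
#' @param min_rel_drop Passed to [detect_drops()].
#' @return An object of class `curve_summary`.
#' @export
summarize_curve <- function(curve, noise_floor = 0.01, radial = TRUE,
                            min_rel_drop = 0.05) {
  stopifnot(inherits(curve, "force_curve"))
  fmax <- max(curve$force)
  if (fmax <= 0) stop("curve carries no load: cannot summarize")
  ipk <- which.max(curve$force)
  floor_f <- noise_floor * fmax
  above <- which(curve$force > floor_f)
  strain_break <- curve$strain[max(above)]
  post <- curve$force[curve$strain > curve$strain[ipk]]
  out <- list(
    peak_force = fmax,
    radial_peak_force = if (radial) fmax else NA_real_,
    strain_at_radial_peak = if (radial) curve$strain[ipk] else NA_real_,
    post_radial_peak_force = if (radial && length(post)) max(post) else NA_real_,
    strain_at_break = strain_break,
    drops = detect_drops(curve, min_rel_drop),
    noise_floor = noise_floor, units = curve$units
  )
  structure(out, class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat("<curve_summary>\n")
  cat(sprintf("  peak force:             %g %s\n", x$peak_force, x$units))
  if (!is.na(x$radial_peak_force)) {
    cat(sprintf("  radial peak:            %g at strain %g\n",
                x$radial_peak_force, x$strain_at_radial_peak))
    cat(sprintf("  post-radial peak force: %g\n", x$post_radial_peak_force))
  }
  cat(sprintf("  strain at break:        %g (%.0f%%)\n", x$strain_at_break,
              100 * x$strain_at_break))
  cat(sprintf("  sawtooth drop events:   %d\n", nrow(x$drops)))
  invisible(x)
}

#' Serialize a curve summary
#'
#' Writes the summary as JSON and, optionally, as a one-row CSV with the
#' column names used for reporting tensile results (`radial_line_peak_force`,
#' `peak_force_before_break`, `strain_at_peak_force`, `strain_at_break`).
#'
#' @param summary A `curve_summary`.
#' @param json_path,csv_path Output paths (`NULL` to skip one of them).
#' @return Invisibly, the paths written.
#' @export
write_summary <- function(summary, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(summary, "curve_summary"))
  written <- character()
  if (!is.null(json_path)) {
    s <- unclass(summary)
    s$drops <- NULL
    s$n_drops <- nrow(summary$drops)
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(
      radial_line_peak_force = summary$radial_peak_force,
      peak_force_before_break = summary$post_radial_peak_force,
      strain_at_peak_force = summary$strain_at_radial_peak,
      strain_at_break = summary$strain_at_break), csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' Strain of a vertically plucked thread from hook travel
#'
#' In a vertical tension test a hook snags the middle of a thread of length
#' `2 * half_length` and pulls perpendicularly by `travel`. Each half
#' stretches from `half_length` to `sqrt(half_length^2 + travel^2)`
#' (Pythagoras), so the engineering strain of the thread is
#' `(2 * sqrt(half_length^2 + travel^2) - 2 * half_length) /
#' (2 * half_length)`.
#'
#' @param travel Perpendicular hook travel, mm (`>= 0`; vectorized).
#' @param half_length Half the free thread length, mm (`> 0`).
#' @return Dimensionless strain.
#' @examples
#' vertical_strain_from_travel(4.25, 4.25) # sqrt(2) - 1
#' @export
vertical_strain_from_travel <- function(travel, half_length) {
  if (any(half_length <= 0)) stop("half_length must be > 0")
  if (any(travel < 0)) stop("travel must be >= 0")
  (2 * sqrt(half_length^2 + travel^2) - 2 * half_length) / (2 * half_length)
}

#' Convert a microbalance weight reading to force
#'
#' A thread plucked upwards from a sample on a balance reduces the apparent
#' weight; the pull force is the magnitude of the (negative) reading times
#' standard gravity. Unit contract: grams x 9.81 m/s^2 = mN.
#'
#' @param min_weight_reading Balance reading in grams (typically negative at
#'   peak pull; vectorized).
#' @return Force in mN.
#' @examples
#' force_from_weight(-0.301) # ~2.95 mN
#' @export
force_from_weight <- function(min_weight_reading) {
  stopifnot(all(is.finite(min_weight_reading)))
  abs(min_weight_reading) * 9.81
}
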