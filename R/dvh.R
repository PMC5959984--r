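#' Cumulative dose-volume histogram
#'
#' Stores volume-at-or-above-dose sampled at ascending dose edges. The
#' first entry is the total structure volume; the curve is non-increasing.
#'
#' @param dose_edges Ascending dose values in Gy (left bin edges).
#' @param volume Volume (cm^3) receiving at least each dose edge.
#' @return An object of class `cumulative_dvh`.
#' @export
cumulative_dvh <- function(dose_edges, volume) {
  if (length(dose_edges) != length(volume) || length(volume) < 2)
    stop("dose_edges and volume must have equal length >= 2")
  if (any(diff(dose_edges) <= 0)) stop("dose_edges must be strictly ascending")
  if (any(diff(volume) > 1e-9 * max(volume, 1)))
    stop("volume must be non-increasing with dose")
  if (any(volume < 0)) stop("volumes must be non-negative")
  structure(list(dose_edges = dose_edges, volume = volume,
                 total_volume = volume[1]),
            class = "cumulative_dvh")
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH: %d bins over [%.3g, %.3g] Gy, total %.3f cm^3\n",
              length(x$dose_edges), min(x$dose_edges), max(x$dose_edges),
              x$total_volume))
  invisible(x)
}

#' Build a cumulative DVH from a dose grid and a structure mask
#'
#' Bin `b` holds the volume of masked voxels whose dose is at or above the
#' left edge of `b`.
#'
#' @param grid A [render_grid()] result.
#' @param mask Mask name (`"gtv"`, `"ptv"`, `"healthy"`) or logical array.
#' @param bin_width Dose bin width in Gy (default 0.1).
#' @return A [cumulative_dvh()].
#' @export
dvh_from_grid <- function(grid, mask, bin_width = 0.1) {
  stopifnot(inherits(grid, "dose_grid"))
  if (bin_width <= 0) stop("bin_width must be positive")
  m <- if (is.character(mask)) grid[[mask]] else mask
  doses <- grid$dose[m]
  if (length(doses) == 0) stop("empty structure")
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  sorted <- sort(doses)
  # count of voxels with dose >= edge; nudge the edge down so voxels landing
  # exactly on an edge are counted in that bin
  n_below <- findInterval(edges - 1e-9 * bin_width, sorted)
  cumulative_dvh(edges, (length(sorted) - n_below) * grid$voxel_volume)
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation between DVH dose edges. Doses above the last edge
#' return 0; doses at or below the first edge return the total volume.
#'
#' @param dvh A [cumulative_dvh()].
#' @param level Dose level in Gy. Vectorised.
#' @return Volume in cm^3.
#' @export
v_at_dose <- function(dvh, level) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  stats::approx(dvh$dose_edges, dvh$volume, xout = level,
                yleft = dvh$total_volume, yright = 0, ties = "ordered")$y
}

#' Highest dose received by at least a given volume
#'
#' Generalised inverse of [v_at_dose()]: the largest dose whose
#' volume-at-or-above is still `volume`. On flat DVH segments the tie is
#' broken toward the higher dose, which makes isotoxic renormalisation
#' conservative.
#'
#' @param dvh A [cumulative_dvh()].
#' @param volume Volume in cm^3 (0 < volume <= total volume).
#' @return Dose in Gy.
#' @export
d_at_volume <- function(dvh, volume) {
  stopifnot(inherits(dvh, "cumulative_dvh"), length(volume) == 1)
  if (volume > dvh$total_volume * (1 + 1e-12))
    stop("requested volume exceeds total structure volume")
  if (volume <= 0) stop("requested volume must be positive")
  v <- dvh$volume
  d <- dvh$dose_edges
  i <- max(which(v >= volume))          # last edge still attaining the volume
  if (i == length(v)) return(d[i])
  if (v[i] == volume) return(d[i])      # ties broken toward higher dose
  d[i] + (v[i] - volume) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
}

#' Rescale a DVH by a global dose factor
#'
#' Multiplies the dose axis by `factor` (the effect of altering monitor
#' units); volumes are untouched, so `v_at_dose(rescaled, x)` equals
#' `v_at_dose(original, x / factor)` exactly.
#'
#' @param dvh A [cumulative_dvh()].
#' @param factor Positive scale factor.
#' @return A rescaled [cumulative_dvh()].
#' @export
rescale_dvh <- function(dvh, factor) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  cumulative_dvh(dvh$dose_edges * factor, dvh$volume)
}

#' RTOG conformity index
#'
#' CI = volume of the prescription isodose / PTV volume. For a calibrated
#' radial model this is evaluated in closed form; for a grid by voxel
#' counting.
#'
#' @param x A `radial_plan_model` or a `dose_grid`.
#' @param rx_dose Prescription dose in Gy (defaults to the model's).
#' @param ... Unused.
#' @return Dimensionless conformity index.
#' @export
rtog_ci <- function(x, rx_dose = NULL, ...) UseMethod("rtog_ci")

#' @export
rtog_ci.radial_plan_model <- function(x, rx_dose = NULL, ...) {
  rx <- if (is.null(rx_dose)) x$rx_dose else rx_dose
  if (rx <= 0) stop("rx_dose must be positive")
  v_rx <- 4 * pi / 3 * radius_at_dose(x, rx)^3
  if (v_rx == 0) stop("prescription isodose volume is zero")
  v_rx / x$v_ptv
}

#' @export
rtog_ci.dose_grid <- function(x, rx_dose, ...) {
  if (missing(rx_dose) || rx_dose <= 0) stop("rx_dose must be positive")
  v_rx <- sum(x$dose >= rx_dose) * x$voxel_volume
  if (v_rx == 0) stop("prescription isodose volume is zero")
  v_rx / mask_volume(x, "ptv")
}

#' Paddick gradient index
#'
#' GI = volume of the half-prescription isodose / volume of the
#' prescription isodose.
#'
#' @inheritParams rtog_ci
#' @return Dimensionless gradient index (> 1 for any falling dose).
#' @export
paddick_gi <- function(x, rx_dose = NULL, ...) UseMethod("paddick_gi")

#' @export
paddick_gi.radial_plan_model <- function(x, rx_dose = NULL, ...) {
  rx <- if (is.null(rx_dose)) x$rx_dose else rx_dose
  if (rx <= 0) stop("rx_dose must be positive")
  r_rx <- radius_at_dose(x, rx)
  if (r_rx == 0) stop("prescription isodose volume is zero")
  (radius_at_dose(x, rx / 2) / r_rx)^3
}

#' @export
paddick_gi.dose_grid <- function(x, rx_dose, ...) {
  if (missing(rx_dose) || rx_dose <= 0) stop("rx_dose must be positive")
  v_rx <- sum(x$dose >= rx_dose)
  if (v_rx == 0) stop("prescription isodose volume is zero")
  sum(x$dose >= rx_dose / 2) / v_rx
}

#' Write / read a cumulative DVH as two-column CSV
#'
#' Columns `dose_gy` and `volume_cm3`.
#'
#' @param dvh A [cumulative_dvh()].
#' @param path File path.
#' @return `write_dvh()` returns `path` invisibly; `read_dvh()` a
#'   [cumulative_dvh()].
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  utils::write.csv(
    data.frame(dose_gy = dvh$dose_edges, volume_cm3 = dvh$volume),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(path) {
  df <- utils::read.csv(path)
  cumulative_dvh(df$dose_gy, df$volume_cm3)
}
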