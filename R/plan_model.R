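#' Plan-quality indices of a VMAT SRS plan
#'
#' The four indices that summarise one plan: maximum and mean PTV dose as a
#' percentage of the prescription, the RTOG conformity index
#' (CI = prescription-isodose volume / PTV volume) and the Paddick gradient
#' index (GI = half-prescription-isodose volume / prescription-isodose
#' volume).
#'
#' @param dmax_pct Maximum PTV dose, % of prescription (>= 100).
#' @param dmean_pct Mean PTV dose, % of prescription.
#' @param rtog_ci RTOG conformity index (> 0).
#' @param paddick_gi Paddick gradient index (> 1).
#' @return An object of class `plan_quality`.
#' @export
plan_quality <- function(dmax_pct, dmean_pct, rtog_ci, paddick_gi) {
  if (paddick_gi <= 1) stop("paddick_gi must exceed 1 (dose must fall off)")
  if (rtog_ci <= 0) stop("rtog_ci must be positive")
  if (dmax_pct < 100) stop("dmax_pct must be at least 100")
  structure(list(dmax_pct = dmax_pct, dmean_pct = dmean_pct,
                 rtog_ci = rtog_ci, paddick_gi = paddick_gi),
            class = "plan_quality")
}

#' Calibrate the radial power-law dose-falloff model
#'
#' A radially symmetric surrogate for a planned VMAT dose distribution.
#' Outside the prescription isodose sphere the dose follows a power law
#' \eqn{D(r) = D_{rx} (r_{rx}/r)^k}; inside it ramps linearly from the
#' tabulated maximum dose at the centre down to the prescription dose at
#' the sphere surface. The two free parameters are fixed by the plan's
#' conformity and gradient indices:
#' \deqn{r_{rx} = (3\,CI\,V_{PTV} / 4\pi)^{1/3}, \qquad
#'       k = 3\ln 2 / \ln GI,}
#' so that the recomputed RTOG CI and Paddick GI reproduce the inputs
#' exactly.
#'
#' @param target A [spherical_target()].
#' @param quality A [plan_quality()].
#' @param rx_dose Prescription dose in Gy (> 0).
#' @return An object of class `radial_plan_model`.
#' @examples
#' t <- spherical_target(4, 0)
#' q <- plan_quality(112, 97, 1.0, 2.6)
#' m <- calibrate_radial_model(t, q, 15)
#' m$k   # 3 ln2 / ln 2.6 = 2.176
#' @export
calibrate_radial_model <- function(target, quality, rx_dose) {
  stopifnot(inherits(target, "spherical_target"),
            inherits(quality, "plan_quality"))
  if (rx_dose <= 0) stop("rx_dose must be positive")
  r_rx <- (3 * quality$rtog_ci * target$ptv_volume / (4 * pi))^(1 / 3)
  k <- 3 * log(2) / log(quality$paddick_gi)
  structure(
    list(rx_dose = rx_dose, r_rx = r_rx, k = k,
         dmax_pct = quality$dmax_pct,
         v_gtv = target$gtv_volume, v_ptv = target$ptv_volume,
         r_gtv = target$gtv_diameter / 2, r_ptv = target$ptv_diameter / 2,
         target = target, quality = quality),
    class = "radial_plan_model"
  )
}

#' @export
print.radial_plan_model <- function(x, ...) {
  cat(sprintf(
    "Radial plan model: rx %.4g Gy at r_rx = %.3f cm, falloff exponent k = %.3f\n",
    x$rx_dose, x$r_rx, x$k))
  cat(sprintf("  GTV %.3f cm^3, PTV %.3f cm^3, Dmax %g%%\n",
              x$v_gtv, x$v_ptv, x$dmax_pct))
  invisible(x)
}

#' Dose at radial distance from the target centre
#'
#' @param model A [calibrate_radial_model()] result.
#' @param r Radius in cm (>= 0). Vectorised.
#' @return Dose in Gy.
#' @export
dose_at_radius <- function(model, r) {
  stopifnot(inherits(model, "radial_plan_model"))
  if (any(r < 0)) stop("radius must be non-negative")
  dmax <- model$dmax_pct / 100 * model$rx_dose
  inner <- dmax - (dmax - model$rx_dose) * r / model$r_rx
  outer <- model$rx_dose * (model$r_rx / pmax(r, .Machine$double.xmin))^model$k
  ifelse(r < model$r_rx, inner, outer)
}

#' Radius of an isodose surface
#'
#' Inverse of [dose_at_radius()]: the radius at which the dose equals
#' `level`. Doses above the central maximum map to radius 0.
#'
#' @param model A `radial_plan_model`.
#' @param level Dose level in Gy (> 0). Vectorised.
#' @return Radius in cm.
#' @export
radius_at_dose <- function(model, level) {
  stopifnot(inherits(model, "radial_plan_model"))
  if (any(level <= 0)) stop("dose level must be positive")
  dmax <- model$dmax_pct / 100 * model$rx_dose
  r <- ifelse(level <= model$rx_dose,
              model$r_rx * (model$rx_dose / level)^(1 / model$k),
              ifelse(level >= dmax, 0,
                     model$r_rx * (dmax - level) / (dmax - model$rx_dose)))
  r
}

#' Healthy-brain-minus-GTV volume receiving at least a dose level
#'
#' Closed-form V(level) for the structure "healthy brain minus GTV" under
#' the infinite homogeneous medium assumption:
#' \eqn{\max(0,\; (4\pi/3) r_{level}^3 - V_{GTV})} with
#' \eqn{r_{level}} from [radius_at_dose()].
#'
#' @param model A `radial_plan_model`.
#' @param level Dose level in Gy (> 0). Vectorised.
#' @return Volume in cm^3.
#' @examples
#' m <- calibrate_radial_model(spherical_target(4, 0),
#'                             plan_quality(112, 97, 1.0, 2.6), 15)
#' healthy_brain_volume_at_dose(m, 12)   # ~12.07 cm^3
#' @export
healthy_brain_volume_at_dose <- function(model, level) {
  r <- radius_at_dose(model, level)
  pmax(0, 4 * pi / 3 * r^3 - model$v_gtv)
}

#' Render the radial model on a voxel grid
#'
#' Samples the dose at voxel centres on a cubic grid centred on the target
#' and builds structure masks (GTV, PTV, healthy brain minus GTV) by a
#' centre-in-sphere test. Volumes derived from the grid are voxel counts
#' times the voxel volume.
#'
#' @param model A `radial_plan_model`.
#' @param spacing Isotropic voxel spacing in mm (default 1, the clinical
#'   calculation grid).
#' @param extent Half-width of the cubic grid in cm. The default covers the
#'   1 Gy isodose, capped at 10 cm for shallow falloffs. If the dose at the
#'   grid boundary is still 1 Gy or more, the result is flagged `truncated`
#'   and a warning is raised.
#' @return An object of class `dose_grid`: a list with the 3-D `dose`
#'   array (Gy), logical masks `gtv`, `ptv`, `healthy`, the voxel volume
#'   in cm^3, `spacing` (mm), `extent` (cm) and the `truncated` flag.
#' @export
render_grid <- function(model, spacing = 1, extent = NULL) {
  stopifnot(inherits(model, "radial_plan_model"))
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(extent))
    extent <- min(10, 1.02 * radius_at_dose(model, 1))
  s <- spacing / 10  # mm -> cm
  n <- max(1L, ceiling(2 * extent / s) + 1L)
  # voxel centres are offset a quarter voxel from the target centre: when a
  # lattice symmetry plane passes through the sphere centre, whole planes of
  # voxels cross an isodose surface together and volume errors grow several-
  # fold (the clinical calculation grid is likewise not aligned to the target)
  centers <- (seq_len(n) - (n + 1) / 2) * s + s / 4
  r2_1d <- centers^2
  r <- sqrt(outer(outer(r2_1d, r2_1d, `+`), r2_1d, `+`))
  dose <- array(dose_at_radius(model, r), dim = dim(r))
  truncated <- dose_at_radius(model, extent) >= 1
  if (truncated)
    warning("grid extent truncates the 1 Gy isodose; volumes may be underestimated")
  gtv <- r <= model$r_gtv
  structure(
    list(dose = dose,
         gtv = gtv,
         ptv = r <= model$r_ptv,
         healthy = !gtv,
         voxel_volume = s^3,
         spacing = spacing, extent = extent, n = n,
         truncated = truncated),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d^3 voxels at %g mm, extent %.2f cm%s\n",
              x$n, x$spacing, x$extent,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Volume of a grid mask
#'
#' @param grid A [render_grid()] result.
#' @param mask Name of a mask (`"gtv"`, `"ptv"`, `"healthy"`) or a logical
#'   array conforming to the grid.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"))
  m <- if (is.character(mask)) grid[[mask]] else mask
  sum(m) * grid$voxel_volume
}
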