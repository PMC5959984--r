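#' Isotoxic prescription dose, closed form
#'
#' Finds the prescription (total) dose at which a calibrated radial plan
#' exactly meets a healthy-brain dose-volume constraint. The constraint
#' isodose must enclose the volume `constraint + V_GTV`, so its radius is
#' \eqn{r_c = (3 (V_c + V_{GTV}) / 4\pi)^{1/3}} and the isotoxic dose is
#' \deqn{D_{IDP} = D_c \, (r_c / r_{rx})^k}
#' with \eqn{r_{rx}, k} from [calibrate_radial_model()]. Renormalisation is
#' a pure global scaling of the dose distribution (altering monitor units),
#' so no re-optimisation is involved and the 99%-PTV-coverage normalisation
#' of the nominal plan carries over unchanged.
#'
#' @param target A [spherical_target()].
#' @param quality A [plan_quality()].
#' @param cst A [constraint()]; its fraction number is attached to the
#'   returned scheme.
#' @param nominal_rx Optional nominal prescription in Gy; used only to
#'   report the scale factor relative to the nominal plan.
#' @return An object of class `idp_result`: `idp_dose` (total Gy),
#'   `scale_factor`, `achieved_volume` (cm^3 at the constraint level after
#'   renormalisation), `scheme`, and `constraint_inside_ptv` (TRUE when the
#'   constraint isodose falls inside the prescription isodose, i.e. the
#'   isotoxic dose is below the constraint level).
#' @examples
#' idp_dose_analytic(spherical_target(4, 0), plan_quality(112, 97, 1, 2.6),
#'                   constraint(12, 10, 1))   # 14.50 Gy
#' @export
idp_dose_analytic <- function(target, quality, cst, nominal_rx = NULL) {
  stopifnot(inherits(cst, "nt_constraint"))
  model <- calibrate_radial_model(target, quality, rx_dose = cst$dose_gy)
  r_c <- (3 * (cst$volume_cm3 + target$gtv_volume) / (4 * pi))^(1 / 3)
  idp <- cst$dose_gy * (r_c / model$r_rx)^model$k
  scaled <- calibrate_radial_model(target, quality, rx_dose = idp)
  achieved <- healthy_brain_volume_at_dose(scaled, cst$dose_gy)
  inside <- r_c < model$r_rx
  # exactness holds in the power-law regime; when the constraint isodose
  # falls inside the prescription isodose the inner ramp governs instead
  if (!inside)
    stopifnot(abs(achieved - cst$volume_cm3) <= 1e-6 * cst$volume_cm3)
  new_idp_result(
    idp_dose = idp,
    scale_factor = if (is.null(nominal_rx)) NA_real_ else idp / nominal_rx,
    achieved_volume = achieved,
    scheme = fractionation_scheme(cst$n_fractions, total_dose = idp),
    constraint = cst,
    constraint_inside_ptv = inside,
    method = "analytic")
}

#' Renormalise a DVH to meet a constraint
#'
#' DVH-based counterpart of [idp_dose_analytic()]: the healthy-brain-minus-
#' GTV DVH is rescaled by the factor
#' `f = dose_level / d_at_volume(dvh, volume)` so that the rescaled curve
#' satisfies `v_at_dose(dose_level) = volume`; the isotoxic prescription is
#' `f` times the nominal prescription.
#'
#' @param dvh A [cumulative_dvh()] of the healthy brain minus GTV.
#' @param nominal_rx Nominal prescription dose in Gy of the plan the DVH
#'   was computed from.
#' @param cst A [constraint()].
#' @return An `idp_result` (see [idp_dose_analytic()]) with the rescaled
#'   DVH attached as `$dvh`.
#' @export
renormalize_dvh_to_constraint <- function(dvh, nominal_rx, cst) {
  stopifnot(inherits(dvh, "cumulative_dvh"), inherits(cst, "nt_constraint"))
  if (cst$volume_cm3 > dvh$total_volume)
    stop("constraint volume exceeds structure volume")
  f <- cst$dose_gy / d_at_volume(dvh, cst$volume_cm3)
  scaled <- rescale_dvh(dvh, f)
  achieved <- v_at_dose(scaled, cst$dose_gy)
  bin <- diff(scaled$dose_edges[1:2])
  # achieved volume must agree with the constraint within one (scaled) bin's
  # worth of volume resolution around the constraint level
  local_slope <- abs(v_at_dose(scaled, cst$dose_gy - bin) -
                       v_at_dose(scaled, cst$dose_gy + bin)) / 2
  stopifnot(abs(achieved - cst$volume_cm3) <= local_slope + 1e-9)
  res <- new_idp_result(
    idp_dose = f * nominal_rx,
    scale_factor = f,
    achieved_volume = achieved,
    scheme = fractionation_scheme(cst$n_fractions,
                                  total_dose = f * nominal_rx),
    constraint = cst,
    constraint_inside_ptv = NA,
    method = "dvh")
  res$dvh <- scaled
  res
}

new_idp_result <- function(idp_dose, scale_factor, achieved_volume, scheme,
                           constraint, constraint_inside_ptv, method) {
  structure(
    list(idp_dose = idp_dose, scale_factor = scale_factor,
         achieved_volume = achieved_volume, scheme = scheme,
         constraint = constraint,
         constraint_inside_ptv = constraint_inside_ptv,
         method = method),
    class = "idp_result")
}

#' @export
print.idp_result <- function(x, ...) {
  cat(sprintf("Isotoxic prescription: %.3f Gy in %d fx (%s)\n",
              x$idp_dose, x$scheme$n_fractions, x$method))
  cat(sprintf("  constraint V%.4gGy = %g cm^3, achieved %.4f cm^3\n",
              x$constraint$dose_gy, x$constraint$volume_cm3,
              x$achieved_volume))
  if (isTRUE(x$constraint_inside_ptv))
    cat("  note: constraint isodose inside PTV (isotoxic dose below constraint level)\n")
  invisible(x)
}
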