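#' Fractionation scheme
#'
#' @param n_fractions Integer number of fractions (>= 1).
#' @param dose_per_fraction Dose per fraction in Gy (> 0). Give either this
#'   or `total_dose`.
#' @param total_dose Total physical dose in Gy.
#' @return An object of class `fractionation_scheme`.
#' @examples
#' fractionation_scheme(3, total_dose = 19.17)
#' @export
fractionation_scheme <- function(n_fractions, dose_per_fraction = NULL,
                                 total_dose = NULL) {
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("n_fractions must be a positive integer")
  if (is.null(dose_per_fraction) == is.null(total_dose))
    stop("give exactly one of dose_per_fraction or total_dose")
  if (is.null(dose_per_fraction)) dose_per_fraction <- total_dose / n_fractions
  if (dose_per_fraction <= 0) stop("dose_per_fraction must be positive")
  structure(list(n_fractions = as.integer(n_fractions),
                 dose_per_fraction = dose_per_fraction,
                 total_dose = n_fractions * dose_per_fraction),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("%d x %.4g Gy (total %.4g Gy)\n",
              x$n_fractions, x$dose_per_fraction, x$total_dose))
  invisible(x)
}

#' Biologically effective dose under the linear-quadratic model
#'
#' \eqn{BED = n d (1 + d / (\alpha/\beta))}. The conventional tissue
#' sensitivities in this setting are \eqn{\alpha/\beta = 3} Gy for late
#' brain toxicity and 12 Gy for brain-metastasis tumor response.
#'
#' @param scheme A [fractionation_scheme()].
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @examples
#' bed(fractionation_scheme(1, 12), 3)   # 60 Gy
#' @export
bed <- function(scheme, alpha_beta) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  with(scheme, n_fractions * dose_per_fraction *
         (1 + dose_per_fraction / alpha_beta))
}

#' Total dose delivering a given BED in n fractions
#'
#' Positive root of \eqn{T^2/(n\,\alpha/\beta) + T - BED = 0}; the exact
#' inverse of [bed()].
#'
#' @param bed_gy Target BED in Gy (> 0).
#' @param n_fractions Number of fractions.
#' @param alpha_beta Tissue alpha/beta ratio in Gy.
#' @return Total physical dose in Gy.
#' @examples
#' isoeffective_total_dose(60, 3, 3)   # 19.17 Gy
#' @export
isoeffective_total_dose <- function(bed_gy, n_fractions, alpha_beta) {
  if (any(bed_gy <= 0)) stop("bed_gy must be positive")
  if (alpha_beta <= 0) stop("alpha_beta must be positive")
  nab <- n_fractions * alpha_beta
  nab / 2 * (sqrt(1 + 4 * bed_gy / nab) - 1)
}

#' Normal-tissue dose-volume constraint
#'
#' A (dose level, volume, fraction number) triple such as "V12Gy = 10 cm^3
#' in a single fraction" -- the volume of healthy brain minus GTV that may
#' receive at least the dose level.
#'
#' @param dose_gy Constraint dose level in Gy (> 0).
#' @param volume_cm3 Constraint volume in cm^3 (> 0).
#' @param n_fractions Fraction number the constraint applies to.
#' @return An object of class `nt_constraint`.
#' @export
constraint <- function(dose_gy, volume_cm3, n_fractions = 1) {
  if (dose_gy <= 0 || volume_cm3 <= 0 || n_fractions < 1)
    stop("dose, volume and fraction number must be positive")
  structure(list(dose_gy = dose_gy, volume_cm3 = volume_cm3,
                 n_fractions = as.integer(n_fractions)),
            class = "nt_constraint")
}

#' @export
print.nt_constraint <- function(x, ...) {
  cat(sprintf("V%.4gGy = %g cm^3 (%d fx)\n",
              x$dose_gy, x$volume_cm3, x$n_fractions))
  invisible(x)
}

#' Radionecrosis-risk constraints for single-, three- and five-fraction SRS
#'
#' The clinical constraint set keeping the risk of radionecrosis low:
#' V12Gy = 10 cm^3 for a single fraction, V19.2Gy = 10 cm^3 for three
#' fractions (the single-fraction constraint recalculated with the LQ model
#' at alpha/beta = 3 Gy, rounded to one decimal as used clinically) and
#' V20Gy = 20 cm^3 for five fractions.
#'
#' @return Named list of [constraint()]s: `fx1`, `fx3`, `fx5`.
#' @export
srs_constraints <- function() {
  list(fx1 = constraint(12, 10, 1),
       fx3 = constraint(19.2, 10, 3),
       fx5 = constraint(20, 20, 5))
}

#' Convert a constraint to another fraction number
#'
#' The constraint dose level is mapped to the isoeffective total dose at
#' the new fraction number under the LQ model; the volume is unchanged.
#'
#' @param cst A [constraint()].
#' @param to_n Target number of fractions.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (default 3, late brain).
#' @return A [constraint()] at `to_n` fractions.
#' @examples
#' convert_constraint(constraint(12, 10, 1), 3)   # V19.17Gy = 10 cm^3
#' @export
convert_constraint <- function(cst, to_n, alpha_beta = 3) {
  stopifnot(inherits(cst, "nt_constraint"))
  b <- bed(fractionation_scheme(cst$n_fractions,
                                total_dose = cst$dose_gy), alpha_beta)
  constraint(isoeffective_total_dose(b, to_n, alpha_beta),
             cst$volume_cm3, to_n)
}

#' Logistic TCP dose-response model
#'
#' Tumor control probability as a logistic function of the tumor BED:
#' \deqn{TCP = 1 / (1 + e^{-(\beta_0 + \beta_1 BED)})}
#' with BED computed at the tumor alpha/beta ratio (default 12 Gy, the
#' convention for brain metastases).
#'
#' @param beta0 Intercept on the logit scale.
#' @param beta1 Slope per Gy of BED (> 0).
#' @param alpha_beta_tumor Tumor alpha/beta ratio in Gy.
#' @return An object of class `tcp_model`.
#' @seealso [calibrate_tcp()], [default_tcp_model()], [tcp()]
#' @export
tcp_model <- function(beta0, beta1, alpha_beta_tumor = 12) {
  if (beta1 <= 0) stop("beta1 must be positive (dose-response must increase)")
  if (alpha_beta_tumor <= 0) stop("alpha_beta_tumor must be positive")
  structure(list(beta0 = beta0, beta1 = beta1,
                 alpha_beta_tumor = alpha_beta_tumor),
            class = "tcp_model")
}

#' @export
print.tcp_model <- function(x, ...) {
  cat(sprintf(
    "Logistic TCP model: logit(TCP) = %.4f + %.5f * BED_{a/b=%g}\n",
    x$beta0, x$beta1, x$alpha_beta_tumor))
  invisible(x)
}

#' Calibrate a logistic TCP model from (scheme, probability) anchors
#'
#' Solves `logit(p) = beta0 + beta1 * BED` -- exactly for two anchors,
#' by least squares in logit space for more.
#'
#' @param anchors List of `list(scheme = fractionation_scheme, p = prob)`.
#' @param alpha_beta_tumor Tumor alpha/beta ratio used for the BED
#'   covariate (Gy).
#' @return A [tcp_model()].
#' @examples
#' calibrate_tcp(list(
#'   list(scheme = fractionation_scheme(1, 15), p = 0.42),
#'   list(scheme = fractionation_scheme(1, 24), p = 0.86)))
#' @export
calibrate_tcp <- function(anchors, alpha_beta_tumor = 12) {
  if (length(anchors) < 2) stop("need at least 2 anchors")
  beds <- vapply(anchors, function(a) bed(a$scheme, alpha_beta_tumor), 0)
  p <- vapply(anchors, function(a) a$p, 0)
  if (any(p <= 0 | p >= 1)) stop("anchor probabilities must lie in (0, 1)")
  if (max(beds) - min(beds) < 1e-9)
    stop("anchors must have distinct BEDs (singular system)")
  fit <- stats::lm.fit(cbind(1, beds), stats::qlogis(p))
  cf <- fit$coefficients
  if (cf[2] <= 0) stop("calibration yields non-increasing dose-response")
  tcp_model(unname(cf[1]), unname(cf[2]), alpha_beta_tumor)
}

#' Default TCP model
#'
#' Two-anchor calibration to the reported single-fraction outcomes for
#' brain metastases: TCP 42% at 1 x 15 Gy and 86% at 1 x 24 Gy
#' (BED at alpha/beta = 12: 33.75 and 72 Gy).
#'
#' @return A [tcp_model()].
#' @export
default_tcp_model <- function() {
  calibrate_tcp(list(
    list(scheme = fractionation_scheme(1, 15), p = 0.42),
    list(scheme = fractionation_scheme(1, 24), p = 0.86)))
}

#' Predicted tumor control probability for a fractionation scheme
#'
#' @param model A [tcp_model()].
#' @param scheme A [fractionation_scheme()].
#' @return Probability in (0, 1).
#' @examples
#' tcp(default_tcp_model(), fractionation_scheme(1, 15))   # 0.42
#' @export
tcp <- function(model, scheme) {
  stopifnot(inherits(model, "tcp_model"))
  stats::plogis(model$beta0 +
                  model$beta1 * bed(scheme, model$alpha_beta_tumor))
}
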