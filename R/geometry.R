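#' Volume of a sphere from its diameter
#'
#' @param diameter Sphere diameter in cm. Vectorised.
#' @return Volume in cm^3, \eqn{(\pi/6) d^3}.
#' @examples
#' sphere_volume(4)   # 33.51 cm^3
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) stop("diameter must be non-negative")
  pi / 6 * diameter^3
}

#' Spherical SRS target (GTV plus isotropic setup margin)
#'
#' Represents an artificial brain metastasis: a perfectly spherical gross
#' tumor volume (GTV) expanded isotropically by a setup margin into the
#' planning target volume (PTV).
#'
#' @param gtv_diameter GTV diameter in cm (> 0).
#' @param margin GTV-PTV margin in mm (>= 0).
#' @return An object of class `spherical_target` with GTV/PTV diameters
#'   (cm) and volumes (cm^3).
#' @examples
#' spherical_target(2.5, margin = 1)
#' @export
spherical_target <- function(gtv_diameter, margin = 0) {
  stopifnot(length(gtv_diameter) == 1, length(margin) == 1)
  if (!is.finite(gtv_diameter) || gtv_diameter <= 0)
    stop("gtv_diameter must be a positive length in cm")
  if (!is.finite(margin) || margin < 0)
    stop("margin must be a non-negative length in mm")
  ptv_diameter <- gtv_diameter + 2 * margin / 10  # mm -> cm
  structure(
    list(
      gtv_diameter = gtv_diameter,
      margin       = margin,
      ptv_diameter = ptv_diameter,
      gtv_volume   = sphere_volume(gtv_diameter),
      ptv_volume   = sphere_volume(ptv_diameter)
    ),
    class = "spherical_target"
  )
}

#' @export
print.spherical_target <- function(x, ...) {
  cat(sprintf(
    "Spherical target: GTV %.2f cm (%.3f cm^3), margin %g mm -> PTV %.2f cm (%.3f cm^3)\n",
    x$gtv_diameter, x$gtv_volume, x$margin, x$ptv_diameter, x$ptv_volume))
  invisible(x)
}

#' PTV diameter after isotropic margin expansion
#'
#' @param target A [spherical_target()].
#' @return PTV diameter in cm (`gtv_diameter + 2 * margin / 10`).
#' @export
expand_margin <- function(target) {
  stopifnot(inherits(target, "spherical_target"))
  target$ptv_diameter
}

#' PTV-size-based prescription protocol
#'
#' A step function mapping PTV volume to a prescribed single-fraction dose.
#' The default is the Dutch consensus protocol for SRS of brain metastases:
#' 24 Gy for PTV < 1 cm^3, then 21, 18 and 15 Gy for PTV in \[1, 10),
#' \[10, 20) and \[20, 65\] cm^3. Bins are half-open on the right except the
#' last, whose upper edge is the SRS eligibility limit.
#'
#' @param upper_volumes Ascending upper bin edges in cm^3.
#' @param doses Prescribed dose per bin in Gy, non-increasing.
#' @return An object of class `prescription_protocol`.
#' @seealso [prescribe_by_ptv_size()], [read_protocol()]
#' @export
prescription_protocol <- function(upper_volumes = c(1, 10, 20, 65),
                                  doses = c(24, 21, 18, 15)) {
  if (length(upper_volumes) != length(doses) || length(doses) < 1)
    stop("upper_volumes and doses must have equal positive length")
  if (any(diff(upper_volumes) <= 0) || any(upper_volumes <= 0))
    stop("upper_volumes must be positive and strictly increasing")
  if (any(diff(doses) > 0))
    stop("doses must be non-increasing with volume")
  structure(list(upper_volumes = upper_volumes, doses = doses),
            class = "prescription_protocol")
}

#' @export
print.prescription_protocol <- function(x, ...) {
  lower <- c(0, x$upper_volumes[-length(x$upper_volumes)])
  cat("PTV-size-based prescription protocol:\n")
  for (i in seq_along(x$doses)) {
    brk <- if (i == length(x$doses)) "]" else ")"
    cat(sprintf("  [%g, %g%s cm^3 -> %g Gy\n",
                lower[i], x$upper_volumes[i], brk, x$doses[i]))
  }
  invisible(x)
}

#' Look up the prescribed dose for a PTV volume
#'
#' @param ptv_volume PTV volume in cm^3 (> 0).
#' @param protocol A [prescription_protocol()].
#' @return Prescribed dose in Gy.
#'
#' A volume above the top bin edge (default 65 cm^3) is outside the SRS
#' eligibility range and raises an error.
#' @examples
#' prescribe_by_ptv_size(0.52)    # 24 Gy
#' prescribe_by_ptv_size(10.31)   # 18 Gy
#' @export
prescribe_by_ptv_size <- function(ptv_volume,
                                  protocol = prescription_protocol()) {
  stopifnot(inherits(protocol, "prescription_protocol"))
  if (any(!is.finite(ptv_volume)) || any(ptv_volume <= 0))
    stop("ptv_volume must be positive")
  top <- protocol$upper_volumes[length(protocol$upper_volumes)]
  if (any(ptv_volume > top))
    stop(sprintf("PTV volume exceeds %g cm^3: ineligible for SRS", top))
  # half-open [lower, upper) bins; the closed top edge maps to the last bin
  idx <- findInterval(ptv_volume, protocol$upper_volumes) + 1L
  idx[ptv_volume == top] <- length(protocol$doses)
  protocol$doses[idx]
}

#' Read a prescription protocol from a YAML file
#'
#' Expected layout: a top-level `protocol` list of
#' `{max_volume_cm3, dose_gy}` entries in ascending volume order. The
#' packaged default lives at
#' `system.file("extdata", "dutch_protocol.yaml", package = "idpsrs")`.
#'
#' @param path Path to the YAML file.
#' @return A [prescription_protocol()].
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$protocol)) stop("no 'protocol' entry in ", path)
  prescription_protocol(
    upper_volumes = vapply(cfg$protocol, function(b) as.numeric(b$max_volume_cm3), 0),
    doses         = vapply(cfg$protocol, function(b) as.numeric(b$dose_gy), 0)
  )
}
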