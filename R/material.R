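#' Density-elasticity law
#'
#' Power-law conversion from calibrated equivalent mineral density to
#' Young's modulus, `E [MPa] = coefficient * rho_app[g/cm^3] ^ exponent`,
#' with the conversion chain `rho_ash = qct_to_ash * rho_qct` and
#' `rho_app = rho_ash / ash_to_apparent` (mg/cm^3 converted to g/cm^3
#' internally). Densities below `density_floor` are clamped to it before
#' exponentiation, since soft-tissue voxels can calibrate below zero.
#'
#' The defaults are the widely used femoral law E = 6850 * rho_app^1.49 MPa
#' with rho_ash = rho_qct and rho_app = rho_ash / 0.6; any published
#' monotone law can be substituted by changing the four constants.
#'
#' @param coefficient MPa multiplier (> 0).
#' @param exponent Dimensionless power (> 0).
#' @param qct_to_ash Dimensionless QCT-to-ash density factor (> 0).
#' @param ash_to_apparent Dimensionless ash-to-apparent divisor (> 0).
#' @param density_floor mg/cm^3 clamp applied to the input density.
#' @return An object of class `elasticity_law`.
#' @export
elasticity_law <- function(coefficient = 6850, exponent = 1.49,
                           qct_to_ash = 1, ash_to_apparent = 0.6,
                           density_floor = 0) {
  vals <- c(coefficient = coefficient, exponent = exponent,
            qct_to_ash = qct_to_ash, ash_to_apparent = ash_to_apparent)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("law constants must be positive and finite", call. = FALSE)
  if (!is.finite(density_floor))
    stop("`density_floor` must be finite", call. = FALSE)
  structure(list(coefficient = coefficient, exponent = exponent,
                 qct_to_ash = qct_to_ash, ash_to_apparent = ash_to_apparent,
                 density_floor = density_floor),
            class = "elasticity_law")
}

#' @export
print.elasticity_law <- function(x, ...) {
  cat("<elasticity_law> E[MPa] = ", format(x$coefficient),
      " * rho_app[g/cm^3]^", format(x$exponent), "\n", sep = "")
  cat("  rho_ash = ", format(x$qct_to_ash), " * rho_qct;  rho_app = rho_ash / ",
      format(x$ash_to_apparent), ";  floor ", format(x$density_floor),
      " mg/cm^3\n", sep = "")
  invisible(x)
}

#' Convert equivalent mineral density to Young's modulus
#'
#' Element-wise application of an [elasticity_law()]: clamp at the floor,
#' convert QCT to ash to apparent density (g/cm^3), raise to the power.
#' Monotone non-decreasing in the input density.
#'
#' @param rho_qct Density in mg/cm^3 (scalar, vector or array).
#' @param law An [elasticity_law()].
#' @return Young's modulus in MPa, same shape as `rho_qct`.
#' @examples
#' density_to_modulus(600, elasticity_law())  # rho_app = 1 g/cm^3 -> 6850 MPa
#' @export
density_to_modulus <- function(rho_qct, law = elasticity_law()) {
  stopifnot(inherits(law, "elasticity_law"))
  if (any(!is.finite(rho_qct)))
    stop("non-finite density input", call. = FALSE)
  rho <- pmax(rho_qct, law$density_floor)
  rho_app <- (law$qct_to_ash * rho / 1000) / law$ash_to_apparent
  out <- law$coefficient * rho_app^law$exponent
  if (is.array(rho_qct)) dim(out) <- dim(rho_qct)
  out
}

#' Calibrated Young's modulus field on a mask
#'
#' Applies a calibration line to the HU values of the masked voxels and maps
#' the resulting densities to Young's modulus. Voxels outside the mask are
#' absent from the output.
#'
#' @param volume A [ct_volume()].
#' @param line A [calibration_line()].
#' @param mask Logical array with the volume's dimensions; must be
#'   non-empty.
#' @param law An [elasticity_law()].
#' @return An object of class `modulus_field`: list with `values` (MPa, one
#'   per masked voxel in array order), `mask`, and provenance (`method` of
#'   the line used).
#' @export
calibrated_modulus_field <- function(volume, line, mask,
                                     law = elasticity_law()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(line, "calibration_line"))
  if (!is.array(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(volume$voxels)))
    stop("`mask` must be a logical array matching the volume dimensions",
         call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  rho <- apply_calibration(line, volume$voxels[mask])
  structure(list(values = density_to_modulus(rho, law), mask = mask,
                 method = line$method, law = law),
            class = "modulus_field")
}

#' @export
print.modulus_field <- function(x, ...) {
  cat("<modulus_field> ", length(x$values), " voxels [", x$method,
      " calibration]\n", sep = "")
  cat("  E range: [", format(min(x$values)), ", ", format(max(x$values)),
      "] MPa\n", sep = "")
  invisible(x)
}
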