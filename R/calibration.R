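#' Densitometric calibration line
#'
#' A linear HU-to-density calibration, `density = intercept + slope * HU`,
#' with the equivalent mineral density in mg/cm^3 of calcium hydroxyapatite
#' (HA). Produced by [fit_calibration()] (phantom route) or
#' [fit_phantomless_calibration()] (internal-tissue route).
#'
#' A physically valid calibration has positive slope; a non-positive slope
#' triggers a warning, not an error, so that degenerate fits remain
#' inspectable.
#'
#' @param intercept Intercept in mg/cm^3.
#' @param slope Slope in mg/cm^3 per HU.
#' @param r_squared Coefficient of determination of the fit, in \[0, 1\].
#' @param n_points Number of (HU, density) pairs used.
#' @param method `"phantom"` or `"phantomless"`.
#' @param details Optional list of fit provenance (e.g. detected peaks,
#'   reference densities, VOI height).
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(intercept, slope, r_squared = NA_real_,
                             n_points = NA_integer_,
                             method = c("phantom", "phantomless"),
                             details = list()) {
  method <- match.arg(method)
  intercept <- as.numeric(intercept); slope <- as.numeric(slope)
  if (length(intercept) != 1L || length(slope) != 1L ||
      !is.finite(intercept) || !is.finite(slope))
    stop("`intercept` and `slope` must be finite scalars", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12))
    stop("`r_squared` must lie in [0, 1]", call. = FALSE)
  if (slope <= 0)
    warning("calibration slope is not positive (", format(slope),
            " mg/cm^3 per HU); the line is physically implausible",
            call. = FALSE)
  structure(list(intercept = intercept, slope = slope,
                 r_squared = min(max(r_squared, 0), 1),
                 n_points = as.integer(n_points), method = method,
                 details = details),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat("<calibration_line> [", x$method, "]\n", sep = "")
  cat("  density [mg/cm^3] = ", format(x$intercept), " + ", format(x$slope),
      " * HU\n", sep = "")
  cat("  R^2 = ", format(x$r_squared), " on ", x$n_points, " points\n",
      sep = "")
  invisible(x)
}

#' Fit a calibration line by ordinary least squares
#'
#' Regresses known equivalent mineral densities on measured mean HU values
#' (density as response, HU as regressor — the direction in which the
#' calibration is consumed). The fit is unweighted OLS via [stats::lm()].
#'
#' @param mean_hu Numeric vector of mean HU values (length >= 2, not all
#'   identical).
#' @param densities Numeric vector of HA-equivalent densities in mg/cm^3,
#'   same length.
#' @param method Provenance tag for the resulting line.
#' @param details Optional provenance list stored on the line.
#' @return A [calibration_line()].
#' @examples
#' fit_calibration(c(100, 180, 340, 660, 1300), c(50, 100, 200, 400, 800))
#' @export
fit_calibration <- function(mean_hu, densities, method = "phantom",
                            details = list()) {
  mean_hu <- as.numeric(mean_hu); densities <- as.numeric(densities)
  if (length(mean_hu) != length(densities))
    stop("`mean_hu` and `densities` must have equal length", call. = FALSE)
  if (length(mean_hu) < 2L)
    stop("calibration requires at least 2 (HU, density) pairs, got ",
         length(mean_hu), call. = FALSE)
  if (any(!is.finite(mean_hu)) || any(!is.finite(densities)))
    stop("calibration inputs must be finite", call. = FALSE)
  if (stats::var(mean_hu) == 0)
    stop("mean HU values are all identical; calibration line is undefined",
         call. = FALSE)
  fit <- stats::lm(densities ~ mean_hu)
  r2 <- if (stats::var(densities) == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)  # silence perfect-fit notice
  calibration_line(intercept = unname(stats::coef(fit)[1]),
                   slope = unname(stats::coef(fit)[2]),
                   r_squared = r2, n_points = length(mean_hu),
                   method = method, details = details)
}

#' Apply a calibration line to HU values
#'
#' Element-wise `density = intercept + slope * HU`; shape is preserved, so
#' scalars, vectors and voxel arrays all work.
#'
#' @param line A [calibration_line()].
#' @param hu HU scalar, vector or array.
#' @return Equivalent mineral density in mg/cm^3, same shape as `hu`.
#' @export
apply_calibration <- function(line, hu) {
  stopifnot(inherits(line, "calibration_line"))
  line$intercept + line$slope * hu
}

#' Serialize a calibration line to JSON
#'
#' @param line A [calibration_line()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_line <- function(line, path) {
  stopifnot(inherits(line, "calibration_line"))
  jsonlite::write_json(unclass(line), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration line from JSON
#'
#' @param path Path written by [write_calibration_line()].
#' @return A [calibration_line()].
#' @export
read_calibration_line <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_line(intercept = obj$intercept, slope = obj$slope,
                   r_squared = obj$r_squared %||% NA_real_,
                   n_points = obj$n_points %||% NA_integer_,
                   method = obj$method,
                   details = as.list(obj$details %||% list()))
}
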