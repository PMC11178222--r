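#' Read a CT volume
#'
#' Reads a CT volume from a NIfTI file or a DICOM series directory into a
#' [ct_volume()] with voxel values in Hounsfield units. NIfTI voxel values
#' are taken as already being HU (any `scl_slope`/`scl_inter` scaling is
#' applied by the reader); DICOM stored values are converted per slice as
#' `HU = stored * RescaleSlope + RescaleIntercept`, which must be present.
#'
#' Only axis-aligned acquisitions are accepted: every image axis must lie
#' within 5 degrees of an anatomical axis, so that the axial-slice geometry
#' used by [build_voi_cut()] is well defined. Oblique volumes are rejected.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or to a directory containing a
#'   DICOM series.
#' @param format `"auto"` (default; directory implies DICOM), `"nifti"` or
#'   `"dicom"`.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (!file.exists(path))
    stop("no such file or directory: ", path, call. = FALSE)
  switch(format,
         nifti = .read_nifti_volume(path),
         dicom = read_dicom_series(path))
}

# Convert a 3x3 direction matrix (columns = image axes, patient LPS frame)
# into orientation labels, requiring each axis within `tol_deg` of anatomical.
.directions_to_orientation <- function(dirs, tol_deg = 5) {
  labels <- character(3)
  lab_tab <- matrix(c("R", "L", "A", "P", "I", "S"), nrow = 2)
  for (a in 1:3) {
    v <- dirs[, a]
    v <- v / sqrt(sum(v^2))
    p <- which.max(abs(v))
    if (abs(v[p]) < cos(tol_deg * pi / 180))
      stop("volume axis ", a, " is oblique (more than ", tol_deg,
           " degrees from any anatomical axis); only axis-aligned ",
           "acquisitions are supported", call. = FALSE)
    labels[a] <- lab_tab[(sign(v[p]) + 3) / 2, p]
  }
  if (length(unique(.AXIS_CODES[labels])) != 3L)
    stop("volume axes do not cover three distinct anatomical directions",
         call. = FALSE)
  labels
}

.read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  M <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  M <- unclass(M)[1:4, 1:4]
  if (all(M[1:3, 1:3] == 0))
    stop("NIfTI file carries no spatial transform (missing spacing/",
         "orientation metadata): ", path, call. = FALSE)
  # NIfTI xform maps 0-based voxel indices to RAS mm; flip x and y for LPS.
  M[1:2, ] <- -M[1:2, ]
  spacing <- sqrt(colSums(M[1:3, 1:3]^2))
  if (any(spacing <= 0))
    stop("NIfTI file has non-positive voxel spacing: ", path, call. = FALSE)
  orientation <- .directions_to_orientation(M[1:3, 1:3])
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(d), " dimensions",
         call. = FALSE)
  vox <- array(as.vector(as.array(img)), dim = d)
  ct_volume(vox, spacing = spacing, origin = M[1:3, 4],
            orientation = orientation)
}

#' Write a CT volume to NIfTI
#'
#' Writes the HU field as float64 so that a round trip through
#' [read_volume()] reproduces the voxel values bit-exactly. The LPS geometry
#' is stored in the sform (converted to the NIfTI RAS convention).
#'
#' @param volume A [ct_volume()] (or a logical mask array paired with a
#'   template volume via `template`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param template Optional [ct_volume()] supplying geometry when `volume` is
#'   a bare array (e.g. a mask).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, template = NULL) {
  if (is.array(volume) && !inherits(volume, "ct_volume")) {
    if (is.null(template))
      stop("writing a bare array requires `template` for geometry",
           call. = FALSE)
    volume <- ct_volume(volume + 0, spacing = template$spacing,
                        origin = template$origin,
                        orientation = template$orientation)
  }
  m <- .axis_map(volume)
  M <- matrix(0, 4, 4); M[4, 4] <- 1
  for (a in 1:3)
    M[m$patient_axis[a], a] <- m$sign[a] * volume$spacing[a]
  M[1:3, 4] <- volume$origin
  M[1:2, ] <- -M[1:2, ]  # LPS -> RAS
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  img <- RNifti::`sform<-`(img, structure(M, code = 2L))
  img <- RNifti::`qform<-`(img, structure(M, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Anatomical landmarks for VOI construction
#'
#' Landmark set used by the phantomless calibration geometry: the femoral
#' head centre and the knee centre (given directly or derived as the midpoint
#' of the medial and lateral epicondyles, see [knee_center()]).
#'
#' @param head_center LPS mm coordinate of the femoral head centre.
#' @param medial_epicondyle,lateral_epicondyle Optional LPS mm coordinates.
#' @param knee_center Optional LPS mm coordinate; computed from the
#'   epicondyles when absent.
#' @return An object of class `landmarks`: a list of LPS mm points.
#' @export
landmarks <- function(head_center, medial_epicondyle = NULL,
                      lateral_epicondyle = NULL, knee_center = NULL) {
  chk <- function(p, name) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p)))
      stop("landmark `", name, "` must be a finite length-3 mm coordinate",
           call. = FALSE)
    p
  }
  head_center <- chk(head_center, "head_center")
  medial_epicondyle <- chk(medial_epicondyle, "medial_epicondyle")
  lateral_epicondyle <- chk(lateral_epicondyle, "lateral_epicondyle")
  knee_center <- chk(knee_center, "knee_center")
  if (is.null(knee_center)) {
    if (is.null(medial_epicondyle) || is.null(lateral_epicondyle))
      stop("landmarks require either `knee_center` or both epicondyles",
           call. = FALSE)
    knee_center <- (medial_epicondyle + lateral_epicondyle) / 2
  }
  structure(list(head_center = head_center,
                 medial_epicondyle = medial_epicondyle,
                 lateral_epicondyle = lateral_epicondyle,
                 knee_center = knee_center),
            class = "landmarks")
}

#' Knee centre from the epicondyles
#'
#' The knee rotation centre is taken as the component-wise midpoint of the
#' most medial and most lateral epicondyle points.
#'
#' @param medial,lateral Length-3 mm coordinates.
#' @return Length-3 mm coordinate.
#' @examples
#' knee_center(c(40, 20, -380), c(-20, 30, -384))
#' @export
knee_center <- function(medial, lateral) {
  medial <- as.numeric(medial); lateral <- as.numeric(lateral)
  if (length(medial) != 3L || length(lateral) != 3L ||
      any(!is.finite(c(medial, lateral))))
    stop("epicondyle points must be finite length-3 coordinates",
         call. = FALSE)
  (medial + lateral) / 2
}

#' Read landmarks from JSON
#'
#' The file must contain named length-3 mm coordinates (`head_center`,
#' `medial_epicondyle`, `lateral_epicondyle`, optional `knee_center`) and a
#' `convention` tag, either `"LPS"` or `"RAS"`; RAS coordinates are converted
#' to the package's internal LPS convention on load.
#'
#' @param path Path to a JSON landmark file.
#' @return A [landmarks()] object (LPS mm).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("no such landmark file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse landmark file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  conv <- toupper(obj$convention %||% "LPS")
  if (!conv %in% c("LPS", "RAS"))
    stop("unsupported landmark coordinate convention: ", conv, call. = FALSE)
  cvt <- function(p) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (conv == "RAS") p <- p * c(-1, -1, 1)
    p
  }
  missing <- character(0)
  if (is.null(obj$head_center)) missing <- c(missing, "head_center")
  if (is.null(obj$knee_center) &&
      (is.null(obj$medial_epicondyle) || is.null(obj$lateral_epicondyle)))
    missing <- c(missing, "knee_center (or both epicondyles)")
  if (length(missing))
    stop("landmark file ", path, " is missing required point(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  landmarks(head_center = cvt(obj$head_center),
            medial_epicondyle = cvt(obj$medial_epicondyle),
            lateral_epicondyle = cvt(obj$lateral_epicondyle),
            knee_center = cvt(obj$knee_center))
}

#' Write landmarks to JSON
#'
#' @param lm A [landmarks()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmarks"))
  obj <- c(list(convention = "LPS"), lm[!vapply(lm, is.null, logical(1))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Check that landmarks fall inside a volume
#'
#' Warns (does not error) for each landmark outside the physical bounds of
#' the volume's voxel centres.
#'
#' @param volume A [ct_volume()].
#' @param lm A [landmarks()] object.
#' @return `TRUE` if all points are inside, else `FALSE`, invisibly.
#' @export
check_landmarks <- function(volume, lm) {
  ok <- TRUE
  for (name in names(lm)) {
    p <- lm[[name]]
    if (is.null(p)) next
    if (!.point_in_bounds(volume, p)) {
      warning("landmark `", name, "` lies outside the volume's physical ",
              "bounds", call. = FALSE)
      ok <- FALSE
    }
  }
  invisible(ok)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
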