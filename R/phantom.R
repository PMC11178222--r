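#' Calibration phantom specification
#'
#' Describes a densitometric calibration phantom: the HA-equivalent densities
#' of its inserts (strictly increasing, at least two) and one region of
#' interest (ROI) per insert. An ROI is either a logical voxel mask matching
#' the volume dimensions, or a [cylinder_roi()] in physical mm that is
#' rasterized against the volume at measurement time.
#'
#' The default densities are the five-insert European Spine Phantom layout
#' (50, 100, 200, 400, 800 mg/cm^3 calcium hydroxyapatite), which spans
#' spongious to cortical bone.
#'
#' @param insert_densities Strictly increasing HA-equivalent densities in
#'   mg/cm^3.
#' @param insert_rois List of ROIs (logical arrays and/or [cylinder_roi()]
#'   objects), one per insert.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(insert_densities = c(50, 100, 200, 400, 800),
                         insert_rois = NULL) {
  insert_densities <- as.numeric(insert_densities)
  if (length(insert_densities) < 2L)
    stop("a phantom needs at least 2 inserts", call. = FALSE)
  if (any(diff(insert_densities) <= 0))
    stop("insert densities must be strictly increasing", call. = FALSE)
  if (!is.null(insert_rois)) {
    if (length(insert_rois) != length(insert_densities))
      stop("need one ROI per insert (", length(insert_densities),
           " inserts, ", length(insert_rois), " ROIs)", call. = FALSE)
    ok <- vapply(insert_rois, function(r)
      inherits(r, "cylinder_roi") || (is.array(r) && is.logical(r)),
      logical(1))
    if (!all(ok))
      stop("each ROI must be a logical mask array or a cylinder_roi",
           call. = FALSE)
  }
  structure(list(insert_densities = insert_densities,
                 insert_rois = insert_rois),
            class = "phantom_spec")
}

#' Cylindrical ROI in physical coordinates
#'
#' A finite cylinder defined in LPS mm: centre, unit axis direction, radius
#' and height. When rasterized, a voxel belongs to the cylinder iff its
#' centre falls inside (axial distance <= height/2 and radial distance <=
#' radius).
#'
#' @param center Length-3 LPS mm centre.
#' @param axis Length-3 axis direction (normalized internally).
#' @param radius Radius in mm (> 0).
#' @param height Height in mm (> 0).
#' @return An object of class `cylinder_roi`.
#' @export
cylinder_roi <- function(center, axis = c(0, 0, 1), radius, height) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  if (length(center) != 3L || length(axis) != 3L ||
      any(!is.finite(c(center, axis))) || sum(axis^2) == 0)
    stop("cylinder centre and axis must be finite length-3 vectors",
         call. = FALSE)
  if (!is.finite(radius) || radius <= 0 || !is.finite(height) || height <= 0)
    stop("cylinder radius and height must be positive", call. = FALSE)
  structure(list(center = center, axis = axis / sqrt(sum(axis^2)),
                 radius = radius, height = height),
            class = "cylinder_roi")
}

#' Rasterize an ROI against a volume grid
#'
#' Converts a [cylinder_roi()] (or passes through a logical mask after a
#' dimension check) into a logical voxel mask on the volume's grid. A voxel
#' is included iff its centre lies inside the cylinder.
#'
#' @param volume A [ct_volume()].
#' @param roi A [cylinder_roi()] or a logical array with the volume's
#'   dimensions.
#' @return Logical array of the volume's dimensions.
#' @export
rasterize_roi <- function(volume, roi) {
  if (is.array(roi) && is.logical(roi)) {
    if (!identical(dim(roi), dim(volume$voxels)))
      stop("mask ROI dimensions do not match the volume", call. = FALSE)
    return(roi)
  }
  if (!inherits(roi, "cylinder_roi"))
    stop("ROI must be a logical mask or a cylinder_roi", call. = FALSE)
  m <- .axis_map(volume)
  d <- dim(volume$voxels)
  # Offset of voxel centres from the cylinder centre, per array axis; the
  # array axis `a` carries the patient axis m$patient_axis[a], so the three
  # offset vectors are separable and outer() sums reconstruct the full grid.
  off <- lapply(1:3, function(a)
    .axis_coords(volume, a) - roi$center[m$patient_axis[a]])
  ax <- roi$axis[m$patient_axis]  # axis components in array-axis order
  t_axis <- outer(outer(off[[1]] * ax[1], off[[2]] * ax[2], "+"),
                  off[[3]] * ax[3], "+")
  r2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+") - t_axis^2
  mask <- abs(t_axis) <= roi$height / 2 & r2 <= roi$radius^2 + 1e-12
  dim(mask) <- d
  mask
}

#' Mean HU over each phantom insert
#'
#' Computes the arithmetic mean HU inside each insert ROI, in insert order.
#' Empty ROIs are errors; an ROI touching the volume boundary triggers a
#' warning (possible truncation). ROIs must be pairwise disjoint.
#'
#' @param volume A [ct_volume()] of the phantom scan.
#' @param spec A [phantom_spec()] with ROIs.
#' @return Numeric vector of mean HU values, one per insert.
#' @export
measure_insert_hu <- function(volume, spec) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "phantom_spec"))
  if (is.null(spec$insert_rois))
    stop("phantom_spec carries no ROIs", call. = FALSE)
  d <- dim(volume$voxels)
  masks <- lapply(spec$insert_rois, function(r) rasterize_roi(volume, r))
  counts <- vapply(masks, sum, numeric(1))
  if (any(counts == 0))
    stop("empty insert ROI(s): ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  total <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  if (any(total > 1L))
    stop("insert ROIs overlap; they must be disjoint", call. = FALSE)
  boundary <- vapply(masks, function(m) {
    any(m[c(1, d[1]), , ]) || any(m[, c(1, d[2]), ]) || any(m[, , c(1, d[3])])
  }, logical(1))
  if (any(boundary))
    warning("insert ROI(s) ", paste(which(boundary), collapse = ", "),
            " touch the volume boundary and may be truncated", call. = FALSE)
  vapply(masks, function(m) mean(volume$voxels[m]), numeric(1))
}

#' Phantom-based calibration in one step
#'
#' Convenience wrapper: [measure_insert_hu()] then [fit_calibration()].
#'
#' @inheritParams measure_insert_hu
#' @return A [calibration_line()] with `method = "phantom"`.
#' @export
phantom_calibration <- function(volume, spec) {
  mean_hu <- measure_insert_hu(volume, spec)
  fit_calibration(mean_hu, spec$insert_densities, method = "phantom",
                  details = list(mean_hu = mean_hu,
                                 insert_densities = spec$insert_densities))
}
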