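# Anatomical axis codes: direction of *increasing* array index, in the
# patient-based LPS frame (+x = Left, +y = Posterior, +z = Superior).
.AXIS_CODES <- c(L = 1, R = 1, A = 2, P = 2, S = 3, I = 3)
.AXIS_SIGNS <- c(L = 1, R = -1, A = -1, P = 1, S = 1, I = -1)

#' CT volume in Hounsfield units
#'
#' Container for a 3-D scalar field of Hounsfield units (HU) together with the
#' geometric metadata needed to map voxel indices to physical patient
#' coordinates. All physical coordinates in this package are expressed in the
#' LPS convention (+x left, +y posterior, +z superior), in millimetres, and a
#' voxel's coordinate refers to its centre.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing Numeric length-3, voxel spacing in mm per array axis; all
#'   components must be positive.
#' @param origin Numeric length-3, LPS coordinate (mm) of the centre of voxel
#'   `[1, 1, 1]`.
#' @param orientation Character length-3, one of `"L"`, `"R"`, `"A"`, `"P"`,
#'   `"S"`, `"I"` per array axis, naming the anatomical direction in which the
#'   array index increases. The three labels must cover three distinct
#'   anatomical axes (e.g. the default `c("L", "P", "S")`).
#'
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, dim = c(4, 4, 3)), spacing = c(2, 2, 3))
#' voxel_to_world(vol, c(1, 1, 1))
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = c("L", "P", "S")) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  orientation <- toupper(as.character(orientation))
  if (length(orientation) != 3L || !all(orientation %in% names(.AXIS_CODES)))
    stop("`orientation` must be three labels from L/R/A/P/S/I", call. = FALSE)
  if (length(unique(.AXIS_CODES[orientation])) != 3L)
    stop("`orientation` labels must cover three distinct anatomical axes",
         call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_volume> ", paste(d, collapse = " x "),
      " voxels @ (", paste(format(x$spacing), collapse = ", "), ") mm\n",
      sep = "")
  cat("  orientation: ", paste(x$orientation, collapse = ""),
      "   origin (LPS mm): ", paste(format(x$origin), collapse = ", "), "\n",
      sep = "")
  cat("  HU range: [", format(min(x$voxels)), ", ", format(max(x$voxels)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# Map from array axes to patient axes: for array axis a,
# patient_axis[a] in 1:3 (x/y/z of LPS) and sign[a] in {-1, +1}.
.axis_map <- function(volume) {
  list(patient_axis = unname(.AXIS_CODES[volume$orientation]),
       sign = unname(.AXIS_SIGNS[volume$orientation]))
}

# Which array axis runs cranio-caudally (patient z), and the index step that
# moves caudally (toward the feet).
.axial_axis <- function(volume) {
  m <- .axis_map(volume)
  a <- which(m$patient_axis == 3L)
  list(axis = a, caudal_step = -m$sign[a])
}

#' Voxel index to physical coordinate
#'
#' Converts 1-based voxel indices to LPS physical coordinates (mm). The
#' centre of voxel `[1, 1, 1]` maps to the volume origin; the mapping is
#' affine and exactly invertible by [world_to_voxel()].
#'
#' @param volume A [ct_volume()].
#' @param ijk Numeric length-3 index, or an n-by-3 matrix of indices.
#' @return A length-3 coordinate, or an n-by-3 matrix of coordinates.
#' @export
voxel_to_world <- function(volume, ijk) {
  m <- .axis_map(volume)
  one <- function(v) {
    w <- numeric(3)
    w[m$patient_axis] <- volume$origin[m$patient_axis] +
      m$sign * (v - 1) * volume$spacing
    w
  }
  if (is.matrix(ijk)) t(apply(ijk, 1, one)) else one(as.numeric(ijk))
}

#' Physical coordinate to (fractional) voxel index
#'
#' Inverse of [voxel_to_world()]. Returns fractional indices; round to get
#' the nearest voxel.
#'
#' @inheritParams voxel_to_world
#' @param world Length-3 LPS coordinate in mm, or an n-by-3 matrix.
#' @return Fractional 1-based voxel indices, same shape as the input.
#' @export
world_to_voxel <- function(volume, world) {
  m <- .axis_map(volume)
  one <- function(w) {
    1 + m$sign * (w[m$patient_axis] - volume$origin[m$patient_axis]) /
      volume$spacing
  }
  if (is.matrix(world)) t(apply(world, 1, one)) else one(as.numeric(world))
}

#' Physical bounds of a volume
#'
#' Axis-aligned LPS bounding box of the voxel *centres*.
#'
#' @inheritParams voxel_to_world
#' @return A 2-by-3 matrix with rows `min` and `max` (mm).
#' @export
volume_bounds <- function(volume) {
  d <- dim(volume$voxels)
  corners <- rbind(c(1, 1, 1), c(d[1], 1, 1), c(1, d[2], 1), c(1, 1, d[3]),
                   c(d[1], d[2], 1), c(d[1], 1, d[3]), c(1, d[2], d[3]), d)
  w <- voxel_to_world(volume, corners)
  out <- rbind(min = apply(w, 2, min), max = apply(w, 2, max))
  colnames(out) <- c("x", "y", "z")
  out
}

# LPS coordinates of all voxel centres along one array axis.
.axis_coords <- function(volume, axis) {
  m <- .axis_map(volume)
  p <- m$patient_axis[axis]
  volume$origin[p] + m$sign[axis] * (seq_len(dim(volume$voxels)[axis]) - 1) *
    volume$spacing[axis]
}

.point_in_bounds <- function(volume, point) {
  b <- volume_bounds(volume)
  all(point >= b["min", ] - 1e-9) && all(point <= b["max", ] + 1e-9)
}
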