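#' Synthetic study subject
#'
#' Parameters of one simulated subject: a ground-truth calibration line, the
#' subject's true tissue equivalent mineral densities, bone compartment
#' densities, the per-voxel HU noise level, the compartment geometry, and
#' the seeds driving voxel noise. HU values are generated by inverting the
#' ground-truth line (`HU = (rho - intercept) / slope`), so the full
#' calibration pipeline can be validated against a known answer.
#'
#' @param true_line Ground-truth [calibration_line()].
#' @param tissue_densities Named numeric (air, adipose, muscle) true
#'   densities in mg/cm^3.
#' @param bone_density Cortical bone compartment density in mg/cm^3.
#' @param trabecular_density Trabecular core density in mg/cm^3 (gives the
#'   femur a realistic low-density interior).
#' @param noise_sd Gaussian HU noise standard deviation (>= 0).
#' @param geometry List of compartment dimensions: `dim` (voxels), `spacing`
#'   (mm), and the nested radii `trabecular_radius < cortical_radius <
#'   muscle_radius < adipose_radius` (mm), all inside the field of view with
#'   surrounding air.
#' @param seed Integer seed for the thigh voxel noise.
#' @param phantom_seed Integer seed for the matching phantom scan's noise.
#' @return An object of class `synthetic_subject`.
#' @export
synthetic_subject <- function(true_line,
                              tissue_densities = c(air = -797, adipose = -95,
                                                   muscle = 38),
                              bone_density = 800, trabecular_density = 200,
                              noise_sd = 15,
                              geometry = default_thigh_geometry(),
                              seed = 1L, phantom_seed = seed + 1L) {
  stopifnot(inherits(true_line, "calibration_line"))
  if (true_line$slope == 0)
    stop("ground-truth line must have non-zero slope", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  tissue_densities <- tissue_densities[c("air", "adipose", "muscle")]
  if (any(is.na(tissue_densities)))
    stop("`tissue_densities` must be named air, adipose, muscle",
         call. = FALSE)
  r <- unlist(geometry[c("trabecular_radius", "cortical_radius",
                         "muscle_radius", "adipose_radius")])
  if (any(diff(r) <= 0))
    stop("compartment radii must be strictly nested: trabecular < cortical ",
         "< muscle < adipose", call. = FALSE)
  fov <- geometry$dim[1:2] * geometry$spacing[1:2]
  if (2 * geometry$adipose_radius >= min(fov))
    stop("adipose compartment does not fit inside the field of view with ",
         "surrounding air", call. = FALSE)
  structure(list(true_line = true_line, tissue_densities = tissue_densities,
                 bone_density = bone_density,
                 trabecular_density = trabecular_density,
                 noise_sd = noise_sd, geometry = geometry,
                 seed = as.integer(seed),
                 phantom_seed = as.integer(phantom_seed)),
            class = "synthetic_subject")
}

#' Default synthetic thigh geometry
#'
#' 128 x 128 x 48 voxels at (2, 2, 3) mm: large enough that every reference
#' tissue contributes well over 1000 voxels to the VOI, small enough for
#' sub-second generation. Circular-annular compartments in axial section:
#' trabecular core (8 mm), cortical bone (15 mm), muscle (45 mm), adipose
#' (60 mm), air outside.
#'
#' @param dim Volume dimensions in voxels.
#' @param spacing Voxel spacing in mm.
#' @return Geometry list for [synthetic_subject()].
#' @export
default_thigh_geometry <- function(dim = c(128L, 128L, 48L),
                                   spacing = c(2, 2, 3)) {
  list(dim = as.integer(dim), spacing = as.numeric(spacing),
       trabecular_radius = 8, cortical_radius = 15, muscle_radius = 45,
       adipose_radius = 60)
}

# Invert the calibration line: the HU at which a tissue of density rho sits.
.hu_of_density <- function(line, rho) (rho - line$intercept) / line$slope

#' Generate a synthetic calibration phantom scan
#'
#' Builds a CT volume containing one cylindrical insert per density in
#' `densities`, with each insert's HU obtained by inverting the ground-truth
#' calibration line and adding seeded Gaussian noise; the background is a
#' configurable soft-tissue HU. The returned [phantom_spec()] carries
#' measurement ROIs eroded to the inner portion of each insert (smaller
#' radius, shorter height) so partial-volume rims and boundary slices are
#' avoided.
#'
#' @param line Ground-truth [calibration_line()] (slope != 0).
#' @param densities Insert densities in mg/cm^3 (default the five-insert
#'   50-800 layout of [phantom_spec()]).
#' @param noise_sd Gaussian HU noise SD (>= 0).
#' @param seed Integer seed.
#' @param background_hu Background soft-tissue HU (default 40).
#' @param dim,spacing Volume geometry.
#' @param insert_radius,roi_radius Physical and measurement radii in mm.
#' @return List with `volume` (a [ct_volume()]) and `spec` (a
#'   [phantom_spec()] with cylinder ROIs).
#' @export
generate_phantom_volume <- function(line,
                                    densities = c(50, 100, 200, 400, 800),
                                    noise_sd = 0, seed = 1L,
                                    background_hu = 40,
                                    dim = c(64L, 64L, 8L),
                                    spacing = c(2, 2, 3),
                                    insert_radius = 8, roi_radius = 6) {
  stopifnot(inherits(line, "calibration_line"))
  if (line$slope == 0) stop("line slope must be non-zero", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  n_ins <- length(densities)
  vol <- ct_volume(array(background_hu, dim = dim), spacing = spacing)
  fov <- dim * spacing
  cx <- (seq_len(n_ins) - 0.5) / n_ins * fov[1]
  cy <- fov[2] / 2
  cz <- (fov[3] - spacing[3]) / 2     # mid-height of the voxel-centre stack
  full_h <- fov[3] + spacing[3]       # insert spans every slice
  roi_h <- max(spacing[3], (dim[3] - 3L) * spacing[3])
  rois <- vector("list", n_ins)
  set.seed(seed)
  vox <- vol$voxels
  for (i in seq_len(n_ins)) {
    ins <- cylinder_roi(c(cx[i], cy, cz), c(0, 0, 1), insert_radius, full_h)
    m <- rasterize_roi(vol, ins)
    vox[m] <- .hu_of_density(line, densities[i])
    rois[[i]] <- cylinder_roi(c(cx[i], cy, cz), c(0, 0, 1), roi_radius, roi_h)
  }
  if (noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), sd = noise_sd)
  vol$voxels <- vox
  list(volume = vol,
       spec = phantom_spec(insert_densities = densities, insert_rois = rois))
}

#' Generate a synthetic single-limb thigh scan
#'
#' Builds a CT volume emulating a single-limb thigh acquisition: nested
#' circular compartments in each axial slice (trabecular and cortical bone
#' core, muscle ring, adipose ring, surrounding air), with each
#' compartment's HU obtained by inverting the subject's ground-truth
#' calibration line and adding seeded Gaussian noise. Landmarks are placed
#' so that the reference point (head/knee midpoint) falls mid-shaft with at
#' least `n_slices` caudal slices available.
#'
#' @param subject A [synthetic_subject()].
#' @return List with `volume` (a [ct_volume()]), `landmarks` (a
#'   [landmarks()] object) and `femur_mask` (logical array; the bone core,
#'   strictly inside the muscle compartment).
#' @export
generate_thigh_volume <- function(subject) {
  stopifnot(inherits(subject, "synthetic_subject"))
  g <- subject$geometry
  d <- g$dim
  sp <- g$spacing
  line <- subject$true_line

  head_k <- d[3] - 4L
  knee_k <- 4L
  rp_k <- (head_k + knee_k) / 2
  if (rp_k - 8 < 1 || head_k <= knee_k)
    stop("geometry too short for a 9-slice caudal VOI below the reference ",
         "point (", d[3], " slices)", call. = FALSE)

  cx <- (d[1] - 1) * sp[1] / 2
  cy <- (d[2] - 1) * sp[2] / 2
  x <- (seq_len(d[1]) - 1) * sp[1] - cx
  y <- (seq_len(d[2]) - 1) * sp[2] - cy
  r <- sqrt(outer(x^2, y^2, "+"))

  rho <- c(subject$trabecular_density, subject$bone_density,
           subject$tissue_densities[["muscle"]],
           subject$tissue_densities[["adipose"]],
           subject$tissue_densities[["air"]])
  radii <- c(g$trabecular_radius, g$cortical_radius, g$muscle_radius,
             g$adipose_radius)
  comp <- findInterval(r, radii, left.open = TRUE) + 1L
  hu_plane <- matrix(.hu_of_density(line, rho[comp]), d[1], d[2])

  vox <- array(hu_plane, dim = d)
  if (subject$noise_sd > 0) {
    set.seed(subject$seed)
    vox <- vox + stats::rnorm(length(vox), sd = subject$noise_sd)
  }
  vol <- ct_volume(vox, spacing = sp)

  zk <- function(k) (k - 1) * sp[3]
  lm <- landmarks(
    head_center = c(cx, cy, zk(head_k)),
    medial_epicondyle = c(cx + 40, cy, zk(knee_k)),
    lateral_epicondyle = c(cx - 40, cy, zk(knee_k))
  )
  femur_mask <- array(r <= g$cortical_radius, dim = d)
  list(volume = vol, landmarks = lm, femur_mask = femur_mask)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws `n` subjects: per-subject true tissue densities are Normal around
#' the reference densities with the given SDs (defaults are the
#' cohort-derived spreads 2.6, 2.3 and 3.1 mg/cm^3 for air, adipose and
#' muscle), ground-truth calibration lines are drawn uniformly from the
#' given slope and intercept ranges, and every subject receives its own
#' noise seeds. All randomness flows from the single `seed`, and the
#' per-subject parameters are drawn up front, so the cohort is bitwise
#' reproducible and a subject's volumes do not depend on the order in which
#' the cohort is later realized.
#'
#' @param n Number of subjects (>= 0).
#' @param seed Master integer seed.
#' @param reference_densities Named numeric (air, adipose, muscle) cohort
#'   mean densities in mg/cm^3.
#' @param tissue_density_sds Per-tissue SDs in mg/cm^3 (air, adipose,
#'   muscle; all >= 0).
#' @param slope_range,intercept_range Uniform ranges for the ground-truth
#'   line coefficients (mg/cm^3 per HU; mg/cm^3).
#' @param noise_sd Per-voxel HU noise SD for every subject.
#' @param bone_density,trabecular_density Bone compartment densities in
#'   mg/cm^3.
#' @param geometry Thigh geometry (see [default_thigh_geometry()]).
#' @return List of [synthetic_subject()] objects (empty for `n = 0`).
#' @export
generate_cohort <- function(n, seed = 1L,
                            reference_densities = c(air = -797,
                                                    adipose = -95,
                                                    muscle = 38),
                            tissue_density_sds = c(air = 2.6, adipose = 2.3,
                                                   muscle = 3.1),
                            slope_range = c(0.60, 0.80),
                            intercept_range = c(-20, 0),
                            noise_sd = 15,
                            bone_density = 800, trabecular_density = 200,
                            geometry = default_thigh_geometry()) {
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be >= 0", call. = FALSE)
  if (any(tissue_density_sds < 0))
    stop("tissue density SDs must be >= 0", call. = FALSE)
  if (n == 0L) return(list())
  set.seed(seed)
  dens <- cbind(
    air = stats::rnorm(n, reference_densities[["air"]],
                       tissue_density_sds[[1]]),
    adipose = stats::rnorm(n, reference_densities[["adipose"]],
                           tissue_density_sds[[2]]),
    muscle = stats::rnorm(n, reference_densities[["muscle"]],
                          tissue_density_sds[[3]])
  )
  slopes <- stats::runif(n, slope_range[1], slope_range[2])
  intercepts <- stats::runif(n, intercept_range[1], intercept_range[2])
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  lapply(seq_len(n), function(i) {
    synthetic_subject(
      true_line = calibration_line(intercept = intercepts[i],
                                   slope = slopes[i], r_squared = 1,
                                   n_points = NA_integer_,
                                   method = "phantom"),
      tissue_densities = dens[i, ],
      bone_density = bone_density,
      trabecular_density = trabecular_density,
      noise_sd = noise_sd, geometry = geometry,
      seed = seeds[2L * i - 1L], phantom_seed = seeds[2L * i]
    )
  })
}
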