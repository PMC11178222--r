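#' Reference tissue for phantomless calibration
#'
#' A tissue used as an internal calibration reference: its name, its
#' HA-equivalent reference density, and the HU window inside which its peak
#' is searched in the VOI HU distribution.
#'
#' @param name One of `"air"`, `"adipose"`, `"muscle"`.
#' @param density HA-equivalent reference density in mg/cm^3.
#' @param hu_window Length-2 HU interval `(low, high)` for the peak search.
#' @return An object of class `tissue_reference`.
#' @export
tissue_reference <- function(name = c("air", "adipose", "muscle"), density,
                             hu_window) {
  name <- match.arg(name)
  density <- as.numeric(density)
  hu_window <- as.numeric(hu_window)
  if (length(density) != 1L || !is.finite(density))
    stop("`density` must be a finite scalar (mg/cm^3)", call. = FALSE)
  if (length(hu_window) != 2L || any(!is.finite(hu_window)) ||
      hu_window[1] >= hu_window[2])
    stop("`hu_window` must be an increasing HU interval", call. = FALSE)
  structure(list(name = name, density = density, hu_window = hu_window),
            class = "tissue_reference")
}

#' Default reference tissues
#'
#' Ships the cohort-derived reference equivalent mineral densities for air,
#' adipose and muscle (-797, -95 and 38 mg/cm^3), obtained by averaging
#' phantom-calibrated tissue peak densities over a 24-subject postmenopausal
#' reference group; populations with different body composition may need
#' cohort-specific values from [derive_reference_densities()]. The HU search
#' windows default to disjoint intervals bracketing the expected peaks on a
#' scanner whose HU scale is nominal (air near -1000 HU); widen them via
#' `windows` when the scanner calibration places tissues elsewhere.
#'
#' @param densities Named or positional numeric length-3
#'   (air, adipose, muscle) in mg/cm^3.
#' @param windows List of three length-2 HU intervals, in the same order.
#' @return List of three [tissue_reference()] objects named air, adipose,
#'   muscle.
#' @export
default_tissue_references <- function(densities = c(air = -797, adipose = -95,
                                                    muscle = 38),
                                      windows = list(air = c(-1050, -850),
                                                     adipose = c(-200, -30),
                                                     muscle = c(10, 90))) {
  refs <- list(
    air = tissue_reference("air", densities[[1]], windows[[1]]),
    adipose = tissue_reference("adipose", densities[[2]], windows[[2]]),
    muscle = tissue_reference("muscle", densities[[3]], windows[[3]])
  )
  .validate_tissue_references(refs)
  refs
}

.validate_tissue_references <- function(refs) {
  if (length(refs) != 3L || !all(vapply(refs, inherits, logical(1),
                                        "tissue_reference")))
    stop("need exactly three tissue_reference objects", call. = FALSE)
  names(refs) <- vapply(refs, `[[`, character(1), "name")
  if (!setequal(names(refs), c("air", "adipose", "muscle")))
    stop("reference tissues must be air, adipose and muscle", call. = FALSE)
  refs <- refs[c("air", "adipose", "muscle")]
  dens <- vapply(refs, `[[`, numeric(1), "density")
  if (any(diff(dens) <= 0))
    stop("reference densities must be ordered air < adipose < muscle",
         call. = FALSE)
  w <- t(vapply(refs, `[[`, numeric(2), "hu_window"))
  if (w["air", 2] >= w["adipose", 1] || w["adipose", 2] >= w["muscle", 1])
    stop("tissue HU windows must be disjoint and ordered ",
         "air < adipose < muscle", call. = FALSE)
  invisible(refs)
}

#' Reference point between femoral head and knee centres
#'
#' The reference point (RP) anchoring the VOI is the component-wise midpoint
#' of the femoral head centre and the knee centre.
#'
#' @param head_center,knee_center Length-3 LPS mm coordinates.
#' @return Length-3 LPS mm coordinate.
#' @examples
#' compute_rp(c(0, 0, 0), c(0, 0, -400))
#' @export
compute_rp <- function(head_center, knee_center) {
  head_center <- as.numeric(head_center)
  knee_center <- as.numeric(knee_center)
  if (length(head_center) != 3L || length(knee_center) != 3L ||
      any(!is.finite(c(head_center, knee_center))))
    stop("RP requires two finite length-3 coordinates", call. = FALSE)
  (head_center + knee_center) / 2
}

#' Build the cut volume of interest around the reference point
#'
#' Constructs the VOIcut voxel mask: the `n_slices` axial slices starting at
#' the slice nearest the reference point (RP) and proceeding caudally
#' (RP slice included), with everything strictly posterior of the coronal
#' plane through OP removed, where OP lies `posterior_offset` mm posterior to
#' RP. No medial restriction is applied (single-limb scans). Ties in "slice
#' nearest RP" resolve toward the caudal slice.
#'
#' @param volume A [ct_volume()].
#' @param rp Length-3 LPS mm reference point (see [compute_rp()]).
#' @param n_slices Number of axial slices (default 9).
#' @param posterior_offset Posterior cut distance in mm (default 50).
#' @return Logical mask array of the volume's dimensions, with attributes
#'   `slices` (the axial slice indices used) and `height_mm` (physical VOI
#'   height).
#' @export
build_voi_cut <- function(volume, rp, n_slices = 9, posterior_offset = 50) {
  stopifnot(inherits(volume, "ct_volume"))
  rp <- as.numeric(rp)
  if (length(rp) != 3L || any(!is.finite(rp)))
    stop("`rp` must be a finite length-3 LPS mm coordinate", call. = FALSE)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  if (posterior_offset < 0)
    stop("`posterior_offset` must be >= 0", call. = FALSE)
  if (!.point_in_bounds(volume, rp))
    stop("reference point lies outside the volume", call. = FALSE)

  ax <- .axial_axis(volume)
  z <- .axis_coords(volume, ax$axis)      # patient-z of each slice centre
  dist <- abs(z - rp[3])
  k0 <- which(dist == min(dist))
  if (length(k0) > 1L) {   # tie: take the caudal one
    k0 <- if (ax$caudal_step > 0) max(k0) else min(k0)
  }
  ks <- k0 + ax$caudal_step * (seq_len(n_slices) - 1L)
  d <- dim(volume$voxels)
  if (any(ks < 1L) || any(ks > d[ax$axis]))
    stop("fewer than ", n_slices, " axial slices available caudally from ",
         "the RP slice (slice ", k0, " of ", d[ax$axis], ")", call. = FALSE)

  m <- .axis_map(volume)
  pax <- which(m$patient_axis == 2L)      # array axis carrying anterior/posterior
  y <- .axis_coords(volume, pax)          # patient-y (posterior positive)
  y_op <- rp[2] + posterior_offset
  keep_y <- y <= y_op + 1e-9

  mask <- array(FALSE, dim = d)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax$axis]] <- ks
  idx[[pax]] <- which(keep_y)
  if (length(idx[[pax]]) > 0L)
    mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  attr(mask, "slices") <- sort(ks)
  attr(mask, "height_mm") <- n_slices * volume$spacing[ax$axis]
  mask
}

#' Fit a Gaussian kernel density to a HU sample
#'
#' Estimates the probability density of a HU sample as the mean of normal
#' kernels with scale `bandwidth` (default 5 HU), evaluated on a regular HU
#' grid with step `grid_step` (default 1 HU) covering
#' `[min(samples) - 3 bandwidth, max(samples) + 3 bandwidth]`. The summation
#' is exact up to a truncation of each kernel at 10 bandwidths, where the
#' normal tail is below double precision relative to any peak value.
#'
#' @param samples Numeric HU values (at least `min_samples`).
#' @param bandwidth Kernel scale in HU (> 0).
#' @param grid_step Grid spacing in HU (> 0).
#' @param min_samples Minimum admissible sample size (default 1000); small
#'   VOIs make peak detection unreliable.
#' @return An object of class `hu_distribution`: list with `samples`,
#'   `bandwidth`, `grid`, `density`, and `peaks` (filled by
#'   [detect_tissue_peaks()]).
#' @export
fit_kde <- function(samples, bandwidth = 5, grid_step = 1,
                    min_samples = 1000) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  if (length(samples) < min_samples)
    stop("HU sample too small for density estimation: ", length(samples),
         " values (minimum ", min_samples, ")", call. = FALSE)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be positive", call. = FALSE)
  if (!is.finite(grid_step) || grid_step <= 0)
    stop("`grid_step` must be positive", call. = FALSE)
  lo <- min(samples) - 3 * bandwidth
  hi <- max(samples) + 3 * bandwidth
  n_grid <- floor((hi - lo) / grid_step) + 1L
  grid <- lo + (seq_len(n_grid) - 1) * grid_step
  dens <- .kde_truncated(samples, grid, bandwidth)
  structure(list(samples = samples, bandwidth = bandwidth,
                 grid_step = grid_step, grid = grid, density = dens,
                 peaks = NULL),
            class = "hu_distribution")
}

# Direct Gaussian-kernel summation, truncated at 10 bandwidths (tail
# contribution < 8e-23 of a kernel peak, below double precision). Samples
# are sorted once; each grid point sums only the samples inside its
# truncation window.
.kde_truncated <- function(samples, grid, bandwidth) {
  x <- sort(samples)
  n <- length(x)
  r <- 10 * bandwidth
  lo_idx <- findInterval(grid - r, x) + 1L
  hi_idx <- findInterval(grid + r, x)
  dens <- numeric(length(grid))
  for (i in seq_along(grid)) {
    if (hi_idx[i] < lo_idx[i]) next
    dens[i] <- sum(stats::dnorm(grid[i] - x[lo_idx[i]:hi_idx[i]],
                                sd = bandwidth))
  }
  dens / n
}

#' @export
print.hu_distribution <- function(x, ...) {
  cat("<hu_distribution> ", length(x$samples), " HU samples, bandwidth ",
      format(x$bandwidth), " HU, grid [", format(min(x$grid)), ", ",
      format(max(x$grid)), "] step ", format(x$grid_step), "\n", sep = "")
  if (!is.null(x$peaks)) {
    cat("  peaks (HU): ",
        paste(names(x$peaks), format(x$peaks, digits = 6), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Detect tissue peaks in a fitted HU distribution
#'
#' For each reference tissue, finds the strict local maximum of the kernel
#' density whose grid location falls inside the tissue's HU window, choosing
#' the one with the greatest density value when several exist. The grid
#' location is then refined off-grid by quadratic interpolation of the
#' log-density through the three grid points around the maximum (exact when
#' a single Gaussian-kernel cluster dominates the window). All three tissues
#' must resolve.
#'
#' @param dist A [fit_kde()] result.
#' @param refs Three [tissue_reference()] objects (see
#'   [default_tissue_references()]).
#' @param refine Logical; quadratic off-grid refinement (default `TRUE`).
#' @return Named numeric vector `c(air =, adipose =, muscle =)` of peak HU
#'   locations.
#' @export
detect_tissue_peaks <- function(dist, refs = default_tissue_references(),
                                refine = TRUE) {
  stopifnot(inherits(dist, "hu_distribution"))
  refs <- .validate_tissue_references(refs)
  d <- dist$density
  g <- dist$grid
  n <- length(g)
  if (n < 3L) stop("density grid too short for peak detection", call. = FALSE)
  core <- 2:(n - 1L)
  is_max <- c(FALSE, d[core] > d[core - 1L] & d[core] > d[core + 1L], FALSE)
  peaks <- vapply(refs, function(ref) {
    cand <- which(is_max & g >= ref$hu_window[1] & g <= ref$hu_window[2])
    if (length(cand) == 0L)
      stop("peak not found for tissue `", ref$name, "` in HU window [",
           ref$hu_window[1], ", ", ref$hu_window[2], "]", call. = FALSE)
    k <- cand[which.max(d[cand])]
    if (!refine) return(g[k])
    l <- log(d[(k - 1L):(k + 1L)])
    if (!all(is.finite(l))) return(g[k])
    denom <- l[1] - 2 * l[2] + l[3]
    if (denom >= 0) return(g[k])
    g[k] + 0.5 * (l[1] - l[3]) / denom * dist$grid_step
  }, numeric(1))
  names(peaks) <- names(refs)
  peaks
}

#' Phantomless calibration line from tissue peaks
#'
#' Ordinary least-squares line through the three (peak HU, reference
#' density) pairs, giving `density = intercept + slope * HU` with
#' `method = "phantomless"`.
#'
#' @param peaks Named numeric vector of peak HU values for air, adipose and
#'   muscle (as from [detect_tissue_peaks()]).
#' @param refs Three [tissue_reference()] objects supplying the reference
#'   densities.
#' @return A [calibration_line()].
#' @export
fit_phantomless_calibration <- function(peaks,
                                        refs = default_tissue_references()) {
  refs <- .validate_tissue_references(refs)
  if (length(peaks) != 3L)
    stop("need exactly three tissue peaks, got ", length(peaks),
         call. = FALSE)
  if (is.null(names(peaks)) || !setequal(names(peaks), names(refs)))
    stop("`peaks` must be named air, adipose and muscle", call. = FALSE)
  peaks <- peaks[names(refs)]
  if (anyDuplicated(peaks))
    stop("duplicated peak HU values; calibration line is undefined",
         call. = FALSE)
  dens <- vapply(refs, `[[`, numeric(1), "density")
  fit_calibration(unname(peaks), unname(dens), method = "phantomless",
                  details = list(peaks = as.list(peaks),
                                 reference_densities = as.list(dens)))
}

#' Full phantomless calibration pipeline
#'
#' Runs the automatic internal-tissue calibration end to end: reference
#' point from the landmarks, VOIcut construction, kernel density fit of the
#' VOI HU sample, tissue peak detection, and the final three-point
#' regression. Peak locations, the VOI mask and the VOI physical height are
#' stored in the returned line's `details`.
#'
#' @param volume A [ct_volume()].
#' @param lm A [landmarks()] object (femoral head + knee centres).
#' @param refs Three [tissue_reference()] objects.
#' @param bandwidth KDE bandwidth in HU (default 5).
#' @param grid_step KDE grid step in HU (default 1).
#' @param n_slices VOI slice count (default 9).
#' @param posterior_offset Posterior cut in mm (default 50).
#' @param min_samples Minimum VOI sample size for the KDE.
#' @param keep_mask Logical; store the VOI mask in `details` (default
#'   `FALSE`, masks are large).
#' @return A [calibration_line()] with `method = "phantomless"`.
#' @export
phantomless_calibration <- function(volume, lm,
                                    refs = default_tissue_references(),
                                    bandwidth = 5, grid_step = 1,
                                    n_slices = 9, posterior_offset = 50,
                                    min_samples = 1000, keep_mask = FALSE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(lm, "landmarks"))
  check_landmarks(volume, lm)
  rp <- compute_rp(lm$head_center, lm$knee_center)
  mask <- build_voi_cut(volume, rp, n_slices = n_slices,
                        posterior_offset = posterior_offset)
  dist <- fit_kde(volume$voxels[mask], bandwidth = bandwidth,
                  grid_step = grid_step, min_samples = min_samples)
  peaks <- detect_tissue_peaks(dist, refs)
  line <- fit_phantomless_calibration(peaks, refs)
  line$details$rp <- rp
  line$details$voi_height_mm <- attr(mask, "height_mm")
  line$details$voi_slices <- attr(mask, "slices")
  line$details$n_voi_voxels <- sum(mask)
  if (keep_mask) line$details$voi_mask <- mask
  line
}

#' Derive cohort reference densities from phantom-calibrated subjects
#'
#' For each subject, the detected tissue peak HU values are converted to
#' equivalent mineral densities through that subject's phantom-based
#' calibration line; the per-tissue densities are then averaged over the
#' cohort. This is how population-specific reference densities (and their
#' spread) are obtained for later phantomless use.
#'
#' @param subjects List of subjects; each a list with elements `peaks`
#'   (named numeric, air/adipose/muscle HU) and `line` (a phantom-based
#'   [calibration_line()]). Names of the list are used in error messages.
#' @param windows HU search windows to attach to the returned references
#'   (defaults to the package defaults).
#' @return A list with `references` (three [tissue_reference()] objects
#'   carrying the cohort means) and `summary` (data.frame with per-tissue
#'   mean, SD and subject count).
#' @export
derive_reference_densities <- function(subjects,
                                       windows = list(air = c(-1050, -850),
                                                      adipose = c(-200, -30),
                                                      muscle = c(10, 90))) {
  if (length(subjects) < 1L)
    stop("need at least one subject", call. = FALSE)
  ids <- names(subjects) %||% as.character(seq_along(subjects))
  ids[ids == ""] <- as.character(which(ids == ""))
  tissues <- c("air", "adipose", "muscle")
  dens <- matrix(NA_real_, nrow = length(subjects), ncol = 3,
                 dimnames = list(ids, tissues))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (is.null(s$line) || !inherits(s$line, "calibration_line"))
      stop("subject ", ids[i], " is missing a phantom calibration line",
           call. = FALSE)
    if (is.null(s$peaks) || !all(tissues %in% names(s$peaks)))
      stop("subject ", ids[i], " is missing detected peak(s): ",
           paste(setdiff(tissues, names(s$peaks)), collapse = ", "),
           call. = FALSE)
    dens[i, ] <- apply_calibration(s$line, unname(s$peaks[tissues]))
  }
  means <- colMeans(dens)
  sds <- apply(dens, 2, stats::sd)
  refs <- default_tissue_references(densities = means, windows = windows)
  list(references = refs,
       summary = data.frame(tissue = tissues, mean = unname(means),
                            sd = unname(sds),
                            n_subjects = length(subjects)))
}
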