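#' Default HU search windows for synthetic cohorts
#'
#' The synthetic cohorts draw ground-truth calibration slopes in
#' 0.60-0.80 mg/cm^3 per HU and intercepts in -20-0 mg/cm^3, which places
#' the air peak anywhere between roughly -1330 and -960 HU (and shifts the
#' adipose and muscle peaks accordingly), so the peak-search windows must be
#' wider than the scanner-nominal defaults of
#' [default_tissue_references()] while staying disjoint.
#'
#' @return Named list of three HU intervals.
#' @export
synthetic_study_windows <- function() {
  list(air = c(-1400, -930), adipose = c(-250, -55), muscle = c(25, 115))
}

#' Phantom-based vs phantomless calibration agreement study
#'
#' Runs the full two-route comparison on a synthetic cohort: each subject is
#' calibrated (a) through a matching synthetic phantom scan sharing the
#' subject's ground-truth line and (b) through the automatic phantomless
#' pipeline with fixed reference densities; both calibrations are mapped to
#' voxel-wise Young's modulus on the subject's femur mask and compared with
#' the mean-normalized RMSRE, point-wise relative differences and pooled
#' regression agreement.
#'
#' @param n_subjects Cohort size (default 17).
#' @param seed Master seed for the cohort.
#' @param reference_densities Fixed reference densities used by the
#'   phantomless route (and as cohort means for the generator).
#' @param windows HU peak-search windows (default
#'   [synthetic_study_windows()]).
#' @param law [elasticity_law()] used for material mapping.
#' @param ... Further arguments passed to [generate_cohort()] (noise level,
#'   line ranges, geometry, ...).
#' @return List with `per_subject` (data.frame: true/recovered line
#'   coefficients, per-subject RMSRE and mean relative difference in
#'   percent), `max_rmsre_pct`, `mean_rel_diff_pct` (cohort average of
#'   per-subject means), `pooled_r_squared`, and `pooled_regression`.
#' @export
run_calibration_study <- function(n_subjects = 17, seed = 1L,
                                  reference_densities = c(air = -797,
                                                          adipose = -95,
                                                          muscle = 38),
                                  windows = synthetic_study_windows(),
                                  law = elasticity_law(), ...) {
  cohort <- generate_cohort(n_subjects, seed = seed,
                            reference_densities = reference_densities, ...)
  refs <- default_tissue_references(densities = reference_densities,
                                    windows = windows)
  rows <- vector("list", length(cohort))
  pooled_a <- vector("list", length(cohort))
  pooled_b <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    thigh <- generate_thigh_volume(s)
    ph <- generate_phantom_volume(s$true_line, noise_sd = s$noise_sd,
                                  seed = s$phantom_seed)
    line_phantom <- phantom_calibration(ph$volume, ph$spec)
    line_phantomless <- phantomless_calibration(thigh$volume,
                                                thigh$landmarks, refs = refs)
    e_phantom <- calibrated_modulus_field(thigh$volume, line_phantom,
                                          thigh$femur_mask, law)
    e_phantomless <- calibrated_modulus_field(thigh$volume, line_phantomless,
                                              thigh$femur_mask, law)
    rep <- compare_fields(e_phantom, e_phantomless)
    rows[[i]] <- data.frame(
      subject = i,
      slope_true = s$true_line$slope,
      intercept_true = s$true_line$intercept,
      slope_phantom = line_phantom$slope,
      intercept_phantom = line_phantom$intercept,
      slope_phantomless = line_phantomless$slope,
      intercept_phantomless = line_phantomless$intercept,
      rmsre_pct = rep$rmsre_pct,
      mean_rel_diff_pct = rep$mean_rel_diff,
      max_rel_diff_pct = rep$max_rel_diff,
      n_voxels = rep$n_total
    )
    pooled_a[[i]] <- e_phantom$values
    pooled_b[[i]] <- e_phantomless$values
  }
  per_subject <- do.call(rbind, rows)
  pooled <- regression_agreement(unlist(pooled_a), unlist(pooled_b))
  list(per_subject = per_subject,
       max_rmsre_pct = max(per_subject$rmsre_pct),
       mean_rel_diff_pct = mean(per_subject$mean_rel_diff_pct),
       pooled_r_squared = pooled$r_squared,
       pooled_regression = pooled)
}

#' Derive cohort reference densities from a synthetic cohort
#'
#' Realizes each synthetic subject (thigh scan plus matching phantom scan),
#' detects its tissue peaks, calibrates them with the subject's
#' phantom-based line, and averages the resulting per-tissue densities via
#' [derive_reference_densities()]. The synthetic analogue of deriving
#' population reference values from a phantom-calibrated reference group.
#'
#' @param cohort List of [synthetic_subject()] objects (see
#'   [generate_cohort()]).
#' @param windows HU peak-search windows (default
#'   [synthetic_study_windows()]).
#' @return See [derive_reference_densities()].
#' @export
cohort_reference_densities <- function(cohort,
                                       windows = synthetic_study_windows()) {
  subjects <- lapply(cohort, function(s) {
    thigh <- generate_thigh_volume(s)
    ph <- generate_phantom_volume(s$true_line, noise_sd = s$noise_sd,
                                  seed = s$phantom_seed)
    line <- phantom_calibration(ph$volume, ph$spec)
    rp <- compute_rp(thigh$landmarks$head_center, thigh$landmarks$knee_center)
    mask <- build_voi_cut(thigh$volume, rp)
    dist <- fit_kde(thigh$volume$voxels[mask])
    refs <- default_tissue_references(
      densities = c(air = -797, adipose = -95, muscle = 38),
      windows = windows)
    list(peaks = detect_tissue_peaks(dist, refs), line = line)
  })
  derive_reference_densities(subjects, windows = windows)
}
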