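---
title: "Phantomless QCT calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantomless QCT calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctcalib)
```

## The problem

Quantitative computed tomography (QCT) turns a CT scan into a mineral-density
map: voxel attenuation in Hounsfield units (HU) is converted to a calcium
hydroxyapatite (HA) equivalent density through a linear calibration,

$$\rho_{QCT} \;[\mathrm{mg/cm^3}] = a + b \cdot HU,$$

and the density map in turn drives material-property assignment for
patient-specific finite-element models of bone. The classical way to obtain
$(a, b)$ is to scan a densitometric phantom whose inserts hold known HA
concentrations. Phantom scans are, however, frequently unavailable —
especially for opportunistic use of clinical CT — which motivates
*phantomless* (internal) calibration: the patient's own tissues, whose
equivalent densities are assumed known, play the role of the phantom inserts.

`qctcalib` implements both routes on voxel data, the material mapping that
consumes them, and the agreement statistics used to compare two calibrated
fields, together with a synthetic-data generator that provides ground-truth
fixtures for every stage.

## Phantom-based route

`phantom_calibration()` computes the arithmetic mean HU inside each insert
region and fits ordinary least squares with density as the response and HU as
the regressor — the direction in which the calibration is consumed. The
inverse regression is deliberately not offered. Insert regions can be
supplied as voxel masks or as cylinders in physical coordinates
(`cylinder_roi()`), rasterized by voxel-centre membership. Whether regions
should be eroded to avoid partial-volume rims is left to the user; the
synthetic generator's own ROIs are eroded (smaller radius, end slices
dropped) as a practitioner would.

The default insert layout is the five-density European-Spine-Phantom-style
set, 50–800 mg/cm³, spanning spongious to cortical bone.

## Phantomless route

The automatic pipeline (`phantomless_calibration()`) takes a volume and two
anatomical landmarks, and proceeds:

1. **Reference point (RP).** The midpoint of the femoral head centre and
   the knee centre; the knee centre itself is the midpoint of the medial and
   lateral epicondyles when not given directly.
2. **VOI.** The axial slice nearest RP plus the following slices in the
   caudal direction, nine in total by default, with the RP slice included.
   Ties in "nearest slice" resolve toward the caudal slice so the selection
   is deterministic.
3. **Posterior cut.** Everything strictly posterior of the coronal plane
   through OP — the point 50 mm posterior to RP — is removed (scan-table and
   artifact region). The cut is a single half-space; no medial restriction
   is applied because single-limb volumes are assumed.
4. **Kernel density.** The HU values inside the cut VOI are fitted with a
   Gaussian kernel density, bandwidth 5 HU, evaluated on a regular 1 HU grid
   covering the sample range plus three bandwidths.
5. **Peaks.** Inside each tissue's HU search window the strict local maxima
   of the density are found; the highest wins. Air, adipose and muscle must
   all resolve, otherwise the pipeline stops with the offending tissue named.
6. **Line.** OLS through the three (peak HU, reference density) pairs.

### Reference densities

The shipped defaults are −797, −95 and 38 mg/cm³ for air, adipose and
muscle — values derived by averaging phantom-calibrated tissue peaks over a
24-subject postmenopausal reference cohort. They are deliberately
configurable: tissue composition varies with age, sex and pathology, and
`derive_reference_densities()` (with `cohort_reference_densities()` as its
synthetic-cohort driver) re-derives population-specific values, reporting
per-tissue means and SDs, whenever phantom-calibrated subjects are
available.

### HU search windows

No universal window set exists, because the HU positions of the tissue peaks
depend on the scanner's effective calibration. Two defaults are provided:

* `default_tissue_references()` uses air [−1050, −850], adipose [−200, −30],
  muscle [10, 90] HU — appropriate for real scanners, whose HU scale anchors
  air near −1000 HU.
* `synthetic_study_windows()` uses air [−1400, −930], adipose [−250, −55],
  muscle [25, 115] HU. The synthetic cohorts draw ground-truth slopes in
  0.60–0.80 mg/cm³/HU and intercepts in −20–0 mg/cm³, which moves the air
  peak anywhere between roughly −1330 and −960 HU; the wider windows bracket
  every admissible draw while remaining disjoint and ordered.

Windows must be disjoint and ordered air < adipose < muscle; this is
validated, since overlapping windows would make peak-to-tissue assignment
ambiguous.

### Numerical choices

* **Exact summation.** The density is the exact mean of Gaussian kernels
  (truncated at ten bandwidths, where the tail is below double precision
  relative to any peak), not a binned FFT approximation. `stats::density()`
  is used in the test suite as an independent cross-check only. Exactness
  matters because the noiseless self-consistency contract below is at
  10⁻⁶ relative error, beyond what binning guarantees.
* **Grid.** 1 HU step. A finer grid buys nothing once peaks are refined
  (next point); a coarser one risks merging the adipose and muscle modes.
* **Peak refinement.** The grid argmax is refined off-grid by quadratic
  interpolation of the log-density through the three surrounding grid
  points. For a single Gaussian-kernel cluster the log-density is exactly
  parabolic, so the refinement is exact in that limit; in noisy data it
  removes the ±0.5 HU quantization of the grid. Refinement is skipped at
  grid boundaries or when the local curvature is not negative.
* **Sample floor.** The KDE refuses fewer than 1000 samples by default;
  peaks from tiny VOIs are not trustworthy.
* **Degenerate inputs.** Duplicate peak HU values, non-finite coordinates,
  empty masks and VOIs that run off the caudal end of the volume are hard
  errors, not warnings.

## Material mapping

`density_to_modulus()` applies a configurable power law
$E = c \cdot \rho_{app}^{\,p}$ with the conversion chain
$\rho_{ash} = k \cdot \rho_{QCT}$, $\rho_{app} = \rho_{ash} / r$ (output in
g/cm³). Defaults are the widely used femoral law $E = 6850\,\rho_{app}^{1.49}$
MPa with $k = 1$, $r = 0.6$. Calibrated densities below the floor (default
0 mg/cm³) are clamped before exponentiation — soft-tissue voxels routinely
calibrate below zero and a negative base under a fractional power is
undefined. The comparison between two calibrations is largely insensitive to
the specific monotone law, but a concrete default keeps the moduli in a
physiological range. Mapping is voxel-wise on the image grid; element-wise
integration over a finite-element mesh is out of scope.

## Comparison metrics

For two calibrated fields $x$ (phantom-based) and $\hat{x}$ (phantomless) on
the same mask:

$$\mathrm{RMSRE} = \sqrt{\frac{1}{n}\sum_{i=1}^{n}
  \left(\frac{x_i - \hat{x}_i}{\bar{x}_i}\right)^2},
  \qquad \bar{x}_i = \frac{x_i + \hat{x}_i}{2}.$$

Point-wise relative differences use the same pairwise-mean normalizer, which
(a) keeps the statistic symmetric in the two routes and (b) makes RMSRE
exactly the root mean square of the relative differences — an identity the
tests assert. The pairwise mean was chosen over "phantom-based as reference"
for these two properties; neither choice is canonical for the violin-plot
style summaries, and the normalizer is a single documented decision applied
throughout.

Summary statistics of the relative differences are screened with the
1.5 × IQR rule (quartiles by linear interpolation between order statistics —
`stats::quantile()` type 7, pinned because quartile conventions differ across
software). Fences are computed once on the full sample, never iteratively,
and the screen applies to summaries only: the RMSRE is always computed on
all pairs. `regression_agreement()` adds the OLS slope/intercept/R² of one
field on the other.

## The synthetic generator

`generate_thigh_volume()` emulates what the method actually consumes: an HU
mixture with air, adipose, muscle and bone modes in a geometry where the VOI
construction is meaningful. Compartments are concentric circles in axial
section — air surround, adipose ring, muscle ring, cortical shell, low-density
trabecular core — with landmarks placed so RP falls mid-shaft. Tissue HU
values are obtained by inverting the subject's ground-truth line, plus i.i.d.
Gaussian voxel noise. `generate_phantom_volume()` produces the matching
phantom scan from the same line. `generate_cohort()` draws subject-level
tissue densities Normal(reference, SD) with default SDs (2.6, 2.3, 3.1)
mg/cm³ for air/adipose/muscle — the spread observed when deriving the
reference values — plus uniform ground-truth lines, with all randomness
flowing from one master seed through per-subject stored seeds, so cohorts
are bitwise reproducible and order-independent.

Default conditions, chosen once as the study conditions and not tuned:
17-subject comparison cohorts (24 for reference-density derivation),
slope U[0.60, 0.80] mg/cm³/HU, intercept U[−20, 0] mg/cm³, voxel noise
σ = 15 HU, volumes 128 × 128 × 48 at (2, 2, 3) mm (roughly 8 × 10⁵ voxels,
about 10⁵ of which land in the cut VOI and ~8 × 10³ in the femur mask).
These sizes give every tissue well over 1000 VOI samples and keep a full
17-subject study under half a minute on one core.

What the generator does **not** model: real anatomy, partial-volume mixing at
compartment boundaries, beam hardening, scatter, tube-voltage effects, or
metal artifacts. Passing the synthetic suites therefore demonstrates the
correctness of the geometry, estimation and regression machinery under the
stated noise model — not robustness to scanner physics, which only real
multi-scanner data can establish. The inter-subject tissue-density SDs stand
in for the biological variability that those confounders would add.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
truth <- calibration_line(intercept = -10, slope = 0.7)
subject <- synthetic_subject(truth, noise_sd = 15, seed = 2)
thigh <- generate_thigh_volume(subject)
refs <- default_tissue_references(windows = synthetic_study_windows())
line <- phantomless_calibration(thigh$volume, thigh$landmarks, refs = refs)
line

phantom <- generate_phantom_volume(truth, noise_sd = 15, seed = 3)
line_ph <- phantom_calibration(phantom$volume, phantom$spec)

e_a <- calibrated_modulus_field(thigh$volume, line_ph, thigh$femur_mask)
e_b <- calibrated_modulus_field(thigh$volume, line, thigh$femur_mask)
compare_fields(e_a, e_b)
```

A full two-route cohort study is one call:

```{r study, eval = FALSE}
study <- run_calibration_study(n_subjects = 17, seed = 1)
study$max_rmsre_pct      # worst per-subject Young's-modulus RMSRE (%)
study$mean_rel_diff_pct  # cohort mean element-wise relative difference (%)
study$pooled_r_squared   # pooled regression agreement
```

## Known limitations

* Only axis-aligned acquisitions (every image axis within 5° of an
  anatomical axis) are accepted; the axial-slice VOI concept does not
  transfer to oblique volumes without resampling, which the package does not
  perform.
* The DICOM reader covers explicit-VR little-endian single-frame CT slices
  with 16-bit integer pixels — the common case for the series this tool
  targets; compressed or implicit-VR series must be converted upstream.
* Landmarks are inputs; the package neither segments the femur nor locates
  the head/epicondyle points automatically.
* Reference tissue variants beyond air/adipose/muscle (aortic blood,
  cortical bone) and inline-phantom workflows are out of scope.
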