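# Shared fixtures: small geometries, reference windows for synthetic lines,
# and a pydicom-backed DICOM series writer (Python is the independent
# producer of DICOM fixtures; the package's own reader is under test).

identity_line <- function() {
  calibration_line(intercept = 0, slope = 1, r_squared = 1, n_points = 2L)
}

# Windows wide enough for ground-truth lines with slope 0.6-0.8 and
# intercept -20-0 (see synthetic_study_windows()).
wide_refs <- function(densities = c(air = -797, adipose = -95, muscle = 38)) {
  default_tissue_references(densities = densities,
                            windows = synthetic_study_windows())
}

small_geometry <- function() {
  default_thigh_geometry(dim = c(64L, 64L, 24L), spacing = c(2, 2, 3))
}

# Writes a DICOM series with pydicom. Stored value of pixel (row r, col c,
# slice k), all 1-based, is (k-1)*100 + (r-1)*cols + (c-1). Returns the
# directory. `omit_pixel_spacing` (1-based slice index) drops the
# PixelSpacing tag from that slice; `z_positions` overrides the regular
# slice stack.
write_dicom_fixture <- function(dir, n_slices = 4, rows = 6, cols = 8,
                                pixel_spacing = c(0.7, 0.9), gap = 2.5,
                                slopes = rep(1, n_slices),
                                intercepts = rep(-1024, n_slices),
                                z_positions = NULL,
                                omit_pixel_spacing = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(z_positions)) z_positions <- (seq_len(n_slices) - 1) * gap
  cfg <- list(out_dir = dir, n_slices = n_slices, rows = rows, cols = cols,
              pixel_spacing = pixel_spacing, slopes = slopes,
              intercepts = intercepts, z_positions = z_positions,
              omit_pixel_spacing = omit_pixel_spacing)
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from pydicom.dataset import Dataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, CTImageStorage, generate_uid",
    "cfg = json.load(open(sys.argv[1]))",
    "rows, cols = cfg['rows'], cfg['cols']",
    "for k in range(cfg['n_slices']):",
    "    fm = FileMetaDataset()",
    "    fm.TransferSyntaxUID = ExplicitVRLittleEndian",
    "    fm.MediaStorageSOPClassUID = CTImageStorage",
    "    fm.MediaStorageSOPInstanceUID = generate_uid()",
    "    ds = Dataset(); ds.file_meta = fm",
    "    ds.SOPClassUID = CTImageStorage",
    "    ds.SOPInstanceUID = fm.MediaStorageSOPInstanceUID",
    "    ds.Rows, ds.Columns = rows, cols",
    "    if cfg['omit_pixel_spacing'] != k + 1:",
    "        ds.PixelSpacing = [float(v) for v in cfg['pixel_spacing']]",
    "    ds.SliceThickness = 2.5",
    "    ds.ImagePositionPatient = [0.0, 0.0, float(cfg['z_positions'][k])]",
    "    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]",
    "    ds.InstanceNumber = k + 1",
    "    ds.RescaleSlope = float(cfg['slopes'][k])",
    "    ds.RescaleIntercept = float(cfg['intercepts'][k])",
    "    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "    ds.PixelRepresentation = 1; ds.SamplesPerPixel = 1",
    "    ds.PhotometricInterpretation = 'MONOCHROME2'",
    "    r, c = np.meshgrid(np.arange(rows), np.arange(cols), indexing='ij')",
    "    stored = (k * 100 + r * cols + c).astype(np.int16)",
    "    ds.PixelData = stored.tobytes()",
    "    ds.save_as(f\"{cfg['out_dir']}/slice{k + 1:03d}.dcm\",",
    "               enforce_file_format=True)"
  ), script)
  status <- system2("python", c(script, cfg_path), stdout = TRUE,
                    stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  dir
}

# The HU volume the fixture above encodes, computed independently in R:
# vox[i, j, k] = stored(row j, col i, slice k) * slope_k + intercept_k.
dicom_fixture_hu <- function(n_slices = 4, rows = 6, cols = 8,
                             slopes = rep(1, n_slices),
                             intercepts = rep(-1024, n_slices)) {
  vox <- array(0, dim = c(cols, rows, n_slices))
  for (k in seq_len(n_slices))
    for (j in seq_len(rows))
      for (i in seq_len(cols))
        vox[i, j, k] <- ((k - 1) * 100 + (j - 1) * cols + (i - 1)) *
          slopes[k] + intercepts[k]
  vox
}
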