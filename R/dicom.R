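# Minimal reader for explicit-VR little-endian DICOM CT series.
#
# Scope: single-frame monochrome CT slices with 16-bit integer pixel data and
# per-slice rescale metadata; enough to assemble an axial series into a
# ct_volume. Compressed transfer syntaxes, implicit VR and undefined-length
# sequences are rejected with a clear error.

.EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.u16 <- function(raw, off)
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
.u32 <- function(raw, off)
  .u16(raw, off) + 65536 * .u16(raw, off + 2L)

.tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

# Parse one DICOM file into a named list of raw element values (tag -> raw),
# stopping after PixelData. `path` is used only for error messages.
.parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 132L
  n <- length(raw)
  elements <- new.env(parent = emptyenv())
  transfer_syntax <- NULL
  while (pos + 8L <= n) {
    group <- .u16(raw, pos)
    elem <- .u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 5L):(pos + 6L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit-VR?) element encoding at byte ", pos,
           " in ", path, call. = FALSE)
    if (vr %in% .LONG_VRS) {
      len <- .u32(raw, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L)
      pos <- pos + 8L
    }
    if (len == 4294967295) # undefined length
      stop("undefined-length DICOM element (", .tag_key(group, elem),
           ") not supported in ", path, call. = FALSE)
    if (pos + len > n)
      stop("truncated DICOM element ", .tag_key(group, elem), " in ", path,
           call. = FALSE)
    key <- .tag_key(group, elem)
    if (key == "0002,0010")
      transfer_syntax <- sub("\\s+$", "", rawToChar(raw[(pos + 1L):(pos + len)]))
    if (vr != "SQ")
      assign(key, raw[seq_len(len) + pos], envir = elements)
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  if (!is.null(transfer_syntax) && transfer_syntax != .EXPLICIT_LE)
    stop("unsupported DICOM transfer syntax ", transfer_syntax, " in ", path,
         " (only explicit-VR little-endian is supported)", call. = FALSE)
  as.list(elements)
}

.dcm_string <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  sub("\\s+$", "", rawToChar(v))
}
.dcm_numbers <- function(el, key) {
  s <- .dcm_string(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_u16 <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  .u16(v, 0L)
}

# Decode one parsed slice into list(hu = matrix[col, row], meta...).
.decode_slice <- function(el, path) {
  need <- function(value, what) {
    if (is.null(value))
      stop("DICOM slice ", path, " is missing required ", what, call. = FALSE)
    value
  }
  rows <- need(.dcm_u16(el, "0028,0010"), "Rows tag")
  cols <- need(.dcm_u16(el, "0028,0011"), "Columns tag")
  pixel_spacing <- need(.dcm_numbers(el, "0028,0030"), "PixelSpacing tag")
  ipp <- need(.dcm_numbers(el, "0020,0032"), "ImagePositionPatient tag")
  iop <- need(.dcm_numbers(el, "0020,0037"), "ImageOrientationPatient tag")
  slope <- need(.dcm_numbers(el, "0028,1053"), "RescaleSlope tag")
  intercept <- need(.dcm_numbers(el, "0028,1052"), "RescaleIntercept tag")
  bits <- need(.dcm_u16(el, "0028,0100"), "BitsAllocated tag")
  if (bits != 16L)
    stop("only 16-bit DICOM pixel data supported, got ", bits, " in ", path,
         call. = FALSE)
  signed <- identical(.dcm_u16(el, "0028,0103"), 1L)
  pix <- need(el[["7fe0,0010"]], "PixelData")
  stored <- readBin(pix, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (length(stored) < rows * cols)
    stop("DICOM pixel data shorter than Rows*Columns in ", path,
         call. = FALSE)
  # Pixel data is row-major (rows of `cols` values); store as [column, row].
  hu <- matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  list(hu = hu, rows = rows, cols = cols, pixel_spacing = pixel_spacing,
       ipp = ipp, iop = iop)
}

#' Read a DICOM series into a CT volume
#'
#' Reads all files in a directory as explicit-VR little-endian DICOM slices,
#' converts stored values to HU with each slice's rescale slope/intercept,
#' sorts slices along the slice normal, and checks that in-plane geometry is
#' shared and inter-slice spacing is uniform (relative tolerance 1e-3);
#' violations are hard errors naming the offending slices. DICOM patient
#' coordinates are already LPS, the package's internal convention.
#'
#' @param path Directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path))
    stop("not a directory: ", path, call. = FALSE)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files in DICOM directory: ", path, call. = FALSE)
  slices <- lapply(files, function(f) .decode_slice(.parse_dicom(f), f))

  ref <- slices[[1]]
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s$rows != ref$rows || s$cols != ref$cols ||
        max(abs(s$pixel_spacing - ref$pixel_spacing)) > 1e-6 ||
        max(abs(s$iop - ref$iop)) > 1e-6)
      stop("DICOM slice ", basename(files[i]), " has in-plane geometry ",
           "inconsistent with ", basename(files[1]), call. = FALSE)
  }

  row_dir <- ref$iop[1:3]  # direction of increasing column index
  col_dir <- ref$iop[4:6]  # direction of increasing row index
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]; files <- files[ord]; proj <- proj[ord]

  if (length(slices) > 1L) {
    gaps <- diff(proj)
    med <- stats::median(gaps)
    if (med <= 0)
      stop("DICOM series has coincident slice positions", call. = FALSE)
    bad <- which(abs(gaps - med) > 1e-3 * med)
    if (length(bad))
      stop("inconsistent inter-slice spacing between slices ",
           paste(sprintf("%s/%s", basename(files[bad]),
                         basename(files[bad + 1L])), collapse = ", "),
           " (gaps ", paste(format(gaps[bad]), collapse = ", "),
           " mm vs median ", format(med), " mm)", call. = FALSE)
    slice_spacing <- med
  } else {
    slice_spacing <- .dcm_numbers(.parse_dicom(files[1]), "0018,0050") %||% 1
  }

  vox <- array(0, dim = c(ref$cols, ref$rows, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  # PixelSpacing is (row spacing, column spacing): row spacing is the distance
  # between rows, i.e. along col_dir; column spacing along row_dir.
  spacing <- c(ref$pixel_spacing[2], ref$pixel_spacing[1], slice_spacing)
  dirs <- cbind(row_dir, col_dir, normal)
  orientation <- .directions_to_orientation(dirs)
  ct_volume(vox, spacing = spacing, origin = slices[[1]]$ipp,
            orientation = orientation)
}
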