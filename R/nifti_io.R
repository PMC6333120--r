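# NIfTI-1 reader/writer. No NIfTI package is a dependency: the format is a
# fixed 348-byte header plus raw voxels, read/written here with readBin /
# writeBin. The sform holds the affine at float32; an additional "comment"
# header extension carries the exact float64 geometry as JSON so that
# spacing/origin/direction round-trip losslessly.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, uint16 = 512L)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a volume from disk
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory containing one
#' single-frame DICOM series. For DICOM, slices are sorted by position along
#' the slice normal and the rescale slope/intercept is applied so CT values
#' are in Hounsfield units.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param modality modality tag to attach, see [volume()].
#' @return A `masct_volume`.
#' @export
read_volume <- function(path, modality = "CT") {
  if (!file.exists(path))
    io_stop("no such file or directory: %s", path)
  if (dir.exists(path)) return(read_dicom_series(path, modality))
  hdr <- read_nifti_header(path)
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = hdr$vox_offset)
  n <- prod(hdr$dim)
  dt <- hdr$datatype
  data <-
    if (dt == NIFTI_DT$uint8) as.double(readBin(con, "integer", n, size = 1, signed = FALSE, endian = hdr$endian))
    else if (dt == NIFTI_DT$int16) as.double(readBin(con, "integer", n, size = 2, signed = TRUE, endian = hdr$endian))
    else if (dt == NIFTI_DT$uint16) as.double(readBin(con, "integer", n, size = 2, signed = FALSE, endian = hdr$endian))
    else if (dt == NIFTI_DT$int32) as.double(readBin(con, "integer", n, size = 4, endian = hdr$endian))
    else if (dt == NIFTI_DT$float32) readBin(con, "double", n, size = 4, endian = hdr$endian)
    else if (dt == NIFTI_DT$float64) readBin(con, "double", n, size = 8, endian = hdr$endian)
    else io_stop("unsupported NIfTI datatype code %d in %s", dt, path)
  if (length(data) != n)
    io_stop("truncated NIfTI data section in %s", path)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    data <- data * hdr$scl_slope + hdr$scl_inter
  dim(data) <- hdr$dim
  g <- hdr$geometry
  if (max(abs(crossprod(g$direction) - diag(3))) > 1e-6)
    stop("non-orthonormal direction matrix in NIfTI header", call. = FALSE)
  volume(data, g$spacing, g$origin, g$direction, modality)
}

read_nifti_header <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  raw348 <- readBin(con, "raw", n = 348)
  if (length(raw348) < 348)
    io_stop("not a NIfTI-1 file (too short): %s", path)
  rd <- function(what, n, size, off, endian = "little", signed = TRUE) {
    readBin(raw348[(off + 1):length(raw348)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0) != 348L) {
    endian <- "big"
    if (rd("integer", 1, 4, 0, "big") != 348L)
      io_stop("not a NIfTI-1 file (bad sizeof_hdr): %s", path)
  }
  magic <- rawToChar(raw348[345:347])
  if (!magic %in% c("n+1", "ni1"))
    io_stop("not a NIfTI-1 file (bad magic): %s", path)
  dims <- rd("integer", 8, 2, 40, endian)
  ndim <- dims[1]
  if (ndim < 3) dims <- c(dims[1], dims[2:(ndim + 1)], rep(1L, 3 - ndim))
  if (any(dims[5:8] > 1))
    stop("only 3-D NIfTI volumes are supported", call. = FALSE)
  datatype <- rd("integer", 1, 2, 70, endian)
  pixdim <- rd("double", 8, 4, 76, endian)
  vox_offset <- rd("double", 1, 4, 108, endian)
  scl_slope <- rd("double", 1, 4, 112, endian)
  scl_inter <- rd("double", 1, 4, 116, endian)
  sform_code <- rd("integer", 1, 2, 254, endian)
  qform_code <- rd("integer", 1, 2, 252, endian)
  srow <- matrix(rd("double", 12, 4, 280, endian), 3, 4, byrow = TRUE)
  geometry <- NULL
  ext_flag <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  readBin(con, "raw", 3)
  if (length(ext_flag) == 1 && !is.na(ext_flag) && ext_flag > 0) {
    pos <- 352
    while (pos < vox_offset) {
      esize <- readBin(con, "integer", 1, size = 4, endian = endian)
      ecode <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (length(esize) == 0 || esize <= 8) break
      payload <- readBin(con, "raw", esize - 8)
      if (ecode == 6L) {
        txt <- rawToChar(payload[payload != as.raw(0)])
        if (grepl("masct-geometry", txt, fixed = TRUE)) {
          js <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
          if (!is.null(js))
            geometry <- list(spacing = as.double(js$spacing),
                             origin = as.double(js$origin),
                             direction = matrix(as.double(js$direction), 3, 3))
        }
      }
      pos <- pos + esize
    }
  }
  if (is.null(geometry)) {
    if (sform_code > 0) {
      A <- srow[, 1:3]
      spacing <- sqrt(colSums(A^2))
      geometry <- list(spacing = spacing,
                       direction = sweep(A, 2, spacing, `/`),
                       origin = srow[, 4])
    } else if (qform_code > 0) {
      b <- rd("double", 1, 4, 256, endian); cq <- rd("double", 1, 4, 260, endian)
      d <- rd("double", 1, 4, 264, endian)
      a2 <- 1 - b^2 - cq^2 - d^2
      a <- sqrt(max(a2, 0))
      R <- matrix(c(a^2 + b^2 - cq^2 - d^2, 2 * (b * cq + a * d), 2 * (b * d - a * cq),
                    2 * (b * cq - a * d), a^2 + cq^2 - b^2 - d^2, 2 * (cq * d + a * b),
                    2 * (b * d + a * cq), 2 * (cq * d - a * b), a^2 + d^2 - cq^2 - b^2),
                  3, 3)
      qfac <- if (pixdim[1] < 0) -1 else 1
      R[, 3] <- R[, 3] * qfac
      geometry <- list(spacing = abs(pixdim[2:4]), direction = R,
                       origin = c(rd("double", 1, 4, 268, endian),
                                  rd("double", 1, 4, 272, endian),
                                  rd("double", 1, 4, 276, endian)))
    } else {
      geometry <- list(spacing = abs(pixdim[2:4]), direction = diag(3),
                       origin = c(0, 0, 0))
    }
  }
  list(dim = dims[2:4], datatype = datatype, vox_offset = vox_offset,
       scl_slope = scl_slope, scl_inter = scl_inter, geometry = geometry,
       endian = endian)
}

#' Write a volume to a NIfTI-1 file
#'
#' Image data are stored as float32 (uint8 for masks and label maps); the
#' exact float64 geometry travels in a header extension in addition to the
#' float32 sform, so `read_volume(write_volume(v))` round-trips geometry
#' exactly and data to float32 precision.
#'
#' @param v a `masct_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  validate_volume(v)
  if (!dir.exists(dirname(path)))
    io_stop("directory does not exist: %s", dirname(path))
  d <- dim(v$data)
  is_int8 <- v$modality %in% c("MASK", "LABELS")
  geo_json <- jsonlite::toJSON(
    list(format = "masct-geometry", spacing = v$spacing, origin = v$origin,
         direction = as.vector(v$direction)),
    auto_unbox = TRUE, digits = NA)
  payload <- charToRaw(as.character(geo_json))
  esize <- 8 + length(payload)
  esize <- as.integer(ceiling(esize / 16) * 16)
  pad <- esize - 8 - length(payload)
  vox_offset <- 352 + esize
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x, size = 4) writeBin(as.double(x), con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                      # sizeof_hdr
  wraw(36)                         # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1-3, intent_code
  wi(if (is_int8) NIFTI_DT$uint8 else NIFTI_DT$float32, 2)  # datatype
  wi(if (is_int8) 8L else 32L, 2)  # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, v$spacing, 0, 0, 0, 0))  # pixdim (qfac = 1)
  wf(vox_offset)                   # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1); wi(2L, 1)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  desc <- charToRaw("masct volume")
  writeBin(c(desc, raw(80 - length(desc))), con)
  wraw(24)                         # aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code, sform_code
  wf(rep(0, 6))                    # quatern_b/c/d, qoffset_x/y/z
  A <- v$direction %*% diag(v$spacing)
  wf(c(A[1, ], v$origin[1]))       # srow_x
  wf(c(A[2, ], v$origin[2]))       # srow_y
  wf(c(A[3, ], v$origin[3]))       # srow_z
  wraw(16)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  writeBin(as.raw(c(1, 0, 0, 0)), con)  # extension flag
  wi(esize, 4); wi(6L, 4)          # esize, ecode (comment)
  writeBin(c(payload, raw(pad)), con)
  if (is_int8) {
    writeBin(as.integer(v$data), con, size = 1)
  } else {
    writeBin(as.double(v$data), con, size = 4, endian = "little")
  }
  invisible(path)
}
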