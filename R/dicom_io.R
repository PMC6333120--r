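# Minimal single-series DICOM import (explicit VR little endian,
# uncompressed, single-frame). This is a convenience path for planning-CT /
# MR series; NIfTI is the package's native interchange format.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  if (!identical(rawToChar(readBin(con, "raw", 4)), "DICM"))
    io_stop("not a DICOM file: %s", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  repeat {
    group <- readBin(con, "integer", 1, size = 2, signed = FALSE)
    if (length(group) == 0) break
    element <- readBin(con, "integer", 1, size = 2, signed = FALSE)
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% long_vrs) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4)
      if (len == -1L)
        stop("undefined-length DICOM sequences are not supported", call. = FALSE)
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE)
    }
    key <- dcm_tag(group, element)
    if (key == dcm_tag(0x7FE0, 0x0010)) {
      tags[["pixel_data_len"]] <- len
      tags[["pixel_data_raw"]] <- readBin(con, "raw", len)
      break
    }
    payload <- readBin(con, "raw", len)
    val <- switch(vr,
      US = readBin(payload, "integer", len / 2, size = 2, signed = FALSE),
      SS = readBin(payload, "integer", len / 2, size = 2, signed = TRUE),
      UL = readBin(payload, "integer", len / 4, size = 4),
      DS = as.double(strsplit(trimws(rawToChar(payload)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(payload)), "\\\\")[[1]]),
      trimws(rawToChar(payload[payload != as.raw(0)])))
    tags[[key]] <- val
  }
  tags
}

read_dicom_series <- function(dir, modality = "CT") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    io_stop("empty DICOM directory: %s", dir)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(s) s[[dcm_tag(0x0020, 0x000E)]] %||% "",
                 character(1))
  if (length(unique(uids)) > 1)
    io_stop("directory contains more than one DICOM series: %s", dir)
  first <- slices[[1]]
  rows <- first[[dcm_tag(0x0028, 0x0010)]]
  cols <- first[[dcm_tag(0x0028, 0x0011)]]
  ps <- first[[dcm_tag(0x0028, 0x0030)]]     # (row spacing, column spacing)
  iop <- first[[dcm_tag(0x0020, 0x0037)]]
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(iop))
    io_stop("DICOM series in %s is missing required geometry tags", dir)
  xdir <- iop[1:3]   # along increasing column index
  ydir <- iop[4:6]   # along increasing row index
  zdir <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
            xdir[3] * ydir[1] - xdir[1] * ydir[3],
            xdir[1] * ydir[2] - xdir[2] * ydir[1])
  pos <- t(vapply(slices, function(s) s[[dcm_tag(0x0020, 0x0032)]],
                  double(3)))
  ord <- order(pos %*% zdir)
  slices <- slices[ord]
  pos <- pos[ord, , drop = FALSE]
  nz <- length(slices)
  zsp <- if (nz > 1) {
    dz <- diff(pos %*% zdir)
    if (max(dz) - min(dz) > 1e-3)
      warning("non-uniform DICOM slice spacing; using the median")
    median(dz)
  } else 1
  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    bits <- s[[dcm_tag(0x0028, 0x0100)]] %||% 16L
    rep_ <- s[[dcm_tag(0x0028, 0x0103)]] %||% 1L
    px <- readBin(s$pixel_data_raw, "integer", rows * cols,
                  size = bits / 8, signed = rep_ == 1L)
    slope <- (s[[dcm_tag(0x0028, 0x1053)]] %||% 1)[1]
    inter <- (s[[dcm_tag(0x0028, 0x1052)]] %||% 0)[1]
    # pixel data is row-major: column index fastest -> our first axis
    arr[, , k] <- matrix(px * slope + inter, nrow = cols, ncol = rows)
  }
  direction <- cbind(xdir, ydir, zdir)
  volume(arr, spacing = c(ps[2], ps[1], abs(zsp)), origin = pos[1, ],
         direction = direction, modality = modality)
}
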