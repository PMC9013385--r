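# Minimal DICOM support: uncompressed explicit-VR little-endian single-frame
# CT series only — the subset the rest of the package needs. The writer exists
# to produce synthetic series (fixtures, phantom export); it emits the same
# subset the reader consumes and round-trips through pydicom-compatible files.

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uint <- function(x, n) {
  # little-endian unsigned integer of n bytes as raw
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(dcm_uint(group, 2), dcm_uint(elem, 2), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    hdr <- c(hdr, raw(2), dcm_uint(length(value_raw), 4))
  } else {
    hdr <- c(hdr, dcm_uint(length(value_raw), 2))
  }
  c(hdr, value_raw)
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", dcm_uint(x, 2))

#' Write a CT volume as a synthetic DICOM series
#'
#' Emits one uncompressed explicit-VR little-endian file per slice, with
#' position, pixel-spacing, rescale and instance-number metadata. Intended for
#' generating synthetic series (tests, phantom export); it covers only the
#' CT image subset that [read_volume()] consumes.
#'
#' @param vol A [ct_volume()] in HU (`windowed = FALSE`).
#' @param dir Output directory (created if needed).
#' @param intercept,slope DICOM rescale: stored = (HU - intercept) / slope.
#' @param z_positions Optional per-slice along-axis positions (mm); defaults
#'   to a regular grid at the section thickness.
#' @return Character vector of file paths, invisibly.
#' @export
write_dicom_series <- function(vol, dir, intercept = -1024, slope = 1,
                               z_positions = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$windowed) abort("DICOM export expects HU intensities, not windowed.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$voxels)
  if (is.null(z_positions)) z_positions <- (seq_len(d[1]) - 1) * vol$spacing[1]
  if (length(z_positions) != d[1]) abort("`z_positions` length must equal slice count.")
  series_uid <- "1.2.826.0.1.3680043.9999.1"
  paths <- character(d[1])
  for (k in seq_len(d[1])) {
    sl <- vol$voxels[k, , ]
    stored <- round((sl - intercept) / slope)
    if (any(stored < -32768 | stored > 32767)) {
      abort("stored pixel values out of int16 range; adjust rescale.")
    }
    # row-major pixel order (rows of the image in sequence)
    px_raw <- writeBin(as.integer(as.vector(t(stored))), raw(),
                       size = 2L, endian = "little")
    z <- z_positions[k]
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      dcm_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%.6f", z)),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us(0x0028, 0x0002, 1),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2]),
      dcm_us(0x0028, 0x0011, d[3]),
      dcm_str(0x0028, 0x0030, "DS",
              sprintf("%.6f\\%.6f", vol$spacing[2], vol$spacing[3])),
      dcm_us(0x0028, 0x0100, 16),
      dcm_us(0x0028, 0x0101, 16),
      dcm_us(0x0028, 0x0102, 15),
      dcm_us(0x0028, 0x0103, 1),
      dcm_str(0x0028, 0x1052, "DS", sprintf("%.6f", intercept)),
      dcm_str(0x0028, 0x1053, "DS", sprintf("%.6f", slope)),
      dcm_element(0x7FE0, 0x0010, "OW", px_raw)
    )
    meta <- c(
      dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta), 4)), meta)
    path <- file.path(dir, sprintf("slice_%03d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# Parse one explicit-VR little-endian DICOM file into a tag -> value list.
parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(bytes) >= 132L &&
      rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
  }
  rd_uint <- function(at, n) {
    sum(as.numeric(bytes[at:(at + n - 1L)]) * 256^(0:(n - 1L)))
  }
  out <- list()
  while (pos + 7L <= length(bytes)) {
    group <- rd_uint(pos, 2); elem <- rd_uint(pos + 2L, 2)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort(paste0("implicit-VR or corrupt DICOM element at byte ", pos,
                   " in ", basename(path)))
    }
    if (vr %in% DICOM_LONG_VRS) {
      len <- rd_uint(pos + 8L, 4); pos <- pos + 12L
    } else {
      len <- rd_uint(pos + 6L, 2); pos <- pos + 8L
    }
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = val)
  }
  out
}

dcm_get_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))
}

dcm_get_ds <- function(tags, key) {
  s <- dcm_get_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_get_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  sum(as.numeric(el$bytes) * 256^(seq_along(el$bytes) - 1L))
}

# Read a directory holding one DICOM series; sort slices by along-axis
# position, verify a consistent inter-slice gap, return HU.
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) abort(paste0("no DICOM files in ", dir))
  parsed <- lapply(files, parse_dicom_file)
  zs <- vapply(parsed, function(t) {
    ipp <- dcm_get_ds(t, "00200032")
    if (is.null(ipp)) abort("DICOM slice lacks ImagePositionPatient.")
    ipp[3]
  }, 1.0)
  ord <- order(zs)
  parsed <- parsed[ord]; zs <- zs[ord]
  first <- parsed[[1]]
  rows <- dcm_get_us(first, "00280010"); cols <- dcm_get_us(first, "00280011")
  ps <- dcm_get_ds(first, "00280030")
  n <- length(parsed)
  if (n > 1) {
    gaps <- diff(zs)
    thickness <- stats::median(gaps)
    off <- which(abs(gaps - thickness) > 1e-3)
    if (length(off)) {
      abort(sprintf(
        "inconsistent DICOM slice spacing: gap %.4f mm between z=%.3f and z=%.3f (expected %.4f mm)",
        gaps[off[1]], zs[off[1]], zs[off[1] + 1L], thickness))
    }
  } else {
    thickness <- dcm_get_ds(first, "00180050")
    if (is.null(thickness)) thickness <- 1
  }
  vox <- array(0, c(n, rows, cols))
  for (k in seq_len(n)) {
    t <- parsed[[k]]
    slope <- dcm_get_ds(t, "00281053"); if (is.null(slope)) slope <- 1
    icpt <- dcm_get_ds(t, "00281052"); if (is.null(icpt)) icpt <- 0
    px <- t[["7FE00010"]]
    if (is.null(px)) abort("DICOM slice lacks PixelData.")
    signed <- identical(dcm_get_us(t, "00280103"), 1)
    stored <- readBin(px$bytes, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    vox[k, , ] <- t(matrix(stored, nrow = cols, ncol = rows)) * slope + icpt
  }
  ct_volume(vox, c(thickness, ps[1], ps[2]), windowed = FALSE)
}
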