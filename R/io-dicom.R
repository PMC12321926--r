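# Minimal DICOM CT series I/O: uncompressed little-endian transfer syntaxes
# (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1) only, which
# covers standard axial CT exports. No installed R package provides DICOM
# parsing, so the small subset needed here is implemented directly.

UID_IMPLICIT <- "1.2.840.10008.1.2"
UID_EXPLICIT <- "1.2.840.10008.1.2.1"
UID_CT_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

dcm_u16 <- function(raw, pos) readBin(raw[pos + 0:1], "integer", size = 2,
                                      endian = "little", signed = FALSE)
dcm_u32 <- function(raw, pos) readBin(raw[pos + 0:3], "integer", size = 4,
                                      endian = "little", signed = TRUE)

dcm_string <- function(value) {
  s <- rawToChar(value[value != as.raw(0)])
  trimws(s)
}

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one element starting at pos (1-based); returns list(tag, value, nxt)
dcm_element <- function(raw, pos, explicit) {
  grp <- dcm_u16(raw, pos); ele <- dcm_u16(raw, pos + 2)
  if (explicit) {
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, pos + 8)
      hdr <- 12L
    } else {
      len <- dcm_u16(raw, pos + 6)
      hdr <- 8L
    }
  } else {
    vr <- NA_character_
    len <- dcm_u32(raw, pos + 4)
    hdr <- 8L
  }
  if (len < 0 || len == 4294967295)
    stop("unsupported DICOM element with undefined length at tag (",
         sprintf("%04X,%04X", grp, ele), ")")
  value <- if (len > 0) raw[pos + hdr + 0:(len - 1)] else raw(0)
  list(group = grp, element = ele, vr = vr, value = value, nxt = pos + hdr + len)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  # file meta group (0002) is always explicit VR little endian
  ts <- NULL
  while (pos < length(raw)) {
    grp <- dcm_u16(raw, pos)
    if (grp != 2L) break
    el <- dcm_element(raw, pos, explicit = TRUE)
    if (el$element == 0x0010) ts <- dcm_string(el$value)
    pos <- el$nxt
  }
  if (is.null(ts)) stop("missing transfer syntax UID: ", path)
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported transfer syntax ", ts,
         " (only uncompressed little endian is supported): ", path))
  tags <- list()
  while (pos < length(raw)) {
    el <- dcm_element(raw, pos, explicit)
    key <- sprintf("%04X,%04X", el$group, el$element)
    tags[[key]] <- el
    pos <- el$nxt
  }
  tags
}

tag_string <- function(tags, key, default = NULL) {
  el <- tags[[key]]
  if (is.null(el)) return(default)
  dcm_string(el$value)
}

tag_numbers <- function(tags, key, default = NULL) {
  s <- tag_string(tags, key)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_u16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read an axial CT DICOM series
#'
#' Reads one uncompressed little-endian axial CT series from a directory,
#' calibrates stored values to Hounsfield units via the rescale slope and
#' intercept, orders slices along the superior-inferior axis, and maps the
#' grid into the canonical anatomical frame.
#'
#' @param directory_path Directory holding exactly one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in ", directory_path)
  slices <- lapply(files, read_dicom_file)

  series <- vapply(slices, function(t) tag_string(t, "0020,000E", ""), "")
  if (length(unique(series)) > 1L)
    stop("directory contains more than one series (mixed SeriesInstanceUID)")

  rows <- vapply(slices, function(t) tag_u16(t, "0028,0010"), 1L)
  cols <- vapply(slices, function(t) tag_u16(t, "0028,0011"), 1L)
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    stop("inconsistent pixel matrix dimensions across slices")

  psp <- lapply(slices, function(t) tag_numbers(t, "0028,0030"))
  if (any(vapply(psp, is.null, TRUE))) stop("missing PixelSpacing")
  psp_mat <- do.call(rbind, psp)
  if (max(psp_mat) - min(psp_mat) > 1e-6 && nrow(unique(round(psp_mat, 6))) > 1L)
    stop("inconsistent pixel spacing across slices")
  pixel_spacing <- psp[[1]]  # (row spacing, column spacing)

  iop <- lapply(slices, function(t) tag_numbers(t, "0020,0037"))
  if (any(vapply(iop, is.null, TRUE)))
    stop("missing ImageOrientationPatient tags")
  iop_mat <- do.call(rbind, iop)
  if (nrow(unique(round(iop_mat, 6))) > 1L) stop("inconsistent slice orientation")
  row_dir <- iop[[1]][1:3]; col_dir <- iop[[1]][4:6]
  if (any(abs(abs(row_dir) - round(abs(row_dir))) > 1e-3) ||
      any(abs(abs(col_dir) - round(abs(col_dir))) > 1e-3))
    stop("oblique acquisition is not supported")
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  ipp <- lapply(slices, function(t) tag_numbers(t, "0020,0032"))
  if (any(vapply(ipp, is.null, TRUE))) stop("missing ImagePositionPatient tags")
  zpos <- vapply(ipp, function(p) sum(p * normal), 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]

  if (length(slices) > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0)) stop("duplicate slice positions in series")
    if (max(dz) - min(dz) > 1e-3)
      stop("non-uniform slice spacing (range ",
           signif(min(dz), 6), " to ", signif(max(dz), 6), " mm)")
    slice_spacing <- mean(dz)
  } else {
    slice_spacing <- tag_numbers(slices[[1]], "0018,0050", default = 1)[1]
  }

  n <- length(slices)
  vol <- array(0, c(n, rows[1], cols[1]))
  for (k in seq_len(n)) {
    t <- slices[[k]]
    bits <- tag_u16(t, "0028,0100")
    if (is.null(bits) || bits != 16L) stop("only 16-bit pixel data is supported")
    signed <- identical(tag_u16(t, "0028,0103"), 1L)
    px <- t[["7FE0,0010"]]
    if (is.null(px)) stop("missing PixelData")
    stored <- readBin(px$value, "integer", n = rows[1] * cols[1],
                      size = 2, endian = "little", signed = signed)
    slope <- tag_numbers(t, "0028,1053", default = 1)[1]
    intercept <- tag_numbers(t, "0028,1052", default = 0)[1]
    hu <- slope * stored + intercept
    # stored row-major: rows of the image are contiguous along columns
    vol[k, , ] <- matrix(hu, nrow = rows[1], ncol = cols[1], byrow = TRUE)
  }

  # slice axis points along `normal` in LPS; array dim2 along col_dir,
  # dim3 along row_dir. Convert LPS directions to RAS (negate x and y).
  lps_to_ras <- function(v) c(-v[1], -v[2], v[3])
  dirs <- cbind(lps_to_ras(normal), lps_to_ras(col_dir), lps_to_ras(row_dir))
  axes <- apply(abs(dirs), 2, which.max)
  signs <- vapply(1:3, function(j) sign(dirs[axes[j], j]), 0)
  spacing <- c(slice_spacing, pixel_spacing[1], pixel_spacing[2])
  can <- canonicalize_array(vol, axes, signs, spacing)
  ct_volume(clamp_hu(can$arr), can$spacing,
            meta = list(source = directory_path,
                        series_uid = tag_string(slices[[1]], "0020,000E"),
                        n_slices = n))
}

# ---- writer (used for phantom export and round-trip testing) ----

dcm_pad <- function(s, pad = " ") {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1)
    r <- c(r, if (identical(pad, "nul")) as.raw(0) else charToRaw(pad))
  r
}

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_enc <- function(group, element, vr, value) {
  hdr <- c(enc_u16(group), enc_u16(element), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(hdr, as.raw(c(0, 0)), enc_u32(length(value)), value)
  } else {
    c(hdr, enc_u16(length(value)), value)
  }
}

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian axial CT series (one file per axial
#' slice) with the given rescale calibration. Intended for phantom export
#' and round-trip testing of [read_dicom_series()].
#'
#' @param volume A [ct_volume()].
#' @param directory_path Output directory (created if needed).
#' @param slope,intercept Rescale calibration; stored values are
#'   `(HU - intercept) / slope`, rounded.
#' @return `directory_path`, invisibly.
#' @export
write_dicom_series <- function(volume, directory_path, slope = 1, intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  sp <- volume$spacing
  series_uid <- paste0("1.2.826.0.1.3680043.9999.1.", format(round(stats::runif(1) * 1e8)))
  study_uid <- paste0(series_uid, ".0")
  fmt_ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")
  for (k in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", k)
    # canonical frame is (I, P, L); DICOM patient space is LPS.
    # dim2 (A->P) is the image row direction's perpendicular: rows advance
    # along +P, columns along +L; slice position moves toward -z as k grows.
    ipp <- c(0, 0, -(k - 1) * sp[1])
    stored <- round((volume$voxels[k, , ] - intercept) / slope)
    stored <- pmin(pmax(stored, -32768), 32767)
    px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    body <- c(
      dcm_enc(0x0008, 0x0016, "UI", dcm_pad(UID_CT_CLASS, "nul")),
      dcm_enc(0x0008, 0x0018, "UI", dcm_pad(sop_uid, "nul")),
      dcm_enc(0x0008, 0x0060, "CS", dcm_pad("CT")),
      dcm_enc(0x0018, 0x0050, "DS", dcm_pad(fmt_ds(sp[1]))),
      dcm_enc(0x0020, 0x000D, "UI", dcm_pad(study_uid, "nul")),
      dcm_enc(0x0020, 0x000E, "UI", dcm_pad(series_uid, "nul")),
      dcm_enc(0x0020, 0x0013, "IS", dcm_pad(as.character(k))),
      dcm_enc(0x0020, 0x0032, "DS", dcm_pad(fmt_ds(ipp))),
      dcm_enc(0x0020, 0x0037, "DS", dcm_pad(fmt_ds(c(1, 0, 0, 0, 1, 0)))),
      dcm_enc(0x0028, 0x0002, "US", enc_u16(1)),
      dcm_enc(0x0028, 0x0004, "CS", dcm_pad("MONOCHROME2")),
      dcm_enc(0x0028, 0x0010, "US", enc_u16(d[2])),
      dcm_enc(0x0028, 0x0011, "US", enc_u16(d[3])),
      dcm_enc(0x0028, 0x0030, "DS", dcm_pad(fmt_ds(c(sp[2], sp[3])))),
      dcm_enc(0x0028, 0x0100, "US", enc_u16(16)),
      dcm_enc(0x0028, 0x0101, "US", enc_u16(16)),
      dcm_enc(0x0028, 0x0102, "US", enc_u16(15)),
      dcm_enc(0x0028, 0x0103, "US", enc_u16(1)),
      dcm_enc(0x0028, 0x1052, "DS", dcm_pad(fmt_ds(intercept))),
      dcm_enc(0x0028, 0x1053, "DS", dcm_pad(fmt_ds(slope))),
      dcm_enc(0x7FE0, 0x0010, "OW", px))
    meta_elems <- c(
      dcm_enc(0x0002, 0x0002, "UI", dcm_pad(UID_CT_CLASS, "nul")),
      dcm_enc(0x0002, 0x0003, "UI", dcm_pad(sop_uid, "nul")),
      dcm_enc(0x0002, 0x0010, "UI", dcm_pad(UID_EXPLICIT, "nul")))
    meta <- c(dcm_enc(0x0002, 0x0000, "UL", enc_u32(length(meta_elems))), meta_elems)
    con <- file(file.path(directory_path, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(directory_path)
}
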