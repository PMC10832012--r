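# Minimal DICOM codec for RT Dose / RT Structure Set, explicit VR little
# endian only. Covers exactly what plan ingest needs: flat elements, the
# RT sequences, and uncompressed integer pixel data. Not a general DICOM
# implementation.

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"

u16 <- function(raw, at) readBin(raw[at:(at + 1)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

decode_value <- function(vr, bytes) {
  if (length(bytes) == 0) return(NULL)
  str <- function() sub(" +$", "", rawToChar(bytes[bytes != as.raw(0)]))
  switch(vr,
         UI = , CS = , SH = , LO = , ST = , DA = , TM = , PN = , AE = str(),
         DS = as.numeric(strsplit(str(), "\\", fixed = TRUE)[[1]]),
         IS = as.integer(strsplit(str(), "\\", fixed = TRUE)[[1]]),
         US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                      endian = "little", signed = FALSE),
         UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                      endian = "little"),
         FL = readBin(bytes, "double", n = length(bytes) / 4, size = 4,
                      endian = "little"),
         FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                      endian = "little"),
         bytes)  # OW/OB/unknown kept raw
}

# parse one dataset (explicit VR LE) from `raw` starting at `pos` until
# `end`; returns list(elements = named list, pos = next offset)
parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos <= end - 7) {
    group <- u16(raw, pos); element <- u16(raw, pos + 2)
    if (group == 0xFFFE) {  # item / sequence delimiters have no VR
      len <- u32(raw, pos + 4)
      return(list(elements = out, pos = pos, delim = c(group, element),
                  delim_len = len))
    }
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- u32(raw, pos + 8); body <- pos + 12
    } else {
      len <- u16(raw, pos + 6); body <- pos + 8
    }
    if (vr == "SQ") {
      sq <- parse_sequence(raw, body, len, end)
      out[[tag_key(group, element)]] <- sq$items
      pos <- sq$pos
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length outside a sequence")
      if (len > 0 && body + len - 1 > length(raw))
        stop("element runs past end of file")
      out[[tag_key(group, element)]] <-
        decode_value(vr, if (len > 0) raw[body:(body + len - 1)] else raw(0))
      pos <- body + len
    }
  }
  list(elements = out, pos = pos)
}

parse_sequence <- function(raw, pos, len, file_end) {
  end <- if (len == 0xFFFFFFFF) file_end else pos + len - 1
  items <- list()
  while (pos <= end - 7) {
    group <- u16(raw, pos); element <- u16(raw, pos + 2)
    ilen <- u32(raw, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence: expected an item tag")
    if (ilen == 0xFFFFFFFF) {
      ds <- parse_dataset(raw, pos, end)
      if (is.null(ds$delim) || !(ds$delim[1] == 0xFFFE && ds$delim[2] == 0xE00D))
        stop("unterminated undefined-length item")
      items[[length(items) + 1]] <- ds$elements
      pos <- ds$pos + 8
    } else {
      ds <- parse_dataset(raw, pos, pos + ilen - 1)
      items[[length(items) + 1]] <- ds$elements
      pos <- pos + ilen
    }
  }
  list(items = items, pos = max(pos, if (len == 0xFFFFFFFF) pos else end + 1))
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM file (missing DICM marker)", path))
  pos <- 133
  meta <- list()
  while (pos <= length(raw) - 7 && u16(raw, pos) == 0x0002) {
    element <- u16(raw, pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) { len <- u32(raw, pos + 8); body <- pos + 12 }
    else { len <- u16(raw, pos + 6); body <- pos + 8 }
    meta[[tag_key(0x0002, element)]] <-
      decode_value(vr, if (len > 0) raw[body:(body + len - 1)] else raw(0))
    pos <- body + len
  }
  ts <- meta[["0002,0010"]]
  if (!is.null(ts) && ts != EXPLICIT_LE_UID)
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian)", ts))
  ds <- parse_dataset(raw, pos, length(raw))
  c(meta, ds$elements)
}

# even-odd polygon rasterization of one closed planar contour onto the
# voxel centers of a slice; returns logical nx x ny matrix
rasterize_polygon <- function(px, py, xc, yc) {
  n <- length(px)
  inside <- matrix(FALSE, length(xc), length(yc))
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (j in seq_along(yc)) {
    yv <- yc[j]
    cross <- (py > yv) != (y2 > yv)
    if (!any(cross)) next
    xcr <- px[cross] + (yv - py[cross]) * (x2[cross] - px[cross]) /
      (y2[cross] - py[cross])
    inside[, j] <- (findInterval(xc, sort(xcr)) %% 2) == 1
  }
  inside
}

#' Read a DICOM RT Dose / RT Structure Set pair into a plan bundle
#'
#' Supports uncompressed, explicit-VR little-endian files with an
#' axis-aligned identity orientation. The dose is converted to Gy through
#' the dose-grid scaling attribute; contours are rasterized slice-wise by
#' even-odd polygon fill onto the dose grid (voxel centers; each contour's
#' plane is matched to the nearest dose slice). Physical DICOM millimetres
#' are converted to the package's centimetre convention at ingest. ROIs
#' with no contours are excluded with a warning. The two files must
#' reference the same frame of reference.
#'
#' @param dose_path path to the RT Dose file.
#' @param struct_path path to the RT Structure Set file.
#' @param plan_id identifier for the bundle; default the dose file name.
#' @param prescription_dose prescription in Gy recorded on the bundle
#'   (DICOM RT Dose does not carry it); default 76.
#' @return a [plan_bundle].
#' @export
read_dicom_rt <- function(dose_path, struct_path,
                          plan_id = basename(dose_path),
                          prescription_dose = 76) {
  dd <- read_dicom_file(dose_path)
  if (!identical(dd[["0008,0060"]], "RTDOSE"))
    stop("first file is not an RT Dose object")
  if (!identical(dd[["3004,0002"]], "GY"))
    stop(sprintf("unsupported dose units '%s' (expected GY)", dd[["3004,0002"]]))
  orient <- dd[["0020,0037"]]
  if (!is.null(orient) && max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only identity image orientation is supported")
  nx <- dd[["0028,0011"]]; ny <- dd[["0028,0010"]]
  nz <- dd[["0028,0008"]][1]
  offsets <- dd[["3004,000C"]]
  if (length(offsets) != nz) stop("grid frame offset vector length mismatch")
  dz <- if (nz > 1) diff(offsets) else 1
  if (nz > 2 && diff(range(dz)) > 1e-6)
    stop("non-uniform dose slice spacing is not supported")
  ps <- dd[["0028,0030"]]  # (row spacing, column spacing) mm
  geom <- grid_geometry(origin = dd[["0020,0032"]] / 10,
                        spacing = c(ps[2], ps[1], dz[1]) / 10,
                        dim = c(nx, ny, nz))
  bits <- dd[["0028,0100"]]
  if (!bits %in% c(16L, 32L)) stop("only 16- or 32-bit dose grids supported")
  pix <- dd[["7FE0,0010"]]
  if (bits == 16) {
    vals <- readBin(pix, "integer", n = nx * ny * nz, size = 2,
                    endian = "little", signed = FALSE)
  } else {
    vals <- readBin(pix, "integer", n = nx * ny * nz, size = 4,
                    endian = "little")
    vals <- ifelse(vals < 0, vals + 2^32, vals)  # stored unsigned
  }
  scaling <- dd[["3004,000E"]]
  if (is.null(scaling)) stop("dose grid scaling attribute missing")
  dose <- dose_grid(array(vals * scaling, c(nx, ny, nz)), geom,
                    prescription_dose = prescription_dose)

  sd_ <- read_dicom_file(struct_path)
  if (!identical(sd_[["0008,0060"]], "RTSTRUCT"))
    stop("second file is not an RT Structure Set object")
  frame_dose <- dd[["0020,0052"]]
  frame_struct <- tryCatch(
    sd_[["3006,0010"]][[1]][["0020,0052"]], error = function(e) NULL)
  if (!is.null(frame_dose) && !is.null(frame_struct) &&
      !identical(frame_dose, frame_struct))
    stop("dose and structure set reference different frames of reference")

  roi_names <- list()
  for (it in sd_[["3006,0020"]])
    roi_names[[as.character(it[["3006,0022"]])]] <- it[["3006,0026"]]
  ax <- axis_coords(geom)
  structures <- list()
  for (it in sd_[["3006,0039"]]) {
    num <- as.character(it[["3006,0084"]])
    name <- roi_names[[num]]
    if (is.null(name)) name <- paste0("ROI", num)
    contours <- it[["3006,0040"]]
    if (is.null(contours) || length(contours) == 0) {
      warning(sprintf("ROI '%s' has no contours; excluded", name))
      next
    }
    occ <- array(FALSE, geom$dim)
    for (ct in contours) {
      pts <- matrix(ct[["3006,0050"]] / 10, ncol = 3, byrow = TRUE)  # cm
      k <- which.min(abs(ax$z - pts[1, 3]))
      fill <- rasterize_polygon(pts[, 1], pts[, 2], ax$x, ax$y)
      occ[, , k] <- xor(occ[, , k], fill)  # even-odd across polygons (holes)
    }
    if (!any(occ)) {
      warning(sprintf("ROI '%s' rasterized to an empty mask; excluded", name))
      next
    }
    structures[[name]] <- structure_mask(occ, geom, name)
  }
  plan_bundle(plan_id, dose, structures,
              provenance = c(sprintf("dose: DICOM RT Dose '%s' (scaling %g)",
                                     basename(dose_path), scaling),
                             sprintf("structures: DICOM RT Structure Set '%s', even-odd rasterization onto the dose grid",
                                     basename(struct_path))))
}

## ---- synthetic writer (test fixtures and round-trip checks) ----

encode_element <- function(group, element, vr, value) {
  body <- if (is.raw(value)) value else switch(
    vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    DS = , IS = , UI = , CS = , LO = , SH = {
      s <- if (is.character(value)) paste(value, collapse = "\\")
      else paste(sprintf("%.10g", value), collapse = "\\")
      charToRaw(s)
    },
    stop("unsupported VR for encoding: ", vr))
  if (length(body) %% 2 == 1)
    body <- c(body, if (vr == "UI") as.raw(0) else charToRaw(" "))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% LONG_VRS)
    c(head, as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  else
    c(head, writeBin(length(body), raw(), size = 2, endian = "little"), body)
}

encode_item <- function(dataset_raw) {
  c(as.raw(c(0xFE, 0xFF, 0x00, 0xE0)),  # (FFFE,E000) little endian
    writeBin(length(dataset_raw), raw(), size = 4, endian = "little"),
    dataset_raw)
}

dicom_file_raw <- function(sop_class, dataset_raw) {
  meta <- c(encode_element(0x0002, 0x0002, "UI", sop_class),
            encode_element(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.1"),
            encode_element(0x0002, 0x0010, "UI", EXPLICIT_LE_UID))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta)), meta)
  c(raw(128), charToRaw("DICM"), meta, dataset_raw)
}

#' Write a synthetic DICOM RT Dose / Structure Set pair
#'
#' Emits minimal, standard-conformant explicit-VR little-endian files for
#' testing the ingest path (`read_dicom_rt`) by write-then-read round
#' trips. `write_dicom_rtdose` stores the grid as unsigned 32-bit integers
#' with a dose-grid scaling attribute; `write_dicom_rtstruct` writes
#' closed planar contours (points in cm, converted to DICOM mm).
#' These writers exist for fixture synthesis, not clinical export.
#'
#' @param dose a [dose_grid].
#' @param path output path.
#' @param frame_uid frame-of-reference UID shared by the pair.
#' @return `path`, invisibly.
#' @export
write_dicom_rtdose <- function(dose, path,
                               frame_uid = "1.2.826.0.1.3680043.9999.2") {
  g <- dose$geometry
  mx <- max(dose$dose)
  scaling <- if (mx == 0) 1 else mx / (2^31 - 1)
  ints <- as.integer(round(dose$dose / scaling))
  ds <- c(
    encode_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    encode_element(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.3"),
    encode_element(0x0008, 0x0060, "CS", "RTDOSE"),
    encode_element(0x0020, 0x0032, "DS", g$origin * 10),
    encode_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    encode_element(0x0020, 0x0052, "UI", frame_uid),
    encode_element(0x0028, 0x0002, "US", 1L),
    encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    encode_element(0x0028, 0x0008, "IS", as.character(g$dim[3])),
    encode_element(0x0028, 0x0010, "US", g$dim[2]),
    encode_element(0x0028, 0x0011, "US", g$dim[1]),
    encode_element(0x0028, 0x0030, "DS", c(g$spacing[2], g$spacing[1]) * 10),
    encode_element(0x0028, 0x0100, "US", 32L),
    encode_element(0x0028, 0x0101, "US", 32L),
    encode_element(0x0028, 0x0102, "US", 31L),
    encode_element(0x0028, 0x0103, "US", 0L),
    encode_element(0x3004, 0x0002, "CS", "GY"),
    encode_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    encode_element(0x3004, 0x000A, "CS", "PLAN"),
    encode_element(0x3004, 0x000C, "DS",
                   (seq_len(g$dim[3]) - 1) * g$spacing[3] * 10),
    encode_element(0x3004, 0x000E, "DS", sprintf("%.17g", scaling)),
    encode_element(0x7FE0, 0x0010, "OW",
                   writeBin(ints, raw(), size = 4, endian = "little")))
  writeBin(dicom_file_raw("1.2.840.10008.5.1.4.1.1.481.2", ds), path)
  invisible(path)
}

#' @rdname write_dicom_rtdose
#' @param rois list of ROIs, each `list(name =, contours =)` where
#'   `contours` is a list of `list(z =, points =)` with `z` the slice
#'   position (cm) and `points` an n x 2 matrix of (x, y) vertices in cm.
#' @export
write_dicom_rtstruct <- function(rois, path,
                                 frame_uid = "1.2.826.0.1.3680043.9999.2") {
  ref_frame <- encode_item(encode_element(0x0020, 0x0052, "UI", frame_uid))
  roi_seq <- raw(); contour_seq <- raw()
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    roi_seq <- c(roi_seq, encode_item(c(
      encode_element(0x3006, 0x0022, "IS", as.character(i)),
      encode_element(0x3006, 0x0024, "UI", frame_uid),
      encode_element(0x3006, 0x0026, "LO", roi$name))))
    citems <- raw()
    for (ct in roi$contours) {
      pts_mm <- cbind(ct$points, ct$z) * 10
      citems <- c(citems, encode_item(c(
        encode_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        encode_element(0x3006, 0x0046, "IS", as.character(nrow(pts_mm))),
        encode_element(0x3006, 0x0050, "DS",
                       sprintf("%.6f", as.numeric(t(pts_mm)))))))
    }
    contour_seq <- c(contour_seq, encode_item(c(
      encode_element(0x3006, 0x0040, "SQ", citems),
      encode_element(0x3006, 0x0084, "IS", as.character(i)))))
  }
  ds <- c(
    encode_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    encode_element(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.4"),
    encode_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    encode_element(0x3006, 0x0010, "SQ", ref_frame),
    encode_element(0x3006, 0x0020, "SQ", roi_seq),
    encode_element(0x3006, 0x0039, "SQ", contour_seq))
  writeBin(dicom_file_raw("1.2.840.10008.5.1.4.1.1.481.3", ds), path)
  invisible(path)
}
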