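# Compact DICOM tag walker and RT Dose / RT Structure Set I/O.
# Supports the two uncompressed little-endian transfer syntaxes (implicit
# and explicit VR) and nested sequences with defined or undefined lengths.
# The matching writers emit valid explicit-VR-little-endian files and exist
# so that synthetic test objects can be generated at run time.

uid_implicit_le <- "1.2.840.10008.1.2"
uid_explicit_le <- "1.2.840.10008.1.2.1"
uid_rtdose <- "1.2.840.10008.5.1.4.1.1.481.2"
uid_rtstruct <- "1.2.840.10008.5.1.4.1.1.481.3"

# tags parsed as sequences even with defined lengths under implicit VR
dcm_sq_tags <- c(
  "3006,0020", "3006,0039", "3006,0040", "3006,0080", "3006,0010",
  "3006,0012", "3006,0014", "3006,0016"
)

long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

read_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)
}

read_u32 <- function(bytes, pos) {
  lo <- read_u16(bytes, pos)
  hi <- read_u16(bytes, pos + 2)
  hi * 65536 + lo
}

# Parse a dataset from `pos` (1-based) up to `end`; returns list(elements, pos).
parse_dcm_dataset <- function(bytes, pos, end, explicit) {
  elements <- list()
  while (pos + 7 <= end + 1 && pos <= end) {
    group <- read_u16(bytes, pos)
    elem <- read_u16(bytes, pos + 2)
    pos <- pos + 4
    tag <- dcm_tag(group, elem)
    if (group == 0xFFFE && elem == 0xE00D) { # item delimiter: caller handles
      pos <- pos + 4
      return(list(elements = elements, pos = pos, delimiter = "item"))
    }
    if (group == 0xFFFE && elem == 0xE0DD) { # sequence delimiter
      pos <- pos + 4
      return(list(elements = elements, pos = pos, delimiter = "sequence"))
    }
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      pos <- pos + 2
      if (vr %in% long_vrs) {
        len <- read_u32(bytes, pos + 2)
        pos <- pos + 6
      } else {
        len <- read_u16(bytes, pos)
        pos <- pos + 2
      }
    } else {
      vr <- NA_character_
      len <- read_u32(bytes, pos)
      pos <- pos + 4
    }
    undefined <- len >= 4294967295
    is_sq <- identical(vr, "SQ") || (undefined && !identical(vr, "OB")) ||
      (!explicit && tag %in% dcm_sq_tags)
    if (is_sq) {
      items <- list()
      item_end <- if (undefined) end else pos + len - 1
      while (pos + 7 <= item_end + 1 && pos <= item_end) {
        ig <- read_u16(bytes, pos)
        ie <- read_u16(bytes, pos + 2)
        ilen <- read_u32(bytes, pos + 4)
        pos <- pos + 8
        if (ig == 0xFFFE && ie == 0xE0DD) break
        if (!(ig == 0xFFFE && ie == 0xE000)) {
          abort(sprintf("Malformed sequence %s: expected an item tag.", tag))
        }
        iund <- ilen >= 4294967295
        iend <- if (iund) item_end else pos + ilen - 1
        res <- parse_dcm_dataset(bytes, pos, iend, explicit)
        items[[length(items) + 1]] <- res$elements
        pos <- res$pos
      }
      elements[[tag]] <- list(vr = "SQ", items = items)
    } else {
      if (undefined) abort(sprintf("Undefined length on non-sequence %s.", tag))
      val <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      elements[[tag]] <- list(vr = vr, bytes = val)
    }
  }
  list(elements = elements, pos = pos, delimiter = NA)
}

# Read a DICOM file: returns list(meta, data) of element lists.
read_dcm_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1
  has_preamble <- length(bytes) > 132 &&
    rawToChar(bytes[129:132]) == "DICM"
  ts <- uid_explicit_le
  meta <- list()
  if (has_preamble) {
    pos <- 133
    # file meta group is always explicit VR LE; bounded by its group length
    g <- read_u16(bytes, pos)
    if (g != 2L) abort("Missing file meta group after DICM marker.")
    # parse elements while group == 0002
    repeat {
      if (pos + 7 > length(bytes)) break
      if (read_u16(bytes, pos) != 2L) break
      res <- parse_one_meta(bytes, pos)
      meta[[res$tag]] <- res$element
      pos <- res$pos
    }
    tsel <- meta[["0002,0010"]]
    if (!is.null(tsel)) ts <- dcm_string(tsel)
  }
  if (!ts %in% c(uid_implicit_le, uid_explicit_le)) {
    abort(sprintf("Unsupported transfer syntax '%s'.", ts))
  }
  res <- parse_dcm_dataset(bytes, pos, length(bytes), ts == uid_explicit_le)
  list(meta = meta, data = res$elements)
}

parse_one_meta <- function(bytes, pos) {
  group <- read_u16(bytes, pos)
  elem <- read_u16(bytes, pos + 2)
  vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
  if (vr %in% long_vrs) {
    len <- read_u32(bytes, pos + 8)
    start <- pos + 12
  } else {
    len <- read_u16(bytes, pos + 6)
    start <- pos + 8
  }
  val <- if (len > 0) bytes[start:(start + len - 1)] else raw(0)
  list(
    tag = dcm_tag(group, elem),
    element = list(vr = vr, bytes = val),
    pos = start + len
  )
}

dcm_string <- function(el) {
  if (is.null(el) || !length(el$bytes)) return("")
  b <- el$bytes
  while (length(b) && b[length(b)] %in% as.raw(c(0L, 32L))) b <- b[-length(b)]
  if (!length(b)) "" else rawToChar(b)
}

dcm_numbers <- function(el) {
  if (is.null(el)) return(numeric(0))
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1]])
}

dcm_u16 <- function(el) {
  readBin(el$bytes, "integer", n = length(el$bytes) / 2, size = 2,
          endian = "little", signed = FALSE)
}

#' Read a DICOM RT Dose object
#'
#' Parses an uncompressed little-endian RT Dose file and returns the dose
#' grid in Gy with mm spacing. The stored integer pixel values are multiplied
#' by the mandatory DoseGridScaling tag; the inter-slice spacing comes from
#' the GridFrameOffsetVector, which must be uniform. Axis order of the
#' returned array is (column/x, row/y, frame/z) with `origin` at the first
#' voxel center (ImagePositionPatient); only identity in-plane orientation
#' is supported.
#'
#' @param path File path.
#' @param slice_tolerance_mm Maximum deviation from uniform slice spacing.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path, slice_tolerance_mm = 0.01) {
  f <- read_dcm_file(path)
  d <- f$data
  need <- function(tag, what) {
    el <- d[[tag]]
    if (is.null(el)) abort(sprintf("RT Dose format error: missing %s (%s).", what, tag))
    el
  }
  scaling <- dcm_numbers(need("3004,000E", "DoseGridScaling"))
  offsets <- dcm_numbers(need("3004,000C", "GridFrameOffsetVector"))
  rows <- dcm_u16(need("0028,0010", "Rows"))
  cols <- dcm_u16(need("0028,0011", "Columns"))
  n_frames <- as.integer(dcm_string(need("0028,0008", "NumberOfFrames")))
  spacing_rc <- dcm_numbers(need("0028,0030", "PixelSpacing"))
  ipp <- dcm_numbers(need("0020,0032", "ImagePositionPatient"))
  iop <- d[["0020,0037"]]
  if (!is.null(iop)) {
    o <- dcm_numbers(iop)
    if (max(abs(o - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
      abort("Only identity ImageOrientationPatient is supported.")
    }
  }
  bits <- dcm_u16(need("0028,0100", "BitsAllocated"))
  if (length(offsets) != n_frames) {
    abort("GridFrameOffsetVector length does not match NumberOfFrames.")
  }
  dz <- diff(offsets)
  if (n_frames > 1 && (any(dz <= 0) || diff(range(dz)) > slice_tolerance_mm)) {
    abort(sprintf(
      "Non-uniform slice spacing (range %.4g-%.4g mm) exceeds tolerance %.4g mm.",
      min(dz), max(dz), slice_tolerance_mm
    ))
  }
  px <- need("7FE0,0010", "PixelData")
  n_vox <- as.numeric(cols) * rows * n_frames
  ints <- if (bits == 16) {
    readBin(px$bytes, "integer", n = n_vox, size = 2, endian = "little",
            signed = FALSE)
  } else if (bits == 32) {
    v <- readBin(px$bytes, "integer", n = n_vox, size = 4, endian = "little")
    if (any(v < 0)) abort("32-bit dose values exceed the supported range.")
    v
  } else {
    abort(sprintf("Unsupported BitsAllocated = %d.", bits))
  }
  if (length(ints) != n_vox) abort("PixelData size does not match grid dimensions.")
  vals <- array(ints * scaling, dim = c(cols, rows, n_frames))
  spacing <- c(spacing_rc[2], spacing_rc[1],
               if (n_frames > 1) dz[1] else spacing_rc[1])
  dose_grid(vals, spacing, origin = ipp + c(0, 0, offsets[1]))
}

#' Read a DICOM RT Structure Set
#'
#' Extracts ROI names, interpreted roles, and closed planar contours from an
#' uncompressed little-endian RT Structure Set. Contours are returned in the
#' tidy format expected by [rasterize_structure()].
#'
#' @param path File path.
#' @return A list of entries `name`, `role` ("target" for PTV/GTV/CTV
#'   interpreted types, else "oar") and `contours` (tibble with `x`, `y`,
#'   `z`, `loop`).
#' @export
read_rtstruct <- function(path) {
  f <- read_dcm_file(path)
  d <- f$data
  rois <- d[["3006,0020"]]
  contours <- d[["3006,0039"]]
  if (is.null(rois) || is.null(contours)) {
    abort("RT Structure Set format error: missing ROI or contour sequence.")
  }
  name_by_number <- list()
  for (it in rois$items) {
    num <- dcm_string(it[["3006,0022"]])
    name_by_number[[num]] <- dcm_string(it[["3006,0026"]])
  }
  role_by_number <- list()
  obs <- d[["3006,0080"]]
  if (!is.null(obs)) {
    for (it in obs$items) {
      num <- dcm_string(it[["3006,0084"]])
      type <- toupper(dcm_string(it[["3006,00A4"]]))
      role_by_number[[num]] <-
        if (type %in% c("PTV", "GTV", "CTV")) "target" else "oar"
    }
  }
  purrr::map(contours$items, function(it) {
    num <- dcm_string(it[["3006,0084"]])
    cs <- it[["3006,0040"]]
    loops <- purrr::imap(cs$items %||% list(), function(ct, i) {
      pts <- dcm_numbers(ct[["3006,0050"]])
      m <- matrix(pts, ncol = 3, byrow = TRUE)
      tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], loop = i)
    })
    list(
      name = name_by_number[[num]] %||% paste0("ROI_", num),
      role = role_by_number[[num]] %||% "oar",
      contours = dplyr::bind_rows(loops)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- writers (explicit VR little endian) ----

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
enc_u32 <- function(x) {
  x <- as.numeric(x)
  c(enc_u16(x %% 65536), enc_u16(x %/% 65536))
}

enc_element <- function(group, elem, vr, payload) {
  if (length(payload) %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  head <- c(enc_u16(group), enc_u16(elem), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(head, as.raw(c(0, 0)), enc_u32(length(payload)), payload)
  } else {
    c(head, enc_u16(length(payload)), payload)
  }
}

enc_str <- function(group, elem, vr, s) {
  enc_element(group, elem, vr, charToRaw(paste(s, collapse = "\\")))
}

enc_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, enc_u16(0xFFFE), enc_u16(0xE000), enc_u32(4294967295),
              it, enc_u16(0xFFFE), enc_u16(0xE00D), enc_u32(0))
  }
  c(enc_u16(group), enc_u16(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    enc_u32(4294967295), body,
    enc_u16(0xFFFE), enc_u16(0xE0DD), enc_u32(0))
}

dcm_preamble <- function(sop_class, sop_uid) {
  meta_body <- c(
    enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    enc_str(0x0002, 0x0002, "UI", sop_class),
    enc_str(0x0002, 0x0003, "UI", sop_uid),
    enc_str(0x0002, 0x0010, "UI", uid_explicit_le),
    enc_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.9999.1")
  )
  c(
    raw(128), charToRaw("DICM"),
    enc_element(0x0002, 0x0000, "UL", enc_u32(length(meta_body))),
    meta_body
  )
}

new_uid <- function() {
  sprintf("1.2.826.0.1.3680043.9.9999.%d.%d",
          as.integer(Sys.time()) %% 100000L,
          sample.int(1000000L, 1))
}

fmt_ds <- function(x) sprintf("%.10g", x)

#' Write a dose grid as a DICOM RT Dose object
#'
#' Emits an explicit-VR little-endian RT Dose file with 16- or 32-bit
#' unsigned integer pixels and the grid scaling required to recover Gy.
#' Intended for generating synthetic test objects and for interoperability
#' checks; geometry is written with identity orientation.
#'
#' @param dose A [dose_grid()].
#' @param path Output file.
#' @param bits 16 (default) or 32 bits per stored value.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, bits = 16) {
  if (!bits %in% c(16, 32)) abort("`bits` must be 16 or 32.")
  d <- dim(dose$values)
  maxval <- max(dose$values)
  top <- if (bits == 16) 65000 else 2^31 - 100
  scaling <- if (maxval > 0) maxval / top else 1
  ints <- as.integer(round(dose$values / scaling))
  offsets <- (seq_len(d[3]) - 1) * dose$spacing[3]
  px <- writeBin(ints, raw(), size = bits / 8, endian = "little")
  sop_uid <- new_uid()
  body <- c(
    enc_str(0x0008, 0x0016, "UI", uid_rtdose),
    enc_str(0x0008, 0x0018, "UI", sop_uid),
    enc_str(0x0008, 0x0060, "CS", "RTDOSE"),
    enc_str(0x0020, 0x0032, "DS", fmt_ds(dose$origin)),
    enc_str(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
    enc_element(0x0028, 0x0002, "US", enc_u16(1)),
    enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    enc_str(0x0028, 0x0008, "IS", as.character(d[3])),
    enc_element(0x0028, 0x0010, "US", enc_u16(d[2])),
    enc_element(0x0028, 0x0011, "US", enc_u16(d[1])),
    enc_str(0x0028, 0x0030, "DS", fmt_ds(dose$spacing[c(2, 1)])),
    enc_element(0x0028, 0x0100, "US", enc_u16(bits)),
    enc_element(0x0028, 0x0101, "US", enc_u16(bits)),
    enc_element(0x0028, 0x0102, "US", enc_u16(bits - 1)),
    enc_element(0x0028, 0x0103, "US", enc_u16(0)),
    enc_str(0x3004, 0x0002, "CS", "GY"),
    enc_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    enc_str(0x3004, 0x000A, "CS", "PLAN"),
    enc_str(0x3004, 0x000C, "DS", fmt_ds(offsets)),
    enc_str(0x3004, 0x000E, "DS", sprintf("%.16g", scaling)),
    enc_element(0x7FE0, 0x0010, "OW", px)
  )
  writeBin(c(dcm_preamble(uid_rtdose, sop_uid), body), path)
  invisible(path)
}

#' Write a DICOM RT Structure Set
#'
#' Emits an explicit-VR little-endian RT Structure Set from tidy contour
#' tables, for generating synthetic test objects.
#'
#' @param structures List of entries with `name`, `role` and `contours`
#'   (tibble with `x`, `y`, `z`, `loop`), as returned by [read_rtstruct()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(structures, path) {
  sop_uid <- new_uid()
  roi_items <- purrr::imap(structures, function(s, i) {
    c(
      enc_str(0x3006, 0x0022, "IS", as.character(i)),
      enc_str(0x3006, 0x0026, "LO", s$name)
    )
  })
  contour_items <- purrr::imap(structures, function(s, i) {
    loops <- split(s$contours, s$contours$loop)
    cs <- purrr::map(loops, function(lp) {
      pts <- as.vector(t(as.matrix(lp[, c("x", "y", "z")])))
      c(
        enc_str(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        enc_str(0x3006, 0x0046, "IS", as.character(nrow(lp))),
        enc_str(0x3006, 0x0050, "DS", paste(fmt_ds(pts), collapse = "\\"))
      )
    })
    c(enc_sq(0x3006, 0x0040, unname(cs)),
      enc_str(0x3006, 0x0084, "IS", as.character(i)))
  })
  obs_items <- purrr::imap(structures, function(s, i) {
    type <- if (identical(s$role, "target")) "PTV" else "ORGAN"
    c(
      enc_str(0x3006, 0x0082, "IS", as.character(i)),
      enc_str(0x3006, 0x0084, "IS", as.character(i)),
      enc_str(0x3006, 0x00A4, "CS", type)
    )
  })
  body <- c(
    enc_str(0x0008, 0x0016, "UI", uid_rtstruct),
    enc_str(0x0008, 0x0018, "UI", sop_uid),
    enc_str(0x0008, 0x0060, "CS", "RTSTRUCT"),
    enc_sq(0x3006, 0x0020, unname(roi_items)),
    enc_sq(0x3006, 0x0039, unname(contour_items)),
    enc_sq(0x3006, 0x0080, unname(obs_items))
  )
  writeBin(c(dcm_preamble(uid_rtstruct, sop_uid), body), path)
  invisible(path)
}
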