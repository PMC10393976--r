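# Minimal DICOM reader/writer (Explicit VR Little Endian).
#
# Covers the secondary-capture grayscale dialect the toolkit needs:
# 8/16-bit single-frame MONOCHROME1/2 images with the image identifier
# carried in PatientID.  The reader parses only what ingestion requires
# and reports structured causes (missing pixel data, missing metadata,
# unparseable stream) instead of raising, because de-identified archives
# routinely contain such files.

DICOM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"       # explicit VR LE
DICOM_SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"    # secondary capture
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.10.9000.1"

# VRs that use the 12-byte header (2 reserved + 4-byte length)
.long_vrs <- c("OB", "OW", "OF", "OL", "SQ", "UC", "UR", "UT", "UN")
.known_vrs <- c(.long_vrs, "AE", "AS", "AT", "CS", "DA", "DS", "DT",
                "FL", "FD", "IS", "LO", "LT", "PN", "SH", "SL", "SS",
                "ST", "TM", "UI", "UL", "US")

uint16_le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

uint32_le <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# one explicit-VR element as raw bytes
dcm_element <- function(group, elem, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    n <- n + 1L
  }
  head <- c(uint16_le(group), uint16_le(elem), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0L, 0L)), uint32_le(n), value_raw)
  } else {
    c(head, uint16_le(n), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", uint16_le(x))

#' Write a grayscale image as a DICOM file
#'
#' Secondary-capture layout, Explicit VR Little Endian, single frame.
#' The image identifier is stored in PatientID (0010,0020).
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @param image_id identifier stored in the file.
#' @param bits bits per stored pixel (8 or 16).
#' @param photometric `"MONOCHROME2"` (default; bright = high values) or
#'   `"MONOCHROME1"` (inverted scale).
#' @param include_pixel_data if `FALSE`, the PixelData element is
#'   omitted entirely, emulating de-identified files whose pixel arrays
#'   were stripped.
#' @return `path`, invisibly.
#' @export
write_dicom_gray <- function(pixels, path, image_id, bits = 8,
                             photometric = c("MONOCHROME2", "MONOCHROME1"),
                             include_pixel_data = TRUE) {
  photometric <- match.arg(photometric)
  stopifnot(is.matrix(pixels), bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  vals <- round(clamp01(pixels) * maxval)
  if (photometric == "MONOCHROME1") vals <- maxval - vals
  # DICOM stores pixels row-major
  vals <- as.integer(t(vals))
  if (bits == 8L) {
    pix_raw <- as.raw(vals)
  } else {
    pix_raw <- writeBin(vals, raw(), size = 2L, endian = "little")
  }

  sop_uid <- paste0(DICOM_IMPL_UID, ".",
                    sum(utf8ToInt(as.character(image_id))), ".",
                    nrow(pixels) * ncol(pixels) %% 99991)
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", DICOM_SC_SOP_CLASS),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", DICOM_TRANSFER_SYNTAX),
    dcm_str(0x0002, 0x0012, "UI", DICOM_IMPL_UID)
  )
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", DICOM_SC_SOP_CLASS),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "OT"),
    dcm_str(0x0010, 0x0020, "LO", image_id),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", photometric),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    dcm_us(0x0028, 0x0100, bits),
    dcm_us(0x0028, 0x0101, bits),
    dcm_us(0x0028, 0x0102, bits - 1L),
    dcm_us(0x0028, 0x0103, 0L)
  )
  if (include_pixel_data) {
    body <- c(body, dcm_element(0x7FE0, 0x0010, "OB", pix_raw))
  }
  stream <- c(raw(128L), charToRaw("DICM"),
              dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta))),
              meta, body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(stream, con)
  invisible(path)
}

# parse the elements of an explicit-VR-LE stream into a named list
# ("GGGG,EEEE" -> raw value); stops with an error on malformed streams
parse_dicom_raw <- function(bytes) {
  n <- length(bytes)
  if (n < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM stream")
  }
  pos <- 133L
  out <- list()
  rd16 <- function(i) {
    as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  }
  rd32 <- function(i) {
    as.double(bytes[i]) + 256 * as.double(bytes[i + 1L]) +
      65536 * as.double(bytes[i + 2L]) + 16777216 * as.double(bytes[i + 3L])
  }
  while (pos + 7L <= n) {
    group <- rd16(pos); elem <- rd16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!vr %in% .known_vrs) stop("unsupported or implicit VR encoding")
    if (vr %in% .long_vrs) {
      len <- rd32(pos + 8L)
      val_start <- pos + 12L
    } else {
      len <- rd16(pos + 6L)
      val_start <- pos + 8L
    }
    if (len < 0 || val_start + len - 1 > n) stop("truncated element")
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- if (len > 0) bytes[val_start:(val_start + len - 1)] else raw(0)
    pos <- val_start + len
  }
  out
}

dcm_get_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0L)]))
}

dcm_get_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v) || length(v) < 2L) return(NULL)
  as.integer(v[1L]) + 256L * as.integer(v[2L])
}

# low-level read; raises on structural problems, returns NULL pixels when
# the PixelData element is absent
read_dicom_gray <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  el <- parse_dicom_raw(bytes)
  ts <- dcm_get_str(el, "0002,0010")
  if (!is.null(ts) && ts != DICOM_TRANSFER_SYNTAX) {
    stop("unsupported transfer syntax: ", ts)
  }
  rows <- dcm_get_us(el, "0028,0010")
  cols <- dcm_get_us(el, "0028,0011")
  bits_alloc <- dcm_get_us(el, "0028,0100") %||% 8L
  bits_stored <- dcm_get_us(el, "0028,0101") %||% bits_alloc
  photometric <- dcm_get_str(el, "0028,0004") %||% "MONOCHROME2"
  image_id <- dcm_get_str(el, "0010,0020")
  pix <- el[["7FE0,0010"]]
  pixels <- NULL
  if (!is.null(pix) && !is.null(rows) && !is.null(cols)) {
    npx <- rows * cols
    if (bits_alloc == 8L) {
      if (length(pix) < npx) stop("pixel data shorter than Rows x Columns")
      vals <- as.integer(pix[seq_len(npx)])
    } else if (bits_alloc == 16L) {
      if (length(pix) < 2L * npx) stop("pixel data shorter than Rows x Columns")
      vals <- readBin(pix, integer(), n = npx, size = 2L, signed = FALSE,
                      endian = "little")
    } else {
      stop("unsupported BitsAllocated: ", bits_alloc)
    }
    p <- vals / (2^bits_stored - 1)
    if (photometric == "MONOCHROME1") p <- 1 - p
    # stored row-major; R matrices are column-major
    pixels <- t(matrix(p, nrow = cols, ncol = rows))
  }
  list(pixels = pixels, image_id = image_id, rows = rows, cols = cols,
       bits = bits_stored, photometric = photometric)
}

#' Write a labeled dataset as DICOM fixture files
#'
#' One DICOM file per record, plus a tab-delimited manifest.  A seeded
#' subset of files has its pixel data removed (`corrupt_fraction`) and a
#' disjoint seeded subset is rendered with its smallest dimension below
#' 128 pixels (`undersized_fraction`), emulating the defects found in
#' de-identified archives.  Subset sizes are `round(n * fraction)`.
#'
#' @param dataset a [labeled_dataset()].
#' @param directory output directory (created if needed).
#' @param corrupt_fraction,undersized_fraction fractions in `[0, 1]`
#'   whose sum is at most 1.
#' @param seed integer seed selecting the altered subsets.
#' @return invisibly, a list with `paths` and the `manifest` data frame
#'   (image_id, path, label, altered, rows, cols); the manifest is also
#'   written to `manifest.tsv` in `directory`.
#' @export
write_dicom_fixtures <- function(dataset, directory, corrupt_fraction = 0,
                                 undersized_fraction = 0, seed = 1L) {
  stopifnot(corrupt_fraction >= 0, undersized_fraction >= 0,
            corrupt_fraction + undersized_fraction <= 1)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  if (file.access(directory, 2L) != 0L) {
    stop("directory not writable: ", directory)
  }
  n <- length(dataset)
  n_corrupt <- floor(n * corrupt_fraction + 0.5)
  n_under <- floor(n * undersized_fraction + 0.5)
  altered <- rep("none", n)
  with_seed(seed, {
    pick <- sample.int(n, n_corrupt + n_under)
    if (n_corrupt > 0) altered[pick[seq_len(n_corrupt)]] <- "corrupt"
    if (n_under > 0) altered[pick[n_corrupt + seq_len(n_under)]] <- "undersized"
  })
  paths <- character(n)
  rows <- integer(n)
  cols <- integer(n)
  for (i in seq_len(n)) {
    rec <- dataset$records[[i]]
    px <- rec$pixels
    if (altered[i] == "undersized") {
      side <- min(96L, max(8L, floor(min(dim(px)) / 2)))
      px <- resize_nearest(center_square_crop(px), side)
    }
    rows[i] <- nrow(px)
    cols[i] <- ncol(px)
    paths[i] <- file.path(directory, paste0(rec$image_id, ".dcm"))
    write_dicom_gray(px, paths[i], rec$image_id,
                     include_pixel_data = altered[i] != "corrupt")
  }
  manifest <- data.frame(
    image_id = vapply(dataset$records, function(r) r$image_id, character(1)),
    path = paths,
    label = dataset_labels(dataset),
    altered = altered,
    rows = rows, cols = cols,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(paths = paths, manifest = manifest))
}
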