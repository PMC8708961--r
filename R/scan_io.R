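# Minimal single-frame planar-NM DICOM codec (Part-10, explicit VR little
# endian). Scope: unsigned 8/16-bit MONOCHROME2 grids plus the handful of
# attributes the pipeline needs; raw counts are stored without any modality
# LUT or rescale so that stored values equal acquired counts.

DCM_SOP_CLASS_NM <- "1.2.840.10008.5.1.4.1.1.20"
DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_IMPL_CLASS <- "1.2.826.0.1.3680043.9.7156.1"

uint16_to_raw <- function(v) {
  v <- as.integer(v)
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2, endian = "little")
}

raw_to_uint <- function(bytes, size) {
  n <- length(bytes) %/% size
  readBin(bytes, "integer", n = n, size = size, signed = FALSE, endian = "little")
}

dcm_string_value <- function(value, vr) {
  b <- charToRaw(value)
  if (length(b) %% 2 == 1) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
  b
}

dcm_element <- function(group, elem, vr, value) {
  payload <- switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OB = as.raw(value),
    OW = value,   # already raw
    dcm_string_value(value, vr)  # UI/CS/LO/SH/...
  )
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(head, writeBin(as.integer(length(payload)), raw(), size = 2, endian = "little"),
      payload)
  }
}

# deterministic numeric UID suffix from a string (so regenerated datasets are
# bit-identical); simple polynomial fold over character codes
det_uid <- function(...) {
  s <- paste(..., sep = "/")
  codes <- utf8ToInt(s)
  acc <- 7
  for (k in codes) acc <- (acc * 131 + k) %% 1e12
  paste0("1.2.826.0.1.3680043.9.7156.2.", acc, ".", sum(codes))
}

write_dicom_image <- function(grid, path, patient_id, view) {
  if (any(grid > 65535L)) {
    stop("pixel counts exceed the 16-bit unsigned range (max 65535); refusing to clip",
         call. = FALSE)
  }
  if (any(grid < 0L)) stop("negative counts cannot be stored", call. = FALSE)
  sop_instance <- det_uid(patient_id, view)
  pixels <- uint16_to_raw(as.vector(t(grid)))  # DICOM order: row-major
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", DCM_SOP_CLASS_NM),
    dcm_element(0x0008, 0x0018, "UI", sop_instance),
    dcm_element(0x0008, 0x0060, "CS", "NM"),
    dcm_element(0x0008, 0x103E, "LO", toupper(view)),
    dcm_element(0x0010, 0x0020, "LO", patient_id),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(grid)),
    dcm_element(0x0028, 0x0011, "US", ncol(grid)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OW", pixels)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", c(0x00, 0x01)),
    dcm_element(0x0002, 0x0002, "UI", DCM_SOP_CLASS_NM),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", DCM_TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", DCM_IMPL_CLASS)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

read_dicom_image <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  tags <- list()
  u16 <- function(i) raw_to_uint(bytes[i:(i + 1)], 2)
  u32 <- function(i) {
    readBin(bytes[i:(i + 3)], "integer", size = 4, endian = "little")
  }
  while (pos + 7 <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported transfer syntax (implicit VR?) in ", path, call. = FALSE)
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); body_at <- pos + 12L
    } else {
      len <- u16(pos + 6); body_at <- pos + 8L
    }
    if (len < 0 || body_at + len - 1 > length(bytes)) {
      stop("truncated DICOM element in ", path, call. = FALSE)
    }
    body <- if (len > 0) bytes[body_at:(body_at + len - 1)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, body = body)
    pos <- body_at + len
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NA_character_)
    b <- t$body  # strip trailing padding (space or NUL) before decoding
    while (length(b) && (b[length(b)] == as.raw(0x00) || b[length(b)] == as.raw(0x20))) {
      b <- b[-length(b)]
    }
    rawToChar(b)
  }
  get_us <- function(key) raw_to_uint(tags[[key]]$body, 2)[1]
  ts <- get_str("0002,0010")
  if (!is.na(ts) && ts != DCM_TS_EXPLICIT_LE) {
    stop("unsupported transfer syntax ", ts, call. = FALSE)
  }
  photometric <- get_str("0028,0004")
  if (is.na(photometric) || !startsWith(photometric, "MONOCHROME")) {
    stop("non-monochrome photometric interpretation: ", photometric, call. = FALSE)
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  if (!bits %in% c(8, 16)) stop("unsupported bit depth: ", bits, call. = FALSE)
  px <- tags[["7FE0,0010"]]
  if (is.null(px)) stop("no pixel data in ", path, call. = FALSE)
  vals <- raw_to_uint(px$body, bits %/% 8)
  if (length(vals) < rows * cols) stop("pixel data shorter than Rows x Columns", call. = FALSE)
  grid <- matrix(vals[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  list(grid = grid, patient_id = get_str("0010,0020"),
       view = get_str("0008,103E"), modality = get_str("0008,0060"))
}

#' Write one scan pair as two DICOM files
#'
#' Stores the anterior and posterior count grids as two single-frame NM
#' MONOCHROME2 DICOM files (16-bit unsigned, explicit VR little endian), raw
#' counts without rescaling. Counts above 65535 raise an overflow error
#' rather than being clipped.
#'
#' @param pair A [scan_pair()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector `(anterior_path, posterior_path)`.
#' @export
write_scan_pair <- function(pair, out_dir) {
  stopifnot(inherits(pair, "scan_pair"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  apath <- file.path(out_dir, paste0(pair$patient_id, "_ant.dcm"))
  ppath <- file.path(out_dir, paste0(pair$patient_id, "_post.dcm"))
  write_dicom_image(pair$anterior, apath, pair$patient_id, "anterior")
  write_dicom_image(pair$posterior, ppath, pair$patient_id, "posterior")
  c(apath, ppath)
}

#' Read one scan pair from two DICOM files
#'
#' Returns the raw stored pixel values (no windowing or LUT application).
#' 8-bit files are widened losslessly to the internal integer grid. The class
#' label is not a DICOM attribute; it is carried by the dataset manifest and
#' can be supplied here.
#'
#' @param anterior_path,posterior_path DICOM file paths.
#' @param label Binary label to attach (default 0).
#' @return A [scan_pair()].
#' @export
read_scan_pair <- function(anterior_path, posterior_path, label = 0L) {
  a <- read_dicom_image(anterior_path)
  p <- read_dicom_image(posterior_path)
  if (!identical(dim(a$grid), dim(p$grid))) {
    stop(sprintf("view shape mismatch: anterior %dx%d vs posterior %dx%d",
                 nrow(a$grid), ncol(a$grid), nrow(p$grid), ncol(p$grid)),
         call. = FALSE)
  }
  scan_pair(a$grid, p$grid,
            patient_id = if (is.na(a$patient_id)) "unknown" else a$patient_id,
            label = label,
            meta = list(modality = a$modality))
}

MANIFEST_COLS <- c("patient_id", "anterior_path", "posterior_path", "label", "split")

#' Write / read the dataset manifest
#'
#' The manifest CSV is the dataset handle: one row per patient with the two
#' DICOM paths (relative to the manifest's directory or absolute), the binary
#' label, and a split tag (`train`, `test`, or `fold_k`).
#'
#' @param manifest Data frame with columns `patient_id`, `anterior_path`,
#'   `posterior_path`, `label`, `split`.
#' @param path CSV path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  missing_cols <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_manifest(manifest, check_paths = FALSE)
  utils::write.csv(as.data.frame(manifest)[, MANIFEST_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_paths Verify that every referenced DICOM file exists.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing_cols <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing_cols)) {
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_manifest(m, check_paths = check_paths, base_dir = dirname(path))
  m
}

check_manifest <- function(m, check_paths, base_dir = ".") {
  if (anyDuplicated(m$patient_id)) {
    stop("duplicate patient_id in manifest", call. = FALSE)
  }
  check_binary_labels(m$label)
  if (check_paths) {
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
    missing_files <- !file.exists(resolve(m$anterior_path)) |
      !file.exists(resolve(m$posterior_path))
    if (any(missing_files)) {
      stop("manifest references missing scan files, e.g. ",
           m$anterior_path[which(missing_files)[1]], call. = FALSE)
    }
  }
  invisible(m)
}
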