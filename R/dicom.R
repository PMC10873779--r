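# Minimal DICOM Part 10 codec (explicit VR, little endian) — just enough
# to carry the synthetic chest-image proxies and to scrub metadata at tag
# level. Tags are keyed "GGGG,EEEE" (uppercase hex).

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
TAG_PIXEL_DATA <- "7FE0,0010"

DICOM_VR <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0010,0010" = "PN", "0010,0020" = "LO", "0010,0030" = "DA",
  "0010,0040" = "CS", "0008,0020" = "DA", "0008,0030" = "TM",
  "0008,0080" = "LO", "0008,0090" = "PN", "0008,1030" = "LO",
  "0020,000D" = "UI", "0020,000E" = "UI",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "7FE0,0010" = "OW")

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

tag_parts <- function(key) {
  strtoi(strsplit(key, ",", fixed = TRUE)[[1]], 16L)
}

dicom_element <- function(key, value, vr = NULL) {
  vr <- vr %||% unname(DICOM_VR[key])
  if (is.null(vr) || is.na(vr)) stop("unknown VR for tag ", key)
  list(key = key, vr = vr, value = value)
}

#' Create an in-memory DICOM dataset
#'
#' Builds a single-frame 8-bit grayscale (MONOCHROME2) secondary-capture
#' dataset from an integer pixel matrix.
#'
#' @param pixels integer matrix (rows x columns) with values in 0..255.
#' @param modality DICOM modality code (e.g. `"CR"`).
#' @param sop_instance_uid,study_uid,series_uid instance/study/series UIDs.
#' @param pixel_spacing two numbers, mm per pixel (row, column).
#' @param extra_elements optional named list `tag key -> list(value, vr)`
#'   for additional (possibly sensitive) elements, used in tests.
#' @return an object of class `dicom_dataset`.
#' @export
dicom_create <- function(pixels, modality = "CR",
                         sop_instance_uid = "1.2.826.0.1.3680043.9999.1",
                         study_uid = "1.2.826.0.1.3680043.9999.2",
                         series_uid = "1.2.826.0.1.3680043.9999.3",
                         pixel_spacing = c(0.5, 0.5),
                         extra_elements = NULL) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 255),
            all(pixels == floor(pixels)))
  els <- list(
    dicom_element("0008,0016", SOP_CLASS_SECONDARY_CAPTURE),
    dicom_element("0008,0018", sop_instance_uid),
    dicom_element("0008,0060", modality),
    dicom_element("0020,000D", study_uid),
    dicom_element("0020,000E", series_uid),
    dicom_element("0028,0002", 1L),
    dicom_element("0028,0004", "MONOCHROME2"),
    dicom_element("0028,0010", nrow(pixels)),
    dicom_element("0028,0011", ncol(pixels)),
    dicom_element("0028,0030", paste(format(pixel_spacing, trim = TRUE),
                                     collapse = "\\")),
    dicom_element("0028,0100", 8L),
    dicom_element("0028,0101", 8L),
    dicom_element("0028,0102", 7L),
    dicom_element("0028,0103", 0L),
    # row-major byte order (rows of the image are contiguous), padded even
    dicom_element(TAG_PIXEL_DATA, as.raw(as.integer(t(pixels))))
  )
  names(els) <- vapply(els, `[[`, "", "key")
  for (key in names(extra_elements %||% list())) {
    e <- extra_elements[[key]]
    els[[key]] <- dicom_element(key, e$value, e$vr)
  }
  structure(list(elements = els[order(names(els))]),
            class = "dicom_dataset")
}

#' @export
print.dicom_dataset <- function(x, ...) {
  cat(sprintf("<dicom_dataset> %d elements\n", length(x$elements)))
  for (e in x$elements)
    cat(sprintf("  (%s) %s %s\n", e$key, e$vr,
                if (is.raw(e$value)) sprintf("<%d bytes>", length(e$value))
                else paste(e$value, collapse = "\\")))
  invisible(x)
}

#' Extract the pixel matrix from a dataset
#' @param ds a `dicom_dataset` with 8-bit grayscale pixel data.
#' @return integer matrix (rows x columns).
#' @export
dicom_pixels <- function(ds) {
  rows <- ds$elements[["0028,0010"]]$value
  cols <- ds$elements[["0028,0011"]]$value
  bytes <- ds$elements[[TAG_PIXEL_DATA]]$value
  matrix(as.integer(bytes[seq_len(rows * cols)]), nrow = rows,
         ncol = cols, byrow = TRUE)
}

encode_uint <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                          endian = "little")

encode_element_value <- function(e) {
  if (e$vr %in% c("OB", "OW")) {
    v <- as.raw(e$value)
    if (length(v) %% 2L) v <- c(v, as.raw(0))
    return(v)
  }
  if (e$vr == "US") return(encode_uint(e$value, 2L))
  if (e$vr == "UL") return(encode_uint(e$value, 4L))
  s <- paste(as.character(e$value), collapse = "\\")
  v <- charToRaw(s)
  if (length(v) %% 2L)
    v <- c(v, if (e$vr == "UI") as.raw(0) else charToRaw(" "))
  v
}

encode_element <- function(e) {
  gp_el <- tag_parts(e$key)
  val <- encode_element_value(e)
  long_form <- e$vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(encode_uint(gp_el[1], 2L), encode_uint(gp_el[2], 2L),
    charToRaw(e$vr),
    if (long_form) c(as.raw(c(0, 0)), encode_uint(length(val), 4L))
    else encode_uint(length(val), 2L),
    val)
}

#' Read/write DICOM Part 10 files (explicit VR little endian)
#'
#' @param ds a `dicom_dataset`.
#' @param path file path.
#' @return `write_dicom` returns the path invisibly; `read_dicom` a
#'   `dicom_dataset`.
#' @export
write_dicom <- function(ds, path) {
  stopifnot(inherits(ds, "dicom_dataset"))
  sop_uid <- ds$elements[["0008,0018"]]$value %||% "0"
  meta <- list(
    dicom_element("0002,0001", as.raw(c(0, 1)), vr = "OB"),
    dicom_element("0002,0002", SOP_CLASS_SECONDARY_CAPTURE, vr = "UI"),
    dicom_element("0002,0003", sop_uid, vr = "UI"),
    dicom_element("0002,0010", TRANSFER_SYNTAX_EXPLICIT_LE, vr = "UI"))
  meta_bytes <- do.call(c, lapply(meta, encode_element))
  group_len <- encode_element(
    dicom_element("0002,0000", length(meta_bytes), vr = "UL"))
  body <- do.call(c, lapply(ds$elements[order(names(ds$elements))],
                            encode_element))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), group_len, meta_bytes, body),
           con)
  invisible(path)
}

decode_element_value <- function(vr, bytes) {
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (vr == "US")
    return(readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                   endian = "little", signed = FALSE))
  if (vr == "UL")
    return(readBin(bytes, "integer", n = length(bytes) / 4L, size = 4L,
                   endian = "little"))
  s <- rawToChar(bytes[bytes != as.raw(0)])
  sub("[ ]+$", "", s)
}

#' @rdname write_dicom
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133L
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                              endian = "little")
  els <- list()
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or malformed element at byte ", pos)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    val <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw()
    key <- tag_key(group, element)
    if (group != 0x0002L)  # skip file meta in the dataset view
      els[[key]] <- list(key = key, vr = vr,
                         value = decode_element_value(vr, val))
    pos <- vstart + len
  }
  structure(list(elements = els[order(names(els))]), class = "dicom_dataset")
}

#' DICOM metadata whitelist
#'
#' Only tags confirmed non-sensitive are retained by [deidentify_dicom()];
#' everything else is removed. The pixel data tag is always allowed; the
#' directly identifying tags (PatientName, PatientID, PatientBirthDate)
#' can never be whitelisted.
#'
#' @param allowed_tags character vector of `"GGGG,EEEE"` keys.
#' @return object of class `dicom_whitelist`.
#' @export
dicom_whitelist <- function(allowed_tags = c(
  "0008,0016", "0008,0018", "0008,0060",  # SOP class/instance, modality
  "0020,000D", "0020,000E",               # study / series UID
  "0028,0002", "0028,0004", "0028,0010", "0028,0011",
  "0028,0030", "0028,0100", "0028,0101", "0028,0102", "0028,0103")) {
  forbidden <- c("0010,0010", "0010,0020", "0010,0030")
  hit <- intersect(toupper(allowed_tags), forbidden)
  if (length(hit))
    stop("patient-identifying tags can never be whitelisted: ",
         paste(hit, collapse = ", "))
  structure(list(allowed_tags = unique(c(toupper(allowed_tags),
                                         TAG_PIXEL_DATA))),
            class = "dicom_whitelist")
}

#' Scrub DICOM metadata with a whitelist
#'
#' Removes every element whose tag is not on the whitelist. Pixel data is
#' passed through byte-identically. Idempotent.
#'
#' @param ds a `dicom_dataset`.
#' @param wl a `dicom_whitelist`.
#' @return the scrubbed `dicom_dataset`.
#' @export
deidentify_dicom <- function(ds, wl = dicom_whitelist()) {
  stopifnot(inherits(ds, "dicom_dataset"), inherits(wl, "dicom_whitelist"))
  ds$elements <- ds$elements[names(ds$elements) %in% wl$allowed_tags]
  ds
}
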