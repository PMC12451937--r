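# Minimal DICOM Part-10 file I/O: Explicit VR Little Endian only.
#
# The harvester needs top-level header elements of single files; pixel data is
# never interpreted, sequence (SQ) content is skipped, and only the explicit
# little-endian transfer syntax is supported for both reading and writing.
# Conformance of the writer is cross-checked against pydicom in the test suite.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_ROOT_TEST <- "1.2.826.0.1.3680043.9999"  # test OID: clearly synthetic UIDs
IMPLEMENTATION_UID <- paste0(UID_ROOT_TEST, ".0.1")
MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"  # MR Image Storage

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) {
  # values may exceed .Machine$integer.max semantics for lengths; all lengths
  # used here are small, but keep the path through double safe
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(uint16_le(lo), uint16_le(hi))
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

encode_value <- function(vr, value) {
  if (vr %in% c("FL")) return(writeBin(as.numeric(value), raw(), size = 4, endian = "little"))
  if (vr %in% c("FD")) return(writeBin(as.numeric(value), raw(), size = 8, endian = "little"))
  if (vr %in% c("SL")) return(writeBin(as.integer(value), raw(), size = 4, endian = "little"))
  if (vr %in% c("UL")) return(uint32_le(value))
  if (vr %in% c("SS")) return(writeBin(as.integer(value), raw(), size = 2, endian = "little"))
  if (vr %in% c("US")) return(uint16_le(value))
  if (vr %in% c("SV", "UV")) {
    # 64-bit integers; values used in fixtures fit in 32 bits
    out <- raw(0)
    for (v in as.numeric(value)) out <- c(out, uint32_le(v), uint32_le(0))
    return(out)
  }
  if (vr == "AT") {
    tags <- canonical_tag(value)
    out <- raw(0)
    for (t in tags) out <- c(out, uint16_le(tag_group(t)), uint16_le(tag_element(t)))
    return(out)
  }
  if (vr %in% c("OB", "OW", "UN")) {
    if (is.raw(value)) return(pad_even(value, as.raw(0)))
    return(pad_even(as.raw(as.integer(value)), as.raw(0)))
  }
  # string VRs: multiple values joined by backslash; UI pads with NUL
  s <- paste(as.character(value), collapse = "\\")
  bytes <- charToRaw(enc2utf8(s))
  pad_even(bytes, if (vr == "UI") as.raw(0) else as.raw(0x20))
}

encode_element <- function(group, element, vr, body) {
  out <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% LONG_FORM_VRS) {
    c(out, as.raw(c(0, 0)), uint32_le(length(body)), body)
  } else {
    if (length(body) > 65534) abort("value too long for short-form VR")
    c(out, uint16_le(length(body)), body)
  }
}

# Encode one item of an SQ value: `elements` is a tibble like the one accepted
# by write_dicom().
encode_sq <- function(items) {
  body <- raw(0)
  for (item in items) {
    item_body <- encode_dataset(item)
    body <- c(body, uint16_le(0xFFFE), uint16_le(0xE000), uint32_le(length(item_body)),
              item_body)
  }
  body
}

encode_dataset <- function(elements) {
  stopifnot(all(c("tag", "vr", "value") %in% names(elements)))
  tags <- canonical_tag(elements$tag)
  ord <- order(tags)  # data sets must be in ascending tag order
  out <- raw(0)
  for (i in ord) {
    vr <- elements$vr[i]
    value <- elements$value[[i]]
    body <- if (vr == "SQ") encode_sq(value) else encode_value(vr, value)
    out <- c(out, encode_element(tag_group(tags[i]), tag_element(tags[i]), vr, body))
  }
  out
}

#' Write a DICOM Part-10 file (Explicit VR Little Endian)
#'
#' Serializes top-level data elements into a Part-10 file: 128-byte preamble,
#' `DICM` magic, file meta-information group, then the data set in explicit
#' VR little-endian encoding. String values of multiplicity > 1 are passed as
#' vectors and joined with `\\`; `SQ` values are lists of element tibbles.
#'
#' @param elements Tibble (or data frame) with columns `tag` (8-hex or
#'   `(gggg,eeee)`), `vr`, and list-column (or character) `value`.
#' @param path Output file path.
#' @param sop_class_uid,sop_instance_uid UIDs for the file meta group; the
#'   instance UID defaults to the `(0008,0018)` element when present.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(elements, path,
                        sop_class_uid = MR_SOP_CLASS,
                        sop_instance_uid = NULL) {
  elements <- as_tibble(elements)
  if (!is.list(elements$value)) elements$value <- as.list(elements$value)
  if (is.null(sop_instance_uid)) {
    hit <- which(canonical_tag(elements$tag) == TAG_SOP_INSTANCE_UID)
    sop_instance_uid <- if (length(hit) > 0) as.character(elements$value[[hit[1]]]) else
      paste0(UID_ROOT_TEST, ".9.1")
  }
  meta_elements <- tibble(
    tag = c("00020001", "00020002", "00020003", "00020010", "00020012"),
    vr = c("OB", "UI", "UI", "UI", "UI"),
    value = list(as.raw(c(0, 1)), sop_class_uid, sop_instance_uid,
                 TS_EXPLICIT_LE, IMPLEMENTATION_UID)
  )
  meta_body <- encode_dataset(meta_elements)
  meta <- c(encode_element(2L, 0L, "UL", uint32_le(length(meta_body))), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(encode_dataset(elements), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

reader_state <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

take <- function(st, n) {
  if (n == 0) return(raw(0))
  if (st$pos + n - 1L > length(st$bytes)) {
    abort("unexpected end of file", class = "dicomop_parse_error")
  }
  out <- st$bytes[st$pos:(st$pos + n - 1L)]
  st$pos <- st$pos + as.integer(n)
  out
}

read_u16 <- function(st) readBin(take(st, 2), "integer", size = 2, signed = FALSE,
                                 endian = "little")
read_u32 <- function(st) {
  b <- take(st, 4)
  lo <- readBin(b[1:2], "integer", size = 2, signed = FALSE, endian = "little")
  hi <- readBin(b[3:4], "integer", size = 2, signed = FALSE, endian = "little")
  lo + hi * 65536
}

decode_string <- function(bytes, vr) {
  s <- rawToChar(bytes[bytes != as.raw(0)])
  s <- iconv(s, from = "UTF-8", to = "UTF-8", sub = "?")
  if (is.na(s)) s <- ""
  sub("[ ]+$", "", s)
}

decode_value <- function(vr, bytes) {
  n <- length(bytes)
  num <- function(size, what, signed = TRUE) {
    if (n == 0) return(character(0))
    v <- readBin(bytes, what, n = n %/% size, size = size, signed = signed,
                 endian = "little")
    vapply(v, format, "", trim = TRUE, scientific = FALSE)
  }
  switch(vr,
    FL = num(4, "double"),
    FD = num(8, "double"),
    SL = num(4, "integer"),
    SS = num(2, "integer"),
    US = num(2, "integer", signed = FALSE),
    UL = {
      if (n == 0) character(0) else {
        k <- n %/% 4
        vapply(seq_len(k), function(i) {
          lo <- readBin(bytes[(4 * i - 3):(4 * i - 2)], "integer", size = 2,
                        signed = FALSE, endian = "little")
          hi <- readBin(bytes[(4 * i - 1):(4 * i)], "integer", size = 2,
                        signed = FALSE, endian = "little")
          format(lo + hi * 65536, scientific = FALSE)
        }, "")
      }
    },
    SV = ,
    UV = {
      if (n == 0) character(0) else {
        k <- n %/% 8
        vapply(seq_len(k), function(i) {
          st <- reader_state(bytes[(8 * i - 7):(8 * i)])
          lo <- read_u32(st); hi <- read_u32(st)
          format(lo + hi * 2^32, scientific = FALSE)
        }, "")
      }
    },
    AT = {
      if (n == 0) character(0) else {
        k <- n %/% 4
        vapply(seq_len(k), function(i) {
          g <- readBin(bytes[(4 * i - 3):(4 * i - 2)], "integer", size = 2,
                       signed = FALSE, endian = "little")
          e <- readBin(bytes[(4 * i - 1):(4 * i)], "integer", size = 2,
                       signed = FALSE, endian = "little")
          sprintf("%04X%04X", g, e)
        }, "")
      }
    },
    {
      s <- decode_string(bytes, vr)
      if (!nzchar(s)) character(0) else strsplit(s, "\\", fixed = TRUE)[[1]]
    }
  )
}

# Skip an undefined-length sequence or item body by walking its delimiters.
skip_undefined <- function(st) {
  repeat {
    group <- read_u16(st); element <- read_u16(st)
    if (group == 0xFFFE && element == 0xE0DD) { read_u32(st); return(invisible()) }
    if (group == 0xFFFE && element == 0xE000) {
      len <- read_u32(st)
      if (len == 0xFFFFFFFF) skip_item_undefined(st) else take(st, len)
    } else {
      abort("malformed undefined-length sequence", class = "dicomop_parse_error")
    }
  }
}

skip_item_undefined <- function(st) {
  repeat {
    group <- read_u16(st); element <- read_u16(st)
    if (group == 0xFFFE && element == 0xE00D) { read_u32(st); return(invisible()) }
    vr <- rawToChar(take(st, 2))
    if (vr %in% LONG_FORM_VRS) { take(st, 2); len <- read_u32(st) } else len <- read_u16(st)
    if (vr == "SQ" && len == 0xFFFFFFFF) skip_undefined(st) else take(st, len)
  }
}

read_element <- function(st) {
  group <- read_u16(st)
  element <- read_u16(st)
  vr <- rawToChar(take(st, 2))
  if (!vr %in% DICOM_VRS) {
    abort(sprintf("unknown VR %s at tag (%04X,%04X)", dQuote(vr), group, element),
          class = "dicomop_parse_error")
  }
  if (vr %in% LONG_FORM_VRS) {
    take(st, 2)
    len <- read_u32(st)
  } else {
    len <- read_u16(st)
  }
  tag <- sprintf("%04X%04X", group, element)
  if (vr == "SQ") {
    if (len == 0xFFFFFFFF) skip_undefined(st) else take(st, len)
    return(list(tag = tag, vr = vr, value = NA_character_, nvalues = NA_integer_))
  }
  if (len == 0xFFFFFFFF) {
    # undefined-length pixel data (encapsulated); skip its item stream
    skip_undefined(st)
    return(list(tag = tag, vr = vr, value = NA_character_, nvalues = NA_integer_))
  }
  body <- take(st, len)
  if (vr %in% c("OB", "OW", "OD", "OF", "OL", "OV", "UN") || tag == TAG_PIXEL_DATA) {
    return(list(tag = tag, vr = vr, value = NA_character_, nvalues = NA_integer_))
  }
  vals <- decode_value(vr, body)
  list(tag = tag, vr = vr,
       value = if (length(vals) == 0) "" else paste(vals, collapse = "\\"),
       nvalues = length(vals))
}

#' Read the header of a DICOM Part-10 file
#'
#' Parses the file meta group and the top-level data set of an explicit VR
#' little-endian Part-10 file. Sequence (`SQ`) contents are skipped, not
#' descended; bulk-data VRs (`OB`, `OW`, ..., pixel data) are recorded with
#' `NA` values and never loaded. Multi-valued attributes are kept as one row
#' with values joined by `\\` (see [harvest_header()] for expansion).
#'
#' @param path Path to a DICOM file.
#' @return Tibble with columns `tag`, `vr`, `value`, `nvalues` in file order,
#'   plus a `meta` attribute holding the file meta-group elements.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("not a DICOM Part-10 file: %s", path),
          class = "dicomop_parse_error")
  }
  st <- reader_state(bytes)
  st$pos <- 133L
  meta <- list()
  # file meta group: always explicit little endian
  first <- read_element(st)
  if (first$tag != "00020000") {
    abort(sprintf("missing file meta group length in %s", path),
          class = "dicomop_parse_error")
  }
  meta_end <- st$pos + as.numeric(first$value)
  while (st$pos < meta_end) meta[[length(meta) + 1]] <- read_element(st)
  meta_df <- bind_rows(lapply(meta, as_tibble))
  ts <- meta_df$value[meta_df$tag == "00020010"]
  if (length(ts) != 1 || ts != TS_EXPLICIT_LE) {
    abort(sprintf("unsupported transfer syntax %s in %s",
                  if (length(ts) == 1) dQuote(ts) else "<missing>", path),
          class = "dicomop_parse_error")
  }
  out <- list()
  while (st$pos <= length(bytes)) {
    el <- tryCatch(
      read_element(st),
      dicomop_parse_error = function(e) {
        abort(sprintf("corrupt DICOM file %s: %s", path, conditionMessage(e)),
              class = "dicomop_parse_error")
      }
    )
    out[[length(out) + 1]] <- el
  }
  res <- bind_rows(lapply(out, as_tibble))
  if (nrow(res) == 0) {
    res <- tibble(tag = character(), vr = character(), value = character(),
                  nvalues = integer())
  }
  attr(res, "meta") <- meta_df
  res
}
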