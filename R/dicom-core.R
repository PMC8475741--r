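# Minimal DICOM Part 10 encoder/decoder, explicit VR little endian only.
#
# No DICOM library exists for this R installation, so the small subset of
# the standard needed for RT Structure Set and CT Image objects is encoded
# here directly: explicit-VR little-endian data elements, defined-length
# sequences/items, and the Part 10 preamble + file meta group. The parser is
# deliberately independent of the writer's in-memory objects: it walks raw
# bytes, so a written file is checked through a genuinely separate path.

UID_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
UID_SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_IMPLEMENTATION <- "2.25.931883247121901"

.vr_long_form <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint_le <- function(x, size) {
  out <- raw(0)
  for (v in x) {
    b <- raw(size)
    for (i in seq_len(size)) {
      b[i] <- as.raw(v %% 256)
      v <- v %/% 256
    }
    out <- c(out, b)
  }
  out
}

# Signed 16-bit little endian (two's complement), vectorized.
int16_le <- function(x) {
  v <- as.integer(x)
  v[v < 0] <- v[v < 0] + 65536L
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  out <- raw(2L * length(v))
  out[c(TRUE, FALSE)] <- lo
  out[c(FALSE, TRUE)] <- hi
  out
}

# Encode a text payload, padded to even length (NUL for UIDs, space else).
dcm_text <- function(x, pad = charToRaw(" ")) {
  b <- charToRaw(paste(x, collapse = "\\"))
  if (length(b) %% 2L) b <- c(b, pad)
  b
}

# One explicit-VR data element.
dcm_elem <- function(group, element, vr, payload) {
  if (is.character(payload)) {
    payload <- dcm_text(payload, pad = if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  stopifnot(is.raw(payload), length(payload) %% 2L == 0L)
  head <- c(uint_le(group, 2), uint_le(element, 2), charToRaw(vr))
  if (vr %in% .vr_long_form) {
    c(head, raw(2), uint_le(length(payload), 4), payload)
  } else {
    if (length(payload) > 65534) stop("element value too long for short-form VR ", vr)
    c(head, uint_le(length(payload), 2), payload)
  }
}

dcm_us <- function(group, element, values) dcm_elem(group, element, "US", uint_le(values, 2))
dcm_ul <- function(group, element, values) dcm_elem(group, element, "UL", uint_le(values, 4))

# Format numbers as DICOM decimal strings (DS), <= 16 bytes each.
format_ds <- function(x, digits = 3) {
  s <- formatC(x, format = "f", digits = digits)
  s <- sub("^(-?)0\\.", "\\1.", s)  # shave a byte; DS allows leading '.'
  long <- nchar(s) > 16
  if (any(long)) s[long] <- formatC(x[long], format = "g", digits = 10)
  s
}

# Sequence with defined lengths; items are lists of already-encoded elements.
dcm_sq <- function(group, element, items) {
  body <- raw(0)
  for (it in items) {
    content <- do.call(c, it)
    body <- c(body, uint_le(0xFFFE, 2), uint_le(0xE000, 2),
              uint_le(length(content), 4), content)
  }
  dcm_elem(group, element, "SQ", body)
}

# Assemble and write a Part 10 file: preamble, DICM, file meta, dataset.
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset_raw) {
  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_elem(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_elem(0x0002, 0x0010, "UI", UID_TRANSFER_SYNTAX_ELE),
    dcm_elem(0x0002, 0x0012, "UI", UID_IMPLEMENTATION),
    dcm_elem(0x0002, 0x0013, "SH", "agephantom")
  )
  bytes <- c(raw(128), charToRaw("DICM"),
             dcm_ul(0x0002, 0x0000, length(meta)), meta, dataset_raw)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

# Deterministic-ish UID from the current RNG stream (callers may seed).
new_uid <- function() {
  digits <- paste(sample(0:9, 30, replace = TRUE), collapse = "")
  paste0("2.25.", sub("^0+", "", paste0("1", digits)))
}

# ---------------------------------------------------------------------------
# Parser

#' Parse a DICOM file (explicit VR little endian)
#'
#' Low-level reader for files written by this package (and any other explicit
#' VR little-endian Part 10 file using the tags it knows). Sequences are
#' returned as nested element lists; values are decoded by VR.
#'
#' @param path DICOM file path.
#' @return A list with `meta` and `dataset`, each a list of elements
#'   `list(group, element, vr, value)`.
#' @export
dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132 || !identical(bytes[129:132], charToRaw("DICM"))) {
    stop("not a DICOM Part 10 file (missing DICM marker): ", path)
  }
  pos <- 133L
  # File meta group is always explicit VR LE.
  meta <- list()
  gl <- parse_one(bytes, pos)
  if (gl$group != 0x0002 || gl$element != 0x0000) stop("missing file meta group length")
  meta_end <- gl$next_pos + dcm_decode_uint(gl$raw_value)
  pos <- gl$next_pos
  while (pos < meta_end) {
    el <- parse_one(bytes, pos)
    meta[[length(meta) + 1]] <- el[c("group", "element", "vr", "value")]
    pos <- el$next_pos
  }
  ts <- dcm_find(meta, 0x0002, 0x0010)
  if (!is.null(ts) && !identical(ts$value, UID_TRANSFER_SYNTAX_ELE)) {
    stop("unsupported transfer syntax: ", ts$value)
  }
  dataset <- parse_elements(bytes, pos, length(bytes) + 1L)
  list(meta = meta, dataset = dataset)
}

parse_elements <- function(bytes, pos, end) {
  out <- list()
  while (pos < end) {
    el <- parse_one(bytes, pos)
    out[[length(out) + 1]] <- el[c("group", "element", "vr", "value")]
    pos <- el$next_pos
  }
  out
}

dcm_decode_uint <- function(b) {
  sum(as.integer(b) * 256^(seq_along(b) - 1))
}

parse_one <- function(bytes, pos) {
  group <- dcm_decode_uint(bytes[pos:(pos + 1)])
  element <- dcm_decode_uint(bytes[(pos + 2):(pos + 3)])
  vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
  if (vr %in% .vr_long_form) {
    len <- dcm_decode_uint(bytes[(pos + 8):(pos + 11)])
    val_start <- pos + 12L
  } else {
    len <- dcm_decode_uint(bytes[(pos + 6):(pos + 7)])
    val_start <- pos + 8L
  }
  if (vr == "SQ") {
    items <- parse_sq_items(bytes, val_start, len)
    return(list(group = group, element = element, vr = vr, value = items$items,
                raw_value = raw(0), next_pos = items$next_pos))
  }
  if (len == 0xFFFFFFFF) stop("undefined length outside SQ not supported")
  raw_value <- if (len > 0) bytes[val_start:(val_start + len - 1L)] else raw(0)
  list(group = group, element = element, vr = vr,
       value = decode_value(vr, raw_value), raw_value = raw_value,
       next_pos = val_start + len)
}

parse_sq_items <- function(bytes, pos, len) {
  undefined <- len == 0xFFFFFFFF
  end <- if (undefined) length(bytes) + 1L else pos + len
  items <- list()
  while (pos < end) {
    tag_g <- dcm_decode_uint(bytes[pos:(pos + 1)])
    tag_e <- dcm_decode_uint(bytes[(pos + 2):(pos + 3)])
    ilen <- dcm_decode_uint(bytes[(pos + 4):(pos + 7)])
    pos <- pos + 8L
    if (tag_g == 0xFFFE && tag_e == 0xE0DD) break # sequence delimiter
    if (!(tag_g == 0xFFFE && tag_e == 0xE000)) stop("malformed sequence item tag")
    if (ilen == 0xFFFFFFFF) {
      # Undefined-length item: parse until the item delimiter.
      inner <- list()
      repeat {
        dg <- dcm_decode_uint(bytes[pos:(pos + 1)])
        de <- dcm_decode_uint(bytes[(pos + 2):(pos + 3)])
        if (dg == 0xFFFE && de == 0xE00D) { pos <- pos + 8L; break }
        el <- parse_one(bytes, pos)
        inner[[length(inner) + 1]] <- el[c("group", "element", "vr", "value")]
        pos <- el$next_pos
      }
      items[[length(items) + 1]] <- inner
    } else {
      items[[length(items) + 1]] <- parse_elements(bytes, pos, pos + ilen)
      pos <- pos + ilen
    }
  }
  list(items = items, next_pos = if (undefined) pos else end)
}

decode_value <- function(vr, b) {
  if (!length(b)) return(if (vr %in% c("US", "UL", "SS", "SL", "FL", "FD", "DS", "IS")) numeric(0) else "")
  switch(vr,
    US = vapply(split_raw(b, 2), dcm_decode_uint, 0),
    UL = vapply(split_raw(b, 4), dcm_decode_uint, 0),
    SS = {
      v <- vapply(split_raw(b, 2), dcm_decode_uint, 0)
      ifelse(v > 32767, v - 65536, v)
    },
    DS = as.numeric(strsplit(trimws(rawToChar(b)), "\\\\")[[1]]),
    IS = as.numeric(strsplit(trimws(rawToChar(b)), "\\\\")[[1]]),
    OB = b,
    OW = b,
    UI = rawToChar(b[b != as.raw(0)]),
    trimws(rawToChar(b), which = "right")
  )
}

split_raw <- function(b, size) {
  split(b, rep(seq_len(length(b) / size), each = size))
}

# First element matching (group, element), searching one level.
dcm_find <- function(elements, group, element) {
  for (el in elements) {
    if (el$group == group && el$element == element) return(el)
  }
  NULL
}

dcm_value <- function(elements, group, element, default = NULL) {
  el <- dcm_find(elements, group, element)
  if (is.null(el)) default else el$value
}
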