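# Minimal MAT-file (level 5) codec: numeric arrays, character arrays and
# struct arrays, with zlib-compressed elements on read. This is the
# subset an EEGLAB SET file uses for continuous data. MAT 7.3 (HDF5)
# files are rejected with a clear error.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L; MI_UTF16 <- 17L
MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L

# ---- writing ---------------------------------------------------------------

mat5_pad8 <- function(r) {
  rem <- length(r) %% 8L
  if (rem) c(r, raw(8L - rem)) else r
}

mat5_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4L, endian = "little"))
}

mat5_element <- function(type, payload) {
  c(mat5_tag(type, length(payload)), mat5_pad8(payload))
}

mat5_flags <- function(class) {
  c(mat5_tag(MI_UINT32, 8L),
    writeBin(as.integer(class), raw(), size = 4L, endian = "little"),
    raw(4))
}

mat5_dims <- function(dims) {
  mat5_element(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L, endian = "little"))
}

mat5_name <- function(name) {
  mat5_element(MI_INT8, if (nchar(name)) charToRaw(name) else raw(0))
}

# value -> raw encoding of one miMATRIX element (unnamed unless top level)
mat5_matrix <- function(value, name = "") {
  if (is.character(value)) {
    stopifnot(length(value) == 1L)
    codes <- utf8ToInt(value)
    body <- c(mat5_flags(MX_CHAR), mat5_dims(c(1L, length(codes))), mat5_name(name),
              mat5_element(MI_UINT16, writeBin(as.integer(codes), raw(),
                                               size = 2L, endian = "little")))
  } else if (is.list(value)) {  # scalar struct or struct array (list of lists)
    elements <- if (!is.null(names(value))) list(value) else value
    fields <- names(elements[[1]])
    fn <- raw(0)
    for (f in fields) {
      fr <- charToRaw(f)
      if (length(fr) > 31L) abort("struct field name too long for MAT5", "format_error")
      fn <- c(fn, fr, raw(32L - length(fr)))
    }
    body <- c(mat5_flags(MX_STRUCT), mat5_dims(c(1L, length(elements))), mat5_name(name),
              mat5_element(MI_INT32, writeBin(32L, raw(), size = 4L, endian = "little")),
              mat5_element(MI_INT8, fn))
    for (el in elements)
      for (f in fields)
        body <- c(body, mat5_matrix(el[[f]]))
  } else {
    m <- as.matrix(value)
    body <- c(mat5_flags(MX_DOUBLE), mat5_dims(dim(m)), mat5_name(name),
              mat5_element(MI_DOUBLE, writeBin(as.numeric(m), raw(),
                                               size = 8L, endian = "little")))
  }
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

# Write named top-level variables (a named list) as an uncompressed MAT5 file.
write_mat5 <- function(vars, path) {
  con <- file(path, "wb"); on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by ftdqeeg")
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                                   # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)                          # little-endian marker
  for (nm in names(vars)) writeBin(mat5_matrix(vars[[nm]], nm), con)
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

mat5_read_int <- function(raw, at, size, signed = TRUE) {
  readBin(raw[at:(at + size - 1L)], integer(), size = size, signed = signed,
          endian = "little")
}

# Parse one data element starting at `at`; returns list(value, name, next_at).
mat5_parse_element <- function(buf, at) {
  type <- mat5_read_int(buf, at, 4L)
  small <- bitwAnd(type, bitwShiftL(-1L, 16L)) != 0L  # upper 16 bits nonzero
  if (small) {
    nbytes <- bitwShiftR(type, 16L)
    type <- bitwAnd(type, 65535L)
    payload <- if (nbytes) buf[(at + 4L):(at + 3L + nbytes)] else raw(0)
    return(list(type = type, payload = payload, next_at = at + 8L))
  }
  nbytes <- mat5_read_int(buf, at + 4L, 4L)
  payload <- if (nbytes) buf[(at + 8L):(at + 7L + nbytes)] else raw(0)
  adv <- nbytes + (8L - nbytes %% 8L) %% 8L
  list(type = type, payload = payload, next_at = at + 8L + adv)
}

mat5_numeric_payload <- function(type, payload) {
  switch(as.character(type),
         "1" = as.numeric(readBin(payload, integer(), n = length(payload), size = 1L, signed = TRUE)),
         "2" = as.numeric(readBin(payload, integer(), n = length(payload), size = 1L, signed = FALSE)),
         "3" = as.numeric(readBin(payload, integer(), n = length(payload) / 2L, size = 2L, signed = TRUE, endian = "little")),
         "4" = as.numeric(readBin(payload, integer(), n = length(payload) / 2L, size = 2L, signed = FALSE, endian = "little")),
         "5" = as.numeric(readBin(payload, integer(), n = length(payload) / 4L, size = 4L, endian = "little")),
         # miUINT32 read as signed 32-bit; values above 2^31 do not occur here
         "6" = as.numeric(readBin(payload, integer(), n = length(payload) / 4L, size = 4L, endian = "little")),
         "7" = readBin(payload, numeric(), n = length(payload) / 4L, size = 4L, endian = "little"),
         "9" = readBin(payload, numeric(), n = length(payload) / 8L, size = 8L, endian = "little"),
         abort(sprintf("unsupported MAT5 numeric type %d", type), "format_error"))
}

mat5_parse_matrix <- function(payload) {
  flags <- mat5_parse_element(payload, 1L)
  class <- bitwAnd(mat5_read_int(flags$payload, 1L, 4L), 255L)
  dims_el <- mat5_parse_element(payload, flags$next_at)
  dims <- readBin(dims_el$payload, integer(), n = length(dims_el$payload) / 4L,
                  size = 4L, endian = "little")
  name_el <- mat5_parse_element(payload, dims_el$next_at)
  name <- rawToChar(name_el$payload)
  at <- name_el$next_at
  if (class == MX_STRUCT) {
    fl_el <- mat5_parse_element(payload, at)            # field name length
    flen <- mat5_read_int(fl_el$payload, 1L, 4L)
    fn_el <- mat5_parse_element(payload, fl_el$next_at) # field names
    nfields <- length(fn_el$payload) / flen
    fields <- vapply(seq_len(nfields), function(i) {
      r <- fn_el$payload[((i - 1L) * flen + 1L):(i * flen)]
      rawToChar(r[r != as.raw(0)])
    }, "")
    at <- fn_el$next_at
    n_el <- prod(dims)
    elements <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      el <- stats::setNames(vector("list", nfields), fields)
      for (f in fields) {
        sub <- mat5_parse_element(payload, at)
        if (sub$type != MI_MATRIX && length(sub$payload))
          abort("malformed MAT5 struct field", "format_error")
        el[[f]] <- if (length(sub$payload)) mat5_parse_matrix(sub$payload)$value else NULL
        at <- sub$next_at
      }
      elements[[e]] <- el
    }
    value <- if (n_el == 1L) elements[[1]] else elements
  } else if (class == MX_CELL) {
    n_el <- prod(dims)
    value <- vector("list", n_el)
    for (e in seq_len(n_el)) {
      sub <- mat5_parse_element(payload, at)
      value[[e]] <- if (length(sub$payload)) mat5_parse_matrix(sub$payload)$value else NULL
      at <- sub$next_at
    }
  } else if (class == MX_CHAR) {
    el <- mat5_parse_element(payload, at)
    codes <- switch(as.character(el$type),
                    "4" = , "17" = readBin(el$payload, integer(), n = length(el$payload) / 2L,
                                           size = 2L, signed = FALSE, endian = "little"),
                    "1" = , "2" = , "16" = as.integer(readBin(el$payload, integer(),
                                                              n = length(el$payload),
                                                              size = 1L, signed = FALSE)),
                    abort(sprintf("unsupported MAT5 char storage type %d", el$type),
                          "format_error"))
    value <- intToUtf8(codes[codes > 0L])
  } else if (class %in% c(MX_DOUBLE, MX_SINGLE, 8L, 9L, 10L, 11L, 12L, 13L)) {
    el <- mat5_parse_element(payload, at)
    v <- mat5_numeric_payload(el$type, el$payload)
    value <- if (length(dims) == 2L) matrix(v, dims[1], dims[2]) else array(v, dims)
    if (length(value) == 1L) value <- as.numeric(value)
  } else {
    abort(sprintf("unsupported MAT5 array class %d", class), "format_error")
  }
  list(value = value, name = name)
}

# Read all top-level variables of a MAT5 file into a named list.
read_mat5 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "format_error")
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 128L) abort(sprintf("%s: truncated MAT file", path), "format_error")
  desc <- rawToChar(buf[1:116])
  if (grepl("MATLAB 7.3", desc, fixed = TRUE))
    abort(sprintf("%s: MAT 7.3 (HDF5) files are not supported; re-save as v5/v7", path),
          "format_error")
  if (!grepl("MATLAB 5", desc, fixed = TRUE) && !grepl("MATLAB", desc, fixed = TRUE))
    abort(sprintf("%s: not a MAT-file (bad header text)", path), "format_error")
  endian <- rawToChar(buf[127:128])
  if (endian != "IM")
    abort(sprintf("%s: big-endian MAT files are not supported", path), "format_error")
  at <- 129L
  out <- list()
  while (at + 7L <= length(buf)) {
    el <- tryCatch(mat5_parse_element(buf, at),
                   error = function(e) abort(sprintf("%s: truncated MAT element", path),
                                             "format_error"))
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$payload, type = "gzip")
      sub <- mat5_parse_element(inner, 1L)
      if (sub$type == MI_MATRIX) {
        pm <- mat5_parse_matrix(sub$payload)
        out[[pm$name]] <- pm$value
      }
    } else if (el$type == MI_MATRIX) {
      pm <- mat5_parse_matrix(el$payload)
      out[[pm$name]] <- pm$value
    }
    at <- el$next_at
  }
  out
}
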