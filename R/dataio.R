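#' Construct a spectral dataset
#'
#' The universal carrier between all stages of the package: a wide matrix of
#' sample spectra, the spectral axis, and one reference value per sample
#' (content in %, w/w, on the printed scale).
#'
#' @param X numeric matrix, n samples x p channels (absorbance, dimensionless).
#' @param y numeric vector of length n; reference content (%, w/w).
#' @param axis numeric vector of length p; channel positions. Must be strictly
#'   monotone (increasing for nm; decreasing is common for cm-1) with uniform
#'   spacing within 1% relative tolerance, as required by derivative filters.
#' @param sample_ids character vector of length n, or NULL for "s0001", ...
#' @param axis_unit "nm" or "cm-1" (metadata only; algorithms work on channel
#'   index except derivatives, which use the median absolute spacing).
#' @return An object of class `spectra_dataset` with fields `X`, `y`, `axis`,
#'   `sample_ids`, `axis_unit`.
#' @export
spectra_dataset <- function(X, y, axis, sample_ids = NULL,
                            axis_unit = c("nm", "cm-1")) {
  axis_unit <- match.arg(axis_unit)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  axis <- as.numeric(axis)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(nrow(X)))
  }
  ds <- structure(
    list(X = X, y = y, axis = axis,
         sample_ids = as.character(sample_ids), axis_unit = axis_unit),
    class = "spectra_dataset")
  validate_spectra_dataset(ds)
  ds
}

#' Validate a spectral dataset
#'
#' Checks all `spectra_dataset` invariants: matching dimensions, no missing
#' values, strictly monotone axis, and uniform axis spacing within 1%
#' relative tolerance. Raises on the first violation.
#'
#' @param ds a `spectra_dataset`.
#' @return `ds`, invisibly.
#' @export
validate_spectra_dataset <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  n <- nrow(ds$X); p <- ncol(ds$X)
  if (length(ds$axis) != p)
    stop("axis length (", length(ds$axis), ") != number of channels (", p, ")")
  if (length(ds$y) != n)
    stop("reference vector length (", length(ds$y), ") != number of samples (", n, ")")
  if (length(ds$sample_ids) != n)
    stop("sample_ids length != number of samples")
  if (anyNA(ds$X) || anyNA(ds$y) || anyNA(ds$axis))
    stop("missing values are not allowed in spectra, reference values, or axis")
  if (p >= 2) {
    d <- diff(ds$axis)
    if (!(all(d > 0) || all(d < 0)))
      stop("axis error: channel positions must be strictly monotone")
    med <- stats::median(abs(d))
    if (any(abs(abs(d) - med) > 0.01 * med))
      stop("axis error: channel spacing non-uniform beyond 1% relative tolerance")
  }
  invisible(ds)
}

#' Median absolute channel spacing of a dataset
#' @param ds a `spectra_dataset`.
#' @return scalar spacing used to scale derivative filters.
#' @export
axis_spacing <- function(ds) {
  if (length(ds$axis) < 2) return(1)
  stats::median(abs(diff(ds$axis)))
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("spectra_dataset: ", nrow(x$X), " samples x ", ncol(x$X), " channels (",
      x$axis_unit, ")\n", sep = "")
  if (length(x$axis) >= 2)
    cat("  axis: ", x$axis[1], " .. ", x$axis[length(x$axis)],
        " (spacing ", signif(axis_spacing(x), 6), ")\n", sep = "")
  cat("  reference: ", signif(min(x$y), 6), " .. ", signif(max(x$y), 6),
      " %, mean ", signif(mean(x$y), 6), "\n", sep = "")
  invisible(x)
}

#' Read a spectral dataset from delimited text
#'
#' Expects comma-delimited UTF-8 text with a single header row: an id column,
#' a reference-value column, and remaining numeric columns as spectral
#' channels whose headers parse as axis positions. Row order is preserved.
#'
#' @param path file to read.
#' @param id_col,ref_col column positions of the sample id and the reference
#'   value (defaults: first and second column).
#' @param axis_unit "nm" or "cm-1".
#' @return a `spectra_dataset`.
#' @export
read_spectra <- function(path, id_col = 1L, ref_col = 2L,
                         axis_unit = c("nm", "cm-1")) {
  axis_unit <- match.arg(axis_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  headers <- names(df)
  if (anyDuplicated(headers))
    stop("format error: duplicate column headers in ", path)
  if (max(id_col, ref_col) > ncol(df) || id_col == ref_col)
    stop("format error: invalid id/reference column positions")
  chan_cols <- setdiff(seq_along(df), c(id_col, ref_col))
  if (length(chan_cols) < 1)
    stop("format error: no spectral channel columns found")
  axis <- suppressWarnings(as.numeric(headers[chan_cols]))
  if (anyNA(axis))
    stop("format error: channel headers must parse as axis positions; first bad header: ",
         headers[chan_cols[which(is.na(axis))[1]]])

  parse_num_col <- function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && nrow(df) > 0) {
      bad <- which(is.na(v))[1]
      stop("parse error: non-numeric value '", df[[j]][bad], "' at row ", bad,
           ", column '", headers[j], "'")
    }
    v
  }
  y <- parse_num_col(ref_col)
  X <- do.call(cbind, lapply(chan_cols, parse_num_col))
  if (nrow(df) == 0) X <- matrix(numeric(0), nrow = 0, ncol = length(chan_cols))
  spectra_dataset(X, y, axis, sample_ids = df[[id_col]], axis_unit = axis_unit)
}

#' Write a spectral dataset to delimited text
#'
#' One header row (id, reference label, axis positions) and one row per
#' sample, at full float precision, so `read_spectra(write_spectra(ds))`
#' round-trips within text precision.
#'
#' @param ds a valid `spectra_dataset`.
#' @param path output file.
#' @param ref_label header for the reference column.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, ref_label = "reference") {
  validate_spectra_dataset(ds)
  header <- c("id", ref_label, format(ds$axis, digits = 17, trim = TRUE,
                                      scientific = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (nrow(ds$X) > 0) {
    body <- cbind(ds$sample_ids,
                  format(ds$y, digits = 17, trim = TRUE),
                  matrix(format(ds$X, digits = 17, trim = TRUE), nrow = nrow(ds$X)))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

# ---- MATLAB v5 container (read-only) --------------------------------------
# Minimal reader for the public corn/tablet reference datasets: numeric
# (double/single/integer) full arrays at top level, plain or zlib-compressed
# data elements. Cell arrays, structs, sparse and char data are not handled.

.mat5_mi_types <- c("miINT8" = 1, "miUINT8" = 2, "miINT16" = 3, "miUINT16" = 4,
                    "miINT32" = 5, "miUINT32" = 6, "miSINGLE" = 7,
                    "miDOUBLE" = 9, "miINT64" = 12, "miUINT64" = 13,
                    "miMATRIX" = 14, "miCOMPRESSED" = 15, "miUTF8" = 16)

.mat5_read_numeric <- function(raw, type, nbytes, endian) {
  switch(as.character(type),
    "1" = readBin(raw, "integer", n = nbytes, size = 1, signed = TRUE, endian = endian),
    "2" = readBin(raw, "integer", n = nbytes, size = 1, signed = FALSE, endian = endian),
    "3" = readBin(raw, "integer", n = nbytes %/% 2, size = 2, signed = TRUE, endian = endian),
    "4" = readBin(raw, "integer", n = nbytes %/% 2, size = 2, signed = FALSE, endian = endian),
    "5" = readBin(raw, "integer", n = nbytes %/% 4, size = 4, endian = endian),
    "6" = readBin(raw, "integer", n = nbytes %/% 4, size = 4, endian = endian),  # uint32 read as signed; data >= 2^31 not expected here
    "7" = readBin(raw, "numeric", n = nbytes %/% 4, size = 4, endian = endian),
    "9" = readBin(raw, "numeric", n = nbytes %/% 8, size = 8, endian = endian),
    stop("MAT reader: unsupported numeric type ", type))
}

# Parse one data element starting at offset `pos` (1-based) of raw vector.
# Returns list(type, data_raw, next_pos). Handles small-element format.
.mat5_element <- function(buf, pos, endian) {
  tag <- buf[pos:(pos + 7)]
  type_field <- readBin(tag[1:4], "integer", size = 4, endian = endian)
  small_len <- bitwAnd(bitwShiftR(type_field, 16), 0xFFFF)
  if (small_len > 0) {  # small data element: data packed into the tag
    type <- bitwAnd(type_field, 0xFFFF)
    data <- buf[(pos + 4):(pos + 4 + small_len - 1)]
    list(type = type, data = data, nbytes = small_len, next_pos = pos + 8)
  } else {
    type <- type_field
    nbytes <- readBin(tag[5:8], "integer", size = 4, endian = endian)
    data <- if (nbytes > 0) buf[(pos + 8):(pos + 8 + nbytes - 1)] else raw(0)
    pad <- (8 - nbytes %% 8) %% 8
    list(type = type, data = data, nbytes = nbytes,
         next_pos = pos + 8 + nbytes + pad)
  }
}

.mat5_parse_matrix <- function(data, endian) {
  pos <- 1
  flags <- .mat5_element(data, pos, endian); pos <- flags$next_pos
  flag_words <- readBin(flags$data, "integer", n = 2, size = 4, endian = endian)
  cls <- bitwAnd(flag_words[1], 0xFF)
  # numeric array classes: 6=double,7=single,8..13 integer
  if (!(cls %in% 6:13))
    return(NULL)  # non-numeric (cell/struct/char/sparse): skipped
  dims_el <- .mat5_element(data, pos, endian); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", n = dims_el$nbytes %/% 4, size = 4,
                  endian = endian)
  name_el <- .mat5_element(data, pos, endian); pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  pr <- .mat5_element(data, pos, endian)
  values <- .mat5_read_numeric(pr$data, pr$type, pr$nbytes, endian)
  if (length(dims) == 2) {
    m <- matrix(as.numeric(values), nrow = dims[1], ncol = dims[2])
  } else {
    m <- array(as.numeric(values), dim = dims)
  }
  list(name = name, value = m)
}

#' Read variables from a MATLAB v5 container
#'
#' Minimal MAT-file (level 5) reader covering the public NIR reference
#' datasets: top-level numeric full arrays, plain or zlib-compressed.
#' Character, cell, struct, and sparse variables are silently skipped.
#'
#' @param path MAT file.
#' @return named list of numeric matrices/arrays.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 128) stop("format error: not a MAT v5 file (too short)")
  magic <- buf[127:128]
  endian <- if (rawToChar(magic) == "IM") "little"
            else if (rawToChar(magic) == "MI") "big"
            else stop("format error: bad MAT v5 endian indicator")
  out <- list()
  pos <- 129
  while (pos + 8 <= length(buf) + 1) {
    el <- .mat5_element(buf, pos, endian)
    pos <- el$next_pos
    payload <- el$data
    type <- el$type
    if (type == 15) {  # miCOMPRESSED: zlib stream wrapping one element
      payload <- memDecompress(payload, type = "gzip")
      inner <- .mat5_element(payload, 1, endian)
      type <- inner$type
      payload <- inner$data
    }
    if (type == 14) {
      v <- .mat5_parse_matrix(payload, endian)
      if (!is.null(v) && nzchar(v$name)) out[[v$name]] <- v$value
    }
  }
  out
}

#' Read a spectral dataset from a MATLAB v5 container
#'
#' Convenience loader for the public corn and tablet reference sets
#' distributed as MAT files. Sample ids are synthesized ("s0001", ...).
#'
#' @param path MAT file.
#' @param spectra_key variable name of the n x p spectra matrix.
#' @param reference_key variable name of the length-n reference vector (or
#'   n x 1 / n x k matrix; see `reference_column`).
#' @param axis explicit axis vector of length p, or NULL to reconstruct from
#'   `axis_start`/`axis_step`.
#' @param axis_start,axis_step axis metadata used when `axis` is NULL.
#' @param reference_column which column of a multi-column reference matrix to
#'   use (e.g. moisture among several assayed properties).
#' @param axis_unit "nm" or "cm-1".
#' @return a `spectra_dataset`.
#' @export
read_matlab_container <- function(path, spectra_key, reference_key,
                                  axis = NULL, axis_start = 1, axis_step = 1,
                                  reference_column = 1L,
                                  axis_unit = c("nm", "cm-1")) {
  axis_unit <- match.arg(axis_unit)
  vars <- read_mat5(path)
  if (is.null(vars[[spectra_key]]))
    stop("key error: '", spectra_key, "' not found in ", path)
  if (is.null(vars[[reference_key]]))
    stop("key error: '", reference_key, "' not found in ", path)
  X <- as.matrix(vars[[spectra_key]])
  yv <- vars[[reference_key]]
  y <- if (is.matrix(yv)) yv[, reference_column] else as.numeric(yv)
  if (length(y) != nrow(X))
    stop("shape error: reference length (", length(y),
         ") != number of spectra (", nrow(X), ")")
  if (is.null(axis))
    axis <- axis_start + axis_step * (seq_len(ncol(X)) - 1)
  spectra_dataset(X, y, axis, axis_unit = axis_unit)
}
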