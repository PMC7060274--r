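# File I/O: TIFF images/stacks, strict CSV tables, key-value sidecar
# metadata. All writes are atomic (tempfile + rename in the target
# directory).

#' Read a TIFF image or stack
#'
#' Multi-page TIFFs are returned as a `(time, rows, cols)` array; a 2D TIFF
#' is treated as a single-frame stack. Multi-channel pages are averaged to
#' grayscale.
#'
#' @param path TIFF file path.
#' @return Numeric array `(time, rows, cols)`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) {
    abort_cmq(sprintf("image file not found: %s", path),
              "cmquant_missing_input")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p
  })
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1)))) {
    abort_cmq("stack pages have inconsistent dimensions",
              "cmquant_invalid_stack")
  }
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Write an image or stack as 32-bit float TIFF
#'
#' @param x matrix (single image) or `(time, rows, cols)` array.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(x, path) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  pages <- lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32L)
  })
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' Labels up to 65535 are stored scaled into the 16-bit range.
#'
#' @param mask integer matrix, background 0.
#' @param path TIFF path.
#' @return `path` invisibly (write); integer matrix (read).
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) abort_cmq("label exceeds 16-bit range",
                                    "cmquant_invalid_mask")
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(mask / 65535, tmp, bits.per.sample = 16L)
  })
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a data.frame as a CSV table
#'
#' UTF-8, header row, '.' decimal separator, atomic.
#'
#' @param records data.frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(records, tmp, row.names = FALSE, fileEncoding = "UTF-8")
  })
}

#' Read a CSV table with strict numeric parsing
#'
#' Columns named in `numeric_cols` must parse as '.'-decimal numbers; a
#' locale comma decimal (or any other malformed value) raises an explicit
#' parse error rather than becoming a silent `NA`.
#'
#' @param path CSV path.
#' @param numeric_cols character vector of column names required to be
#'   numeric (default: all columns).
#' @return data.frame.
#' @export
read_numeric_csv <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) {
    abort_cmq(sprintf("input file not found: %s", path),
              "cmquant_missing_input")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (is.null(numeric_cols)) numeric_cols <- names(df)
  for (nm in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- is.na(v) & !is.na(df[[nm]]) & !(df[[nm]] %in% c("NA", ""))
    if (any(bad)) {
      abort_cmq(sprintf(
        "column `%s` of %s contains non-numeric values (e.g. \"%s\"); use '.' as the decimal separator",
        nm, basename(path), df[[nm]][which(bad)[1]]),
        "cmquant_parse_error")
    }
    df[[nm]] <- v
  }
  df
}

#' Write / read a key-value sidecar metadata file
#'
#' One `key = value` pair per line, recording the generating spec and seed
#' next to each dataset.
#'
#' @param meta named list of scalars.
#' @param path destination path (write) or source path (read).
#' @return `path` invisibly (write); named character list (read).
#' @export
write_sidecar <- function(meta, path) {
  scalars <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1L,
                         logical(1))]
  lines <- sprintf("%s = %s", names(scalars),
                   vapply(scalars, format, character(1), digits = 17))
  atomic_write(path, function(tmp) writeLines(lines, tmp))
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

# Write via a tempfile in the destination directory, then rename.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
  }
  invisible(path)
}
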