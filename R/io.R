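# Delimited text formats for surfaces and decay histograms. Units are fixed
# at the file level: ps / nm / mOD for TA surfaces, ns / counts for TCSPC.
# Numeric payloads are written with 17 significant digits so that a
# write -> read round trip is bit-identical.

format_num <- function(x) sprintf("%.17g", x)

write_metadata <- function(metadata, con) {
  keep <- metadata[!vapply(metadata, function(v) {
    is.null(v) || (length(v) == 1L && is.na(v)) || !is.atomic(v) || length(v) != 1L
  }, logical(1))]
  for (key in names(keep)) {
    writeLines(sprintf("# %s: %s", key, format(keep[[key]])), con)
  }
}

read_metadata_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write / read a transient-absorption surface
#'
#' Tab-delimited text: `#`-prefixed metadata header lines, then a column
#' header `delay_ps` followed by the wavelengths (nm, ascending), then one
#' row per delay with the delay (ps) and the dA values (mOD). The numeric
#' payload round-trips bit-for-bit at 17 significant digits.
#'
#' @param surface A [ta_surface()].
#' @param path File path.
#' @return `write_surface()` returns `path` invisibly; `read_surface()`
#'   returns a [ta_surface()].
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "ta_surface"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  write_metadata(surface$metadata, con)
  writeLines(paste(c("delay_ps", format_num(surface$wavelengths_nm)),
                   collapse = "\t"), con)
  body <- vapply(seq_along(surface$times_ps), function(i) {
    paste(c(format_num(surface$times_ps[i]), format_num(surface$data[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop_quenchkin("Empty surface file: ", path)
  meta <- read_metadata_lines(lines)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(data_idx) < 2L) {
    stop_quenchkin("Surface file needs a header row and at least one data row.")
  }
  header <- strsplit(lines[data_idx[1]], "\t", fixed = TRUE)[[1]]
  if (header[1] != "delay_ps") {
    stop_quenchkin("Missing header: first column must be \"delay_ps\".")
  }
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(wl))) stop_quenchkin("Non-numeric wavelength in header.")
  dup <- which(duplicated(wl))
  if (length(dup) > 0L) {
    stop_quenchkin(sprintf("Duplicated wavelength column: %s nm.",
                           paste(unique(wl[dup]), collapse = ", ")))
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop_quenchkin("Wavelength axis must be strictly ascending.")
  }
  rows_idx <- data_idx[-1]
  ncols <- length(header)
  parsed <- lapply(rows_idx, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != ncols) {
      stop_quenchkin(sprintf(
        "Ragged row at line %d: %d fields, expected %d.", i, length(fields), ncols))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_quenchkin(sprintf("Malformed numeric value at line %d.", i))
    }
    vals
  })
  mat <- do.call(rbind, parsed)
  times <- mat[, 1]
  if (is.unsorted(times, strictly = TRUE)) {
    stop_quenchkin("Delay axis must be strictly ascending.")
  }
  ta_surface(times, wl, mat[, -1, drop = FALSE], metadata = meta)
}

#' Write / read a TCSPC decay histogram
#'
#' Tab-delimited text with `#`-metadata headers and columns `time_ns`,
#' `counts` and (optionally) `irf_counts`.
#'
#' @param decay A [fluor_decay()].
#' @param path File path.
#' @return `write_decay()` returns `path` invisibly; `read_decay()` returns
#'   a [fluor_decay()].
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "fluor_decay"))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  write_metadata(decay$metadata, con)
  has_irf <- !is.null(decay$irf_counts)
  writeLines(paste(c("time_ns", "counts", if (has_irf) "irf_counts"),
                   collapse = "\t"), con)
  body <- vapply(seq_along(decay$time_ns), function(i) {
    paste(c(format_num(decay$time_ns[i]), format(decay$counts[i]),
            if (has_irf) format(decay$irf_counts[i])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  meta <- read_metadata_lines(lines)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(data_idx) < 2L) {
    stop_quenchkin("Decay file needs a header row and at least one data row.")
  }
  header <- strsplit(lines[data_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("time_ns", "counts"))) {
    stop_quenchkin("Missing header: columns must start with time_ns, counts.")
  }
  has_irf <- length(header) >= 3L && header[3] == "irf_counts"
  mat <- do.call(rbind, lapply(data_idx[-1], function(i) {
    fields <- suppressWarnings(as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]]))
    if (length(fields) != length(header) || any(is.na(fields))) {
      stop_quenchkin(sprintf("Malformed row at line %d.", i))
    }
    fields
  }))
  fluor_decay(mat[, 1], mat[, 2],
              irf_counts = if (has_irf) mat[, 3] else NULL,
              metadata = meta)
}
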