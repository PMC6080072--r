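## Plain-text I/O for spectra and reference-concentration tables.
## Dialect: CSV/TSV, UTF-8, '.' decimal separator, '#' comment lines.

#' Read a spectral table
#'
#' Two layouts are supported.  `wide`: first column is the wavelength (nm),
#' each further column is one sample (column name = sample id).  `long`:
#' three columns `sample_id, wavelength, intensity`.  An optional separate
#' concentration table (see [read_concentration_table()]) can be joined by
#' sample id.
#'
#' @param source path to a delimited text file, or a character vector of
#'   lines.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator; `","` default, use `"\t"` for TSV.
#' @param concentrations optional named numeric vector (names = sample ids)
#'   to attach as reference values.
#' @return a [spectra_dataset()]; wavelengths sorted ascending, samples in
#'   first-appearance order.
#' @export
read_spectra_table <- function(source, layout = c("wide", "long"),
                               sep = ",", concentrations = NULL) {
  layout <- match.arg(layout)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("spectral table needs a header and data rows")
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 which(widths != widths[1L])[1L],
                 widths[widths != widths[1L]][1L], widths[1L]))
  header <- trimws(cells[[1L]])
  body <- cells[-1L]
  num <- function(x, row) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
      stop(sprintf("non-numeric cell in data row %d: '%s'",
                   row, x[which(is.na(v))[1L]]))
    v
  }
  if (layout == "wide") {
    if (length(header) < 2L) stop("wide layout needs >= 2 columns")
    m <- t(vapply(seq_along(body),
                  function(i) num(body[[i]], i), numeric(length(header))))
    wl <- m[, 1L]
    if (anyDuplicated(wl)) {
      d <- wl[duplicated(wl)][1L]
      stop(sprintf("duplicated wavelength row: %g nm", d))
    }
    ord <- order(wl)
    ids <- header[-1L]
    ds <- spectra_dataset(wl[ord], t(m[ord, -1L, drop = FALSE]),
                          sample_ids = ids)
  } else {
    if (length(header) != 3L)
      stop("long layout needs exactly 3 columns (sample_id, wavelength, intensity)")
    ids_raw <- vapply(body, function(r) trimws(r[1L]), character(1L))
    wl_raw <- vapply(seq_along(body),
                     function(i) num(body[[i]][2L], i), numeric(1L))
    in_raw <- vapply(seq_along(body),
                     function(i) num(body[[i]][3L], i), numeric(1L))
    ids <- unique(ids_raw)
    key <- paste(ids_raw, wl_raw)
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop(sprintf("duplicate (sample, wavelength) pair in row %d: %s at %g nm",
                   d, ids_raw[d], wl_raw[d]))
    }
    wl <- sort(unique(wl_raw))
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, NULL))
    m[cbind(match(ids_raw, ids), match(wl_raw, wl))] <- in_raw
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("sample '%s' is missing intensity at %g nm",
                   ids[miss[1L]], wl[miss[2L]]))
    }
    ds <- spectra_dataset(wl, m, sample_ids = ids)
  }
  if (!is.null(concentrations)) {
    if (is.null(names(concentrations)))
      stop("concentrations must be named by sample id")
    missing_ids <- setdiff(ds$sample_ids, names(concentrations))
    if (length(missing_ids))
      stop("no concentration for sample(s): ",
           paste(missing_ids, collapse = ", "))
    ds$concentrations <- as.numeric(concentrations[ds$sample_ids])
    ds <- spectra_dataset(ds$wavelengths, ds$intensities,
                          ds$concentrations, ds$sample_ids)
  }
  ds
}

#' Write a spectral table
#'
#' Inverse of [read_spectra_table()]: `read(write(ds))` reproduces the
#' dataset to full double precision (17 significant digits are written).
#'
#' @param ds a [spectra_dataset()].
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator.
#' @return (invisibly) the character vector of lines written.
#' @export
write_spectra_table <- function(ds, path = NULL, layout = c("wide", "long"),
                                sep = ",") {
  stopifnot(inherits(ds, "spectra_dataset"))
  layout <- match.arg(layout)
  fmt <- function(x) sprintf("%.17g", x)
  if (layout == "wide") {
    header <- paste(c("wavelength_nm", ds$sample_ids), collapse = sep)
    rows <- vapply(seq_along(ds$wavelengths), function(j)
      paste(c(fmt(ds$wavelengths[j]), fmt(ds$intensities[, j])),
            collapse = sep), character(1L))
    out <- c(header, rows)
  } else {
    header <- paste(c("sample_id", "wavelength_nm", "intensity"),
                    collapse = sep)
    rows <- unlist(lapply(seq_along(ds$sample_ids), function(i)
      vapply(seq_along(ds$wavelengths), function(j)
        paste(c(ds$sample_ids[i], fmt(ds$wavelengths[j]),
                fmt(ds$intensities[i, j])), collapse = sep),
        character(1L))))
    out <- c(header, rows)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a reference-concentration table
#'
#' Two columns: `sample_id, concentration_g_per_100g`.
#'
#' @param source path or character lines.
#' @param sep field separator.
#' @return named numeric vector of concentrations (g/100 g).
#' @export
read_concentration_table <- function(source, sep = ",") {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cells <- strsplit(lines[-1L], sep, fixed = TRUE)
  ids <- vapply(cells, function(r) trimws(r[1L]), character(1L))
  val <- suppressWarnings(as.numeric(vapply(cells, `[`, character(1L), 2L)))
  if (anyNA(val))
    stop(sprintf("non-numeric concentration in row %d", which(is.na(val))[1L]))
  stats::setNames(val, ids)
}

#' Write a reference-concentration table
#' @param concentrations named numeric vector (names = sample ids).
#' @param path output path or `NULL`.
#' @param sep field separator.
#' @return (invisibly) the lines written.
#' @export
write_concentration_table <- function(concentrations, path = NULL, sep = ",") {
  out <- c(paste(c("sample_id", "concentration_g_per_100g"), collapse = sep),
           paste(names(concentrations),
                 sprintf("%.17g", concentrations), sep = sep))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
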