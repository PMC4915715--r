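#' Construct a raw spectrum
#'
#' A peak list: integer m/z values with nonnegative intensities, tagged by a
#' compound id (CAS number or name). Fractional m/z values are rounded to
#' the nearest integer (nominal mass) with a warning; intensities at m/z
#' values that collide after rounding are summed.
#'
#' @param id Compound identifier string.
#' @param mz Numeric vector of m/z values.
#' @param intensity Nonnegative intensities, same length.
#' @return List with class `"raw_spectrum"`: `id`, `mz` (sorted integer),
#'   `intensity`.
#' @export
raw_spectrum <- function(id, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) && min(intensity) < 0)
    stop("raw_spectrum: negative intensity for '", id, "'")
  if (length(mz) && any(abs(mz - round(mz)) > 1e-9)) {
    warning("raw_spectrum: fractional m/z in '", id,
            "' rounded to nominal (integer) mass")
    mz <- round(mz)
  }
  mz <- as.integer(round(mz))
  if (length(mz) && min(mz) < 1)
    stop("raw_spectrum: m/z values must be positive integers")
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  } else {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(id = as.character(id), mz = mz,
                 intensity = as.numeric(intensity)),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat("EI mass spectrum '", x$id, "': ", length(x$mz), " peaks",
      if (length(x$mz)) paste0(", m/z ", min(x$mz), "-", max(x$mz)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Canonicalize a CAS registry number
#'
#' Strips whitespace and normalizes hyphenation (`"64 17 5"` and `"64-17-5"`
#' both become `"64-17-5"`). No checksum validation is performed; an id that
#' does not look like a CAS number is returned trimmed, unchanged.
#'
#' @param id Character vector of ids.
#' @return Character vector of canonical ids.
#' @export
normalize_cas <- function(id) {
  id <- gsub("^\\s+|\\s+$", "", as.character(id))
  looks_cas <- grepl("^[0-9]{2,7}[-[:space:]][0-9]{2}[-[:space:]][0-9]$", id)
  id[looks_cas] <- gsub("[-[:space:]]", "-", id[looks_cas])
  id
}

#' Read mass spectra from MSP, JCAMP-DX or CSV files
#'
#' `"msp"` parses NIST-style text records (`Name:`, optional `CAS#:`,
#' `Num Peaks:` followed by `m/z intensity` pairs separated by `;` or
#' whitespace). `"jcamp"` parses JCAMP-DX blocks with `(XY..XY)` peak tables
#' (`##PEAK TABLE=` or `##XYDATA=`). `"csv"` expects a matrix layout: first
#' column sample id, remaining header names the integer m/z of each column.
#' An empty file yields an empty list with a warning.
#'
#' @param path Path to the file.
#' @param format One of `"msp"`, `"jcamp"`, `"csv"`; the default guesses
#'   from the file extension.
#' @return List of [raw_spectrum()] objects.
#' @export
read_spectra <- function(path, format = c("auto", "msp", "jcamp", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_spectra: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, msp = "msp", jdx = "jcamp", dx = "jcamp",
                     jcamp = "jcamp", csv = "csv",
                     stop("read_spectra: cannot guess format from '.", ext,
                          "'; pass format explicitly"))
  }
  switch(format,
         msp = read_msp(path),
         jcamp = read_jcamp(path),
         csv = read_spectra_csv(path))
}

parse_peak_pairs <- function(lines) {
  txt <- gsub(";", " ", paste(lines, collapse = " "))
  vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
  if (anyNA(vals) || length(vals) %% 2 != 0) return(NULL)
  list(mz = vals[seq(1, length(vals), by = 2)],
       intensity = vals[seq(2, length(vals), by = 2)])
}

read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(trimws(lines) == "")) {
    warning("read_spectra: empty file: ", path)
    return(list())
  }
  blank <- trimws(lines) == ""
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  recs <- split(lines[!blank], rec_id[!blank])
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    fields <- grepl("^[A-Za-z#][^:]*:", rec)
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "\\s*:"), rec, ignore.case = TRUE,
                  value = TRUE)
      if (!length(hit)) return(NULL)
      trimws(sub("^[^:]*:", "", hit[1]))
    }
    name <- get_field("Name")
    cas <- get_field("CAS#")
    if (is.null(cas)) cas <- get_field("CASNO")
    np <- get_field("Num ?Peaks")
    if (is.null(name) || is.null(np))
      stop("read_spectra: malformed MSP record ", i, " in ", path,
           " (missing Name or Num Peaks)")
    peak_lines <- rec[!fields]
    peaks <- parse_peak_pairs(peak_lines)
    if (is.null(peaks) || length(peaks$mz) != as.integer(np))
      stop("read_spectra: malformed peak table in MSP record ", i,
           " ('", name, "'): expected ", np, " peaks")
    id <- if (!is.null(cas) && nzchar(cas)) normalize_cas(cas) else name
    out[[i]] <- raw_spectrum(id, peaks$mz, peaks$intensity)
  }
  out
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(trimws(lines) == "")) {
    warning("read_spectra: empty file: ", path)
    return(list())
  }
  starts <- grep("^##TITLE=", lines)
  if (!length(starts))
    stop("read_spectra: no ##TITLE= record found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    title <- trimws(sub("^##TITLE=", "", blk[1]))
    cas <- grep("^##CAS( REGISTRY NO)?=", blk, value = TRUE)
    id <- if (length(cas)) normalize_cas(sub("^##[^=]*=", "", cas[1])) else title
    tab <- grep("^##(PEAK ?TABLE|XYDATA)=", blk)
    if (!length(tab))
      stop("read_spectra: JCAMP record ", i, " ('", title,
           "') has no peak table")
    stop_at <- grep("^##", blk)
    stop_at <- stop_at[stop_at > tab[1]]
    last <- if (length(stop_at)) stop_at[1] - 1L else length(blk)
    raw <- blk[(tab[1] + 1L):last]
    raw <- gsub("[(),]", " ", raw)
    peaks <- parse_peak_pairs(raw)
    if (is.null(peaks))
      stop("read_spectra: malformed peak table in JCAMP record ", i,
           " ('", title, "')")
    out[[i]] <- raw_spectrum(id, peaks$mz, peaks$intensity)
  }
  out
}

read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("read_spectra: empty file: ", path)
    return(list())
  }
  mz <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(mz))
    stop("read_spectra: CSV header columns after the id must be numeric m/z")
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -1])
    keep <- v != 0
    raw_spectrum(df[i, 1], mz[keep], v[keep])
  })
}

#' Write spectra to an MSP file
#'
#' Round-trip counterpart of `read_spectra(format = "msp")`.
#'
#' @param spectra List of [raw_spectrum()] objects.
#' @param path Output path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(paste0("Name: ", s$id),
                 paste0("Num Peaks: ", length(s$mz)),
                 paste(s$mz, s$intensity, sep = " ", collapse = "; "),
                 ""), con)
  }
  invisible(path)
}

#' Bin spectra onto a dense integer m/z window
#'
#' Maps peak lists onto the inclusive integer window `[lo, hi]` (default
#' 51-262, giving 212 columns): column `j` holds the intensity at m/z
#' `lo + j - 1`, absent m/z values are 0, and peaks outside the window are
#' dropped. Fragments below m/z 51 largely stem from odorless small
#' molecules, and heavy fragments from compounds too involatile to smell,
#' which motivates the default window.
#'
#' @param spectra List of [raw_spectrum()] objects.
#' @param lo,hi Inclusive integer window bounds.
#' @return Numeric matrix, rows named by compound id, columns named by m/z,
#'   with attribute `mz_range = c(lo, hi)`. Unnormalized.
#' @export
window_mz <- function(spectra, lo = 51, hi = 262) {
  if (lo > hi) stop("window_mz: lo > hi")
  lo <- as.integer(lo); hi <- as.integer(hi)
  n <- length(spectra)
  ids <- vapply(spectra, function(s) s$id, "")
  M <- matrix(0, nrow = n, ncol = hi - lo + 1L,
              dimnames = list(ids, as.character(lo:hi)))
  for (i in seq_len(n)) {
    s <- spectra[[i]]
    keep <- s$mz >= lo & s$mz <= hi
    M[i, s$mz[keep] - lo + 1L] <- s$intensity[keep]
  }
  attr(M, "mz_range") <- c(lo, hi)
  M
}

#' Max-normalize a data matrix
#'
#' Divides every element by the single global maximum of the dataset so the
#' result lies in `[0, 1]` with maximum exactly 1. This is one scalar per
#' dataset, not per row; set `per_sample = TRUE` for row-wise normalization
#' (each row's maximum becomes 1).
#'
#' @param x Nonnegative numeric matrix.
#' @param per_sample Normalize each row by its own maximum instead.
#' @return Normalized matrix (attributes preserved).
#' @export
normalize_max <- function(x, per_sample = FALSE) {
  if (min(x) < 0)
    stop("normalize_max: negative entries; intensities and applicabilities ",
         "must be nonnegative")
  if (per_sample) {
    mx <- apply(x, 1, max)
    if (any(mx == 0)) stop("normalize_max: all-zero row; cannot normalize")
    return(x / mx)
  }
  mx <- max(x)
  if (mx == 0) stop("normalize_max: all-zero matrix; cannot normalize")
  x / mx
}

#' Pair spectrum and sensory matrices by sample id
#'
#' Restricts both matrices to the ids they share (rownames, CAS-normalized)
#' and returns them in the same order. Duplicated ids and an empty
#' intersection are errors.
#'
#' @param spec Spectrum matrix with rownames.
#' @param sens Sensory matrix with rownames.
#' @return List with `spectra` and `sensory`, row-aligned, plus `ids`.
#' @export
align_by_id <- function(spec, sens) {
  if (is.null(rownames(spec)) || is.null(rownames(sens)))
    stop("align_by_id: both matrices need rownames (sample ids)")
  ids_a <- normalize_cas(rownames(spec))
  ids_b <- normalize_cas(rownames(sens))
  for (ids in list(ids_a, ids_b)) {
    dup <- ids[duplicated(ids)]
    if (length(dup))
      stop("align_by_id: duplicated sample id '", dup[1], "'")
  }
  common <- intersect(ids_a, ids_b)
  if (!length(common)) stop("align_by_id: no common sample ids")
  a <- spec[match(common, ids_a), , drop = FALSE]
  b <- sens[match(common, ids_b), , drop = FALSE]
  rownames(a) <- rownames(b) <- common
  list(spectra = a, sensory = b, ids = common)
}

#' Write a sample-by-feature matrix as CSV
#'
#' First column `id` (rownames), remaining columns the feature names
#' (m/z values or descriptor labels). Round-trips with
#' `read_spectra(format = "csv")` and [read_matrix_csv()].
#'
#' @param x Matrix with rownames and colnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sample-by-feature CSV matrix
#'
#' @param path CSV with first column `id` and one column per feature.
#' @return Numeric matrix with rownames from the id column.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
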