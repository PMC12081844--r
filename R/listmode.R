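#' List-mode stream containers
#'
#' The pipeline exchanges two list-mode record types: pixel hits from the
#' 256 x 256 pixel detector and gamma events from the scintillator channel.
#' Both are stored as plain data frames with a class tag and validated on
#' construction.  Pixel streams carry a `calibrated` attribute: `TRUE` when
#' the energy column is in keV, `FALSE` when it still holds raw
#' time-over-threshold (ToT) units.
#'
#' @param col,row 0-based pixel indices in `[0, 255]`.
#' @param toa_ns time of arrival in ns (non-negative).
#' @param energy numeric; deposited energy in keV for calibrated streams,
#'   raw ToT units otherwise.
#' @param calibrated logical flag; `TRUE` when `energy` is in keV.
#' @return A `data.frame` of class `qpid_hits` with columns
#'   `col`, `row`, `toa_ns`, `energy_kev`.
#' @examples
#' h <- pixel_hits(col = c(10, 11), row = c(5, 5),
#'                 toa_ns = c(0, 1.5625), energy = c(60, 40))
#' @export
pixel_hits <- function(col = integer(), row = integer(),
                       toa_ns = numeric(), energy = numeric(),
                       calibrated = TRUE) {
  df <- data.frame(col = as.integer(col), row = as.integer(row),
                   toa_ns = as.numeric(toa_ns),
                   energy_kev = as.numeric(energy))
  validate_pixel_hits(df, calibrated = calibrated)
  attr(df, "calibrated") <- isTRUE(calibrated)
  class(df) <- c("qpid_hits", "data.frame")
  df
}

validate_pixel_hits <- function(df, calibrated = TRUE, where = NULL) {
  bad_px <- which(df$col < 0L | df$col > 255L | df$row < 0L | df$row > 255L)
  if (length(bad_px))
    stop("pixel index out of range [0, 255] in record(s) ",
         record_ref(bad_px, where), call. = FALSE)
  bad_t <- which(!is.finite(df$toa_ns) | df$toa_ns < 0)
  if (length(bad_t))
    stop("negative or non-finite time of arrival in record(s) ",
         record_ref(bad_t, where), call. = FALSE)
  if (isTRUE(calibrated)) {
    bad_e <- which(!is.finite(df$energy_kev) | df$energy_kev <= 0)
    if (length(bad_e))
      stop("non-positive energy in calibrated record(s) ",
           record_ref(bad_e, where), call. = FALSE)
  }
  invisible(df)
}

record_ref <- function(idx, where = NULL) {
  idx <- utils::head(idx, 5L)
  lab <- if (is.null(where)) idx else where[idx]
  paste(lab, collapse = ", ")
}

#' @rdname pixel_hits
#' @param time_ns gamma detection time in ns (non-negative).
#' @param pulse_area digitizer pulse area, arbitrary units.
#' @param energy_kev calibrated gamma energy in keV (`NA` before
#'   calibration).
#' @export
gamma_events <- function(time_ns = numeric(), pulse_area = numeric(),
                         energy_kev = NA_real_) {
  df <- data.frame(time_ns = as.numeric(time_ns),
                   pulse_area = as.numeric(pulse_area),
                   energy_kev = as.numeric(energy_kev))
  validate_gamma_events(df)
  class(df) <- c("qpid_gammas", "data.frame")
  df
}

validate_gamma_events <- function(df, where = NULL) {
  bad_t <- which(!is.finite(df$time_ns) | df$time_ns < 0)
  if (length(bad_t))
    stop("negative or non-finite gamma time in record(s) ",
         record_ref(bad_t, where), call. = FALSE)
  bad_e <- which(!is.na(df$energy_kev) & df$energy_kev < 0)
  if (length(bad_e))
    stop("negative gamma energy in record(s) ", record_ref(bad_e, where),
         call. = FALSE)
  invisible(df)
}

#' Is a pixel stream energy-calibrated?
#' @param hits a `qpid_hits` data frame.
#' @return logical.
#' @export
is_calibrated <- function(hits) isTRUE(attr(hits, "calibrated"))

LISTMODE_MAGIC <- "#qpid-listmode v1"

#' Read and write the v1 list-mode text dialect
#'
#' A transparent tab-separated dialect used in place of the proprietary
#' vendor binaries.  Layout: a `#qpid-listmode v1` magic line, a
#' `#kind pixel|gamma` line, for pixel streams a `#calibrated true|false`
#' line, a column-header line, then one record per line.  Byte output for
#' a given record sequence is deterministic (fixed column order, fixed
#' `%.6f`/`%.4f` float formatting), so write-read-write is idempotent.
#'
#' @param path file path.
#' @param kind `"pixel"` or `"gamma"`; checked against the file header when
#'   supplied, inferred from it when `NULL`.
#' @return `read_listmode`: a `qpid_hits` or `qpid_gammas` data frame in
#'   file order. `write_listmode`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' h <- pixel_hits(1, 2, 3.125, 59.5)
#' write_listmode(h, f)
#' identical(read_listmode(f)$energy_kev, 59.5)
#' @export
read_listmode <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1L] != LISTMODE_MAGIC)
    stop("not a qpid list-mode v1 file (missing '", LISTMODE_MAGIC,
         "' header): ", path, call. = FALSE)
  hdr <- grep("^#", lines)
  hdr <- hdr[hdr == seq_along(hdr)]  # leading comment block only
  meta <- lines[hdr]
  kind_line <- grep("^#kind ", meta, value = TRUE)
  if (!length(kind_line))
    stop("list-mode header lacks a '#kind' line: ", path, call. = FALSE)
  file_kind <- sub("^#kind\\s+", "", kind_line[1L])
  if (!file_kind %in% c("pixel", "gamma"))
    stop("unknown list-mode kind '", file_kind, "' in ", path, call. = FALSE)
  if (!is.null(kind) && !identical(kind, file_kind))
    stop("file ", path, " holds a '", file_kind,
         "' stream, not '", kind, "'", call. = FALSE)
  calibrated <- TRUE
  cal_line <- grep("^#calibrated ", meta, value = TRUE)
  if (length(cal_line))
    calibrated <- identical(sub("^#calibrated\\s+", "", cal_line[1L]), "true")

  body_start <- length(hdr) + 1L
  if (body_start > length(lines))
    stop("list-mode file has no column-header line: ", path, call. = FALSE)
  cols <- strsplit(lines[body_start], "\t", fixed = TRUE)[[1L]]
  want <- if (file_kind == "pixel") c("col", "row", "toa_ns", "energy_kev")
          else c("time_ns", "pulse_area", "energy_kev")
  if (!identical(cols, want))
    stop("unexpected columns in ", path, ": got '",
         paste(cols, collapse = ","), "'", call. = FALSE)

  data_lines <- lines[-seq_len(body_start)]
  n <- length(data_lines)
  line_no <- seq_len(n) + body_start
  if (n == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric()), length(want)), want))
  } else {
    parts <- strsplit(data_lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(want)))
      stop("malformed record at line(s) ",
           record_ref(which(nf != length(want)), line_no), " of ", path,
           call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = length(want), byrow = TRUE)
    bad <- which(apply(is.na(m), 1L, any) &
                   !grepl("\tNA$", data_lines))
    if (length(bad))
      stop("non-numeric field at line(s) ", record_ref(bad, line_no),
           " of ", path, call. = FALSE)
    df <- as.data.frame(m)
    names(df) <- want
  }
  if (file_kind == "pixel") {
    df$col <- as.integer(df$col); df$row <- as.integer(df$row)
    validate_pixel_hits(df, calibrated = calibrated, where = line_no)
    attr(df, "calibrated") <- calibrated
    class(df) <- c("qpid_hits", "data.frame")
  } else {
    validate_gamma_events(df, where = line_no)
    class(df) <- c("qpid_gammas", "data.frame")
  }
  df
}

#' @rdname read_listmode
#' @param records a `qpid_hits` or `qpid_gammas` data frame.
#' @export
write_listmode <- function(records, path) {
  if (inherits(records, "qpid_hits")) {
    validate_pixel_hits(records, calibrated = is_calibrated(records))
    hdr <- c(LISTMODE_MAGIC, "#kind pixel",
             paste0("#calibrated ",
                    if (is_calibrated(records)) "true" else "false"),
             "col\trow\ttoa_ns\tenergy_kev")
    body <- sprintf("%d\t%d\t%.6f\t%.6f", records$col, records$row,
                    records$toa_ns, records$energy_kev)
  } else if (inherits(records, "qpid_gammas")) {
    validate_gamma_events(records)
    hdr <- c(LISTMODE_MAGIC, "#kind gamma",
             "time_ns\tpulse_area\tenergy_kev")
    body <- sprintf("%.6f\t%.4f\t%s", records$time_ns, records$pulse_area,
                    ifelse(is.na(records$energy_kev), "NA",
                           sprintf("%.6f", records$energy_kev)))
  } else {
    stop("records must be created by pixel_hits() or gamma_events()",
         call. = FALSE)
  }
  con <- file(path, open = "wb")  # binary mode: LF on every platform
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}
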