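.format_version <- 1L

#' Write / read a spectrum in the CSV exchange format
#'
#' The exchange format is a plain CSV with columns `ppm`, `re`, `im`,
#' `intensity`, preceded by comment lines carrying a `format_version` and a
#' JSON metadata block (scheme, Larmor frequency, carrier, reference).
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  meta <- spectrum_meta(spectrum)
  meta$baseline <- NULL
  meta <- meta[!vapply(meta, is.null, logical(1))]
  header <- c(
    sprintf("# ptnmr_spectrum format_version=%d", .format_version),
    paste0("# meta ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  )
  writeLines(header, path)
  readr::write_csv(tibble(ppm = spectrum$ppm, re = spectrum$re,
                          im = spectrum$im, intensity = spectrum$intensity),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path, n = 2)
  if (!grepl("^# ptnmr_spectrum format_version=", lines[1])) {
    pt_data_error("Not a ptnmr spectrum exchange file (missing format header).")
  }
  meta <- jsonlite::fromJSON(sub("^# meta ", "", lines[2]))
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("ppm", "intensity") %in% names(tbl))) {
    pt_data_error("Spectrum exchange file must have `ppm` and `intensity` columns.")
  }
  if (is.null(tbl$re)) tbl$re <- tbl$intensity
  if (is.null(tbl$im)) tbl$im <- 0
  out <- new_tibble(list(ppm = tbl$ppm, re = tbl$re, im = tbl$im,
                         intensity = tbl$intensity),
                    nrow = nrow(tbl), class = "nmr_spectrum")
  for (a in .spectrum_attr_names) attr(out, a) <- meta[[a]]
  if (!is.null(meta$phases)) attr(out, "phases") <- unlist(meta$phases)
  out
}

#' Write / read an FID in the JSON exchange format
#'
#' @param fid An `nmr_fid`.
#' @param path Output path.
#' @return `path` invisibly, or the FID.
#' @export
write_fid_json <- function(fid, path) {
  stopifnot(inherits(fid, "nmr_fid"))
  payload <- c(list(format = "ptnmr_fid", format_version = .format_version),
               fid_meta(fid), list(re = fid$re, im = fid$im))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fid_json
#' @export
read_fid_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!identical(x$format, "ptnmr_fid")) {
    pt_data_error("Not a ptnmr FID exchange file.")
  }
  new_fid(complex(real = x$re, imaginary = x$im),
          dwell_time = x$dwell_time, scheme = x$scheme,
          larmor_c = x$larmor_c, carrier_ppm = x$carrier_ppm)
}

#' Read a 1D JCAMP-DX spectrum
#'
#' Minimal reader for single-block 1D JCAMP-DX files with an
#' `##XYDATA=(X++(Y..Y))` table in plain (AFFN) form, honouring
#' `XFACTOR`/`YFACTOR`, `FIRSTX`/`LASTX` and `XUNITS`.  Hz axes are
#' converted to ppm via `.OBSERVE FREQUENCY` when present.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return An `nmr_spectrum` (real intensities; `re = intensity`, `im = 0`).
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    i <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE)
    if (length(i) == 0) return(NULL)
    trimws(sub(sprintf("^##%s=", name), "", lines[i[1]], ignore.case = TRUE))
  }
  num <- function(name) {
    v <- ldr(name)
    if (is.null(v)) NULL else as.numeric(v)
  }
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(start) == 0) pt_data_error("No ##XYDATA block found.")
  form <- toupper(gsub("[[:space:]]", "", sub("^##XYDATA=", "", lines[start[1]],
                                              ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    pt_data_error("Only (X++(Y..Y)) AFFN XYDATA tables are supported.")
  }
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start[1]]
  body <- lines[(start[1] + 1):(if (length(stop_at)) min(stop_at) - 1 else length(lines))]
  xf <- num("XFACTOR") %||% 1
  yf <- num("YFACTOR") %||% 1
  ys <- lapply(strsplit(trimws(body), "[[:space:],]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (length(tok) < 2) return(numeric(0))
    as.numeric(tok[-1]) * yf
  })
  y <- unlist(ys)
  n <- num("NPOINTS") %||% length(y)
  if (length(y) != n) pt_data_error("NPOINTS does not match the data table.")
  firstx <- num("FIRSTX") * xf
  lastx <- num("LASTX") * xf
  x <- seq(firstx, lastx, length.out = n)
  units <- toupper(ldr("XUNITS") %||% "PPM")
  obs <- num(".OBSERVEFREQUENCY") %||% num("\\.OBSERVE FREQUENCY")
  if (units == "HZ") {
    if (is.null(obs)) pt_data_error("Hz axis without .OBSERVE FREQUENCY.")
    x <- x / obs  # MHz denominator: Hz / MHz = ppm
  }
  ord <- order(x, decreasing = TRUE)
  out <- new_tibble(list(ppm = x[ord], re = y[ord], im = rep(0, n),
                         intensity = y[ord]),
                    nrow = as.integer(n), class = "nmr_spectrum")
  attr(out, "scheme") <- ldr("TITLE") %||% NA_character_
  attr(out, "reference_ppm") <- NA_real_
  out
}

#' Export an efficiency map as CSV
#'
#' Long-format CSV with a `format_version` comment header and, on request,
#' per-scheme or joint normalization columns.
#'
#' @param map An [efficiency_map()].
#' @param path Output path.
#' @param normalization `"per_scheme"`, `"joint"` or `"both"`; normalized
#'   columns are added next to the raw intensities.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path, normalization = c("both", "per_scheme", "joint")) {
  stopifnot(inherits(map, "efficiency_map"))
  normalization <- match.arg(normalization)
  out <- as_tibble(map)
  if (normalization %in% c("per_scheme", "both")) {
    out$cp_per_scheme <- out$i_cp / max(out$i_cp)
    out$inept_per_scheme <- out$i_inept / max(out$i_inept)
  }
  if (normalization %in% c("joint", "both")) {
    joint <- max(out$i_cp, out$i_inept)
    out$cp_joint <- out$i_cp / joint
    out$inept_joint <- out$i_inept / joint
  }
  writeLines(sprintf("# ptnmr_efficiency_map format_version=%d", .format_version),
             path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a classification report as JSON and text
#'
#' @param calls A tibble of per-window calls ([classify_peaks()] output) or
#'   a [series_report()].
#' @param path_json,path_txt Output paths (`NULL` to skip one of them).
#' @param meta Optional metadata list echoed into the JSON.
#' @return Invisibly, the JSON payload as a list.
#' @export
write_report <- function(calls, path_json = NULL, path_txt = NULL, meta = list()) {
  if (inherits(calls, "series_report")) {
    payload <- list(format = "ptnmr_report", format_version = .format_version,
                    meta = meta, by = calls$by,
                    groups = calls$groups, calls = calls$calls)
    txt_tbl <- calls$calls
  } else {
    payload <- list(format = "ptnmr_report", format_version = .format_version,
                    meta = meta, calls = calls)
    txt_tbl <- calls
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(path_txt)) {
    writeLines(c(utils::capture.output(print(as.data.frame(txt_tbl)))), path_txt)
  }
  invisible(payload)
}
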