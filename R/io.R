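# File interfaces: JCAMP-DX for FIDs/spectra, delimited text for tables.

fmt_num <- function(x) formatC(x, format = "e", digits = 9)

write_xy_block <- function(con, x0, dx, y, per_line = 5L) {
  n <- length(y)
  starts <- seq(1L, n, by = per_line)
  lines <- vapply(starts, function(s) {
    e <- min(s + per_line - 1L, n)
    paste(c(fmt_num(x0 + (s - 1L) * dx), fmt_num(y[s:e])), collapse = " ")
  }, character(1))
  writeLines(lines, con)
}

#' Write a FID or spectrum to JCAMP-DX
#'
#' FIDs are written as an NTUPLES record with real and imaginary pages in
#' AFFN form; spectra as an XYDATA `(X++(Y..Y))` record on the ppm axis.
#' Acquisition metadata travel in standard and `##$`-prefixed labels, so a
#' round trip through [read_jdx()] restores the object to within the
#' printed precision.
#'
#' @param x an `nmr_fid` or `nmr_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jdx <- function(x, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (inherits(x, "nmr_fid")) {
    acq <- x$acq
    writeLines(c(
      sprintf("##TITLE= %s", x$sample_id),
      "##JCAMP-DX= 5.01",
      "##DATA TYPE= NMR FID",
      "##DATA CLASS= NTUPLES",
      sprintf("##.OBSERVE FREQUENCY= %.10g", acq$frequency_mhz),
      sprintf("##$SPECTRALWINDOWPPM= %.10g", acq$spectral_window_ppm),
      sprintf("##$NPOINTSACQ= %d", acq$n_points),
      sprintf("##$NSCANS= %d", acq$n_scans),
      sprintf("##$RELAXATIONDELAY= %.10g", acq$relaxation_delay_s),
      sprintf("##$LINEBROADENING= %.10g", acq$line_broadening_hz),
      sprintf("##$CARRIERPPM= %.10g", acq$carrier_ppm),
      "##NTUPLES= NMR FID",
      "##VAR_NAME= TIME, FID/REAL, FID/IMAG",
      sprintf("##VAR_DIM= %d, %d, %d", length(x$signal), length(x$signal),
              length(x$signal)),
      "##PAGE= N=1",
      "##DATA TABLE= (X++(R..R)), XYDATA"
    ), con)
    write_xy_block(con, 0, dwell_s(acq), Re(x$signal))
    writeLines(c("##PAGE= N=2", "##DATA TABLE= (X++(I..I)), XYDATA"), con)
    write_xy_block(con, 0, dwell_s(acq), Im(x$signal))
    writeLines(c("##END NTUPLES= NMR FID", "##END="), con)
  } else if (inherits(x, "nmr_spectrum")) {
    acq <- x$acq
    n <- length(x$intensity)
    writeLines(c(
      sprintf("##TITLE= %s", x$sample_id),
      "##JCAMP-DX= 5.01",
      "##DATA TYPE= NMR SPECTRUM",
      "##DATA CLASS= XYDATA",
      sprintf("##.OBSERVE FREQUENCY= %.10g",
              if (!is.null(acq$frequency_mhz)) acq$frequency_mhz else NA),
      "##XUNITS= PPM",
      "##YUNITS= ARBITRARY UNITS",
      sprintf("##FIRSTX= %.10g", x$ppm[1]),
      sprintf("##LASTX= %.10g", x$ppm[n]),
      sprintf("##NPOINTS= %d", n),
      sprintf("##$CALIBRATED= %s", if (isTRUE(x$calibrated)) "TRUE" else "FALSE"),
      "##XYDATA= (X++(Y..Y))"
    ), con)
    write_xy_block(con, x$ppm[1], (x$ppm[n] - x$ppm[1]) / (n - 1), x$intensity)
    writeLines("##END=", con)
  } else {
    abort("write_jdx() expects an nmr_fid or nmr_spectrum",
          "urinmr_validation_error")
  }
  invisible(path)
}

parse_jdx_numeric_block <- function(lines) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  unlist(lapply(toks, function(t) as.numeric(t[-1])), use.names = FALSE)
}

#' Read a JCAMP-DX file written by [write_jdx()]
#'
#' Parses the AFFN subset this package emits (NTUPLES FIDs with real and
#' imaginary pages, and XYDATA spectra). Malformed or truncated files raise
#' a `urinmr_parse_error` identifying the offending line.
#'
#' @param path JCAMP-DX file path.
#' @return an `nmr_fid` or `nmr_spectrum`.
#' @export
read_jdx <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines) || !grepl("^##TITLE=", lines[1])) {
    abort(sprintf("%s: not a JCAMP-DX file (line 1)", path), "urinmr_parse_error")
  }
  if (!any(grepl("^##END=", lines))) {
    abort(sprintf("%s: truncated file, missing ##END= (line %d)",
                  path, length(lines)),
          "urinmr_parse_error")
  }
  is_label <- grepl("^##", lines)
  labels <- sub("=.*$", "", lines[is_label])
  values <- trimws(sub("^[^=]*=", "", lines[is_label]))
  names(values) <- labels
  getv <- function(lab, required = TRUE) {
    v <- values[match(lab, labels)]
    if (required && is.na(v)) {
      abort(sprintf("%s: missing required label %s", path, lab),
            "urinmr_parse_error")
    }
    unname(v)
  }
  dtype <- getv("##DATA TYPE")
  title <- getv("##TITLE")

  block_after <- function(start_pattern) {
    i0 <- grep(start_pattern, lines)
    if (!length(i0)) {
      abort(sprintf("%s: missing data block %s", path, start_pattern),
            "urinmr_parse_error")
    }
    i0 <- i0[1] + 1L
    i1 <- i0
    while (i1 <= length(lines) && !grepl("^##", lines[i1])) i1 <- i1 + 1L
    if (i1 == i0) {
      abort(sprintf("%s: empty data block at line %d", path, i0),
            "urinmr_parse_error")
    }
    vals <- parse_jdx_numeric_block(lines[i0:(i1 - 1L)])
    if (anyNA(vals)) {
      abort(sprintf("%s: non-numeric value inside data block starting line %d",
                    path, i0),
            "urinmr_parse_error")
    }
    vals
  }

  if (grepl("FID", dtype)) {
    acq <- acq_params(
      frequency_mhz = as.numeric(getv("##.OBSERVE FREQUENCY")),
      spectral_window_ppm = as.numeric(getv("##$SPECTRALWINDOWPPM")),
      n_points = as.integer(getv("##$NPOINTSACQ")),
      n_scans = as.integer(getv("##$NSCANS")),
      relaxation_delay_s = as.numeric(getv("##$RELAXATIONDELAY")),
      line_broadening_hz = as.numeric(getv("##$LINEBROADENING")),
      carrier_ppm = as.numeric(getv("##$CARRIERPPM"))
    )
    pages <- grep("^##PAGE=", lines)
    if (length(pages) < 2) {
      abort(sprintf("%s: FID needs real and imaginary pages", path),
            "urinmr_parse_error")
    }
    re <- block_after("^##DATA TABLE= \\(X\\+\\+\\(R\\.\\.R\\)\\)")
    im <- block_after("^##DATA TABLE= \\(X\\+\\+\\(I\\.\\.I\\)\\)")
    if (length(re) != length(im)) {
      abort(sprintf("%s: real/imaginary pages differ in length", path),
            "urinmr_parse_error")
    }
    structure(list(signal = complex(real = re, imaginary = im), acq = acq,
                   sample_id = title),
              class = "nmr_fid")
  } else {
    n <- as.integer(getv("##NPOINTS"))
    firstx <- as.numeric(getv("##FIRSTX"))
    lastx <- as.numeric(getv("##LASTX"))
    y <- block_after("^##XYDATA=")
    if (length(y) != n) {
      abort(sprintf("%s: expected %d points, found %d", path, n, length(y)),
            "urinmr_parse_error")
    }
    ppm <- seq(firstx, lastx, length.out = n)
    freq <- suppressWarnings(as.numeric(getv("##.OBSERVE FREQUENCY",
                                             required = FALSE)))
    new_spectrum(y, NULL, ppm,
                 list(frequency_mhz = if (is.na(freq)) 500 else freq),
                 title,
                 calibrated = identical(getv("##$CALIBRATED",
                                             required = FALSE), "TRUE"))
  }
}

#' Read spectra or FIDs from files
#'
#' @param paths character vector of file paths.
#' @param format `"jdx"` (JCAMP-DX, FID or spectrum) or `"tsv"` (delimited
#'   two-column ppm/intensity spectrum with a header row). Delimited axes
#'   are expected descending; ascending input is reordered with a warning.
#' @param frequency_mhz assumed proton frequency for delimited spectra.
#' @return a list of `nmr_fid`/`nmr_spectrum` objects.
#' @export
read_spectra <- function(paths, format = c("jdx", "tsv"),
                         frequency_mhz = 500) {
  format <- match.arg(format)
  lapply(paths, function(p) {
    if (format == "jdx") return(read_jdx(p))
    tab <- utils::read.table(p, header = TRUE, sep = "\t")
    if (ncol(tab) < 2) {
      abort(sprintf("%s: expected two columns (ppm, intensity)", p),
            "urinmr_parse_error")
    }
    ppm <- tab[[1]]
    y <- tab[[2]]
    if (anyNA(ppm) || anyNA(y)) {
      abort(sprintf("%s: non-numeric values in spectrum table", p),
            "urinmr_parse_error")
    }
    if (ppm[1] < ppm[length(ppm)]) {
      warning(sprintf("%s: ascending ppm axis reordered to descending", p))
      o <- order(ppm, decreasing = TRUE)
      ppm <- ppm[o]
      y <- y[o]
    }
    new_spectrum(y, NULL, ppm, list(frequency_mhz = frequency_mhz),
                 sub("\\.[^.]*$", "", basename(p)))
  })
}

#' Write a delimited spectrum (ppm, intensity)
#'
#' @param spec an `nmr_spectrum`.
#' @param path output path (tab-separated, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Shared writer for result tables.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
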