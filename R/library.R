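#' Default urinary metabolite signal panel
#'
#' The panel covers 27 urinary metabolite signals routinely profiled in
#' 1D proton NMR of urine, plus the TSP concentration/chemical-shift
#' reference. Chemical shifts, multiplicities, proton counts and molecular
#' weights are bundled editable defaults approximating standard urine NMR
#' reference positions; minor spacing adjustments (up to a few hundredths of
#' a ppm) keep the default integration windows free of cross-signal overlap
#' so that window-based quantification is well conditioned. Lactate
#' contributes two signals (methyl doublet and methine quartet), so the two
#' rows `Lactate_CH3` and `Lactate_CH` share the compound `Lactate` and a
#' single simulated concentration.
#'
#' Columns: `signal` (unique row identifier), `compound` (concentration is
#' simulated per compound), `center_ppm`, `pattern` (`s`, `d`, `q`, or
#' `custom`), `j_hz` (scalar coupling for `d`/`q`), `offsets_ppm` /
#' `weights` (comma-separated, for `custom`), `protons` (per signal),
#' `mw` (g/mol), `window_lo`, `window_hi` (default quantification window).
#'
#' @return a data.frame with one row per panel signal plus the `TSP` row.
#' @export
default_metabolite_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
signal compound center_ppm pattern j_hz offsets_ppm weights protons mw window_lo window_hi
Valine Valine 0.99 d 7 NA NA 3 117.15 0.970 1.010
2-Methylglutarate 2-Methylglutarate 1.05 d 7 NA NA 3 146.14 1.030 1.070
PropyleneGlycol PropyleneGlycol 1.11 d 7 NA NA 3 76.09 1.090 1.130
3-Hydroxybutyrate 3-Hydroxybutyrate 1.17 d 7 NA NA 3 104.10 1.150 1.190
Methylmalonate Methylmalonate 1.23 d 7 NA NA 3 118.09 1.210 1.250
3-Hydroxyisovalerate 3-Hydroxyisovalerate 1.29 s NA NA NA 6 118.13 1.270 1.310
Lactate_CH3 Lactate 1.35 d 7 NA NA 3 90.08 1.330 1.370
2-Hydroxyisobutyrate 2-Hydroxyisobutyrate 1.41 s NA NA NA 6 104.10 1.390 1.430
Alanine Alanine 1.48 d 7 NA NA 3 89.09 1.460 1.500
Lipids Lipids 1.60 s NA NA NA 2 282.46 1.560 1.640
Acetate Acetate 1.92 s NA NA NA 3 60.05 1.895 1.945
Nacetylglucosamine Nacetylglucosamine 2.04 s NA NA NA 3 221.21 2.015 2.065
Piruvate Piruvate 2.37 s NA NA NA 3 88.06 2.345 2.395
Citrate Citrate 2.60 custom NA -0.068,-0.052,0.052,0.068 0.25,0.25,0.25,0.25 4 192.12 2.500 2.700
Sarcosine Sarcosine 2.73 s NA NA NA 3 89.09 2.705 2.755
Creatinine Creatinine 3.05 s NA NA NA 3 113.12 3.020 3.080
AcetylcholineCholine AcetylcholineCholine 3.19 s NA NA NA 9 104.17 3.165 3.215
Carnitine Carnitine 3.27 s NA NA NA 9 161.20 3.245 3.295
Methanol Methanol 3.36 s NA NA NA 3 32.04 3.335 3.385
Creatine Creatine 3.93 s NA NA NA 2 131.13 3.905 3.955
Lactate_CH Lactate 4.11 q 7 NA NA 1 90.08 4.060 4.160
Glucose Glucose 5.23 d 3.8 NA NA 1 180.16 5.190 5.270
Urea Urea 5.78 s NA NA NA 4 60.06 5.700 5.860
Phenylalanine Phenylalanine 7.37 custom NA -0.05,0,0.05 0.4,0.2,0.4 5 165.19 7.280 7.460
Hippurate Hippurate 7.83 d 7.8 NA NA 2 179.17 7.790 7.870
Formate Formate 8.46 s NA NA NA 1 46.03 8.430 8.490
Trigonelline Trigonelline 9.12 s NA NA NA 1 137.14 9.090 9.150
TSP TSP 0.00 s NA NA NA 9 172.24 -0.025 0.025
')
  tab
}

# Expand one table row into explicit line positions and weights.
signal_lines <- function(row, frequency_mhz) {
  center <- row$center_ppm
  j_ppm <- if (is.na(row$j_hz)) 0 else row$j_hz / frequency_mhz
  switch(row$pattern,
    s = data.frame(ppm = center, weight = 1),
    d = data.frame(ppm = center + c(-0.5, 0.5) * j_ppm, weight = c(0.5, 0.5)),
    q = data.frame(ppm = center + c(-1.5, -0.5, 0.5, 1.5) * j_ppm,
                   weight = c(1, 3, 3, 1) / 8),
    custom = {
      off <- as.numeric(strsplit(row$offsets_ppm, ",")[[1]])
      w <- as.numeric(strsplit(row$weights, ",")[[1]])
      data.frame(ppm = center + off, weight = w / sum(w))
    },
    abort(sprintf("unknown multiplet pattern '%s'", row$pattern),
          "urinmr_validation_error")
  )
}

#' Build the metabolite signal library
#'
#' Assembles the default panel (see [default_metabolite_table()]) into a
#' library of fully expanded signal entries: explicit line positions and
#' relative weights, proton counts, molecular weights and quantification
#' windows, plus the TSP reference entry (a 9-proton singlet at 0.00 ppm).
#' Entries may be overridden field-by-field.
#'
#' @param overrides optional named list; each element is itself a named list
#'   of fields (`center_ppm`, `protons`, `mw`, `window`, ...) replacing the
#'   defaults for that signal. Unknown signal names raise a lookup error.
#' @param frequency_mhz proton frequency used to convert scalar couplings
#'   (Hz) into ppm offsets.
#' @param water_exclusion ppm interval reserved for residual water; signal
#'   windows must not overlap it.
#' @return an object of class `metabolite_library` with elements `entries`
#'   (named list of signal entries) and `reference` (the TSP entry).
#' @examples
#' lib <- generate_metabolite_library()
#' length(lib$entries)            # 27 panel signals
#' lib$reference$protons          # 9
#' @export
generate_metabolite_library <- function(overrides = NULL,
                                        frequency_mhz = 500,
                                        water_exclusion = c(4.65, 4.95)) {
  tab <- default_metabolite_table()
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("overrides must be a named list", "urinmr_validation_error")
    }
    unknown <- setdiff(names(overrides), tab$signal)
    if (length(unknown)) {
      abort(sprintf("unknown metabolite signal name(s): %s",
                    paste(unknown, collapse = ", ")),
            "urinmr_lookup_error")
    }
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      i <- match(nm, tab$signal)
      for (field in names(ov)) {
        if (field == "window") {
          tab$window_lo[i] <- ov$window[1]
          tab$window_hi[i] <- ov$window[2]
        } else if (field %in% names(tab)) {
          tab[[field]][i] <- ov[[field]]
        } else {
          abort(sprintf("unknown override field '%s' for '%s'", field, nm),
                "urinmr_lookup_error")
        }
      }
    }
  }
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    if (row$protons < 1) {
      abort(sprintf("'%s': protons must be >= 1", row$signal),
            "urinmr_validation_error")
    }
    if (row$window_lo >= row$window_hi) {
      abort(sprintf("'%s': quantification window must satisfy lo < hi", row$signal),
            "urinmr_validation_error")
    }
    if (row$signal != "TSP" &&
        row$window_lo < water_exclusion[2] && row$window_hi > water_exclusion[1]) {
      abort(sprintf("'%s': quantification window overlaps the water exclusion region",
                    row$signal),
            "urinmr_validation_error")
    }
    list(
      signal = row$signal,
      compound = row$compound,
      lines = signal_lines(row, frequency_mhz),
      protons = row$protons,
      mw = row$mw,
      window = c(row$window_lo, row$window_hi)
    )
  })
  names(entries) <- tab$signal
  if (anyDuplicated(names(entries))) {
    abort("metabolite signal names must be unique", "urinmr_validation_error")
  }
  structure(
    list(
      entries = entries[setdiff(names(entries), "TSP")],
      reference = entries[["TSP"]]
    ),
    class = "metabolite_library"
  )
}

#' Look up a signal entry in a metabolite library
#'
#' @param lib a `metabolite_library`.
#' @param name signal name (`"TSP"` returns the reference entry).
#' @return the signal entry (a list).
#' @export
library_entry <- function(lib, name) {
  stopifnot(inherits(lib, "metabolite_library"))
  if (identical(name, "TSP")) return(lib$reference)
  entry <- lib$entries[[name]]
  if (is.null(entry)) {
    abort(sprintf("unknown metabolite signal name: '%s'", name),
          "urinmr_lookup_error")
  }
  entry
}

# Compounds present in the library (concentrations are per compound).
library_compounds <- function(lib) {
  unique(vapply(lib$entries, `[[`, character(1), "compound"))
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf("<metabolite_library> %d panel signals (%d compounds) + TSP reference\n",
              length(x$entries), length(library_compounds(x))))
  invisible(x)
}
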