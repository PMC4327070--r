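#' Construct a spectrum
#'
#' A spectrum is the raw observable of the sensor: sampled emission intensity
#' (detector counts) versus vacuum wavelength (nm), plus acquisition metadata.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of non-negative detector counts, same
#'   length as `wavelength_nm`.
#' @param meta Named list of acquisition metadata. Recognised keys:
#'   `grating_lines_per_mm`, `pump_power_uW`, `time_s`, `label`; other keys
#'   are carried along untouched.
#' @return An object of class `wgm_spectrum`: a list with elements
#'   `wavelength_nm`, `intensity`, `meta`.
#' @export
#' @examples
#' s <- wgm_spectrum(c(620.000, 620.004), c(100, 110))
#' length(s$wavelength_nm)
wgm_spectrum <- function(wavelength_nm, intensity, meta = list()) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity must have the same length")
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least 2 samples")
  if (anyNA(wavelength_nm) || anyNA(intensity))
    stop("NA values are not allowed in a spectrum")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  if (!is.list(meta)) stop("meta must be a list")
  structure(
    list(wavelength_nm = wavelength_nm, intensity = intensity, meta = meta),
    class = "wgm_spectrum"
  )
}

#' @export
print.wgm_spectrum <- function(x, ...) {
  cat(sprintf(
    "<wgm_spectrum> %d samples, %.3f-%.3f nm, max %.4g counts\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    max(x$intensity)
  ))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Instrument (detector) model
#'
#' Models the monochromator + CCD sampling: `n_pixels` samples spread evenly
#' across a wavelength window.  The per-pixel spacing is the wavelength
#' resolution; with a 2400 L/mm grating the detection system resolves about
#' 4 pm, which with 2048 pixels corresponds to a window of roughly 8 nm.
#' The wavelength window per grating is a configuration choice; the default
#' covers the full dye emission band.
#'
#' @param n_pixels Integer number of detector pixels (default 2048).
#' @param wavelength_window_nm Length-2 numeric, the recorded window in nm
#'   (default `c(570, 650)`).
#' @return An object of class `wgm_instrument` with fields `n_pixels`,
#'   `wavelength_window_nm` and the derived `resolution_nm` (pixel spacing).
#' @export
#' @examples
#' # high-resolution grating setting: 4 pm sampling around the lasing band
#' instrument_model(2048, c(616, 616 + 2047 * 0.004))$resolution_nm
instrument_model <- function(n_pixels = 2048,
                             wavelength_window_nm = c(570, 650)) {
  n_pixels <- as.integer(n_pixels)
  if (is.na(n_pixels) || n_pixels < 2L) stop("n_pixels must be >= 2")
  if (length(wavelength_window_nm) != 2L ||
      diff(wavelength_window_nm) <= 0)
    stop("wavelength_window_nm must be an increasing length-2 range")
  res <- diff(wavelength_window_nm) / (n_pixels - 1L)
  structure(
    list(n_pixels = n_pixels,
         wavelength_window_nm = as.numeric(wavelength_window_nm),
         resolution_nm = res),
    class = "wgm_instrument"
  )
}

#' @export
print.wgm_instrument <- function(x, ...) {
  cat(sprintf("<wgm_instrument> %d px, %.3f-%.3f nm, %.4g pm/px\n",
              x$n_pixels, x$wavelength_window_nm[1],
              x$wavelength_window_nm[2], 1000 * x$resolution_nm))
  invisible(x)
}

# wavelength grid of an instrument
instrument_grid <- function(instrument) {
  seq(instrument$wavelength_window_nm[1], instrument$wavelength_window_nm[2],
      length.out = instrument$n_pixels)
}

#' Read a spectrum from a CSV/TSV file
#'
#' The dialect is two numeric columns (wavelength in nm, intensity in counts),
#' comma- or tab/whitespace-separated, with optional `#key=value` metadata
#' header lines and an optional column-name header.  If the wavelengths are
#' stored in descending order the spectrum is sorted ascending with a warning.
#'
#' @param path Path to the file.
#' @return A [wgm_spectrum()] object; metadata comments populate `meta`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  wl <- numeric(0)
  it <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- sub("^#\\s*", "", ln)
      if (grepl("=", body, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", body))
        val <- trimws(sub("^[^=]*=", "", body))
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (!is.na(num)) num else val
      }
      next
    }
    parts <- strsplit(ln, if (grepl(",", ln, fixed = TRUE)) "," else "[\t ]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L)
      stop("line ", i, ": expected two columns, got ", length(parts))
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (anyNA(vals)) {
      # allow a single column-name header line
      if (length(wl) == 0L && all(is.na(suppressWarnings(as.numeric(parts)))))
        next
      stop("line ", i, ": non-numeric value in '", ln, "'")
    }
    wl <- c(wl, vals[1])
    it <- c(it, vals[2])
  }
  if (length(wl) < 2L)
    stop("empty input: fewer than 2 data rows in ", path)
  if (is.unsorted(wl, strictly = TRUE)) {
    warning("wavelengths not ascending in ", path, "; sorting")
    o <- order(wl)
    wl <- wl[o]
    it <- it[o]
  }
  wgm_spectrum(wl, it, meta)
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum()]: scalar metadata as `#key=value` comments,
#' a `wavelength_nm,intensity` header, then the data at 12 significant
#' digits.  A write/read/write round trip reproduces the file byte for byte.
#'
#' @param spectrum A [wgm_spectrum()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "wgm_spectrum"))
  hdr <- character(0)
  for (key in names(spectrum$meta)) {
    val <- spectrum$meta[[key]]
    if (length(val) == 1L && (is.numeric(val) || is.character(val)))
      hdr <- c(hdr, sprintf("#%s=%s", key,
                            if (is.numeric(val)) sprintf("%.12g", val) else val))
  }
  rows <- sprintf("%.12g,%.12g", spectrum$wavelength_nm, spectrum$intensity)
  writeLines(c(hdr, "wavelength_nm,intensity", rows), path)
  invisible(path)
}

# classes write_results knows how to serialize
.result_classes <- c(
  "resonance_peak", "peak_track", "threshold_fit", "binding_series",
  "kinetics_summary", "surface_loading", "deposition_report",
  "lod_decision", "mie_mode_table", "radius_estimate"
)

#' Write an analysis result record as JSON
#'
#' Serializes any of the package's result objects (fitted peaks, threshold
#' fits, surface loadings, kinetics summaries, ...) to a small JSON document
#' with a schema version and the object class recorded.  Units are encoded
#' in the field names themselves (`center_nm`, `d_g_m2`, ...).
#'
#' @param obj A result object of a documented class (see Details).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @details Supported classes: `resonance_peak`, `peak_track`,
#'   `threshold_fit`, `binding_series`, `kinetics_summary`,
#'   `surface_loading`, `deposition_report`, `lod_decision`,
#'   `mie_mode_table`, `radius_estimate`.  Anything else is a schema error.
#' @seealso [read_results()]
#' @export
write_results <- function(obj, path) {
  cls <- intersect(class(obj), .result_classes)
  if (length(cls) == 0L)
    stop("schema error: don't know how to serialize an object of class ",
         paste(class(obj), collapse = "/"))
  payload <- list(
    schema_version = "1.0",
    type = cls[[1]],
    data = if (is.data.frame(obj)) as.list(as.data.frame(obj)) else
      unclass(obj)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a result record written by [write_results()]
#'
#' @param path Path to a JSON file produced by [write_results()].
#' @return The result object with its class restored.  Numeric values round
#'   trip to 12 significant digits.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || !(doc$type %in% .result_classes))
    stop("schema error: not a wgmsense result document: ", path)
  out <- doc$data
  if (doc$type %in% c("peak_track", "binding_series", "deposition_report",
                      "mie_mode_table"))
    out <- as.data.frame(out)
  class(out) <- c(doc$type, class(out))
  out
}

#' Read a YAML configuration file
#'
#' A configuration has up to four sections: `resonator`, `molecule`,
#' `instrument` and `simulation`.  Each present section is passed through
#' the corresponding constructor so invalid values fail fast.
#'
#' @param path Path to a YAML file.
#' @return Named list with any of `resonator` ([resonator_model()]),
#'   `molecule` ([molecule_properties()]), `instrument`
#'   ([instrument_model()]) and `simulation` (plain list of scene
#'   overrides).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$resonator))
    out$resonator <- do.call(resonator_model, raw$resonator)
  if (!is.null(raw$molecule)) {
    # an unquoted "n:" key is a YAML 1.1 boolean; map it back
    names(raw$molecule)[names(raw$molecule) %in% c("FALSE", "no")] <- "n"
    out$molecule <- do.call(molecule_properties, raw$molecule)
  }
  if (!is.null(raw$instrument))
    out$instrument <- do.call(instrument_model, raw$instrument)
  if (!is.null(raw$simulation))
    out$simulation <- raw$simulation
  out
}
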