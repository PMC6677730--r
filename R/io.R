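#' Read a grayscale image
#'
#' Reads 8/16-bit PNG or 8/16/32-bit TIFF into a floating matrix. RGB(A)
#' input is converted to a single channel by Rec. 709 luminance; integer
#' formats arrive scaled to \[0, 1\].
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric matrix with attributes `bit_depth` (or NA when the
#'   format does not expose it) and `source` (the path).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    depth <- NA_integer_
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
    if (is.null(depth)) depth <- NA_integer_
  } else {
    stopf("unsupported image format '.%s' (use .png, .tif or .tiff)", ext)
  }
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img <- as.matrix(img)
  attr(img, "bit_depth") <- as.integer(depth)
  attr(img, "source") <- path
  img
}

#' Write a grayscale image
#'
#' 8-bit PNG, or 8/16-bit integer / 32-bit float TIFF. All depths store
#' values in \[0, 1\] (out-of-range values are clipped before writing, the
#' TIFF container does not define their storage otherwise); writing and
#' re-reading a 16-bit TIFF of 16-bit data is lossless, and 32-bit float
#' keeps full single precision. Callers with data on another scale divide
#' by their maximum and record the scale (the pipeline stores it in the
#' sidecar).
#'
#' @param image Numeric matrix.
#' @param path Output path; the extension selects the container.
#' @param bit_depth 8, 16 or 32 (32 valid for TIFF only).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- pmin(pmax(image, 0), 1)
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(8, 16, 32)) stopf("bit_depth must be 8, 16 or 32")
    img <- pmin(pmax(image, 0), 1)
    tiff::writeTIFF(img, path, bits.per.sample = bit_depth,
                    compression = "none")
  } else {
    stopf("unsupported image format '.%s' (use .png, .tif or .tiff)", ext)
  }
  invisible(path)
}

.config_keys <- c("wavelength", "bandwidth", "source_detector_distance",
                  "object_detector_distance", "pixel_count", "pixel_pitch",
                  "source_aperture_diameter", "seed", "use_effective_geometry",
                  "saturation_fraction", "input", "background", "output")
.config_lengths <- c("wavelength", "bandwidth", "source_detector_distance",
                     "object_detector_distance", "pixel_pitch",
                     "source_aperture_diameter")

#' Load a run configuration
#'
#' Reads a YAML key-value file describing an [optical_setup()] plus
#' processing options. Every length carries a mandatory unit suffix
#' (`wavelength: "405 nm"`). Unknown keys, missing required keys and
#' invariant violations raise errors naming the key.
#'
#' Keys: `wavelength`, `source_detector_distance`,
#' `object_detector_distance`, `pixel_count`, `pixel_pitch` (required);
#' `bandwidth` (default "0 m"), `source_aperture_diameter` (default "0 m"),
#' `seed` (default 1), `use_effective_geometry` (default FALSE),
#' `saturation_fraction` (default 0.002), `input`, `background`, `output`
#' (paths, optional).
#'
#' @param path Path to the YAML file.
#' @return A list of class `run_config`: `setup` ([optical_setup()]),
#'   `seed`, `use_effective_geometry`, `saturation_fraction`, `paths`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (key in c("wavelength", "source_detector_distance",
                "object_detector_distance", "pixel_count", "pixel_pitch"))
    if (is.null(raw[[key]])) stopf("config is missing required key '%s'", key)
  lens <- list()
  for (key in .config_lengths)
    if (!is.null(raw[[key]])) lens[[key]] <- parse_length(raw[[key]], key)
  setup <- optical_setup(
    wavelength = lens$wavelength,
    source_detector_distance = lens$source_detector_distance,
    object_detector_distance = lens$object_detector_distance,
    pixel_count = raw$pixel_count,
    pixel_pitch = lens$pixel_pitch,
    bandwidth = if (is.null(lens$bandwidth)) 0 else lens$bandwidth,
    source_aperture_diameter =
      if (is.null(lens$source_aperture_diameter)) 0 else lens$source_aperture_diameter)
  structure(list(
    setup = setup,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    use_effective_geometry = isTRUE(raw$use_effective_geometry),
    saturation_fraction =
      if (is.null(raw$saturation_fraction)) 0.002 else as.numeric(raw$saturation_fraction),
    paths = list(input = raw$input, background = raw$background,
                 output = raw$output)),
    class = "run_config")
}

#' Save a run configuration
#'
#' Writes a `run_config` back to YAML; lengths are emitted in metres at
#' full double precision so that `load_config(save_config(x)) == x`.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  s <- config$setup
  out <- list(
    wavelength = sprintf("%.17g m", s$wavelength),
    bandwidth = sprintf("%.17g m", s$bandwidth),
    source_detector_distance = sprintf("%.17g m", s$source_detector_distance),
    object_detector_distance = sprintf("%.17g m", s$object_detector_distance),
    pixel_count = s$pixel_count,
    pixel_pitch = sprintf("%.17g m", s$pixel_pitch),
    source_aperture_diameter = sprintf("%.17g m", s$source_aperture_diameter),
    seed = config$seed,
    use_effective_geometry = config$use_effective_geometry,
    saturation_fraction = config$saturation_fraction)
  for (key in c("input", "background", "output"))
    if (!is.null(config$paths[[key]])) out[[key]] <- config$paths[[key]]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed", x$seed, "\n")
  print(x$setup)
  invisible(x)
}
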