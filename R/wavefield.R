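#' Complex scalar wave field on a uniform grid
#'
#' @param amplitude Complex (or real, promoted) matrix of field samples,
#'   rows = y, cols = x, origin at the image centre.
#' @param pixel_pitch Sample spacing \[m\].
#' @param wavelength Wavelength \[m\].
#' @return An object of class `wave_field`.
#' @export
wave_field <- function(amplitude, pixel_pitch, wavelength) {
  if (!is.matrix(amplitude) || nrow(amplitude) < 2L || ncol(amplitude) < 2L)
    stopf("amplitude must be a matrix with at least 2 rows and 2 columns")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  if (wavelength <= 0) stopf("wavelength must be > 0")
  storage.mode(amplitude) <- "complex"
  structure(list(amplitude = amplitude, pixel_pitch = pixel_pitch,
                 wavelength = wavelength),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("<wave_field> %d x %d, pitch %s, wavelength %s\n",
              nrow(x$amplitude), ncol(x$amplitude),
              format_length(x$pixel_pitch), format_length(x$wavelength)))
  invisible(x)
}

#' Recorded (or simulated) hologram
#'
#' Bundles a nonnegative intensity image with the [optical_setup()] that
#' produced it and, optionally, an object-free background recording of the
#' same shape used for background subtraction.
#'
#' @param intensity Nonnegative real matrix (detector counts, arbitrary scale).
#' @param setup The [optical_setup()] describing the recording geometry.
#' @param background Optional background intensity matrix, same shape.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, setup, background = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stopf("intensity must be a numeric matrix")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stopf("intensities must be finite and nonnegative")
  stopifnot(inherits(setup, "optical_setup"))
  if (!is.null(background)) {
    if (!is.matrix(background) || !all(dim(background) == dim(intensity)))
      stopf("background shape (%s) does not match intensity shape (%s)",
            paste(dim(background), collapse = "x"),
            paste(dim(intensity), collapse = "x"))
    if (any(!is.finite(background)) || any(background < 0))
      stopf("background intensities must be finite and nonnegative")
  }
  structure(list(intensity = intensity, setup = setup, background = background),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d, %s background\n",
              nrow(x$intensity), ncol(x$intensity),
              if (is.null(x$background)) "no" else "with"))
  print(x$setup)
  invisible(x)
}
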