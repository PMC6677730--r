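#' Describe one DIHM instrument geometry
#'
#' A lens-less inline holographic microscope is fully described by its
#' illumination (wavelength, spectral bandwidth, source aperture), the
#' source-to-detector distance `f`, the object-to-detector distance `s`, and
#' the detector sampling (pixel count per side used for reconstruction and
#' pixel pitch). All lengths are metres.
#'
#' @param wavelength Centre wavelength of the illumination \[m\].
#' @param source_detector_distance Distance `f` between point source and
#'   detector plane \[m\].
#' @param object_detector_distance Distance `s` between object plane and
#'   detector plane \[m\]; must satisfy `0 < s < f`.
#' @param pixel_count Number of detector pixels per side `N` used for
#'   reconstruction (integer, >= 2).
#' @param pixel_pitch Detector pixel pitch `p` \[m\].
#' @param bandwidth Full-width-half-maximum spectral bandwidth \[m\];
#'   0 for an effectively monochromatic laser line.
#' @param source_aperture_diameter Pinhole diameter or fibre mode-field
#'   diameter \[m\]; 0 for an ideal point source.
#' @return An object of class `optical_setup`.
#' @examples
#' # Laser-diode arm: 405 nm through a single-mode fibre, camera at 30 mm
#' ld <- optical_setup(405e-9, 30e-3, 5.91e-3, 2464, 1.12e-6,
#'                     source_aperture_diameter = 3.3e-6)
#' lateral_resolution(ld)  # 8.67e-7 m
#' @export
optical_setup <- function(wavelength, source_detector_distance,
                          object_detector_distance, pixel_count, pixel_pitch,
                          bandwidth = 0, source_aperture_diameter = 0) {
  if (!is.numeric(wavelength) || wavelength <= 0) stopf("wavelength must be > 0")
  if (bandwidth < 0) stopf("bandwidth must be >= 0")
  if (source_detector_distance <= 0) stopf("source_detector_distance must be > 0")
  if (object_detector_distance <= 0 || object_detector_distance >= source_detector_distance)
    stopf("object_detector_distance must satisfy 0 < s < f (got s=%g, f=%g)",
          object_detector_distance, source_detector_distance)
  pixel_count <- as.integer(pixel_count)
  if (is.na(pixel_count) || pixel_count < 2L) stopf("pixel_count must be an integer >= 2")
  if (pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  if (source_aperture_diameter < 0) stopf("source_aperture_diameter must be >= 0")
  structure(list(wavelength = wavelength,
                 bandwidth = bandwidth,
                 source_detector_distance = source_detector_distance,
                 object_detector_distance = object_detector_distance,
                 pixel_count = pixel_count,
                 pixel_pitch = pixel_pitch,
                 source_aperture_diameter = source_aperture_diameter),
            class = "optical_setup")
}

#' @export
print.optical_setup <- function(x, ...) {
  cat("<optical_setup>\n")
  cat("  wavelength      :", format_length(x$wavelength), "\n")
  cat("  bandwidth (FWHM):", format_length(x$bandwidth), "\n")
  cat("  source-detector :", format_length(x$source_detector_distance), "\n")
  cat("  object-detector :", format_length(x$object_detector_distance), "\n")
  cat("  pixels / pitch  :", x$pixel_count, "x", format_length(x$pixel_pitch), "\n")
  cat("  source aperture :", format_length(x$source_aperture_diameter), "\n")
  invisible(x)
}

#' Fundamental-mode Gaussian beam
#'
#' @param waist_radius Beam waist radius `w0` (half the mode-field diameter) \[m\].
#' @param wavelength Wavelength \[m\].
#' @return An object of class `gaussian_beam`.
#' @examples
#' # 3.3 um mode-field diameter single-mode fibre at 405 nm
#' b <- gaussian_beam(1.65e-6, 405e-9)
#' rayleigh_length(b)       # ~21 um
#' beam_diameter(b, 30e-3)  # ~4.7 mm
#' @export
gaussian_beam <- function(waist_radius, wavelength) {
  if (waist_radius <= 0) stopf("waist_radius must be > 0")
  if (wavelength <= 0) stopf("wavelength must be > 0")
  structure(list(waist_radius = waist_radius, wavelength = wavelength),
            class = "gaussian_beam")
}

#' Numerical-aperture bound on lateral resolution
#'
#' The lateral resolution of an inline holographic microscope is bounded by
#' the effective numerical aperture of the recording: delta = lambda / (2 NA).
#'
#' @param wavelength Wavelength \[m\], > 0.
#' @param na Numerical aperture, in (0, 1].
#' @return Lateral resolution \[m\].
#' @export
lateral_resolution_from_na <- function(wavelength, na) {
  if (wavelength <= 0) stopf("wavelength must be > 0")
  if (na <= 0 || na > 1) stopf("numerical aperture must lie in (0, 1], got %g", na)
  wavelength / (2 * na)
}

#' Pixel-grid limited lateral resolution
#'
#' For a detector of `N` pixels with pitch `p` at distance `s` from the
#' object, the NA bound translates to delta = s * lambda / (N * p): the
#' half-width of the detector, seen from the object, sets the effective NA.
#'
#' @param setup An [optical_setup()].
#' @return Lateral resolution \[m\].
#' @export
lateral_resolution <- function(setup) {
  stopifnot(inherits(setup, "optical_setup"))
  setup$object_detector_distance * setup$wavelength /
    (setup$pixel_count * setup$pixel_pitch)
}

#' Object distance maximising lateral resolution
#'
#' Moving the object towards the detector improves the geometric resolution
#' but packs the interference fringes more densely; the pixel grid stops
#' resolving neighbouring fringes below a critical distance. The optimum is
#' s_opt = f / (1 + f * lambda / (N * p^2)).
#'
#' @param source_detector_distance Distance `f` \[m\].
#' @param wavelength Wavelength \[m\].
#' @param pixel_count Pixels per detector side `N`.
#' @param pixel_pitch Pixel pitch `p` \[m\].
#' @return Optimal object-to-detector distance \[m\], strictly in (0, f).
#' @export
optimal_object_distance <- function(source_detector_distance, wavelength,
                                    pixel_count, pixel_pitch) {
  if (source_detector_distance <= 0 || wavelength <= 0 ||
      pixel_count <= 0 || pixel_pitch <= 0)
    stopf("all arguments must be > 0")
  source_detector_distance /
    (1 + source_detector_distance * wavelength / (pixel_count * pixel_pitch^2))
}

#' Axial resolution of a DIHM recording
#'
#' delta_ax = lambda / (2 NA^2) = 2 s^2 lambda / (N p)^2.
#'
#' @inheritParams lateral_resolution
#' @return Axial resolution \[m\].
#' @export
axial_resolution <- function(setup) {
  stopifnot(inherits(setup, "optical_setup"))
  2 * setup$object_detector_distance^2 * setup$wavelength /
    (setup$pixel_count * setup$pixel_pitch)^2
}

#' Temporal coherence length of a Gaussian spectral line
#'
#' L_c = lambda^2 / (pi * delta_lambda) for a Gaussian intensity spectrum of
#' full-width-half-maximum `bandwidth`. A bandwidth of exactly 0 models an
#' ideal monochromatic source and returns `Inf` (documented sentinel rather
#' than an error: laser-like configurations are legitimate).
#'
#' @param wavelength Centre wavelength \[m\].
#' @param bandwidth FWHM spectral width \[m\], >= 0.
#' @return Coherence length \[m\]; `Inf` when `bandwidth == 0`.
#' @export
coherence_length <- function(wavelength, bandwidth) {
  if (wavelength <= 0) stopf("wavelength must be > 0")
  if (bandwidth < 0) stopf("bandwidth must be >= 0")
  if (bandwidth == 0) return(Inf)
  wavelength^2 / (pi * bandwidth)
}

#' Rayleigh length of a Gaussian beam
#'
#' z_r = pi * w0^2 / lambda, the distance over which the beam area doubles.
#'
#' @param beam A [gaussian_beam()].
#' @return Rayleigh length \[m\].
#' @export
rayleigh_length <- function(beam) {
  stopifnot(inherits(beam, "gaussian_beam"))
  pi * beam$waist_radius^2 / beam$wavelength
}

#' 1/e^2 intensity diameter of a Gaussian beam at distance z
#'
#' d(z) = 2 w0 sqrt(1 + (z / z_r)^2).
#'
#' @param beam A [gaussian_beam()].
#' @param z Propagation distance from the waist \[m\], >= 0.
#' @return Beam diameter \[m\].
#' @export
beam_diameter <- function(beam, z) {
  stopifnot(inherits(beam, "gaussian_beam"))
  if (any(z < 0)) stopf("z must be >= 0")
  zr <- rayleigh_length(beam)
  2 * beam$waist_radius * sqrt(1 + (z / zr)^2)
}

#' Tabulated design report for a DIHM geometry
#'
#' Collects the closed-form design quantities for one instrument: NA,
#' lateral and axial resolution, optimal object distance, coherence length,
#' fringe magnification, object-side field of view and (when a source
#' aperture is given) Gaussian-beam diameters at object and detector plane.
#'
#' The object-side field of view is the detector side length demagnified by
#' the fringe magnification M = f/(f-s): FOV = N p (f-s) / f.
#'
#' @param setup An [optical_setup()].
#' @return A `data.frame` with columns `quantity`, `value`, `unit`,
#'   `pretty`; class `design_report`.
#' @export
design_report <- function(setup) {
  stopifnot(inherits(setup, "optical_setup"))
  f <- setup$source_detector_distance
  s <- setup$object_detector_distance
  N <- setup$pixel_count
  p <- setup$pixel_pitch
  lam <- setup$wavelength
  na <- (N * p / 2) / s
  geo <- effective_geometry(setup)
  rows <- list(
    list("numerical_aperture", na, ""),
    list("lateral_resolution", lateral_resolution(setup), "m"),
    list("axial_resolution", axial_resolution(setup), "m"),
    list("optimal_object_distance", optimal_object_distance(f, lam, N, p), "m"),
    list("coherence_length", coherence_length(lam, setup$bandwidth), "m"),
    list("fringe_magnification", geo$magnification, ""),
    list("field_of_view", N * p * (f - s) / f, "m")
  )
  if (setup$source_aperture_diameter > 0) {
    beam <- gaussian_beam(setup$source_aperture_diameter / 2, lam)
    rows <- c(rows, list(
      list("rayleigh_length", rayleigh_length(beam), "m"),
      list("beam_diameter_object_plane", beam_diameter(beam, f - s), "m"),
      list("beam_diameter_detector_plane", beam_diameter(beam, f), "m")
    ))
  }
  out <- data.frame(quantity = vapply(rows, `[[`, "", 1),
                    value = vapply(rows, `[[`, 0, 2),
                    unit = vapply(rows, `[[`, "", 3),
                    stringsAsFactors = FALSE)
  out$pretty <- ifelse(out$unit == "m",
                       vapply(out$value, format_length, ""),
                       vapply(out$value, function(v) format(signif(v, 4)), ""))
  class(out) <- c("design_report", "data.frame")
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat("DIHM design report\n")
  w <- max(nchar(x$quantity))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-*s : %s\n", w, x$quantity[i], x$pretty[i]))
  invisible(x)
}
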