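#' Angular-spectrum transfer function
#'
#' Free-space propagation over a distance `z` multiplies the field's
#' Fourier transform by H(fx, fy) = exp(i z sqrt(k^2 - 4 pi^2 (fx^2 + fy^2)))
#' with k = 2 pi / lambda. Evanescent components, where the argument of the
#' square root is negative, are set to exactly 0: at the millimetre-scale
#' distances of inline holography they have decayed by many orders of
#' magnitude, and hard zeroing is numerically safe. On all propagating
#' components |H| = 1, so propagation is unitary.
#'
#' @param rows,cols Grid dimensions.
#' @param pitch Sample spacing \[m\].
#' @param wavelength Wavelength \[m\].
#' @param z Propagation distance \[m\]; any sign (negative back-propagates).
#' @return Complex `rows x cols` matrix in DFT frequency ordering.
#' @export
angular_spectrum_kernel <- function(rows, cols, pitch, wavelength, z) {
  if (pitch <= 0) stopf("pitch must be > 0")
  if (wavelength <= 0) stopf("wavelength must be > 0")
  k <- 2 * pi / wavelength
  fx <- fft_freq(cols, pitch)
  fy <- fft_freq(rows, pitch)
  arg <- k^2 - 4 * pi^2 * (outer(fy^2, fx^2, `+`))
  H <- matrix(0i, rows, cols)
  prop <- arg >= 0
  H[prop] <- exp(1i * z * sqrt(arg[prop]))
  H
}

#' Propagate a wave field through free space
#'
#' Computes the inverse Fourier transform of the field's Fourier transform
#' multiplied by the [angular_spectrum_kernel()]. Shape, pitch and
#' wavelength are preserved. Non-square grids (or grids with awkward prime
#' factors) are zero-padded to a square power-of-two size for the FFT and
#' cropped back.
#'
#' @param field A [wave_field()].
#' @param z Propagation distance \[m\] (negative to back-propagate).
#' @return A [wave_field()] at the new plane.
#' @export
propagate <- function(field, z) {
  stopifnot(inherits(field, "wave_field"))
  U <- field$amplitude
  nr <- nrow(U); nc <- ncol(U)
  n <- max(nr, nc)
  # mixed-radix FFTs stay fast for 5-smooth sizes; pad only when needed
  npad <- if (nr == nc && nr == nextn(nr, c(2, 3, 5))) nr
          else nextn(n, c(2, 3, 5))
  if (npad != nr || npad != nc) {
    P <- matrix(0i, npad, npad)
    r0 <- (npad - nr) %/% 2
    c0 <- (npad - nc) %/% 2
    P[r0 + seq_len(nr), c0 + seq_len(nc)] <- U
    H <- angular_spectrum_kernel(npad, npad, field$pixel_pitch, field$wavelength, z)
    V <- fft(fft(P) * H, inverse = TRUE) / (npad * npad)
    out <- V[r0 + seq_len(nr), c0 + seq_len(nc)]
  } else {
    H <- angular_spectrum_kernel(nr, nc, field$pixel_pitch, field$wavelength, z)
    out <- fft(fft(U) * H, inverse = TRUE) / (nr * nc)
  }
  wave_field(out, field$pixel_pitch, field$wavelength)
}

#' Background-subtract a hologram into a contrast field
#'
#' Reconstruction operates on the real-valued contrast hologram. With a
#' background recording the contrast is I - B, recentred to zero mean and
#' scaled to unit maximum absolute value; without one, the mean intensity is
#' removed (suppressing the zero-order term). Pitch and wavelength are taken
#' from the hologram's setup.
#'
#' @param holo A [hologram()].
#' @return A [wave_field()] holding the (real-valued) contrast.
#' @export
preprocess_hologram <- function(holo) {
  stopifnot(inherits(holo, "hologram"))
  I <- holo$intensity
  if (!is.null(holo$background)) {
    C <- I - holo$background
    C <- C - mean(C)
    m <- max(abs(C))
    if (m > 0) C <- C / m
  } else {
    C <- I - mean(I)
  }
  wave_field(C, holo$setup$pixel_pitch, holo$setup$wavelength)
}

#' Point-source to plane-wave equivalent geometry
#'
#' A hologram recorded with a point source at distance `f` and the object at
#' distance `s` from the detector is, to paraxial accuracy, identical to a
#' plane-wave hologram of the object magnified by M = f / (f - s) and
#' located at the effective distance z_eff = s (f - s) / f. Reconstructing
#' at z_eff with the pixel pitch divided by M therefore yields object-plane
#' coordinates directly.
#'
#' @param setup An [optical_setup()] (uses its `s` and `f`).
#' @return A list with elements `z_eff` \[m\] and `magnification`.
#' @export
effective_geometry <- function(setup) {
  stopifnot(inherits(setup, "optical_setup"))
  f <- setup$source_detector_distance
  s <- setup$object_detector_distance
  if (s >= f) stopf("object_detector_distance must be < source_detector_distance")
  list(z_eff = s * (f - s) / f, magnification = f / (f - s))
}

#' Reconstruct a hologram at one plane
#'
#' Back-propagates the background-subtracted contrast hologram by `z` and
#' returns amplitude, phase and intensity images. With
#' `use_effective_geometry = TRUE` the point-source recording is first
#' mapped to its plane-wave equivalent: back-propagation happens over
#' z_eff(z) = z (f - z) / f and the returned images sample the object plane
#' at pitch p / M(z) with M(z) = f / (f - z). With the flag off, plain
#' plane-wave back-propagation over `z` is performed, mirroring the common
#' practice of feeding acquisition distance, wavelength and image size to a
#' two-FFT reconstruction.
#'
#' @param holo A [hologram()].
#' @param z Reconstruction distance \[m\], > 0, measured from the detector
#'   towards the source.
#' @param use_effective_geometry Apply the point-source equivalence mapping.
#' @return A list of class `holo_recon`: `amplitude`, `phase`, `intensity`
#'   matrices plus `z` and the object-plane `pixel_pitch` of the images.
#' @export
reconstruct <- function(holo, z, use_effective_geometry = FALSE) {
  stopifnot(inherits(holo, "hologram"))
  if (z <= 0) stopf("reconstruction distance z must be > 0, got %g", z)
  field <- preprocess_hologram(holo)
  pitch_out <- field$pixel_pitch
  z_back <- z
  if (use_effective_geometry) {
    f <- holo$setup$source_detector_distance
    if (z >= f) stopf("z must be smaller than the source-detector distance f = %g", f)
    M <- f / (f - z)
    z_back <- z * (f - z) / f
    field$pixel_pitch <- field$pixel_pitch / M
    pitch_out <- pitch_out / M
  }
  U <- propagate(field, -z_back)$amplitude
  structure(list(amplitude = Mod(U), phase = Arg(U), intensity = Mod(U)^2,
                 z = z, pixel_pitch = pitch_out),
            class = "holo_recon")
}

#' @export
print.holo_recon <- function(x, ...) {
  cat(sprintf("<holo_recon> %d x %d at z = %s (object pitch %s)\n",
              nrow(x$amplitude), ncol(x$amplitude),
              format_length(x$z), format_length(x$pixel_pitch)))
  invisible(x)
}

#' Reconstruct a z-stack
#'
#' One [reconstruct()] per requested plane; all parameters identical apart
#' from the reconstruction distance. This is the numerical-refocusing use of
#' inline holography: a single exposure encodes a whole sample volume.
#'
#' @inheritParams reconstruct
#' @param z_values Strictly increasing reconstruction distances \[m\], all > 0.
#' @return An object of class `recon_stack`: list with `z` (vector) and
#'   `planes` (list of `holo_recon`).
#' @export
reconstruct_stack <- function(holo, z_values, use_effective_geometry = FALSE) {
  if (length(z_values) == 0) stopf("z_values must not be empty")
  if (any(z_values <= 0)) stopf("all z_values must be > 0")
  if (is.unsorted(z_values, strictly = TRUE)) stopf("z_values must be strictly increasing")
  planes <- lapply(z_values, function(z) reconstruct(holo, z, use_effective_geometry))
  structure(list(z = z_values, planes = planes), class = "recon_stack")
}

#' @export
print.recon_stack <- function(x, ...) {
  cat(sprintf("<recon_stack> %d planes, z in [%s, %s]\n", length(x$z),
              format_length(min(x$z)), format_length(max(x$z))))
  invisible(x)
}

#' Sharpness score of a reconstructed image
#'
#' Normalised intensity variance, var(x) / mean(x)^2: scale-invariant,
#' higher for sharper planes. Chosen as the autofocus criterion for its
#' robustness and cost; any metric with the same contract (replaceable:
#' Tamura coefficient, gradient energy) could be substituted.
#'
#' @param image Nonnegative real matrix (typically the amplitude image).
#' @return Scalar score; 0 for a constant image.
#' @export
focus_metric <- function(image) {
  if (length(image) == 0) stopf("image must be non-empty")
  m <- mean(image)
  if (m == 0 && all(image == 0)) stopf("focus_metric is undefined for an all-zero image")
  v <- mean((image - m)^2)
  v / m^2
}

#' Autofocus: find the sharpest reconstruction distance
#'
#' Evaluates [focus_metric()] on the amplitude image over a uniform grid of
#' `steps` distances in `[z_min, z_max]`, then refines the best grid point by
#' golden-section search in its bracketing interval. Deterministic. When the
#' best grid point lies on the search boundary a warning is emitted and the
#' boundary value returned (the true focus likely lies outside the window).
#'
#' @inheritParams reconstruct
#' @param z_min,z_max Search window \[m\], 0 < z_min < z_max.
#' @param steps Number of coarse grid points, >= 3.
#' @param tol Absolute tolerance of the golden-section refinement \[m\];
#'   defaults to 1e-3 of the coarse step.
#' @return Best reconstruction distance \[m\].
#' @export
autofocus <- function(holo, z_min, z_max, steps = 25,
                      use_effective_geometry = FALSE, tol = NULL) {
  if (!(0 < z_min && z_min < z_max)) stopf("need 0 < z_min < z_max")
  steps <- as.integer(steps)
  if (steps < 3L) stopf("steps must be >= 3")
  zs <- seq(z_min, z_max, length.out = steps)
  score <- function(z) focus_metric(reconstruct(holo, z, use_effective_geometry)$amplitude)
  vals <- vapply(zs, score, 0)
  i <- which.max(vals)
  if (i == 1L || i == steps) {
    warning(sprintf("focus metric maximal at search boundary z = %s; true focus may lie outside [%s, %s]",
                    format_length(zs[i]), format_length(z_min), format_length(z_max)))
    return(zs[i])
  }
  a <- zs[i - 1L]; b <- zs[i + 1L]
  if (is.null(tol)) tol <- (zs[2] - zs[1]) * 1e-3
  golden_section_max(score, a, b, tol)
}

# Golden-section maximisation of f on [a, b]; deterministic.
golden_section_max <- function(f, a, b, tol) {
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a)
  d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while ((b - a) > tol) {
    if (fc >= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  (a + b) / 2
}
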