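#' Micro-object in a synthetic scene
#'
#' Three object classes cover the samples typically imaged by a lens-less
#' inline microscope: `opaque_disk` (absorbing micro-sphere projection, e.g.
#' a 6.5 um polystyrene bead), `phase_sphere` (weakly refracting cell model:
#' the projected thickness of a sphere of uniform refractive-index contrast)
#' and `bar_target` (a five-bar resolution-chart element).
#'
#' @param kind One of `"opaque_disk"`, `"phase_sphere"`, `"bar_target"`.
#' @param x,y Centre position in the object plane \[m\], origin on the
#'   optical axis.
#' @param z Depth: distance from the detector plane \[m\].
#' @param radius Disk/sphere radius \[m\] (disk and sphere kinds).
#' @param line_width Bar width \[m\] (`bar_target` only).
#' @param amplitude_transmittance Amplitude transmission inside the object,
#'   in \[0, 1\] (0 = fully opaque). Default 0 for disks and bars, 1 for
#'   phase spheres.
#' @param dn Refractive-index contrast of a `phase_sphere` (dimensionless).
#' @param orientation Bar orientation for `bar_target`: `"vertical"` bars
#'   modulate along x, `"horizontal"` bars along y.
#' @param n_bars Number of dark bars in a `bar_target` (default 5, matching
#'   the contrast-analysis convention of 4 contrast values per element).
#' @return An object of class `scene_object`.
#' @export
scene_object <- function(kind = c("opaque_disk", "phase_sphere", "bar_target"),
                         x = 0, y = 0, z, radius = NULL, line_width = NULL,
                         amplitude_transmittance = NULL, dn = 0.06,
                         orientation = c("vertical", "horizontal"), n_bars = 5L) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (z <= 0) stopf("object depth z must be > 0 (distance from detector)")
  if (is.null(amplitude_transmittance))
    amplitude_transmittance <- if (kind == "phase_sphere") 1 else 0
  if (amplitude_transmittance < 0 || amplitude_transmittance > 1)
    stopf("amplitude_transmittance must lie in [0, 1]")
  if (kind %in% c("opaque_disk", "phase_sphere")) {
    if (is.null(radius) || radius <= 0) stopf("%s requires radius > 0", kind)
  } else {
    if (is.null(line_width) || line_width <= 0) stopf("bar_target requires line_width > 0")
  }
  structure(list(kind = kind, x = x, y = y, z = z, radius = radius,
                 line_width = line_width,
                 amplitude_transmittance = amplitude_transmittance,
                 dn = dn, orientation = orientation, n_bars = as.integer(n_bars)),
            class = "scene_object")
}

#' Scene: objects plus the instrument that images them
#'
#' Object depths must lie strictly between detector (0) and source (`f`).
#' Overlapping objects within one plane are legal but warned about.
#'
#' @param objects List of [scene_object()]s (possibly empty).
#' @param setup The [optical_setup()] used to image the scene.
#' @return An object of class `scene`.
#' @export
scene <- function(objects, setup) {
  stopifnot(inherits(setup, "optical_setup"))
  if (inherits(objects, "scene_object")) objects <- list(objects)
  ok <- vapply(objects, inherits, TRUE, what = "scene_object")
  if (!all(ok)) stopf("objects must all be scene_object")
  f <- setup$source_detector_distance
  for (ob in objects)
    if (ob$z >= f)
      stopf("object depth z = %g not in (0, f = %g)", ob$z, f)
  # same-plane overlap check (circles only; bars are laid out by the generator)
  if (length(objects) > 1) {
    for (i in seq_along(objects)) for (j in seq_len(i - 1L)) {
      a <- objects[[i]]; b <- objects[[j]]
      if (a$z == b$z && !is.null(a$radius) && !is.null(b$radius)) {
        if (sqrt((a$x - b$x)^2 + (a$y - b$y)^2) < a$radius + b$radius)
          warning("scene objects overlap within one plane")
      }
    }
  }
  structure(list(objects = objects, setup = setup), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d object(s)\n", length(x$objects)))
  for (ob in x$objects)
    cat(sprintf("  %s at (%s, %s), z = %s\n", ob$kind,
                format_length(ob$x), format_length(ob$y), format_length(ob$z)))
  invisible(x)
}

#' Detector noise model
#'
#' Photon shot noise (Poisson at a stated mean photon count per pixel at
#' unit intensity) followed by uniform quantisation to a bit depth. `NULL`
#' entries disable the respective stage; the seed is mandatory whenever the
#' Poisson stage is active so that every noisy hologram is reproducible.
#'
#' @param photons_per_pixel Expected photon count at unit intensity (> 0),
#'   or `NULL` for no shot noise.
#' @param bit_depth 8, 10 or 16, or `NULL` for no quantisation.
#' @param seed Integer RNG seed (required with `photons_per_pixel`).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photons_per_pixel = NULL, bit_depth = NULL, seed = NULL) {
  if (!is.null(photons_per_pixel)) {
    if (photons_per_pixel <= 0) stopf("photons_per_pixel must be > 0")
    if (is.null(seed)) stopf("a seed is required for a stochastic noise model")
  }
  if (!is.null(bit_depth) && !bit_depth %in% c(8, 10, 16))
    stopf("bit_depth must be one of 8, 10, 16")
  structure(list(photons_per_pixel = photons_per_pixel,
                 bit_depth = bit_depth, seed = seed),
            class = "noise_model")
}

#' Complex transmission map of one scene plane
#'
#' Multiplies the transmission functions of all objects whose depth equals
#' `z_plane`: an opaque disk transmits `amplitude_transmittance` inside its
#' radius and 1 outside; a phase sphere adds the phase k * dn * thickness
#' with thickness 2 sqrt(r^2 - rho^2) (projected chord of the sphere); a bar
#' target is `n_bars` dark bars of the given width, spaced one width apart,
#' with bar length five times the width. An empty plane is all ones.
#'
#' @param sc A [scene()].
#' @param z_plane Depth of the plane to render \[m\].
#' @param rows,cols Grid dimensions.
#' @param pitch Sample spacing \[m\].
#' @return Complex `rows x cols` matrix.
#' @export
transmission_map <- function(sc, z_plane, rows, cols, pitch) {
  stopifnot(inherits(sc, "scene"))
  if (rows < 2 || cols < 2 || pitch <= 0) stopf("invalid grid")
  xs <- grid_coords(cols, pitch)
  ys <- grid_coords(rows, pitch)
  t_map <- matrix(1 + 0i, rows, cols)
  k <- 2 * pi / sc$setup$wavelength
  for (ob in sc$objects) {
    if (ob$z != z_plane) next
    if (ob$kind %in% c("opaque_disk", "phase_sphere")) {
      rho2 <- outer((ys - ob$y)^2, (xs - ob$x)^2, `+`)
      inside <- rho2 <= ob$radius^2
      t_ob <- matrix(1 + 0i, rows, cols)
      if (ob$kind == "opaque_disk") {
        t_ob[inside] <- ob$amplitude_transmittance
      } else {
        thick <- 2 * sqrt(pmax(ob$radius^2 - rho2[inside], 0))
        t_ob[inside] <- ob$amplitude_transmittance * exp(1i * k * ob$dn * thick)
      }
    } else {
      t_ob <- bar_patch(ob, xs, ys)
    }
    t_map <- t_map * t_ob
  }
  t_map
}

# Render one five-bar element: n_bars dark bars of width w at period 2w,
# bar length 5w, centred on (x, y); vertical bars modulate along x.
bar_patch <- function(ob, xs, ys) {
  w <- ob$line_width
  n <- ob$n_bars
  span <- (2 * n - 1) * w            # first bar edge to last bar edge
  len <- 5 * w
  if (ob$orientation == "vertical") { u <- xs - ob$x; v <- ys - ob$y }
  else                              { u <- ys - ob$y; v <- xs - ob$x }
  du <- u + span / 2                 # 0 at leading bar edge
  in_bar <- du >= 0 & du < span & (floor(du / w) %% 2 == 0)
  in_len <- abs(v) <= len / 2
  if (ob$orientation == "vertical") {
    dark <- outer(in_len, in_bar, `&`)   # rows = y (v), cols = x (u)
  } else {
    dark <- outer(in_bar, in_len, `&`)
  }
  t_ob <- matrix(1 + 0i, length(ys), length(xs))
  t_ob[dark] <- ob$amplitude_transmittance
  t_ob
}

#' Paraxial spherical illumination wave
#'
#' The diverging wave of a point source at distance `d = f - z_plane` from
#' the requested plane: amplitude f/d (so the detector-plane amplitude is
#' 1), phase k (d + rho^2 / (2 d)) in paraxial approximation. With
#' `type = "plane"` a unit plane wave is returned instead. `source_offset`
#' shifts the source laterally (used for partial spatial coherence).
#'
#' @param setup An [optical_setup()].
#' @param rows,cols Grid dimensions.
#' @param pitch Sample spacing \[m\].
#' @param z_plane Plane depth (distance from detector) \[m\], in \[0, f).
#' @param type `"point"` (default) or `"plane"`.
#' @param source_offset Length-2 vector (x, y) of the source position \[m\].
#' @param wavelength Optional wavelength override \[m\] (defaults to the
#'   setup's; used when averaging over a spectral line).
#' @return A [wave_field()].
#' @export
spherical_illumination <- function(setup, rows, cols, pitch, z_plane,
                                   type = c("point", "plane"),
                                   source_offset = c(0, 0), wavelength = NULL) {
  stopifnot(inherits(setup, "optical_setup"))
  type <- match.arg(type)
  lam <- if (is.null(wavelength)) setup$wavelength else wavelength
  if (type == "plane")
    return(wave_field(matrix(1 + 0i, rows, cols), pitch, lam))
  f <- setup$source_detector_distance
  if (z_plane < 0 || z_plane >= f) stopf("z_plane must lie in [0, f)")
  d <- f - z_plane
  k <- 2 * pi / lam
  xs <- grid_coords(cols, pitch) - source_offset[1]
  ys <- grid_coords(rows, pitch) - source_offset[2]
  rho2 <- outer(ys^2, xs^2, `+`)
  U <- (f / d) * exp(1i * (k * d + k * rho2 / (2 * d)))
  wave_field(U, pitch, lam)
}

#' Simulate the hologram of a scene
#'
#' Thin-object cascade forward model: the illumination wave is evaluated at
#' the plane farthest from the detector, multiplied by that plane's
#' transmission map, angular-spectrum propagated to the next occupied plane,
#' and so on down to the detector, where the intensity |U|^2 is recorded.
#' The matching object-free background hologram (same illumination, unit
#' transmission) is propagated through the same FFT pipeline so that
#' background subtraction cancels common numerical edge effects exactly.
#'
#' @param sc A [scene()].
#' @param rows,cols Detector grid dimensions (pitch taken from the setup).
#' @param illumination `"point"` or `"plane"`.
#' @param noise Optional [noise_model()] applied to the object hologram.
#' @param source_offset,wavelength Passed to [spherical_illumination()].
#' @param pad_factor Numeric >= 1. With 1 (default) the simulation grid is
#'   the detector grid and the FFT's periodic boundary lets diffraction
#'   orders that would leave the detector wrap back in. A larger factor
#'   simulates on a grid that much larger and crops the central detector
#'   region, so light diffracted beyond the camera aperture is genuinely
#'   lost -- the mechanism behind the pixel-limited resolution bound.
#' @return A [hologram()] carrying its background.
#' @export
simulate_hologram <- function(sc, rows, cols, illumination = c("point", "plane"),
                              noise = NULL, source_offset = c(0, 0),
                              wavelength = NULL, pad_factor = 1L) {
  stopifnot(inherits(sc, "scene"))
  illumination <- match.arg(illumination)
  if (pad_factor < 1) stopf("pad_factor must be >= 1")
  setup <- sc$setup
  pitch <- setup$pixel_pitch
  lam <- if (is.null(wavelength)) setup$wavelength else wavelength
  rs <- 2L * ceiling(rows * pad_factor / 2)
  cs <- 2L * ceiling(cols * pad_factor / 2)
  depths <- sort(unique(vapply(sc$objects, `[[`, 0, "z")), decreasing = TRUE)
  z0 <- if (length(depths)) depths[1] else 0
  U <- spherical_illumination(setup, rs, cs, pitch, z0,
                              type = illumination,
                              source_offset = source_offset, wavelength = lam)
  B <- U
  if (length(depths)) {
    zs <- c(depths, 0)
    for (j in seq_along(depths)) {
      t_map <- transmission_map(sc, depths[j], rs, cs, pitch)
      U <- wave_field(U$amplitude * t_map, pitch, lam)
      dz <- zs[j] - zs[j + 1]
      U <- propagate(U, dz)
      B <- propagate(B, dz)
    }
  }
  crop <- function(m) {
    r0 <- (rs - rows) %/% 2
    c0 <- (cs - cols) %/% 2
    m[r0 + seq_len(rows), c0 + seq_len(cols), drop = FALSE]
  }
  Uc <- crop(U$amplitude)
  Bc <- crop(B$amplitude)
  h <- hologram(Mod(Uc)^2, setup, background = Mod(Bc)^2)
  # complex detector fields (object run and reference run); their difference
  # is the object-scattered wave, free of aperture-truncation artifacts
  attr(h, "field") <- Uc
  attr(h, "background_field") <- Bc
  if (!is.null(noise)) h <- add_noise(h, noise)
  h
}

#' Direct Fresnel-Kirchhoff double-sum reference
#'
#' Brute-force discretisation of the forward diffraction integral with
#' exact (non-paraxial) point-to-point distances:
#' U(X, Y) = -(i / lambda) * sum over object pixels of
#' U_in t exp(i k |r - R|) / |r - R| * pitch^2. Quadratic cost; grids are
#' limited to `max_side` per side. Serves as the independent oracle for the
#' FFT forward model and is never used in the production path.
#'
#' @param sc A [scene()] whose objects all share one depth (or empty).
#' @param rows,cols Grid dimensions, each <= `max_side`.
#' @param pitch Sample spacing \[m\].
#' @param illumination `"point"` (exact spherical wave from the on-axis
#'   source) or `"plane"`.
#' @param z_plane Object-plane depth \[m\]; defaults to the scene's single
#'   object depth (required for an empty scene).
#' @param max_side Refusal limit for the grid side (default 64).
#' @return A [hologram()] carrying its background.
#' @export
direct_integral_oracle <- function(sc, rows, cols, pitch,
                                   illumination = c("point", "plane"),
                                   z_plane = NULL, max_side = 64L) {
  stopifnot(inherits(sc, "scene"))
  illumination <- match.arg(illumination)
  if (rows > max_side || cols > max_side)
    stopf("direct_integral_oracle refuses grids larger than %d per side (got %dx%d)",
          max_side, rows, cols)
  depths <- unique(vapply(sc$objects, `[[`, 0, "z"))
  if (length(depths) > 1) stopf("the oracle supports single-plane scenes only")
  if (is.null(z_plane)) {
    if (length(depths) == 0) stopf("z_plane is required for an empty scene")
    z_plane <- depths[1]
  }
  setup <- sc$setup
  lam <- setup$wavelength
  k <- 2 * pi / lam
  f <- setup$source_detector_distance
  xs <- grid_coords(cols, pitch)
  ys <- grid_coords(rows, pitch)
  xo <- rep(xs, each = rows)    # object-plane pixels, column-major flatten
  yo <- rep(ys, times = cols)
  if (illumination == "point") {
    Rs <- sqrt(xo^2 + yo^2 + (f - z_plane)^2)   # exact source distance
    U_in <- (f / Rs) * exp(1i * k * Rs)
  } else {
    U_in <- rep(1 + 0i, rows * cols)
  }
  t_obj <- as.vector(transmission_map(sc, z_plane, rows, cols, pitch))
  field_obj <- U_in * t_obj
  field_bg <- U_in
  sum_rows <- function(fo) {
    out <- matrix(0i, rows, cols)
    for (i in seq_len(rows)) {
      dy2 <- (ys[i] - yo)^2
      dx2 <- outer(xs, xo, function(X, x) (X - x)^2)   # cols x n_obj
      rho <- sqrt(sweep(dx2, 2, dy2 + z_plane^2, `+`))
      out[i, ] <- (exp(1i * k * rho) / rho) %*% fo
    }
    -(1i / lam) * out * pitch^2
  }
  U_det <- sum_rows(field_obj)
  B_det <- sum_rows(field_bg)
  h <- hologram(Mod(U_det)^2, setup, background = Mod(B_det)^2)
  attr(h, "field") <- U_det
  attr(h, "background_field") <- B_det
  h
}

#' Partially coherent hologram by incoherent averaging
#'
#' Models finite spectral bandwidth and finite source size by averaging
#' intensity holograms over (i) Gauss-Hermite nodes of the Gaussian
#' spectral line of FWHM `bandwidth` and (ii) a deterministic sunflower
#' sampling of the uniform source disk of the given diameter, each sample
#' offsetting the illumination origin. With one wavelength node and zero
#' source diameter the result reduces exactly to the coherent hologram.
#'
#' For a single-depth scene the paraxial forward model obeys an exact
#' shift identity: moving the point source laterally by xi rigidly shifts
#' the detector intensity by -xi z / (f - z). The source average is then
#' computed as one forward simulation per wavelength followed by Fourier
#' subpixel shifts of its intensity, which is mathematically identical to
#' re-simulating each source point and substantially cheaper. Multi-depth
#' scenes (where each plane shifts differently) fall back to one full
#' simulation per (wavelength, source point) pair.
#'
#' @param sc A [scene()].
#' @param rows,cols Detector grid dimensions.
#' @param bandwidth FWHM spectral width \[m\] (0 = monochromatic).
#' @param source_diameter Source aperture diameter \[m\] (0 = point).
#' @param n_wavelengths Number of spectral quadrature nodes (>= 1).
#' @param n_source_points Number of source-disk sample points (>= 1).
#' @param noise Optional [noise_model()] applied to the averaged hologram.
#' @param seed Optional seed forwarded to the noise stage.
#' @param pad_factor Passed to [simulate_hologram()].
#' @return A [hologram()] carrying its averaged background.
#' @export
apply_partial_coherence <- function(sc, rows, cols,
                                    bandwidth = sc$setup$bandwidth,
                                    source_diameter = sc$setup$source_aperture_diameter,
                                    n_wavelengths = 7L, n_source_points = 13L,
                                    noise = NULL, seed = NULL, pad_factor = 1L) {
  stopifnot(inherits(sc, "scene"))
  if (n_wavelengths < 1 || n_source_points < 1) stopf("sample counts must be >= 1")
  lam0 <- sc$setup$wavelength
  if (bandwidth > 0 && n_wavelengths > 1) {
    gh <- gauss_hermite(n_wavelengths)
    sigma <- bandwidth / (2 * sqrt(2 * log(2)))   # FWHM -> sd of the Gaussian line
    lams <- lam0 + sqrt(2) * sigma * gh$nodes
    wl <- gh$weights / sqrt(pi)                   # normalised Gaussian weights
  } else {
    lams <- lam0
    wl <- 1
  }
  pts <- disk_points(n_source_points, source_diameter / 2)
  depths <- unique(vapply(sc$objects, `[[`, 0, "z"))
  single_plane <- length(depths) <= 1
  I <- matrix(0, rows, cols)
  B <- matrix(0, rows, cols)
  for (a in seq_along(lams)) {
    if (single_plane && nrow(pts) > 1) {
      h <- simulate_hologram(sc, rows, cols, illumination = "point",
                             wavelength = lams[a], pad_factor = pad_factor)
      z <- if (length(depths)) depths[1] else 0
      f <- sc$setup$source_detector_distance
      p <- sc$setup$pixel_pitch
      for (j in seq_len(nrow(pts))) {
        sh <- -pts[j, ] * z / (f - z) / p       # detector shift in pixels
        w <- wl[a] / nrow(pts)
        I <- I + w * fft_shift(h$intensity, sh[1], sh[2])
        B <- B + w * fft_shift(h$background, sh[1], sh[2])
      }
    } else {
      for (j in seq_len(nrow(pts))) {
        h <- simulate_hologram(sc, rows, cols, illumination = "point",
                               source_offset = c(pts[j, 1], pts[j, 2]),
                               wavelength = lams[a], pad_factor = pad_factor)
        w <- wl[a] / nrow(pts)
        I <- I + w * h$intensity
        B <- B + w * h$background
      }
    }
  }
  I[I < 0] <- 0                                 # interpolation undershoot
  B[B < 0] <- 0
  h <- hologram(I, sc$setup, background = B)
  if (!is.null(noise)) {
    if (!is.null(seed) && is.null(noise$seed)) noise$seed <- seed
    h <- add_noise(h, noise)
  }
  h
}

# Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) by
# Golub-Welsch: eigen-decomposition of the symmetric Jacobi matrix.
gauss_hermite <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# Subpixel image translation by (dx, dy) pixels (x = columns, y = rows)
# via a Fourier-domain phase ramp; real output.
fft_shift <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  fr <- fft_freq(nrow(img), 1)
  fc <- fft_freq(ncol(img), 1)
  ramp <- exp(-2i * pi * outer(fr * dy, fc * dx, `+`))
  Re(fft(fft(img) * ramp, inverse = TRUE)) / length(img)
}

# Deterministic quasi-uniform sampling of a disk of radius R ("sunflower"
# / golden-angle spiral); n = 1 returns the centre point.
disk_points <- function(n, R) {
  n <- as.integer(n)
  if (n == 1L || R <= 0) return(matrix(0, max(n, 1L), 2))
  k <- seq_len(n)
  r <- R * sqrt((k - 0.5) / n)
  th <- k * pi * (3 - sqrt(5))
  cbind(r * cos(th), r * sin(th))
}

#' Apply a detector noise model to a hologram
#'
#' Poisson shot noise at the stated photon scale (intensity x
#' `photons_per_pixel` expected counts, sampled and rescaled back), then
#' uniform quantisation of \[0, max\] to `2^bit_depth` levels. Deterministic
#' per seed; the global RNG state is left untouched.
#'
#' @param holo A [hologram()].
#' @param noise A [noise_model()] (a model with both stages `NULL` is the
#'   identity).
#' @return A [hologram()] with degraded intensity (background unchanged).
#' @export
add_noise <- function(holo, noise) {
  stopifnot(inherits(holo, "hologram"), inherits(noise, "noise_model"))
  I <- holo$intensity
  if (!is.null(noise$photons_per_pixel)) {
    if (is.null(noise$seed)) stopf("a seed is required for a stochastic noise model")
    ppp <- noise$photons_per_pixel
    I <- with_seed(noise$seed, {
      counts <- rpois(length(I), lambda = as.vector(I) * ppp)
      matrix(counts / ppp, nrow(I), ncol(I))
    })
  }
  if (!is.null(noise$bit_depth)) {
    levels <- 2^noise$bit_depth - 1
    top <- max(I)
    if (top > 0) I <- round(I / top * levels) / levels * top
  }
  hologram(I, holo$setup, background = holo$background)
}
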