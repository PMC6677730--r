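# Bench instrument geometries: 405 nm Blu-ray laser-diode arm and 430 nm
# LED arm, 2464-pixel camera side at 1.12 um pitch, source at 30 mm,
# object slide at 5.91 mm.
ld_bench <- function() {
  optical_setup(405e-9, 30e-3, 5.91e-3, 2464L, 1.12e-6,
                bandwidth = 0, source_aperture_diameter = 3.3e-6)
}
led_bench <- function() {
  optical_setup(430e-9, 30e-3, 5.91e-3, 2464L, 1.12e-6,
                bandwidth = 15e-9, source_aperture_diameter = 15e-6)
}

# smooth band-limited complex field (Gaussian envelope, mild phase)
smooth_field <- function(n = 128, pitch = 1.12e-6, lam = 405e-9,
                         width = 15e-6) {
  xs <- holokit:::grid_coords(n, pitch)
  env <- exp(-outer(xs^2, xs^2, `+`) / (2 * width^2))
  wave_field(env * exp(0.4i), pitch, lam)
}

# Independent brute-force Rayleigh-Sommerfeld sum over a sampled field
# (oracle for propagate(); kept deliberately separate from the package's
# scene-based direct_integral_oracle code path).
rs_field_sum <- function(U, pitch, lam, z) {
  n_r <- nrow(U); n_c <- ncol(U)
  xs <- holokit:::grid_coords(n_c, pitch)
  ys <- holokit:::grid_coords(n_r, pitch)
  k <- 2 * pi / lam
  xo <- rep(xs, each = n_r)
  yo <- rep(ys, times = n_c)
  fo <- as.vector(U)
  out <- matrix(0i, n_r, n_c)
  for (i in seq_len(n_r)) {
    dy2 <- (ys[i] - yo)^2
    dx2 <- outer(xs, xo, function(X, x) (X - x)^2)
    rho <- sqrt(sweep(dx2, 2, dy2 + z^2, `+`))
    out[i, ] <- (exp(1i * k * rho) / rho) %*% fo
  }
  -(1i / lam) * out * pitch^2
}

# single-object recovery scene used by the parameter-recovery fixture
# suite: polystyrene-microsphere-like disks and red-blood-cell-like phase
# spheres at the paper's sizes, random depth and lateral position
recovery_scene <- function(seed, kind = c("opaque_disk", "phase_sphere"),
                           n = 256L) {
  kind <- match.arg(kind)
  arm <- fixture_setup("ld", pixel_count = n)
  withr::with_seed(seed, {
    z <- runif(1, 1.2e-3, 2.0e-3)
    r <- if (kind == "opaque_disk") 3.25e-6 * runif(1, 0.95, 1.05)
         else 4e-6 * runif(1, 0.9, 1.1)
    x <- runif(1, -30, 30) * 1.12e-6
    y <- runif(1, -30, 30) * 1.12e-6
    ob <- if (kind == "opaque_disk")
      scene_object(kind, x, y, z = z, radius = r, amplitude_transmittance = 0.1)
    else
      scene_object(kind, x, y, z = z, radius = r, dn = 0.06)
    list(scene = scene(ob, arm), x = x, y = y, z = z, r = r, kind = kind,
         setup = arm)
  })
}
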