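test_that("angular-spectrum kernel: identity, on-axis phase, unitarity, evanescence", {
  n <- 32L; pitch <- 1.12e-6; lam <- 405e-9
  H0 <- angular_spectrum_kernel(n, n, pitch, lam, 0)
  prop <- H0 != 0
  expect_true(all(H0[prop] == 1 + 0i))
  z <- 3.7e-4
  H <- angular_spectrum_kernel(n, n, pitch, lam, z)
  expect_equal(H[1, 1], exp(1i * 2 * pi / lam * z))
  Hm <- angular_spectrum_kernel(n, n, pitch, lam, -z)
  expect_equal(Mod(H[prop]), rep(1, sum(prop)), tolerance = 1e-12)
  expect_equal((H * Hm)[prop], rep(1 + 0i, sum(prop)), tolerance = 1e-12)
  # sampling finer than half the wavelength creates evanescent components
  He <- angular_spectrum_kernel(64, 64, 0.15e-6, lam, z)
  expect_true(any(He == 0))
  expect_error(angular_spectrum_kernel(32, 32, -1e-6, lam, z), "pitch")
})

test_that("propagation conserves energy and inverts exactly on smooth fields", {
  U <- smooth_field(128)
  z <- 5e-4
  Uz <- propagate(U, z)
  e0 <- sum(Mod(U$amplitude)^2)
  expect_lt(abs(sum(Mod(Uz$amplitude)^2) - e0) / e0, 1e-9)
  back <- propagate(Uz, -z)
  expect_lt(max(abs(back$amplitude - U$amplitude)), 1e-9)
  zero <- wave_field(matrix(0i, 32, 32), 1.12e-6, 405e-9)
  expect_true(all(propagate(zero, z)$amplitude == 0))
})

test_that("FFT propagation of a subresolution spot matches the direct diffraction sum", {
  n <- 64L; pitch <- 1.12e-6; lam <- 405e-9; z <- 200 * pitch
  xs <- holokit:::grid_coords(n, pitch)
  g <- exp(-outer(xs^2, xs^2, `+`) / (2 * (1 * pitch)^2))   # ~1 px spot
  I_fft <- Mod(propagate(wave_field(g + 0i, pitch, lam), z)$amplitude)^2
  I_ref <- Mod(rs_field_sum(g + 0i, pitch, lam, z))^2
  cen <- (n / 4 + 1):(3 * n / 4)
  rel <- sqrt(mean((I_fft[cen, cen] - I_ref[cen, cen])^2)) /
    sqrt(mean(I_ref[cen, cen]^2))
  expect_lt(rel, 0.01)
})

test_that("preprocessing: background subtraction and mean removal", {
  setup <- fixture_setup("ld")
  I <- matrix(runif(64^2, 0.4, 0.6), 64)
  h_same <- hologram(I, setup, background = I)
  expect_true(all(preprocess_hologram(h_same)$amplitude == 0))
  h_const <- hologram(matrix(0.5, 64, 64), setup)
  expect_true(all(preprocess_hologram(h_const)$amplitude == 0))
  expect_error(hologram(I, setup, background = matrix(0.5, 32, 32)), "shape")
  # with a background, contrast is zero-mean and unit-max
  B <- matrix(0.5, 64, 64)
  hp <- preprocess_hologram(hologram(I, setup, background = B))
  C <- Re(hp$amplitude)
  expect_equal(mean(C), 0, tolerance = 1e-12)
  expect_equal(max(abs(C)), 1, tolerance = 1e-12)
})

test_that("preprocessed disk hologram carries the oracle's fringe spectrum", {
  pitch <- 1.12e-6
  setup <- optical_setup(405e-9, 30e-3, 5e-3, 64L, pitch)
  z <- 200 * pitch
  sc <- scene(scene_object("opaque_disk", 0, 0, z = z, radius = 4 * pitch,
                           amplitude_transmittance = 0), setup)
  h_fft <- simulate_hologram(sc, 64, 64)
  h_orc <- direct_integral_oracle(sc, 64, 64, pitch)
  spec_of <- function(h) Mod(fft(Re(preprocess_hologram(h)$amplitude)))^2
  s_f <- spec_of(h_fft); s_o <- spec_of(h_orc)
  s_f[1, 1] <- 0; s_o[1, 1] <- 0          # ignore residual DC
  # the energy-dominant fringe bins of the two spectra coincide (the
  # near-radial pattern makes the single argmax bin degenerate)
  top_f <- order(s_f, decreasing = TRUE)[1:40]
  top_o <- order(s_o, decreasing = TRUE)[1:40]
  expect_gt(length(intersect(top_f, top_o)) / 40, 0.7)
})

test_that("effective point-source geometry: values and limits", {
  geo <- effective_geometry(ld_bench())
  expect_equal(geo$magnification, 1.24533001245, tolerance = 1e-10)
  expect_equal(geo$z_eff, 4.74573e-3, tolerance = 1e-8)
  near <- optical_setup(405e-9, 30e-3, 1e-6, 64L, 1.12e-6)
  g2 <- effective_geometry(near)
  expect_equal(g2$magnification, 1, tolerance = 1e-4)
  expect_equal(g2$z_eff, 1e-6, tolerance = 1e-4)
  mid <- optical_setup(405e-9, 30e-3, 15e-3, 64L, 1.12e-6)
  g3 <- effective_geometry(mid)
  expect_equal(g3$magnification, 2)
  expect_equal(g3$z_eff, 30e-3 / 4)
})

test_that("reconstruction recovers a simulated disk in place", {
  n <- 128L
  arm <- fixture_setup("ld", pixel_count = n)
  z <- 1.5e-3; r <- 3.25e-6; x0 <- 8 * 1.12e-6; y0 <- -5 * 1.12e-6
  sc <- scene(scene_object("opaque_disk", x0, y0, z = z, radius = r,
                           amplitude_transmittance = 0.1), arm)
  h <- simulate_hologram(sc, n, n)
  rec <- reconstruct(h, z, use_effective_geometry = TRUE)
  expect_true(all(is.finite(rec$amplitude)) && all(rec$amplitude >= 0))
  dev <- abs(rec$amplitude - median(rec$amplitude))
  mask <- dev > 0.3 * max(dev)
  idx <- which(mask, arr.ind = TRUE)
  w <- dev[mask]
  xs <- holokit:::grid_coords(n, rec$pixel_pitch)
  cx <- sum(xs[idx[, 2]] * w) / sum(w)
  cy <- sum(xs[idx[, 1]] * w) / sum(w)
  expect_lt(abs(cx - x0), rec$pixel_pitch)
  expect_lt(abs(cy - y0), rec$pixel_pitch)
  d <- sqrt((xs[idx[, 2]] - cx)^2 + (xs[idx[, 1]] - cy)^2)
  expect_lt(abs(quantile(d, 0.99, names = FALSE) - r), rec$pixel_pitch)
  expect_error(reconstruct(h, -1e-3), "z")
  expect_error(reconstruct(h, 0), "z")
})

test_that("z-stacks preserve shape and agree with single reconstructions", {
  n <- 64L
  arm <- fixture_setup("ld", pixel_count = n)
  sc <- scene(scene_object("opaque_disk", 0, 0, z = 1.5e-3, radius = 4e-6,
                           amplitude_transmittance = 0), arm)
  h <- simulate_hologram(sc, n, n)
  zs <- seq(1e-3, 2e-3, length.out = 10)
  st <- reconstruct_stack(h, zs)
  expect_length(st$planes, 10)
  expect_true(all(vapply(st$planes, function(p) all(dim(p$amplitude) == n), TRUE)))
  one <- reconstruct_stack(h, 1.5e-3)
  expect_equal(one$planes[[1]]$amplitude, reconstruct(h, 1.5e-3)$amplitude)
  expect_error(reconstruct_stack(h, numeric(0)), "empty")
  expect_error(reconstruct_stack(h, c(2e-3, 1e-3)), "increasing")
})

test_that("a two-depth scene refocuses at both true depths", {
  n <- 256L
  arm <- fixture_setup("ld", pixel_count = n)
  z1 <- 1.2e-3; z2 <- 1.9e-3
  sc <- scene(list(
    scene_object("opaque_disk", -30e-6, 0, z = z1, radius = 4e-6,
                 amplitude_transmittance = 0),
    scene_object("opaque_disk", 35e-6, 10e-6, z = z2, radius = 5e-6,
                 amplitude_transmittance = 0)), arm)
  h <- simulate_hologram(sc, n, n)
  zs <- seq(1.0e-3, 2.2e-3, length.out = 25)
  st <- reconstruct_stack(h, zs, use_effective_geometry = TRUE)
  local_curve <- function(x0, y0) {
    vapply(st$planes, function(p) {
      jc <- round(n %/% 2 + x0 / p$pixel_pitch) + 1L
      ic <- round(n %/% 2 + y0 / p$pixel_pitch) + 1L
      focus_metric(p$amplitude[(ic - 16):(ic + 16), (jc - 16):(jc + 16)])
    }, 0)
  }
  dax <- 2 * z2^2 * arm$wavelength / (n * arm$pixel_pitch)^2
  expect_lt(abs(zs[which.max(local_curve(-30e-6, 0))] - z1), 2 * dax)
  expect_lt(abs(zs[which.max(local_curve(35e-6, 10e-6))] - z2), 2 * dax)
})

test_that("focus metric: constant, scale invariance, sharpness ordering", {
  expect_equal(focus_metric(matrix(3, 16, 16)), 0)
  img <- matrix(runif(256, 0, 1), 16)
  expect_equal(focus_metric(img), focus_metric(7.3 * img), tolerance = 1e-12)
  chk <- matrix(rep(c(0.1, 0.9), length.out = 64^2), 64)
  blur <- (chk + chk[, c(2:64, 1)] + chk[c(2:64, 1), ]) / 3
  expect_gt(focus_metric(chk), focus_metric(blur))
  expect_error(focus_metric(matrix(0, 4, 4)), "all-zero")
})

test_that("autofocus finds a simulated disk within the axial resolution", {
  n <- 256L
  arm <- fixture_setup("ld", pixel_count = n, s = 5e-3, f = 21.5e-3)
  z <- 5e-3
  sc <- scene(scene_object("opaque_disk", 0, 0, z = z, radius = 3.25e-6,
                           amplitude_transmittance = 0), arm)
  h <- simulate_hologram(sc, n, n)
  z1 <- autofocus(h, 3e-3, 8e-3, steps = 25, use_effective_geometry = TRUE)
  dax <- 2 * z^2 * arm$wavelength / (n * arm$pixel_pitch)^2
  expect_lt(abs(z1 - z), 2 * dax)
  # determinism
  z2 <- autofocus(h, 3e-3, 8e-3, steps = 25, use_effective_geometry = TRUE)
  expect_identical(z1, z2)
  # a window strictly below the object returns a boundary value with a warning
  expect_warning(zb <- autofocus(h, 1.2e-3, 2.5e-3, steps = 9,
                                 use_effective_geometry = TRUE), "boundary")
  expect_true(zb %in% c(1.2e-3, 2.5e-3))
  expect_error(autofocus(h, 2e-3, 1e-3, 9), "z_min")
  expect_error(autofocus(h, 1e-3, 2e-3, 2), "steps")
})
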