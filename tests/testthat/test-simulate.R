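test_that("transmission maps render disks, spheres and bars correctly", {
  arm <- fixture_setup("ld", pixel_count = 128L)
  p <- arm$pixel_pitch
  empty <- scene(list(), arm)
  expect_true(all(transmission_map(empty, 1e-3, 32, 32, p) == 1 + 0i))

  r <- 20.3 * p
  sc <- scene(scene_object("opaque_disk", 0.4 * p, 0.2 * p, z = 1e-3,
                           radius = r, amplitude_transmittance = 0), arm)
  tm <- transmission_map(sc, 1e-3, 128, 128, p)
  covered <- sum(tm == 0)
  expect_lt(abs(covered - pi * r^2 / p^2) / (pi * r^2 / p^2), 0.02)
  expect_true(all(tm %in% c(0 + 0i, 1 + 0i)))

  # projected-thickness phase of a sphere: centre phase k * dn * 2r
  r2 <- 3.25e-6; dn <- 0.1
  sp <- scene(scene_object("phase_sphere", 0, 0, z = 1e-3, radius = r2,
                           dn = dn), arm)
  tms <- transmission_map(sp, 1e-3, 65, 65, p)
  centre <- tms[33, 33]
  expect_equal(Mod(centre), 1, tolerance = 1e-12)
  phi_max <- 2 * pi / arm$wavelength * dn * 2 * r2
  expect_equal(phi_max, 10.0841245671, tolerance = 1e-8)
  expect_equal(Arg(centre), ((phi_max + pi) %% (2 * pi)) - pi, tolerance = 1e-10)

  # five-bar element: dark pixel count = 5 bars of width x (5 width) length
  w <- 6 * p
  bt <- scene(scene_object("bar_target", 0, 0, z = 1e-3, line_width = w,
                           orientation = "vertical"), arm)
  tmb <- transmission_map(bt, 1e-3, 128, 128, p)
  expect_equal(sum(tmb == 0), 5 * 6 * 30, tolerance = 0.05)
})

test_that("spherical illumination: plane option, on-axis and quadratic phase", {
  arm <- fixture_setup("ld", pixel_count = 64L)
  p <- arm$pixel_pitch
  pl <- spherical_illumination(arm, 32, 32, p, 1e-3, type = "plane")
  expect_true(all(pl$amplitude == 1 + 0i))
  z <- 1.5e-3
  d <- arm$source_detector_distance - z
  k <- 2 * pi / arm$wavelength
  U <- spherical_illumination(arm, 65, 65, p, z)
  on_axis <- U$amplitude[33, 33]
  expect_equal(Arg(on_axis), ((k * d + pi) %% (2 * pi)) - pi, tolerance = 1e-6)
  # phase difference between centre and a pixel at radius rho
  rho <- 10 * p
  dphi <- Arg(U$amplitude[33, 43] / on_axis)
  expect_equal(dphi, ((k * rho^2 / (2 * d) + pi) %% (2 * pi)) - pi,
               tolerance = 1e-6)
  expect_error(spherical_illumination(arm, 32, 32, p, arm$source_detector_distance),
               "z_plane")
})

test_that("an empty scene's hologram equals its own background", {
  arm <- fixture_setup("ld", pixel_count = 64L)
  h <- simulate_hologram(scene(list(), arm), 64, 64)
  expect_lt(max(abs(h$intensity - h$background)) / mean(h$background), 1e-12)
})

test_that("direct integral: plane-wave free propagation stays near-uniform, big grids refused", {
  arm <- fixture_setup("ld", pixel_count = 64L)
  p <- arm$pixel_pitch
  empty <- scene(list(), arm)
  h <- direct_integral_oracle(empty, 48, 48, p, illumination = "plane",
                              z_plane = 200 * p)          # Fresnel regime
  cen <- 13:36
  amp <- sqrt(h$intensity[cen, cen])
  # a hard-truncated 48^2 aperture keeps slowly decaying edge-wave ripples
  # of roughly ten percent at any distance; the central region stays at
  # the incident amplitude with bounded variation
  expect_lt(abs(mean(amp) - 1), 0.1)
  expect_lt(sd(amp) / mean(amp), 0.15)
  expect_error(direct_integral_oracle(empty, 128, 128, p, z_plane = 1e-3),
               "refuses")
})

test_that("weak in-line holograms superpose approximately", {
  p <- 1.12e-6
  setup <- optical_setup(405e-9, 30e-3, 5e-3, 64L, p)
  z <- 200 * p
  mk <- function(objs) simulate_hologram(scene(objs, setup), 64, 64)
  oa <- scene_object("opaque_disk", -18 * p, 0, z = z, radius = 3 * p,
                     amplitude_transmittance = 0.6)
  ob <- scene_object("opaque_disk", 18 * p, 0, z = z, radius = 3 * p,
                     amplitude_transmittance = 0.6)
  ha <- mk(list(oa)); hb <- mk(list(ob)); hab <- mk(list(oa, ob))
  Ca <- ha$intensity - ha$background
  Cb <- hb$intensity - hb$background
  Cab <- hab$intensity - hab$background
  resid <- Cab - (Ca + Cb)
  expect_lt(max(abs(resid)) / max(abs(Cab)), 0.05)
})

test_that("partial coherence degenerates exactly to the coherent hologram", {
  arm <- fixture_setup("ld", pixel_count = 64L)   # zero bandwidth, point source
  sc <- scene(scene_object("opaque_disk", 0, 0, z = 1.5e-3, radius = 4e-6,
                           amplitude_transmittance = 0), arm)
  hc <- simulate_hologram(sc, 64, 64)
  hp <- apply_partial_coherence(sc, 64, 64, bandwidth = 0, source_diameter = 0,
                                n_wavelengths = 1, n_source_points = 1)
  expect_identical(hp$intensity, hc$intensity)
})

test_that("LED-like illumination suppresses the outer fringes a laser retains", {
  p <- 1.12e-6
  n <- 128L
  ld <- optical_setup(405e-9, 21.5e-3, 224e-6, n, p)
  led <- optical_setup(430e-9, 21.5e-3, 224e-6, n, p,
                       bandwidth = 15e-9, source_aperture_diameter = 15e-6)
  ob <- function(setup) scene(scene_object("opaque_disk", 0, 0, z = 224e-6,
                                           radius = 4 * p,
                                           amplitude_transmittance = 0), setup)
  h_ld <- simulate_hologram(ob(ld), n, n)
  h_led <- apply_partial_coherence(ob(led), n, n)
  count_fringes <- function(h) {
    C <- h$intensity - h$background
    xs <- holokit:::grid_coords(n, 1)
    rr <- sqrt(outer(xs^2, xs^2, `+`))
    prof <- vapply(0:59, function(k) mean(C[rr >= k & rr < k + 1]), 0)
    ks <- extrema_contrasts(abs(prof) / max(abs(prof)), prominence = 0.02)
    length(ks)
  }
  expect_lt(count_fringes(h_led), count_fringes(h_ld))
})

test_that("fringe visibility decreases monotonically with source size", {
  p <- 1.12e-6
  n <- 128L
  z <- 1.5e-3
  vis <- vapply(c(0, 5e-6, 15e-6, 30e-6), function(D) {
    setup <- optical_setup(405e-9, 21.5e-3, 4.25e-3, n, p,
                           source_aperture_diameter = D)
    sc <- scene(scene_object("opaque_disk", 0, 0, z = z, radius = 4 * p,
                             amplitude_transmittance = 0), setup)
    h <- apply_partial_coherence(sc, n, n, bandwidth = 0, source_diameter = D,
                                 n_wavelengths = 1, n_source_points = 13)
    C <- h$intensity - h$background
    # source blur is a convolution: the fine-fringe energy fraction falls
    # strictly with the source diameter
    S <- Mod(fft(C))^2
    fr <- holokit:::fft_freq(n, 1)
    rr <- sqrt(outer(fr^2, fr^2, `+`))
    sum(S[rr > 0.25]) / sum(S)
  }, 0)
  expect_true(all(diff(vis) < 0))
})

test_that("detector noise: identity, Poisson mean, quantisation, reproducibility", {
  arm <- fixture_setup("ld", pixel_count = 16L)
  h <- hologram(matrix(0.5, 16, 16), arm, background = matrix(0.5, 16, 16))
  none <- noise_model()
  expect_identical(add_noise(h, none)$intensity, h$intensity)
  # Monte-Carlo mean of noisy replicates approaches the clean intensity
  means <- vapply(0:999, function(s)
    mean(add_noise(h, noise_model(200, seed = s))$intensity), 0)
  expect_lt(abs(mean(means) - 0.5) / 0.5, 0.01)
  q <- add_noise(hologram(matrix(runif(256), 16), arm),
                 noise_model(bit_depth = 8))
  expect_lte(length(unique(as.vector(q$intensity))), 2^8)
  n1 <- add_noise(h, noise_model(1000, 8, seed = 42))
  n2 <- add_noise(h, noise_model(1000, 8, seed = 42))
  expect_identical(n1$intensity, n2$intensity)
  expect_error(noise_model(1000), "seed")
  # the global RNG stream is not disturbed
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(add_noise(h, noise_model(100, seed = 3))); b <- runif(1)
  expect_identical(a, b)
})

test_that("Gauss-Hermite rule matches published nodes and integrates exactly", {
  gh2 <- holokit:::gauss_hermite(2)
  expect_equal(gh2$nodes, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(gh2$weights, rep(sqrt(pi) / 2, 2), tolerance = 1e-12)
  gh3 <- holokit:::gauss_hermite(3)
  expect_equal(gh3$nodes, c(-1.2247448714, 0, 1.2247448714), tolerance = 1e-9)
  expect_equal(gh3$weights, c(0.2954089752, 1.1816359006, 0.2954089752),
               tolerance = 1e-9)
  # degree-3 polynomial integrated exactly by the 2-point rule
  gh <- holokit:::gauss_hermite(2)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical noisy holograms", {
  arm <- fixture_setup("ld", pixel_count = 64L)
  sc <- scene(scene_object("opaque_disk", 0, 0, z = 1.5e-3, radius = 4e-6,
                           amplitude_transmittance = 0.1), arm)
  h1 <- simulate_hologram(sc, 64, 64, noise = noise_model(1e4, 8, seed = 11))
  h2 <- simulate_hologram(sc, 64, 64, noise = noise_model(1e4, 8, seed = 11))
  expect_identical(h1$intensity, h2$intensity)
})
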