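test_that("pixel-limited lateral resolution reproduces the bench design values", {
  expect_equal(round(lateral_resolution(ld_bench()) * 1e6, 2), 0.87)
  expect_equal(round(lateral_resolution(led_bench()) * 1e6, 2), 0.92)
  # doubling the object distance doubles the resolution limit exactly
  s2 <- optical_setup(405e-9, 30e-3, 2 * 5.91e-3, 2464L, 1.12e-6)
  expect_equal(lateral_resolution(s2), 2 * lateral_resolution(ld_bench()))
})

test_that("NA-bound resolution formula and its domain checks", {
  expect_equal(lateral_resolution_from_na(430e-9, 0.5), 430e-9)
  expect_equal(lateral_resolution_from_na(405e-9, 1), 202.5e-9)
  expect_equal(lateral_resolution_from_na(405e-9, 0.234), 8.65384615385e-7,
               tolerance = 1e-10)
  expect_error(lateral_resolution_from_na(-1e-9, 0.5), "wavelength")
  expect_error(lateral_resolution_from_na(405e-9, 0), "aperture")
  expect_error(lateral_resolution_from_na(405e-9, 1.2), "aperture")
})

test_that("NA bound and pixel bound agree when NA = half detector / s", {
  set.seed(7)
  for (i in 1:20) {
    lam <- runif(1, 300e-9, 700e-9)
    f <- runif(1, 10e-3, 60e-3)
    s <- runif(1, 0.05, 0.9) * f
    N <- sample(128:4096, 1)
    p <- runif(1, 0.8e-6, 5e-6)
    setup <- optical_setup(lam, f, s, N, p)
    na <- (N * p / 2) / s
    if (na > 1) next
    expect_equal(lateral_resolution(setup),
                 lateral_resolution_from_na(lam, na),
                 tolerance = 1e-12)
  }
})

test_that("optimal object distance: values, limits and monotonicity", {
  expect_equal(optimal_object_distance(30e-3, 405e-9, 2464, 1.12e-6),
               6.08399788106e-3, tolerance = 1e-10)
  expect_equal(optimal_object_distance(30e-3, 430e-9, 2464, 1.12e-6),
               5.79864714563e-3, tolerance = 1e-10)
  # vanishing wavelength pushes the optimum to the source plane
  expect_equal(optimal_object_distance(30e-3, 1e-15, 2464, 1.12e-6), 30e-3,
               tolerance = 1e-6)
  # strictly decreasing in wavelength, increasing in pitch
  lams <- seq(350e-9, 700e-9, length.out = 8)
  vals <- vapply(lams, function(l) optimal_object_distance(30e-3, l, 2464, 1.12e-6), 0)
  expect_true(all(diff(vals) < 0))
  ps <- seq(0.9e-6, 3e-6, length.out = 8)
  vals <- vapply(ps, function(p) optimal_object_distance(30e-3, 405e-9, 2464, p), 0)
  expect_true(all(diff(vals) > 0))
  s_opt <- optimal_object_distance(30e-3, 405e-9, 2464, 1.12e-6)
  expect_true(s_opt > 0 && s_opt < 30e-3)
  expect_error(optimal_object_distance(-1, 405e-9, 2464, 1.12e-6), "positive|> 0")
})

test_that("axial resolution: values and quadratic scaling in s", {
  expect_equal(axial_resolution(ld_bench()), 3.71486065814e-6, tolerance = 1e-10)
  expect_equal(axial_resolution(led_bench()), 3.94417304445e-6, tolerance = 1e-10)
  half <- optical_setup(405e-9, 30e-3, 5.91e-3 / 2, 2464L, 1.12e-6)
  expect_equal(axial_resolution(half), axial_resolution(ld_bench()) / 4)
})

test_that("coherence length: LED value, scaling, and the monochromatic sentinel", {
  expect_equal(round(coherence_length(430e-9, 15e-9) * 1e6, 1), 3.9)
  expect_equal(coherence_length(405e-9, 2e-9),
               coherence_length(405e-9, 1e-9) / 2)
  expect_equal(coherence_length(405e-9, 1e-9), 5.22107790813e-5, tolerance = 1e-10)
  expect_identical(coherence_length(405e-9, 0), Inf)
  expect_error(coherence_length(405e-9, -1e-9), "bandwidth")
})

test_that("Gaussian fibre mode: Rayleigh length and beam diameters", {
  fibre <- gaussian_beam(1.65e-6, 405e-9)     # 3.3 um mode-field diameter
  expect_equal(round(rayleigh_length(fibre) * 1e6), 21)
  expect_equal(round(beam_diameter(fibre, 30e-3) * 1e3, 1), 4.7)
  expect_equal(round(beam_diameter(fibre, 24.09e-3) * 1e3, 1), 3.8)
  expect_equal(beam_diameter(fibre, 0), 2 * 1.65e-6)
  wide <- gaussian_beam(2 * 1.65e-6, 405e-9)
  expect_equal(rayleigh_length(wide), 4 * rayleigh_length(fibre))
  expect_equal(rayleigh_length(gaussian_beam(1e-6, 430e-9)),
               7.30602942695e-6, tolerance = 1e-10)
  expect_error(beam_diameter(fibre, -1e-3), "z")
})

test_that("USAF element arithmetic matches the chart's progression", {
  expect_equal(usaf_spatial_frequency(usaf_element(7, 1)), 128)
  expect_equal(round(usaf_spatial_frequency(usaf_element(8, 3)), 1), 322.5)
  expect_equal(round(usaf_line_width(usaf_element(7, 1)) * 1e6, 2), 3.91)
  expect_equal(round(usaf_line_width(usaf_element(8, 3)) * 1e6, 2), 1.55)
  expect_equal(round(usaf_line_width(usaf_element(11, 6)) * 1e9), 137)
  # one group up doubles the frequency at fixed element
  for (e in 1:6)
    expect_equal(usaf_spatial_frequency(usaf_element(8, e)),
                 2 * usaf_spatial_frequency(usaf_element(7, e)))
  # strictly increasing along (group, element) lexicographic order
  freqs <- unlist(lapply(4:9, function(g)
    vapply(1:6, function(e) usaf_spatial_frequency(usaf_element(g, e)), 0)))
  expect_true(all(diff(freqs) > 0))
  expect_error(usaf_element(7, 0), "element")
  expect_error(usaf_element(7, 7), "element")
})

test_that("setup invariants are enforced and outputs are positive", {
  expect_error(optical_setup(405e-9, 30e-3, 31e-3, 2464, 1.12e-6), "s < f")
  expect_error(optical_setup(405e-9, 30e-3, 5.91e-3, 1, 1.12e-6), "pixel_count")
  expect_error(optical_setup(-405e-9, 30e-3, 5.91e-3, 2464, 1.12e-6), "wavelength")
  for (setup in list(ld_bench(), led_bench())) {
    expect_gt(lateral_resolution(setup), 0)
    expect_gt(axial_resolution(setup), 0)
  }
})

test_that("design report collects the derived quantities", {
  rep <- design_report(ld_bench())
  expect_s3_class(rep, "design_report")
  get <- function(q) rep$value[rep$quantity == q]
  expect_equal(round(get("lateral_resolution") * 1e6, 2), 0.87)
  expect_equal(round(get("rayleigh_length") * 1e6), 21)
  expect_equal(round(get("beam_diameter_detector_plane") * 1e3, 1), 4.7)
  expect_equal(round(get("beam_diameter_object_plane") * 1e3, 1), 3.8)
  expect_equal(get("fringe_magnification"), 1.24533001245, tolerance = 1e-10)
  expect_output(print(rep), "lateral_resolution")
})
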