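#' Bar-target resolution study, one element per exposure
#'
#' Measures the achieved lateral resolution of an instrument arm by
#' simulating, reconstructing and contrast-analysing five-bar elements one
#' at a time: each element is placed alone at the centre of the object
#' plane, imaged through the full forward model (partially coherent when
#' the setup carries a nonzero bandwidth or source aperture), reconstructed
#' at the known depth in effective point-source geometry, normalised, and
#' summarised by its four extremum contrasts. Imaging the elements
#' individually keeps the coherent ringing, twin image and periodic
#' wrap-around of one element from contaminating another's averaged
#' profile; on a small simulation grid a full multi-element panel occupies
#' a far larger fraction of the field of view than a physical USAF slide
#' does on a real camera, which would make such crosstalk dominate.
#'
#' @param setup An [optical_setup()]; its `bandwidth` and
#'   `source_aperture_diameter` decide whether the arm is imaged
#'   coherently or by [apply_partial_coherence()].
#' @param groups Integer vector of USAF group numbers.
#' @param rows,cols Detector grid dimensions.
#' @param z Element depth \[m\]; defaults to the setup's object distance.
#' @param orientations Orientations to measure (default both).
#' @param threshold Resolvability threshold on mean K (default 0.05).
#' @param saturation_fraction Passed to [normalize_enhance()].
#' @param n_wavelengths,n_source_points Partial-coherence quadrature sizes.
#' @param pad_factor Forward-model padding (default 1.5: the simulation
#'   loses light diffracted beyond the camera aperture, which is what
#'   limits the resolution of the real instrument; see
#'   [simulate_hologram()]).
#' @param subpixel_offsets Sub-pixel placements of the element along its
#'   modulation axis, in reconstruction pixels, averaged per element
#'   (default 0, 1/3, 2/3). Rasterising bars a few pixels wide at a single
#'   alignment biases individual contrasts by several hundredths; a
#'   physical slide sits at an arbitrary alignment, and averaging over
#'   placements removes this discretisation artifact.
#' @return A list: `report` (a [contrast_report()] over all printable
#'   elements), `last` (the [last_resolvable()] element or NULL), and
#'   `prediction` (the pixel-limited resolution [lateral_resolution()] of
#'   the setup \[m\]).
#' @export
usaf_resolution_study <- function(setup, groups, rows, cols,
                                  z = setup$object_detector_distance,
                                  orientations = c("vertical", "horizontal"),
                                  threshold = 0.05,
                                  saturation_fraction = 0.002,
                                  n_wavelengths = 7L, n_source_points = 13L,
                                  pad_factor = 1.5,
                                  subpixel_offsets = c(0, 1, 2) / 3) {
  stopifnot(inherits(setup, "optical_setup"))
  partial <- setup$bandwidth > 0 || setup$source_aperture_diameter > 0
  p <- setup$pixel_pitch
  f <- setup$source_detector_distance
  M <- f / (f - z)
  rp <- p / M                               # reconstruction pixel pitch
  rows_out <- list()
  elements <- expand.grid(element = 1:6, group = sort(groups))
  for (i in seq_len(nrow(elements))) {      # increasing spatial frequency
    g <- elements$group[i]; e <- elements$element[i]
    el <- usaf_element(g, e)
    w <- usaf_line_width(el)
    if (w < 2 * p) next                     # below grid resolution
    span <- (2L * 5L - 1L) * w
    len <- 5 * w
    el_rows <- list()
    for (orient in orientations) {
    per_offset <- lapply(subpixel_offsets * rp, function(off) {
      # offset along the modulation axis: x for vertical bars, y for horizontal
      ob <- scene_object("bar_target",
                         x = if (orient == "vertical") off else 0,
                         y = if (orient == "vertical") 0 else off,
                         z = z, line_width = w, orientation = orient)
      sc <- scene(list(ob), setup)
      h <- if (partial) {
        apply_partial_coherence(sc, rows, cols,
                                n_wavelengths = n_wavelengths,
                                n_source_points = n_source_points,
                                pad_factor = pad_factor)
      } else {
        simulate_hologram(sc, rows, cols, pad_factor = pad_factor)
      }
      rec <- reconstruct(h, z, use_effective_geometry = TRUE)
      img <- normalize_enhance(rec$amplitude, saturation_fraction)
      box <- if (orient == "vertical")
        roi_box(c(off, 0), ex = span + 2 * w, ey = len, rp, rows, cols)
      else
        roi_box(c(0, off), ex = len, ey = span + 2 * w, rp, rows, cols)
      # (roi_box centre = (x, y))
      roi <- data.frame(group = g, element = e, orientation = orient,
                        width_px = w / rp,
                        row0 = box[1], col0 = box[2],
                        row1 = box[3], col1 = box[4])
      element_contrast(img, roi, threshold)
    })
      el_rows[[length(el_rows) + 1L]] <- combine_offset_rows(per_offset, threshold)
    }
    rows_out <- c(rows_out, el_rows)
    # the scan stops at the first unresolved element: finer elements are
    # never consulted by the last-resolvable rule, so they are not measured
    if (!all(vapply(el_rows, `[[`, TRUE, "resolvable"))) break
  }
  if (!length(rows_out)) stopf("no printable elements in the requested groups")
  report <- do.call(rbind, rows_out)
  report <- report[order(report$lp_per_mm, report$orientation), ]
  rownames(report) <- NULL
  class(report) <- c("contrast_report", "data.frame")
  list(report = report, last = last_resolvable(report, threshold),
       prediction = z * setup$wavelength / (rows * p))
}

# average the per-placement contrast rows of one element: K statistics are
# means over the placements that yielded the expected four contrasts; the
# element counts as clean (n_k = 4) when the majority of placements do
combine_offset_rows <- function(rows_list, threshold) {
  out <- rows_list[[1]]
  nk <- vapply(rows_list, `[[`, 0, "n_k")
  ok <- nk == 4
  out$n_k <- if (mean(ok) > 0.5) 4L else as.integer(round(median(nk)))
  if (any(ok)) {
    for (col in c("k1", "k2", "k3", "k4", "mean_k", "min_k", "max_k"))
      out[[col]] <- mean(vapply(rows_list[ok], `[[`, 0, col))
  }
  out$resolvable <- out$n_k == 4 && !is.na(out$mean_k) && out$mean_k >= threshold
  out
}
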