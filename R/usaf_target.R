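#' Lay out USAF-1951 elements on a grid
#'
#' Internal helper shared by [synth_usaf_target()] and [usaf_scene()].
#' Each element consists of `n_bars` dark bars of one line width, spaced
#' one width apart, bar length five widths. For every group, a column of
#' vertical-bar patches and a column of horizontal-bar patches are placed
#' side by side, elements stacked top to bottom, group blocks left to
#' right. Stacking along the bar direction keeps the neighbouring patches
#' off each patch's modulation axis, so that coherent ringing from one
#' element does not leak into another's averaged profile. Elements whose
#' line width falls below `2 * render_pitch` cannot be rendered at grid
#' resolution; they are skipped with a warning and flagged
#' `printable = FALSE` in the table.
#'
#' @param groups Integer vector of group numbers.
#' @param width,height Usable extent of the target area \[m\].
#' @param roi_pitch Pixel pitch used to express the returned ROI pixel
#'   boxes \[m\] (the pitch of the image the ROIs will be applied to).
#' @param nrow_img,ncol_img Dimensions of that image (for ROI clamping).
#' @param render_pitch Pitch at which the bars will be rasterised \[m\]
#'   (printability limit).
#' @param n_bars Dark bars per element.
#' @return A data.frame with one row per (element, orientation): group,
#'   element, orientation, cx, cy (centre, m), line_width, lp_per_mm,
#'   printable, and the half-open 0-based pixel box row0, col0, row1, col1.
#' @keywords internal
usaf_layout <- function(groups, width, height, roi_pitch, nrow_img, ncol_img,
                        render_pitch = roi_pitch, n_bars = 5L) {
  rows_out <- list()
  skipped <- character()
  x <- -width / 2
  for (g in sort(groups)) {
    wmax <- usaf_line_width(usaf_element(g, 1))
    span_f <- 2 * n_bars - 1            # modulation extent in line widths
    for (orient in c("vertical", "horizontal")) {
      colw <- if (orient == "vertical") span_f * wmax else 5 * wmax
      y <- -height / 2
      for (e in 1:6) {
        el <- usaf_element(g, e)
        w <- usaf_line_width(el)
        printable <- w >= 2 * render_pitch
        span <- span_f * w
        len <- 5 * w
        if (!printable) {
          skipped <- c(skipped, sprintf("g%de%d-%s (%s)", g, e,
                                        substr(orient, 1, 1), format_length(w)))
          rows_out[[length(rows_out) + 1L]] <- data.frame(
            group = g, element = e, orientation = orient,
            cx = NA_real_, cy = NA_real_, line_width = w,
            width_px = w / roi_pitch,
            lp_per_mm = usaf_spatial_frequency(el), printable = FALSE,
            row0 = NA_integer_, col0 = NA_integer_,
            row1 = NA_integer_, col1 = NA_integer_)
          next
        }
        ph <- if (orient == "vertical") len else span   # patch height
        if (y + ph > height / 2)
          stopf("USAF layout does not fit: group %d element %d exceeds the target area", g, e)
        ctr <- c(x + colw / 2, y + ph / 2)
        # ROI: bars plus one line width of bright margin along the modulation axis
        roi <- if (orient == "vertical")
          roi_box(ctr, ex = span + 2 * w, ey = len, roi_pitch, nrow_img, ncol_img)
        else
          roi_box(ctr, ex = len, ey = span + 2 * w, roi_pitch, nrow_img, ncol_img)
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          group = g, element = e, orientation = orient,
          cx = ctr[1], cy = ctr[2], line_width = w,
          width_px = w / roi_pitch,
          lp_per_mm = usaf_spatial_frequency(el), printable = TRUE,
          row0 = roi[1], col0 = roi[2], row1 = roi[3], col1 = roi[4])
        y <- y + ph + 2 * w             # stack with two line widths of margin
      }
      x <- x + colw + 3 * wmax          # next column
    }
  }
  if (length(skipped))
    warning(sprintf("skipped elements below grid resolution: %s",
                    paste(skipped, collapse = ", ")))
  do.call(rbind, rows_out)
}

# Half-open 0-based pixel box around centre (m) with extents ex, ey (m).
roi_box <- function(centre, ex, ey, pitch, nrow_img, ncol_img) {
  c0 <- ncol_img %/% 2
  r0 <- nrow_img %/% 2
  col0 <- max(0L, floor(c0 + (centre[1] - ex / 2) / pitch))
  col1 <- min(ncol_img, ceiling(c0 + (centre[1] + ex / 2) / pitch) + 1L)
  row0 <- max(0L, floor(r0 + (centre[2] - ey / 2) / pitch))
  row1 <- min(nrow_img, ceiling(r0 + (centre[2] + ey / 2) / pitch) + 1L)
  as.integer(c(row0, col0, row1, col1))
}

#' Synthesise a USAF-1951 bar-target panel
#'
#' Renders five-bar elements (horizontal and vertical per element) for the
#' requested groups as a binary amplitude transmission map, together with a
#' table of per-element ROI bounding boxes for contrast analysis.
#'
#' @param groups Integer vector of group numbers.
#' @param rows,cols Grid dimensions.
#' @param pitch Sample spacing \[m\].
#' @return A list: `map` (complex `rows x cols` transmission grid) and
#'   `rois` (the layout data.frame, see [usaf_layout()]).
#' @export
synth_usaf_target <- function(groups, rows, cols, pitch) {
  rois <- usaf_layout(groups, width = cols * pitch, height = rows * pitch,
                      roi_pitch = pitch, nrow_img = rows, ncol_img = cols,
                      render_pitch = pitch)
  xs <- grid_coords(cols, pitch)
  ys <- grid_coords(rows, pitch)
  map <- matrix(1 + 0i, rows, cols)
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    if (!r$printable) next
    ob <- scene_object("bar_target", x = r$cx, y = r$cy, z = 1,
                       line_width = r$line_width, orientation = r$orientation)
    map <- map * bar_patch(ob, xs, ys)
  }
  list(map = map, rois = rois)
}

#' Build a scene imaging a USAF panel at depth z
#'
#' Places the same five-bar elements as [synth_usaf_target()] into a
#' [scene()] at object depth `z`, sized so that the panel's projection
#' (fringe magnification M = f/(f-z)) stays inside the detector. The
#' returned ROI table is expressed in the pixels of an
#' effective-geometry reconstruction (pitch p / M), so that
#' `reconstruct(holo, z, use_effective_geometry = TRUE)` can be analysed
#' directly with it.
#'
#' @param groups Integer vector of group numbers.
#' @param setup An [optical_setup()].
#' @param rows,cols Detector grid dimensions.
#' @param z Panel depth (distance from detector) \[m\].
#' @param fill Fraction of the demagnified detector extent usable by the
#'   layout (default 0.9, leaving an edge margin).
#' @return A list: `scene` (a [scene()] of bar targets) and `rois`
#'   (layout table in reconstruction pixels).
#' @export
usaf_scene <- function(groups, setup, rows, cols, z, fill = 0.9) {
  stopifnot(inherits(setup, "optical_setup"))
  p <- setup$pixel_pitch
  f <- setup$source_detector_distance
  M <- f / (f - z)
  rois <- usaf_layout(groups,
                      width = cols * p / M * fill, height = rows * p / M * fill,
                      roi_pitch = p / M, nrow_img = rows, ncol_img = cols,
                      render_pitch = p)
  objs <- list()
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    if (!r$printable) next
    objs[[length(objs) + 1L]] <-
      scene_object("bar_target", x = r$cx, y = r$cy, z = z,
                   line_width = r$line_width, orientation = r$orientation)
  }
  list(scene = scene(objs, setup), rois = rois)
}
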