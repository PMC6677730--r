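#' Region of interest over one bar element
#'
#' Half-open, 0-based pixel bounding box plus the bar orientation:
#' `"vertical"` bars modulate along x (profile taken along columns after
#' averaging over rows), `"horizontal"` the transpose.
#'
#' @param row0,col0,row1,col1 Half-open 0-based pixel bounds.
#' @param bar_axis `"vertical"` or `"horizontal"`.
#' @param element Optional [usaf_element()] the ROI belongs to.
#' @return An object of class `profile_roi`.
#' @export
profile_roi <- function(row0, col0, row1, col1,
                        bar_axis = c("vertical", "horizontal"), element = NULL) {
  bar_axis <- match.arg(bar_axis)
  if (row1 <= row0 || col1 <= col0) stopf("empty ROI box")
  mod_extent <- if (bar_axis == "vertical") col1 - col0 else row1 - row0
  if (mod_extent < 5) stopf("ROI must cover >= 5 pixels along the modulation direction")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1),
                 bar_axis = bar_axis, element = element),
            class = "profile_roi")
}

#' Average a bar element along its bar axis
#'
#' Mean intensity over the bar-parallel direction, returned along the
#' modulation direction; length equals the ROI extent in that direction.
#'
#' @param image Real matrix.
#' @param roi A [profile_roi()] (must lie inside the image).
#' @return Numeric vector (the averaged profile).
#' @export
averaged_profile <- function(image, roi) {
  stopifnot(inherits(roi, "profile_roi"))
  if (roi$row0 < 0 || roi$col0 < 0 ||
      roi$row1 > nrow(image) || roi$col1 > ncol(image))
    stopf("ROI [%d,%d)x[%d,%d) lies outside the %dx%d image",
          roi$row0, roi$row1, roi$col0, roi$col1, nrow(image), ncol(image))
  sub <- image[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, drop = FALSE]
  if (roi$bar_axis == "vertical") colMeans(sub) else rowMeans(sub)
}

#' Contrast of consecutive profile extrema
#'
#' Detects alternating local minima and maxima of the profile after
#' moving-average smoothing, discards the weaker of two same-type
#' neighbours, and merges away adjacent extremum pairs whose amplitude
#' difference is below `prominence` times the profile range (coherent
#' imaging superimposes diffraction-scale ringing on the bar modulation;
#' low-prominence wiggles are not bar structure). One Michelson contrast
#' K = (I_max - I_min) / (I_max + I_min) is then computed per interior
#' *gap* between bars -- the extremum type matching the polarity of the
#' profile's margins (bright gaps between dark bars, or dark gaps between
#' bright bars, as in background-subtracted amplitude reconstructions
#' where opaque bars appear bright) -- against the mean of its two
#' neighbouring bar extrema. A clean five-bar element has four interior
#' gaps and yields exactly four values. Fewer than two surviving extrema
#' signal an unresolved element: the empty vector is returned.
#'
#' @param profile Numeric vector, length >= 5, nonnegative.
#' @param prominence Minimum amplitude of a retained oscillation,
#'   relative to the profile range (default 0.15).
#' @param smooth_window Odd moving-average window; the default 3 suits
#'   bars a few pixels wide, callers that know the bar width use about
#'   half of it (see [element_contrast()]).
#' @return Numeric vector of K values (possibly empty).
#' @export
extrema_contrasts <- function(profile, prominence = 0.15, smooth_window = 3L) {
  if (length(profile) < 5) stopf("profile must have length >= 5")
  sm <- smooth_ma(profile, smooth_window)
  ex <- find_extrema(sm)
  if (nrow(ex) < 2) return(numeric(0))
  ex <- enforce_alternation(ex)
  ex <- prune_prominence(ex, prominence * diff(range(sm)))
  n <- nrow(ex)
  if (n < 3) return(numeric(0))
  bg <- mean(c(sm[seq_len(min(2, length(sm)))], sm[seq(length(sm) - 1, length(sm))]))
  gap_type <- if (bg >= mean(sm)) "max" else "min"
  ks <- numeric(0)
  for (j in 2:(n - 1L)) {
    if (ex$type[j] != gap_type) next
    gap <- ex$value[j]
    bar <- (ex$value[j - 1L] + ex$value[j + 1L]) / 2
    hi <- max(gap, bar); lo <- min(gap, bar)
    if (hi + lo > 0) ks <- c(ks, (hi - lo) / (hi + lo))
  }
  ks
}

# centred 3-sample moving average, endpoints kept
smooth3 <- function(x) {
  n <- length(x)
  y <- x
  if (n >= 3) y[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  y
}

# centred moving average of odd window k (k = 3 delegates to smooth3)
smooth_ma <- function(x, k = 3L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 3L) return(smooth3(x))
  n <- length(x)
  if (n < k) return(smooth3(x))
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  y <- x
  for (i in (h + 1L):(n - h)) y[i] <- (cs[i + h + 1L] - cs[i - h]) / k
  y
}

# locate sign changes of diff(sm); plateaus collapse to their middle;
# values reported from the smoothed profile
find_extrema <- function(sm) {
  d <- diff(sm)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2)
    return(data.frame(idx = integer(), type = character(), value = numeric()))
  idx <- integer(); type <- character()
  for (j in seq_len(length(nz) - 1L)) {
    a <- nz[j]; b <- nz[j + 1L]
    if (s[a] != s[b]) {
      pos <- as.integer(ceiling((a + 1 + b) / 2))   # middle of any plateau
      idx <- c(idx, pos)
      type <- c(type, if (s[a] > 0) "max" else "min")
    }
  }
  data.frame(idx = idx, type = type, value = sm[idx], stringsAsFactors = FALSE)
}

# drop the weaker of two same-type neighbours until strict alternation
enforce_alternation <- function(ex) {
  repeat {
    same <- which(ex$type[-1] == ex$type[-nrow(ex)])
    if (!length(same)) return(ex)
    j <- same[1]
    drop <- if (ex$type[j] == "max") {
      if (ex$value[j] >= ex$value[j + 1]) j + 1 else j
    } else {
      if (ex$value[j] <= ex$value[j + 1]) j + 1 else j
    }
    ex <- ex[-drop, , drop = FALSE]
  }
}

# repeatedly merge away the adjacent extremum pair with the smallest
# amplitude difference while it falls below min_amp; re-enforcing
# alternation after each removal fuses the surviving neighbours
prune_prominence <- function(ex, min_amp) {
  repeat {
    n <- nrow(ex)
    if (n < 2) return(ex)
    amp <- abs(diff(ex$value))
    j <- which.min(amp)
    if (amp[j] >= min_amp) return(ex)
    keep <- setdiff(seq_len(n), c(j, j + 1L))
    ex <- enforce_alternation(ex[keep, , drop = FALSE])
  }
}

#' Contrast statistics of one bar element
#'
#' Runs [averaged_profile()] and [extrema_contrasts()] on one ROI and
#' summarises: individual K values (padded to four with NA), their mean,
#' minimum and maximum, the element's spatial frequency, and a
#' resolvability flag (all of the expected `n_bars - 1` contrasts found and
#' mean K at or above `threshold`).
#'
#' @param image Real matrix (typically a normalised reconstructed
#'   amplitude image).
#' @param roi A [profile_roi()] with its `element` set, or one row of a
#'   [usaf_layout()] table.
#' @param threshold Minimum mean K for resolvability (default 0.05).
#' @return A one-row data.frame: group, element, orientation, lp_per_mm,
#'   n_k, k1..k4, mean_k, min_k, max_k, resolvable.
#' @export
element_contrast <- function(image, roi, threshold = 0.05) {
  width_px <- NA_real_
  if (is.data.frame(roi)) {
    el <- usaf_element(roi$group, roi$element)
    if (!is.null(roi$width_px)) width_px <- roi$width_px
    roi <- profile_roi(roi$row0, roi$col0, roi$row1, roi$col1,
                       bar_axis = roi$orientation, element = el)
  }
  stopifnot(inherits(roi, "profile_roi"))
  el <- roi$element
  if (is.null(el)) stopf("ROI carries no usaf_element")
  # smooth over about half a bar width: wide enough to suppress
  # diffraction-scale ringing on coarse bars, narrow enough to keep the
  # bar modulation itself
  win <- if (is.finite(width_px)) max(3L, round(width_px / 2)) else 3L
  ks <- extrema_contrasts(averaged_profile(image, roi), smooth_window = win)
  k4 <- rep(NA_real_, 4)
  k4[seq_len(min(4, length(ks)))] <- ks[seq_len(min(4, length(ks)))]
  data.frame(group = el$group, element = el$element,
             orientation = roi$bar_axis,
             lp_per_mm = usaf_spatial_frequency(el),
             n_k = length(ks),
             k1 = k4[1], k2 = k4[2], k3 = k4[3], k4 = k4[4],
             mean_k = if (length(ks)) mean(ks) else NA_real_,
             min_k = if (length(ks)) min(ks) else NA_real_,
             max_k = if (length(ks)) max(ks) else NA_real_,
             resolvable = length(ks) == 4 &&
               length(ks) > 0 && mean(ks) >= threshold,
             stringsAsFactors = FALSE)
}

#' Contrast report over a set of element ROIs
#'
#' One [element_contrast()] row per printable ROI, ordered by spatial
#' frequency. The error bars of a contrast-vs-frequency plot are the
#' min-max range of the four K values per element.
#'
#' @param image Real matrix.
#' @param rois A [usaf_layout()]-style data.frame (rows with
#'   `printable = FALSE` are dropped).
#' @param threshold Passed to [element_contrast()].
#' @return A data.frame of class `contrast_report`.
#' @export
contrast_report <- function(image, rois, threshold = 0.05) {
  if ("printable" %in% names(rois)) rois <- rois[rois$printable, , drop = FALSE]
  if (!nrow(rois)) stopf("no printable ROIs to analyse")
  out <- do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    element_contrast(image, rois[i, ], threshold)))
  out <- out[order(out$lp_per_mm, out$orientation), ]
  rownames(out) <- NULL
  class(out) <- c("contrast_report", "data.frame")
  out
}

#' Finest element still resolved
#'
#' Scans elements in order of increasing spatial frequency and returns the
#' highest-frequency element that satisfies the resolvability criterion;
#' scanning stops at the first failing element (coarser elements beyond a
#' failure are not trusted). By default an element counts as resolved only
#' if both orientations yield exactly four contrast values with mean K at
#' or above the threshold.
#'
#' @param report A [contrast_report()].
#' @param threshold Minimum mean K (default 0.05).
#' @param require_both Require both orientations to pass (default TRUE;
#'   with FALSE a single passing orientation suffices).
#' @return A [usaf_element()], or `NULL` when not even the coarsest
#'   element is resolved.
#' @export
last_resolvable <- function(report, threshold = 0.05, require_both = TRUE) {
  if (!nrow(report)) return(NULL)
  key <- paste(report$group, report$element)
  best <- NULL
  for (kk in unique(key[order(report$lp_per_mm)])) {
    rows <- report[key == kk, , drop = FALSE]
    pass <- rows$n_k == 4 & !is.na(rows$mean_k) & rows$mean_k >= threshold
    ok <- if (require_both) all(pass) else any(pass)
    if (!ok) break
    best <- usaf_element(rows$group[1], rows$element[1])
  }
  best
}

#' Normalise and contrast-enhance an image
#'
#' Linear rescale to \[0, 1\] after clipping a small fraction of pixels at
#' each intensity tail (percentile clip), the usual "enhance contrast by
#' 0.2%" post-processing step applied to reconstructed amplitude images.
#'
#' @param image Real matrix.
#' @param saturation_fraction Fraction clipped at each tail, in
#'   \[0, 0.05\]; default 0.002.
#' @return Matrix with values in \[0, 1\].
#' @export
normalize_enhance <- function(image, saturation_fraction = 0.002) {
  if (saturation_fraction < 0 || saturation_fraction > 0.05)
    stopf("saturation_fraction must lie in [0, 0.05]")
  lo <- quantile(image, saturation_fraction, names = FALSE)
  hi <- quantile(image, 1 - saturation_fraction, names = FALSE)
  if (hi <= lo) {
    if (max(image) > min(image)) {
      lo <- min(image); hi <- max(image)
    } else {
      warning("constant image: returning zeros")
      return(matrix(0, nrow(image), ncol(image)))
    }
  }
  out <- (image - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Reconstruct and contrast-analyse a bar-target hologram
#'
#' Convenience pipeline used for resolution studies: reconstructs the
#' hologram at the known target depth (effective point-source geometry so
#' that the images are in object-plane pixels), normalises the amplitude
#' image, computes the [contrast_report()] over the generator's ROI table
#' and determines the [last_resolvable()] element.
#'
#' @param holo A [hologram()] of a bar-target scene.
#' @param rois ROI table from [usaf_scene()].
#' @param z Target depth \[m\].
#' @param use_effective_geometry Passed to [reconstruct()] (default TRUE).
#' @param threshold,saturation_fraction Analysis parameters.
#' @return A list: `recon`, `image` (normalised amplitude), `report`,
#'   `last` (a [usaf_element()] or NULL).
#' @export
analyze_bar_target <- function(holo, rois, z, use_effective_geometry = TRUE,
                               threshold = 0.05, saturation_fraction = 0.002) {
  rec <- reconstruct(holo, z, use_effective_geometry)
  img <- normalize_enhance(rec$amplitude, saturation_fraction)
  rep <- contrast_report(img, rois, threshold)
  list(recon = rec, image = img, report = rep,
       last = last_resolvable(rep, threshold))
}
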