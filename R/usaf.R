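#' USAF-1951 element arithmetic
#'
#' The 1951 USAF resolution chart arranges bar patterns in groups and
#' elements whose spatial frequency follows the geometric progression
#' 2^(group + (element - 1)/6) line pairs per millimetre; each successive
#' element is a sixth of an octave finer and each group doubles the
#' frequency. `usaf_line_width()` is the width of a single bar, half a
#' line-pair period.
#'
#' @param group Group number (integer, may be negative).
#' @param element Element number within the group, 1..6.
#' @return `usaf_element()` returns an object of class `usaf_element`.
#' @examples
#' usaf_spatial_frequency(usaf_element(7, 1))   # 128 lp/mm
#' usaf_line_width(usaf_element(8, 3))          # ~1.55e-6 m
#' @export
usaf_element <- function(group, element) {
  group <- as.integer(group)
  element <- as.integer(element)
  if (is.na(group)) stopf("group must be an integer")
  if (is.na(element) || element < 1L || element > 6L)
    stopf("element must be an integer in 1..6, got %s", element)
  structure(list(group = group, element = element), class = "usaf_element")
}

#' @export
print.usaf_element <- function(x, ...) {
  cat(sprintf("<usaf_element> group %d element %d (%.4g lp/mm, line width %s)\n",
              x$group, x$element, usaf_spatial_frequency(x),
              format_length(usaf_line_width(x))))
  invisible(x)
}

#' @rdname usaf_element
#' @param e A `usaf_element`.
#' @return `usaf_spatial_frequency()` returns line pairs per millimetre.
#' @export
usaf_spatial_frequency <- function(e) {
  stopifnot(inherits(e, "usaf_element"))
  2^(e$group + (e$element - 1) / 6)
}

#' @rdname usaf_element
#' @return `usaf_line_width()` returns the single-bar width in metres.
#' @export
usaf_line_width <- function(e) {
  # frequency is in lp/mm; one line pair spans 1/freq mm, a bar half of that
  1 / (2 * usaf_spatial_frequency(e)) * 1e-3
}
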