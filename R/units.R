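#' Unit handling and small numeric utilities
#'
#' All lengths inside the toolkit are SI metres. Configuration files spell
#' lengths with an explicit unit suffix (`"405 nm"`, `"5.91 mm"`) so that a
#' nanometre/micrometre slip cannot silently corrupt a geometry.
#'
#' @name units
NULL

.length_units <- c("nm" = 1e-9, "um" = 1e-6, "µm" = 1e-6,
                   "mm" = 1e-3, "cm" = 1e-2, "m" = 1)

#' Parse a length with unit suffix into metres
#'
#' @param x A string such as `"405 nm"` or `"1.12 um"`. Recognised suffixes:
#'   nm, um (or µm), mm, cm, m.
#' @param key Name used in error messages (typically the config key).
#' @return Length in metres (numeric scalar).
#' @examples
#' parse_length("5.91 mm")
#' parse_length("1.12 um")
#' @export
parse_length <- function(x, key = "length") {
  if (is.numeric(x)) {
    stop(sprintf("'%s': bare number %g; an explicit unit suffix (nm, um, mm, cm, m) is required",
                 key, x), call. = FALSE)
  }
  if (!is.character(x) || length(x) != 1L) {
    stop(sprintf("'%s': expected a single string like \"405 nm\"", key), call. = FALSE)
  }
  m <- regmatches(x, regexec("^\\s*([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\s*([a-zµ]+)\\s*$", x))[[1]]
  if (length(m) != 3L || !(m[3] %in% names(.length_units))) {
    stop(sprintf("'%s': cannot parse length \"%s\" (use e.g. \"405 nm\", \"1.12 um\", \"5.91 mm\")",
                 key, x), call. = FALSE)
  }
  as.numeric(m[2]) * .length_units[[m[3]]]
}

#' Format a length in metres with a readable unit
#' @param x Length in metres.
#' @param digits Significant digits.
#' @return A string such as `"0.87 um"`.
#' @export
format_length <- function(x, digits = 4) {
  if (!is.finite(x)) return(as.character(x))
  ax <- abs(x)
  u <- if (ax == 0) "m" else if (ax < 1e-6) "nm" else if (ax < 1e-3) "um" else if (ax < 1) "mm" else "m"
  sprintf("%s %s", signif(x / .length_units[[u]], digits), u)
}

# stop() with sprintf formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Run an expression with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# DFT sample frequencies (cycles per metre), numpy-style ordering.
fft_freq <- function(n, d) {
  m <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  m / (n * d)
}

# Centered pixel coordinates (metres); pixel (n %/% 2 + 1) sits at 0.
grid_coords <- function(n, pitch) (seq_len(n) - 1L - n %/% 2) * pitch
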