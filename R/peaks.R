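#' Detect local maxima with prominences
#'
#' Strict local maxima of a sample sequence; a plateau contributes its first
#' sample. Prominence follows the standard topographic definition: walk left
#' and right from the peak until a strictly higher sample (or the signal
#' edge), take the minimum on each side, and measure the peak height above
#' the *higher* of those two flanking minima.
#'
#' @param x Numeric vector (length >= 3 for any peak to exist).
#' @param min_prominence Keep only peaks at least this prominent (same units
#'   as `x`). Default 0 keeps every local maximum, matching a bare
#'   `findpeaks`-style call.
#' @return Tibble with columns `index` (1-based), `height`, `prominence`;
#'   zero rows when no peak exists.
#' @export
detect_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) {
    return(tibble::tibble(index = integer(), height = numeric(),
                          prominence = numeric()))
  }
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # climb a potential plateau: first sample of the plateau is the peak
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(idx)) {
    return(tibble::tibble(index = integer(), height = numeric(),
                          prominence = numeric()))
  }
  prom <- vapply(idx, function(p) {
    h <- x[p]
    lo <- p
    while (lo > 1L && x[lo - 1L] <= h) lo <- lo - 1L
    left_min <- min(x[lo:p])
    hi <- p
    while (hi < n && x[hi + 1L] <= h) hi <- hi + 1L
    right_min <- min(x[p:hi])
    h - max(left_min, right_min)
  }, 1.0)
  out <- tibble::tibble(index = as.integer(idx), height = x[idx],
                        prominence = prom)
  out[out$prominence >= min_prominence, ]
}

#' Inter-peak intervals
#' @param peaks Result of [detect_peaks()].
#' @return Integer vector of successive index differences (length
#'   `nrow(peaks) - 1`).
#' @export
peak_intervals <- function(peaks) diff(peaks$index)
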