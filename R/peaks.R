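#' Peak detection with topographic prominence and minimum distance
#'
#' Finds local maxima, computes their topographic prominence (height of the
#' peak above the higher of the two saddles separating it from taller
#' terrain or the signal edge), discards peaks below `min_prominence`, and
#' then enforces a minimum peak separation by keeping higher peaks and
#' discarding lower ones within the exclusion distance (equal heights: the
#' earlier peak wins). Plateau maxima are reported at their left edge.
#'
#' @param x numeric vector.
#' @param min_prominence minimum topographic prominence.
#' @param min_distance minimum separation between returned peaks, in samples.
#' @return data frame with columns `index` (1-based), `height`,
#'   `prominence`, sorted by index. Zero rows if nothing qualifies.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 0) {
  n <- length(x)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3L) return(empty)

  # local maxima with plateau handling: between consecutive non-zero slopes,
  # a +/- sign change marks a peak; its left plateau edge is reported
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(empty)
  s <- sign(d[nz])
  turn <- which(s[-length(s)] > 0 & s[-1] < 0)
  peaks <- nz[turn] + 1L
  if (!length(peaks)) return(empty)

  prom <- vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h; j <- p - 1L
    while (j >= 1L && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    rmin <- h; j <- p + 1L
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))

  keep <- prom >= min_prominence
  peaks <- peaks[keep]; prom <- prom[keep]
  if (!length(peaks)) return(empty)

  if (min_distance > 0 && length(peaks) > 1L) {
    ord <- order(-x[peaks], peaks)   # highest first; ties -> earlier index
    alive <- rep(TRUE, length(peaks))
    for (k in ord) {
      if (!alive[k]) next
      too_close <- abs(peaks - peaks[k]) < min_distance & seq_along(peaks) != k
      alive[too_close & alive & (x[peaks] < x[peaks[k]] |
        (x[peaks] == x[peaks[k]] & peaks > peaks[k]))] <- FALSE
    }
    peaks <- peaks[alive]; prom <- prom[alive]
  }

  data.frame(index = peaks, height = x[peaks], prominence = prom)
}
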