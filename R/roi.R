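# Line-scan bundle counting and fixed-box ROI measurement.

# Topographic prominence of each local maximum of a 1-D profile: the peak
# height minus the higher of the two saddle minima separating it from the
# nearest greater point on each side (or the profile end).
peak_prominences <- function(profile) {
  n <- length(profile)
  # local maxima; plateaus count once, at their first pixel; ends excluded
  is_peak <- logical(n)
  i <- 2L
  while (i < n) {
    if (profile[i] > profile[i - 1L]) {
      j <- i
      while (j < n && profile[j + 1L] == profile[j]) j <- j + 1L
      if (j < n && profile[j + 1L] < profile[j]) is_peak[i] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks <- which(is_peak)
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- profile[p]
    left <- p; lmin <- h
    while (left > 1L && profile[left - 1L] <= h) {
      left <- left - 1L
      lmin <- min(lmin, profile[left])
    }
    right <- p; rmin <- h
    while (right < n && profile[right + 1L] <= h) {
      right <- right + 1L
      rmin <- min(rmin, profile[right])
    }
    prom[k] <- h - max(lmin, rmin)
  }
  list(peaks = peaks, prominence = prom)
}

#' Count bundles along a line scan
#'
#' Counts the peaks of a 1-D fluorescence intensity profile recorded along
#' a line drawn across a network — each filament bundle crossing the line
#' produces one peak. A local maximum is counted when its topographic
#' prominence is at least `min_prominence`, which rejects noise ripples.
#'
#' @param profile Numeric intensity profile (length >= 3).
#' @param min_prominence Minimum peak prominence.
#' @return Integer bundle count, with the peak positions as attribute
#'   `peaks`.
#' @export
count_peaks_linescan <- function(profile, min_prominence = 0) {
  if (length(profile) < 3L) stopf("profile needs at least 3 samples")
  pp <- peak_prominences(profile)
  keep <- pp$prominence >= min_prominence & pp$prominence > 0
  structure(sum(keep), peaks = pp$peaks[keep])
}

#' Mean intensity in a fixed axis-aligned pixel box
#'
#' Mean over a `box_shape = c(rows, cols)` box centred on `center`
#' (half-open pixel ranges; for even extents the box extends one pixel
#' further down/right of centre). Used for fixed-geometry readouts such as
#' a 21 x 6 box on the actin channel or a 14 x 14 box on a linker channel.
#'
#' @param image Numeric matrix.
#' @param center `(row, col)` of the box centre (1-based).
#' @param box_shape `(rows, cols)` box extent in pixels.
#' @return Mean intensity over the box.
#' @export
measure_roi <- function(image, center, box_shape) {
  if (length(center) != 2L || length(box_shape) != 2L)
    stopf("`center` and `box_shape` must each have length 2")
  if (any(box_shape < 1)) stopf("box extents must be >= 1")
  r0 <- center[1L] - box_shape[1L] %/% 2L
  c0 <- center[2L] - box_shape[2L] %/% 2L
  r1 <- r0 + box_shape[1L] - 1L
  c1 <- c0 + box_shape[2L] - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(image) || c1 > ncol(image))
    stopf("box [%d:%d, %d:%d] lies outside the %d x %d image",
          r0, r1, c0, c1, nrow(image), ncol(image))
  mean(image[r0:r1, c0:c1])
}
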