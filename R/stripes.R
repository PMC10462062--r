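#' Render a periodic stripe micropattern mask
#'
#' Builds the binary on-pattern mask for a micropatterned surface of
#' alternating motor-coated stripes and passivated gaps, the geometry used
#' to trap tensed filament networks spanning the inter-stripe gaps.
#' Typical layouts are 10 um stripes with 10 um spacing, or 2.5 um stripes
#' with 17.5 um spacing.
#'
#' The pattern is periodic with period `stripe_width + gap_width`; the first
#' stripe begins at the first pixel row/column. A pixel is on-stripe when its
#' centre falls inside a stripe interval (half-open intervals), so the
#' on-pixel fraction equals `stripe_width / (stripe_width + gap_width)` up to
#' one pixel row of rounding.
#'
#' @param stripe_width Stripe width in micrometres (>= 0; 0 gives an all-off
#'   mask).
#' @param gap_width Gap (spacing) width in micrometres (> 0).
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param shape Image shape as `c(rows, cols)`.
#' @param orientation `"vertical"` (stripes are columns) or `"horizontal"`.
#' @return An object of class `stripe_pattern`: a list with the logical
#'   `mask` (`TRUE` = on-stripe), the integer `gap_id` image labelling each
#'   gap region (0 on stripes), and the geometry parameters.
#' @examples
#' p <- make_stripe_pattern(10, 10, 1, c(100, 100))
#' mean(p$mask) # 0.5
#' @export
make_stripe_pattern <- function(stripe_width, gap_width, pixel_size, shape,
                                orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  check_scalar(stripe_width, "stripe_width", lower = 0)
  check_scalar(gap_width, "gap_width", lower = 0, strict_lower = TRUE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape)))
    stopf("`shape` must be two positive integers (rows, cols)")
  shape <- as.integer(shape)

  n_axis <- if (orientation == "vertical") shape[2L] else shape[1L]
  centers <- (seq_len(n_axis) - 0.5) * pixel_size
  period <- stripe_width + gap_width
  on_axis <- (centers %% period) < stripe_width

  # gap regions: consecutive runs of off pixels, numbered left to right
  gap_axis <- integer(n_axis)
  if (any(!on_axis)) {
    r <- rle(!on_axis)
    gid <- cumsum(r$values) * r$values
    gap_axis <- rep.int(gid, r$lengths)
  }

  if (orientation == "vertical") {
    mask <- matrix(on_axis, nrow = shape[1L], ncol = shape[2L], byrow = TRUE)
    gap_id <- matrix(gap_axis, nrow = shape[1L], ncol = shape[2L], byrow = TRUE)
  } else {
    mask <- matrix(on_axis, nrow = shape[1L], ncol = shape[2L])
    gap_id <- matrix(gap_axis, nrow = shape[1L], ncol = shape[2L])
  }

  structure(
    list(mask = mask, gap_id = gap_id,
         stripe_width = stripe_width, gap_width = gap_width,
         pixel_size = pixel_size, shape = shape, orientation = orientation),
    class = "stripe_pattern")
}

#' @export
print.stripe_pattern <- function(x, ...) {
  cat(sprintf(
    "stripe_pattern: %g um stripes / %g um gaps, %s, %d x %d px @ %g um/px (on fraction %.3f)\n",
    x$stripe_width, x$gap_width, x$orientation,
    x$shape[1L], x$shape[2L], x$pixel_size, mean(x$mask)))
  invisible(x)
}

# Gap intervals along the striping axis, as a matrix with columns
# (gap, first, last) in pixel indices. Only gaps bounded by stripes on both
# sides ("full" gaps) can host network knots.
gap_runs <- function(pattern, full_only = TRUE) {
  axis_id <- if (pattern$orientation == "vertical") pattern$gap_id[1L, ]
             else pattern$gap_id[, 1L]
  on <- axis_id == 0L
  ids <- setdiff(unique(axis_id), 0L)
  out <- do.call(rbind, lapply(ids, function(g) {
    w <- which(axis_id == g)
    c(gap = g, first = min(w), last = max(w))
  }))
  if (is.null(out)) return(matrix(numeric(0), ncol = 3))
  if (full_only) {
    n <- length(axis_id)
    keep <- out[, "first"] > 1L & out[, "last"] < n
    out <- out[keep, , drop = FALSE]
  }
  out
}
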