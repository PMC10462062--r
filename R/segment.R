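# Bundle-network segmentation: threshold -> skeletonize -> find branch
# points -> debranch & label -> dilate to fixed-width measurement masks.

# Exact Otsu criterion: scan every boundary between consecutive distinct
# intensities and maximize the between-class variance w0*w1*(mu0-mu1)^2.
# Done on raw values (no histogram quantization) so the threshold is
# shift-equivariant and matches a brute-force scan exactly.
otsu_threshold <- function(x) {
  v <- sort(as.vector(x))
  n <- length(v)
  distinct <- which(diff(v) > 0)
  if (!length(distinct)) return(NA_real_)  # constant image
  cs <- cumsum(v)
  k <- distinct                      # lower class = v[1..k]
  w0 <- k / n
  mu0 <- cs[k] / k
  mu1 <- (cs[n] - cs[k]) / (n - k)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  k_best <- k[which.max(bcv)]
  (v[k_best] + v[k_best + 1L]) / 2   # midpoint between the two classes
}

# Li's minimum cross-entropy threshold (iterative fixed point). Suits
# sparse fluorescence images whose foreground spans several intensity
# classes, where the Otsu criterion tends to cut between dim and bright
# structures instead of between background and signal.
li_threshold <- function(x) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NA_real_)
  eps <- (rng[2L] - rng[1L]) * 1e-9
  x <- x - rng[1L] + eps
  t <- mean(x)
  for (i in 1:200) {
    mb <- mean(x[x <= t]); mf <- mean(x[x > t])
    if (!is.finite(mb) || !is.finite(mf) || mb <= 0) break
    tn <- (mf - mb) / (log(mf) - log(mb))
    if (!is.finite(tn)) break
    done <- abs(tn - t) < 1e-10
    t <- tn
    if (done) break
  }
  t + rng[1L] - eps
}

#' Threshold an intensity image to a binary mask
#'
#' First stage of the network segmentation pipeline: the F-actin channel is
#' thresholded to a binary foreground mask. The mask is `image > t`.
#'
#' Automatic methods:
#' * `"otsu"` — between-class-variance maximization, computed exactly over
#'   the observed intensities (no histogram quantization).
#' * `"li"` — minimum cross-entropy. On sparse line images whose bundles
#'   span several brightness classes, Otsu often cuts between dim and
#'   bright bundles and drops the dim ones; Li cuts between background and
#'   signal.
#' * `"robust"` (pipeline default) — `max(li, median + k_mad * mad)`: Li's
#'   threshold floored at a robust background excess, so it can neither
#'   drop dim bundles (Otsu's failure mode) nor descend into the noise
#'   floor (Li's failure mode on noisy frames).
#'
#' @param image 2-D numeric matrix with finite values.
#' @param method `"otsu"`, `"li"`, `"robust"` or `"fixed"`.
#' @param threshold Threshold value, required for `method = "fixed"`.
#' @param k_mad MAD multiplier of the background floor for `"robust"`.
#' @return Logical mask with attributes `threshold` (the value used),
#'   `method`, and `constant` (`TRUE` with an all-background mask and a
#'   warning when an automatic threshold was requested on a constant
#'   image).
#' @export
binarize <- function(image, method = c("otsu", "li", "robust", "fixed"),
                     threshold = NULL, k_mad = 5) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stopf("`image` must be a finite numeric matrix")
  constant <- FALSE
  if (method == "fixed") {
    if (is.null(threshold)) stopf("`threshold` is required for method 'fixed'")
    t <- threshold
  } else {
    t <- switch(method,
                otsu = otsu_threshold(image),
                li = li_threshold(image),
                robust = max(li_threshold(image),
                             stats::median(image) + k_mad * stats::mad(image)))
    if (is.na(t)) {
      warning("constant image: automatic threshold undefined, returning empty mask")
      constant <- TRUE
    }
  }
  mask <- if (constant) matrix(FALSE, nrow(image), ncol(image)) else image > t
  structure(mask, threshold = if (constant) NA_real_ else t,
            method = method, constant = constant)
}

#' Skeletonize a binary mask
#'
#' Topology-preserving Zhang-Suen thinning to 1-pixel-wide centrelines.
#' The skeleton is a subset of the input mask and preserves its 8-connected
#' component structure.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Logical skeleton matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (!any(mask != 0)) return(out)
  # zero-padded copy; foreground tracked as linear indices so each pass
  # touches only live pixels
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- (mask != 0) + 0
  nrp <- nr + 2L
  # clockwise ring from north (p2..p9), column-major linear offsets
  offs <- c(-1L, -1L + nrp, nrp, 1L + nrp, 1L, 1L - nrp, -nrp, -1L - nrp)
  idx <- which(P == 1)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      if (!length(idx)) break
      nb <- vapply(offs, function(o) P[idx + o], numeric(length(idx)))
      if (length(idx) == 1L) nb <- matrix(nb, nrow = 1L)
      b <- rowSums(nb)
      a <- rowSums(nb[, c(1:8), drop = FALSE] <
                   nb[, c(2:8, 1L), drop = FALSE])
      cond <- if (sub == 1)
        nb[, 1L] * nb[, 3L] * nb[, 5L] == 0 &
        nb[, 3L] * nb[, 5L] * nb[, 7L] == 0
      else
        nb[, 1L] * nb[, 3L] * nb[, 7L] == 0 &
        nb[, 1L] * nb[, 5L] * nb[, 7L] == 0
      del <- which(b >= 2 & b <= 6 & a == 1 & cond)
      if (length(del)) {
        P[idx[del]] <- 0
        idx <- idx[-del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  P[2:(nr + 1L), 2:(nc + 1L)] > 0
}

#' Locate skeleton branch points
#'
#' Finds the junction pixels of a 1-pixel-wide skeleton with a 3 x 3
#' neighbourhood filter, the step that separates individual filament
#' bundle segments. The default `"crossing"` rule flags a skeleton pixel
#' when at least three distinct skeleton branches emanate from it: the
#' number of off-to-on transitions when walking the 8-neighbourhood ring
#' (the Yokoi crossing number) is >= 3. This counts a straight or corner
#' pixel as ordinary (2 branches) regardless of the diagonal staircases
#' thinning produces, so a plus-shaped skeleton yields exactly its centre.
#' `method = "count"` instead flags pixels with >= 3 on-neighbours (a raw
#' 3 x 3 neighbour-count convolution); on staircase skeletons this also
#' fires on corner pixels and is provided for comparison only.
#' Diagonally adjacent double junctions are each flagged.
#'
#' @param skel Logical skeleton matrix (see [skeletonize_mask()]).
#' @param method `"crossing"` (default) or `"count"`.
#' @return Integer matrix of branch-point coordinates (columns `row`,
#'   `col`), with the logical branch-point image as attribute `image`.
#' @export
branch_points <- function(skel, method = c("crossing", "count")) {
  method <- match.arg(method)
  stopifnot(is.matrix(skel))
  s <- (skel != 0) + 0
  if (method == "count") {
    kern <- matrix(1, 3, 3); kern[2, 2] <- 0
    nb <- EBImage::filter2(s, kern, boundary = 0)
    bp <- s > 0 & round(nb) >= 3
  } else {
    # ring neighbours clockwise from north; transitions 0 -> 1 around the
    # closed ring count the branches leaving the pixel
    ring <- list(shift_mat(s, 1, 0), shift_mat(s, 1, -1),
                 shift_mat(s, 0, -1), shift_mat(s, -1, -1),
                 shift_mat(s, -1, 0), shift_mat(s, -1, 1),
                 shift_mat(s, 0, 1), shift_mat(s, 1, 1))
    cross <- matrix(0L, nrow(s), ncol(s))
    for (i in seq_along(ring)) {
      j <- if (i == length(ring)) 1L else i + 1L
      cross <- cross + (ring[[i]] < ring[[j]])
    }
    bp <- s > 0 & cross >= 3L
  }
  coords <- which(bp, arr.ind = TRUE)
  colnames(coords) <- c("row", "col")
  structure(coords, image = bp)
}

#' Debranch a skeleton and label bundle segments
#'
#' Removes each branch point together with its surrounding guard
#' neighbourhood (Chebyshev radius `guard_px`; the default 1 is the 3 x 3
#' neighbourhood) from the skeleton and labels the remaining pieces as
#' 8-connected components — the individual debranched bundle segments.
#' The guard ring is what actually disconnects the branches: skeleton
#' pixels flanking a junction touch each other diagonally, so removing the
#' junction pixel alone leaves the arms 8-connected (a plus-shaped
#' skeleton would stay one component). A larger guard additionally keeps
#' the eventual measurement masks clear of the junction zone where the
#' blurred signals of all meeting bundles mix (see [segment_config()]).
#' Components smaller than `min_segment_px` are discarded.
#' Labels run 1..K in order of decreasing pixel count, ties broken by the
#' lexicographically smallest (row, col) pixel.
#'
#' @param skel Logical skeleton matrix.
#' @param branch_pts Output of [branch_points()] (coordinate matrix), or a
#'   logical matrix of branch pixels.
#' @param min_segment_px Minimum component size in pixels.
#' @param guard_px Chebyshev radius of the removed neighbourhood around
#'   each branch point (>= 1).
#' @return Integer label image (0 = background) with attribute `sizes`
#'   (pixel count per label).
#' @export
split_segments <- function(skel, branch_pts, min_segment_px = 5L,
                           guard_px = 1L) {
  if (guard_px < 1L) stopf("`guard_px` must be >= 1")
  s <- skel != 0
  bp <- if (is.matrix(branch_pts) && is.logical(branch_pts)) branch_pts
        else if (!is.null(attr(branch_pts, "image"))) attr(branch_pts, "image")
        else {
      b <- matrix(FALSE, nrow(s), ncol(s))
      if (length(branch_pts)) b[branch_pts[, , drop = FALSE]] <- TRUE
      b
    }
  if (any(bp)) {
    g <- as.integer(guard_px)
    kern <- matrix(1, 2L * g + 1L, 2L * g + 1L)
    guard <- EBImage::dilate(bp + 0, kern) > 0
    s[guard] <- FALSE
  }
  lab <- label_components8(s)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_segment_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_by_size(lab)
  }
  sizes <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer(0)
  structure(lab, sizes = sizes)
}

#' Dilate labelled skeletons to fixed-width measurement masks
#'
#' Each labelled segment skeleton is dilated with a disk of radius
#' `(target_width_px - 1) / 2`, producing consistent fixed-width masks
#' (5 pixels wide by default) containing the actin filament bundles.
#' Pixels claimed by two or more dilated segments are assigned to the
#' segment with the nearest skeleton pixel (Euclidean distance), ties to
#' the lower label.
#'
#' @param labels Integer label image from [split_segments()].
#' @param target_width_px Odd mask width in pixels.
#' @return Integer label image of the widened masks.
#' @export
widen <- function(labels, target_width_px = 5L) {
  if (target_width_px %% 2 == 0)
    stopf("`target_width_px` must be odd, got %d", target_width_px)
  K <- max(labels)
  if (K == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  r <- (target_width_px - 1L) %/% 2L
  if (r == 0L) return(labels + 0L)
  # sweep disk offsets in rings of increasing Euclidean distance; the first
  # ring that reaches a pixel determines its nearest skeleton distance, and
  # the minimum positive label within that ring implements the
  # ties-to-lower-label rule exactly.
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs$d2 <- offs$dr^2 + offs$dc^2
  offs <- offs[offs$d2 <= r^2, ]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (d in sort(unique(offs$d2))) {
    ring <- offs[offs$d2 == d, ]
    cand <- matrix(0L, nrow(labels), ncol(labels))
    for (i in seq_len(nrow(ring))) {
      sh <- shift_mat(labels, ring$dr[i], ring$dc[i], fill = 0L)
      take <- sh > 0L & (cand == 0L | sh < cand)
      cand[take] <- sh[take]
    }
    fill <- out == 0L & cand > 0L
    out[fill] <- cand[fill]
  }
  out
}

#' Segmentation pipeline configuration
#'
#' @param method Threshold method: `"robust"` (default), `"otsu"`, `"li"`
#'   or `"fixed"` (see [binarize()]).
#' @param threshold Fixed threshold value (when `method = "fixed"`).
#' @param min_segment_px Minimum debranched segment size in skeleton pixels.
#' @param target_width_px Width of the dilated measurement masks (odd).
#' @param junction_guard_px Chebyshev radius removed around each branch
#'   point before labelling. The default 4 keeps the 5-pixel measurement
#'   masks (dilation radius 2) clear of the ~2-pixel PSF mixing zone
#'   around a junction, so per-segment ratios are not contaminated by the
#'   other bundles meeting there.
#' @param region_mask Optional logical matrix restricting segmentation to a
#'   region (e.g. the inter-stripe gaps of a micropattern).
#' @return A `segment_config` list.
#' @export
segment_config <- function(method = "robust", threshold = NULL,
                           min_segment_px = 5L, target_width_px = 5L,
                           junction_guard_px = 4L, region_mask = NULL) {
  structure(list(method = method, threshold = threshold,
                 min_segment_px = as.integer(min_segment_px),
                 target_width_px = as.integer(target_width_px),
                 junction_guard_px = as.integer(junction_guard_px),
                 region_mask = region_mask),
            class = "segment_config")
}

#' Automated bundle-network segmentation
#'
#' Full pipeline from an F-actin intensity image to per-segment measurement
#' masks: threshold ([binarize()]), thin ([skeletonize_mask()]), find
#' branch points ([branch_points()]), debranch and label
#' ([split_segments()]), and dilate to fixed-width masks ([widen()]).
#' Deterministic: identical input and configuration give identical output.
#'
#' @param image 2-D numeric intensity image (F-actin channel).
#' @param config A [segment_config()].
#' @return A list of class `segmentation`: `labels` (debranched skeleton
#'   label image), `masks` (widened mask label image), `branch_points`,
#'   and `metadata` (threshold, counts, parameters, warning flags).
#' @export
segment_pipeline <- function(image, config = segment_config()) {
  stopifnot(inherits(config, "segment_config"))
  bin <- binarize(image, config$method, config$threshold)
  thr <- attr(bin, "threshold")
  empty <- attr(bin, "constant")
  if (!is.null(config$region_mask)) {
    stopifnot(dim(config$region_mask) == dim(image))
    bin <- bin & config$region_mask
  }
  skel <- skeletonize_mask(bin)
  bp <- branch_points(skel)
  labels <- split_segments(skel, bp, config$min_segment_px,
                           guard_px = config$junction_guard_px)
  masks <- widen(labels, config$target_width_px)
  n_seg <- max(labels)
  structure(list(
    labels = labels, masks = masks, branch_points = bp,
    metadata = list(threshold = thr, method = config$method,
                    n_segments = n_seg,
                    n_branch_points = nrow(bp),
                    min_segment_px = config$min_segment_px,
                    target_width_px = config$target_width_px,
                    empty = isTRUE(empty) || n_seg == 0L)),
    class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("segmentation: %d segment(s), %d branch point(s), threshold %s (%s)\n",
              md$n_segments, md$n_branch_points,
              format(md$threshold, digits = 4), md$method))
  invisible(x)
}
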