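# Per-segment two-channel quantification: state-window time averaging,
# ratiometric measurement, segment matching across states, fold-change
# tracking, normalization, quadrant statistics.

#' Construct state windows
#'
#' A "state" is a time window between substantive network transitions
#' (bundles breaking or changing position) over which frames are averaged
#' before measurement. Windows are half-open frame ranges `[start, stop)`
#' (1-based), must be ordered and non-overlapping.
#'
#' @param start,stop Integer vectors of window starts (inclusive) and stops
#'   (exclusive), same length.
#' @param provenance `"manual"` or `"auto"`.
#' @return A data frame of class `state_windows` with columns `state_id`,
#'   `start`, `stop`, `provenance`.
#' @export
state_windows <- function(start, stop, provenance = "manual") {
  if (length(start) != length(stop)) stopf("`start` and `stop` lengths differ")
  if (any(stop <= start)) stopf("each window needs stop > start")
  o <- order(start)
  start <- as.integer(start[o]); stop <- as.integer(stop[o])
  if (length(start) > 1L && any(start[-1L] < stop[-length(stop)]))
    stopf("state windows overlap")
  structure(data.frame(state_id = seq_along(start), start = start,
                       stop = stop, provenance = provenance),
            class = c("state_windows", "data.frame"))
}

#' Time-average a stack over a state window
#'
#' Per-pixel arithmetic mean of all frames in the half-open window
#' `[start, stop)`, computed independently per channel.
#'
#' @param stack An [image_stack()].
#' @param window One row of a [state_windows()] frame, or any list with
#'   `start` and `stop`.
#' @return Array (rows, cols, channels) of the averaged image, with channel
#'   names on the third dimension.
#' @export
time_average <- function(stack, window) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  start <- as.integer(window$start); stop <- as.integer(window$stop)
  if (length(start) != 1L || length(stop) != 1L || stop <= start)
    stopf("window must satisfy stop > start")
  if (start < 1L || stop > d[1L] + 1L)
    stopf("window [%d, %d) outside stack with %d frame(s)", start, stop, d[1L])
  frames <- start:(stop - 1L)
  out <- array(0, dim = c(d[2L], d[3L], d[4L]),
               dimnames = list(NULL, NULL, stack$channels))
  for (ci in seq_len(d[4L])) {
    sub <- stack$data[frames, , , ci, drop = FALSE]
    out[, , ci] <- apply(sub, c(2L, 3L), mean)
  }
  out
}

#' Detect state transitions from frame-to-frame change
#'
#' Automates state splitting: the mean absolute frame-to-frame difference
#' of the chosen channel is computed, and frames where it exceeds
#' `mean + z_threshold * sd` of the difference series mark window
#' boundaries. The returned windows tile the stack exhaustively and do not
#' overlap. Manual windows remain the primary route; this detector is a
#' convenience for long recordings.
#'
#' @param stack An [image_stack()] with at least 3 frames.
#' @param channel Channel used for change detection (default `"actin"`).
#' @param z_threshold Z-score cut on the difference series.
#' @return A [state_windows()] data frame with `provenance = "auto"`.
#' @export
detect_transitions <- function(stack, channel = "actin", z_threshold = 2) {
  stopifnot(inherits(stack, "image_stack"))
  T_ <- dim(stack$data)[1L]
  if (T_ < 3L) stopf("need at least 3 frames, got %d", T_)
  ci <- match(channel, stack$channels)
  if (is.na(ci)) stopf("unknown channel '%s'", channel)
  d <- vapply(seq_len(T_ - 1L), function(t)
    mean(abs(stack$data[t + 1L, , , ci] - stack$data[t, , , ci])),
    numeric(1))
  cut <- mean(d) + z_threshold * stats::sd(d)
  # d[t] compares frames t and t+1: a spike means frame t+1 starts a state
  bnd <- which(d > cut) + 1L
  starts <- unique(c(1L, bnd))
  stops <- c(starts[-1L], T_ + 1L)
  state_windows(starts, stops, provenance = "auto")
}

#' Measure per-segment channel intensities and ratios
#'
#' One row per segment mask: pixel count, mean F-actin intensity, mean ABP
#' intensity (each minus an optional channel background), and the
#' ABP : F-actin ratio of means — the canonical per-segment statistic.
#' Rows whose background-subtracted mean actin intensity is not positive
#' are flagged `valid = FALSE` and carry `ratio = NA`; exclude them from
#' ratio statistics.
#'
#' @param masks Integer label image of segment masks (e.g. the `masks`
#'   element of [segment_pipeline()] output), or a list of logical masks.
#' @param actin_img,abp_img Numeric matrices, same shape as `masks`.
#' @param state_id,region_id Identifiers copied into every row.
#' @param background Length-2 numeric `(actin, abp)` subtracted from the
#'   channel means before forming ratios.
#' @return Data frame with columns `segment_id`, `state_id`, `region_id`,
#'   `area_px`, `mean_actin`, `mean_abp`, `ratio`, `valid`.
#' @export
measure <- function(masks, actin_img, abp_img, state_id = NA, region_id = NA,
                    background = c(0, 0)) {
  if (is.list(masks)) {
    lab <- matrix(0L, nrow(masks[[1L]]), ncol(masks[[1L]]))
    for (k in seq_along(masks)) {
      if (any(lab[masks[[k]]] != 0L)) stopf("masks must be disjoint")
      lab[masks[[k]]] <- k
    }
    masks <- lab
  }
  if (!all(dim(masks) == dim(actin_img)) || !all(dim(actin_img) == dim(abp_img)))
    stopf("masks and images must share the same shape")
  background <- rep_len(background, 2L)
  K <- max(masks)
  if (K == 0L)
    return(data.frame(segment_id = integer(0), state_id = integer(0),
                      region_id = integer(0), area_px = integer(0),
                      mean_actin = numeric(0), mean_abp = numeric(0),
                      ratio = numeric(0), valid = logical(0)))
  idx <- masks > 0L
  f <- factor(masks[idx], levels = seq_len(K))
  area <- as.integer(table(f))
  mean_actin <- as.numeric(tapply(actin_img[idx], f, mean)) - background[1L]
  mean_abp <- as.numeric(tapply(abp_img[idx], f, mean)) - background[2L]
  valid <- mean_actin > 0
  ratio <- ifelse(valid, mean_abp / mean_actin, NA_real_)
  data.frame(segment_id = seq_len(K), state_id = state_id,
             region_id = region_id, area_px = area,
             mean_actin = mean_actin, mean_abp = mean_abp,
             ratio = ratio, valid = valid)
}

#' Per-pixel ABP : F-actin ratio heatmap
#'
#' Diagnostic/display companion to the per-segment ratio of means:
#' `abp / actin` per pixel inside `mask`. Pixels outside the mask, or whose
#' actin intensity does not exceed `actin_floor`, are `NA` and excluded
#' from any statistic computed on the map.
#'
#' @param actin_img,abp_img Numeric matrices of the same shape.
#' @param mask Logical matrix (or label image; nonzero = inside).
#' @param actin_floor Minimum actin intensity for a defined ratio.
#' @return Numeric matrix of per-pixel ratios (`NA` where undefined).
#' @export
ratio_image <- function(actin_img, abp_img, mask, actin_floor = 0) {
  if (!all(dim(actin_img) == dim(abp_img)) ||
      !all(dim(actin_img) == dim(mask)))
    stopf("images and mask must share the same shape")
  out <- matrix(NA_real_, nrow(actin_img), ncol(actin_img))
  ok <- (mask != 0) & actin_img > actin_floor
  out[ok] <- abp_img[ok] / actin_img[ok]
  out
}

#' Match segment labels between two label images
#'
#' Greedy maximum-IoU (intersection over union) matching between the
#' segments of two label images, e.g. the same network segmented in two
#' states. Pairs are accepted in decreasing IoU order; each label is
#' matched at most once and pairs below `min_iou` are left unmatched.
#'
#' @param labels_a,labels_b Integer label images of the same shape.
#' @param min_iou Minimum IoU for an accepted match.
#' @return Data frame with columns `label_a`, `label_b`, `iou`.
#' @export
match_segments <- function(labels_a, labels_b, min_iou = 0.5) {
  if (!all(dim(labels_a) == dim(labels_b)))
    stopf("label images must share the same shape")
  Ka <- max(labels_a); Kb <- max(labels_b)
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      iou = numeric(0))
  if (Ka == 0L || Kb == 0L) return(empty)
  both <- labels_a > 0L & labels_b > 0L
  if (!any(both)) return(empty)
  inter <- table(factor(labels_a[both], levels = seq_len(Ka)),
                 factor(labels_b[both], levels = seq_len(Kb)))
  area_a <- tabulate(labels_a[labels_a > 0L], Ka)
  area_b <- tabulate(labels_b[labels_b > 0L], Kb)
  iou <- as.matrix(inter) /
    (outer(area_a, area_b, `+`) - as.matrix(inter))
  pairs <- which(iou >= min_iou, arr.ind = TRUE)
  if (!nrow(pairs)) return(empty)
  ord <- order(iou[pairs], decreasing = TRUE)
  pairs <- pairs[ord, , drop = FALSE]
  used_a <- logical(Ka); used_b <- logical(Kb)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    if (!used_a[a] && !used_b[b]) {
      keep[i] <- TRUE; used_a[a] <- TRUE; used_b[b] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(label_a = as.integer(pairs[, 1L]),
             label_b = as.integer(pairs[, 2L]),
             iou = iou[pairs])
}

#' Maximal fold change of a tracked segment
#'
#' For a series of per-state intensities of one tracked segment, the
#' maximal fold change over the imaging period: `max(series / series[1])`.
#'
#' @param series Non-empty numeric vector, first value the baseline state.
#' @return The maximal fold change; `NA` (with a warning) when the baseline
#'   is not positive.
#' @examples
#' max_fold_change(c(2, 1, 5, 4)) # 2.5
#' @export
max_fold_change <- function(series) {
  if (!length(series)) stopf("`series` is empty")
  if (!is.finite(series[1L]) || series[1L] <= 0) {
    warning("non-positive baseline; fold change undefined")
    return(NA_real_)
  }
  max(series / series[1L])
}

#' Normalize channel intensities within trials
#'
#' Divides each intensity channel by its per-trial median so segments from
#' independent trials (different illumination/gain) can be pooled on a
#' common scale. Median normalization is robust to the bright-outlier
#' segments common in these networks.
#'
#' @param table Data frame of segment measurements with a trial identifier
#'   column.
#' @param channels Columns to normalize.
#' @param trial Name of the trial identifier column.
#' @return The table with the named channels normalized per trial.
#' @export
normalize_per_trial <- function(table, channels = c("mean_actin", "mean_abp"),
                                trial = "trial") {
  if (!trial %in% names(table)) stopf("no `%s` column in table", trial)
  if (!all(channels %in% names(table)))
    stopf("missing channel column(s): %s",
          paste(setdiff(channels, names(table)), collapse = ", "))
  for (ch in channels) {
    med <- tapply(table[[ch]], table[[trial]], stats::median, na.rm = TRUE)
    if (any(!is.finite(med)) || any(med == 0))
      stopf("trial with zero or undefined median in channel `%s`", ch)
    table[[ch]] <- table[[ch]] / as.numeric(med[as.character(table[[trial]])])
  }
  table
}

#' Small-bundle enrichment quadrant fraction
#'
#' Fraction of segments simultaneously in the top 50% of ABP intensity and
#' the bottom 50% of F-actin intensity — the operational readout of
#' force-activated enrichment on small bundles. Medians are computed over
#' the supplied table (per condition); inequalities are strict.
#'
#' @param table Segment table with at least 2 rows.
#' @param abp,actin Column names of the ABP and F-actin intensities.
#' @return List with `fraction`, the logical row indicator `in_quadrant`,
#'   and the medians used.
#' @export
quadrant_fraction <- function(table, abp = "mean_abp", actin = "mean_actin") {
  if (nrow(table) < 2L) stopf("need at least 2 rows")
  m_abp <- stats::median(table[[abp]], na.rm = TRUE)
  m_actin <- stats::median(table[[actin]], na.rm = TRUE)
  inq <- table[[abp]] > m_abp & table[[actin]] < m_actin
  list(fraction = mean(inq, na.rm = TRUE), in_quadrant = inq,
       median_abp = m_abp, median_actin = m_actin)
}
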