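#' Configuration for synthetic network generation
#'
#' Describes the ground-truth filament networks the simulator draws on a
#' stripe micropattern: star/Y-shaped assemblies whose central knot sits in
#' an inter-stripe gap while the prong endpoints anchor on the flanking
#' motor stripes. Each prong is one bundle segment with its own filament
#' count `n`; all segments of a scene share the scene's tension model.
#'
#' @param n_stars Number of star/Y assemblies per scene.
#' @param prongs_per_star Prongs (bundle segments) per assembly (>= 2).
#' @param bundle_sizes Candidate filament counts per segment.
#' @param size_probs Sampling probabilities for `bundle_sizes` (default
#'   uniform).
#' @param F_seg Total tension per segment (arbitrary units). Under the
#'   load-sharing premise motors apply a similar total force to a network
#'   segment regardless of its size, so the default applies the same
#'   `F_seg` to every segment (`F_dist = "fixed"`); `F_dist = "lognormal"`
#'   draws per-segment tensions with mean `F_seg` and log-sd `F_sdlog`.
#' @param F_dist `"fixed"` or `"lognormal"`.
#' @param F_sdlog Log-scale sd of per-segment tension for the lognormal
#'   option.
#' @param a0 F-actin photon density per pixel per filament.
#' @param binding A [binding_params()] object for the ABP channel.
#' @param margin_px Vertical margin kept free at the image border.
#' @param min_separation_px Minimum spacing (pixels) between prong endpoint
#'   anchors so rendered prongs stay resolvable after dilation to the
#'   analysis mask width.
#' @param prong_reach_px How far (pixels) endpoints extend into a stripe.
#' @param min_prong_px Minimum prong length in pixels; a gap too narrow to
#'   accommodate it is a generation error.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_stars = 2, prongs_per_star = 3,
                           bundle_sizes = 1:4, size_probs = NULL,
                           F_seg = 6, F_dist = c("fixed", "lognormal"),
                           F_sdlog = 0.6,
                           a0 = 30, binding = binding_params(k0 = 1, beta = 0.5),
                           margin_px = 8, min_separation_px = 22,
                           prong_reach_px = 5, min_prong_px = 10) {
  F_dist <- match.arg(F_dist)
  check_scalar(n_stars, "n_stars", lower = 1)
  check_scalar(prongs_per_star, "prongs_per_star", lower = 2)
  check_scalar(F_seg, "F_seg", lower = 0)
  check_scalar(a0, "a0", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(binding, "binding_params"))
  if (any(bundle_sizes < 1)) stopf("bundle sizes must be >= 1")
  if (!is.null(size_probs) && length(size_probs) != length(bundle_sizes))
    stopf("`size_probs` must match `bundle_sizes`")
  structure(list(n_stars = as.integer(n_stars),
                 prongs_per_star = as.integer(prongs_per_star),
                 bundle_sizes = bundle_sizes, size_probs = size_probs,
                 F_seg = F_seg, F_dist = F_dist, F_sdlog = F_sdlog,
                 a0 = a0, binding = binding,
                 margin_px = as.integer(margin_px),
                 min_separation_px = as.integer(min_separation_px),
                 prong_reach_px = as.integer(prong_reach_px),
                 min_prong_px = as.integer(min_prong_px)),
            class = "network_config")
}

#' Sample a ground-truth network scene on a stripe pattern
#'
#' Draws star/Y assemblies spanning the gaps of `pattern`: each assembly has
#' a knot placed inside a gap and prongs anchored on the stripes bordering
#' that gap, alternating sides so neighbouring prongs remain separated.
#' Bundle sizes are drawn from the configured distribution and per-filament
#' ABP occupancies follow the configured force-activated binding law.
#' Identical `(pattern, config, seed)` reproduce the scene exactly.
#'
#' @param pattern A [make_stripe_pattern()] object (must contain at least
#'   one gap bounded by stripes on both sides).
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return An object of class `scene_ground_truth`: `segments` (data frame
#'   with `segment_id`, `star_id`, `n`, `F_seg`, `rho`, `a0`), `paths`
#'   (list of 2-column (row, col) polylines, knot first), `knots`, `shape`,
#'   and the generating `pattern`/`config`/`seed`.
#' @export
sample_network <- function(pattern, config = network_config(), seed = 1L) {
  stopifnot(inherits(pattern, "stripe_pattern"),
            inherits(config, "network_config"))
  runs <- gap_runs(pattern, full_only = TRUE)
  if (nrow(runs) == 0L)
    stopf("pattern has no gap bounded by stripes on both sides")
  gapw <- runs[, "last"] - runs[, "first"] + 1L
  # a prong must reach from the gap centre onto a stripe
  need <- config$min_prong_px
  if (all(gapw / 2 + config$prong_reach_px < need))
    stopf("all gaps are narrower than the minimum prong length (%d px)", need)
  runs <- runs[gapw / 2 + config$prong_reach_px >= need, , drop = FALSE]

  nr <- pattern$shape[1L]; nc <- pattern$shape[2L]
  vertical <- pattern$orientation == "vertical"
  long_axis <- if (vertical) nr else nc
  sep <- config$min_separation_px
  span_per_star <- (config$prongs_per_star + 1L) * sep
  usable <- long_axis - 2L * config$margin_px
  # vertical slots per gap; stars fill gaps round-robin
  slots_per_gap <- max(1L, usable %/% span_per_star)

  with_seed(seed, {
    segs <- list(); paths <- list(); knots <- list()
    seg_id <- 0L
    for (s in seq_len(config$n_stars)) {
      g <- ((s - 1L) %% nrow(runs)) + 1L
      slot <- ((s - 1L) %/% nrow(runs)) %% slots_per_gap
      if (s > nrow(runs) * slots_per_gap)
        stopf("cannot place %d stars on this pattern without crowding",
              config$n_stars)
      gfirst <- runs[g, "first"]; glast <- runs[g, "last"]
      mid <- (gfirst + glast) / 2
      jit <- (glast - gfirst) / 8
      knot_c <- round(mid + stats::runif(1, -jit, jit))
      knot_r <- config$margin_px + slot * span_per_star +
        span_per_star / 2 + round(stats::runif(1, -sep / 4, sep / 4))
      knot_r <- min(max(knot_r, config$margin_px + 1L),
                    long_axis - config$margin_px)
      np <- config$prongs_per_star
      # symmetric fan of anchor offsets, alternating gap sides
      offs <- (seq_len(np) - (np + 1) / 2) * sep
      sides <- rep_len(c(-1L, 1L), np)
      ns <- sample(rep(config$bundle_sizes, 2L), np, replace = TRUE,
                   prob = if (is.null(config$size_probs)) NULL
                          else rep(config$size_probs, 2L))
      Fs <- switch(config$F_dist,
                   fixed = rep(config$F_seg, np),
                   lognormal = stats::rlnorm(np,
                     meanlog = log(config$F_seg) - config$F_sdlog^2 / 2,
                     sdlog = config$F_sdlog))
      for (p in seq_len(np)) {
        seg_id <- seg_id + 1L
        reach <- sample.int(config$prong_reach_px, 1L)
        end_c <- if (sides[p] < 0) gfirst - reach else glast + reach
        end_r <- round(knot_r + offs[p])
        end_r <- min(max(end_r, 2L), long_axis - 1L)
        if (vertical) {
          path <- rbind(c(knot_r, knot_c), c(end_r, end_c))
        } else {
          path <- rbind(c(knot_c, knot_r), c(end_c, end_r))
        }
        segs[[seg_id]] <- data.frame(
          segment_id = seg_id, star_id = s, n = ns[p], F_seg = Fs[p])
        paths[[seg_id]] <- path
      }
      knots[[s]] <- if (vertical) c(knot_r, knot_c) else c(knot_c, knot_r)
    }
    segments <- do.call(rbind, segs)
    segments$rho <- binding_density(config$binding, segments$n, segments$F_seg)
    segments$a0 <- config$a0
    structure(list(segments = segments, paths = paths,
                   knots = do.call(rbind, knots),
                   shape = pattern$shape, pattern = pattern,
                   config = config, seed = seed),
              class = "scene_ground_truth")
  })
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  cat(sprintf("scene_ground_truth: %d segments (%d stars) on %d x %d px\n",
              nrow(x$segments), length(unique(x$segments$star_id)),
              x$shape[1L], x$shape[2L]))
  print(utils::head(x$segments, 10))
  invisible(x)
}

# Supercover line rasterization: the set of pixels stepped through when
# walking the segment at unit-length steps along its dominant axis.
raster_line <- function(p0, p1) {
  d <- p1 - p0
  nsteps <- max(abs(d), 1)
  t <- seq(0, 1, length.out = nsteps + 1)
  px <- cbind(round(p0[1L] + t * d[1L]), round(p0[2L] + t * d[2L]))
  px[!duplicated(px), , drop = FALSE]
}

#' Rasterize a ground-truth scene to a segment label image
#'
#' Draws each segment's polyline as a 1-pixel path (path pixels shared by
#' several segments go to the lowest id) and, for `width_px > 1`, widens
#' the paths with [widen()] — every pixel within the disk radius of a path
#' is assigned to the nearest path (Euclidean, ties to the lower id),
#' matching how recovered masks are built. Used both by the renderer and
#' as the reference when scoring recovered masks against the ground truth.
#'
#' @param scene A [sample_network()] scene.
#' @param width_px Odd mask width (1 = bare path).
#' @return Integer label image (rows x cols).
#' @export
rasterize_scene <- function(scene, width_px = 1L) {
  stopifnot(inherits(scene, "scene_ground_truth"))
  if (width_px %% 2 == 0) stopf("`width_px` must be odd")
  nr <- scene$shape[1L]; nc <- scene$shape[2L]
  lab <- matrix(0L, nr, nc)
  for (i in rev(seq_along(scene$paths))) {  # lowest id wins path overlaps
    path <- scene$paths[[i]]
    px <- do.call(rbind, lapply(seq_len(nrow(path) - 1L), function(k)
      raster_line(path[k, ], path[k + 1L, ])))
    ok <- px[, 1L] >= 1 & px[, 1L] <= nr & px[, 2L] >= 1 & px[, 2L] <= nc
    lab[px[ok, , drop = FALSE]] <- scene$segments$segment_id[i]
  }
  if (width_px > 1L) lab <- widen(lab, width_px)
  lab
}
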