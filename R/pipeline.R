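# End-to-end drivers: simulate -> segment -> quantify -> compare.

#' Estimate the image background level
#'
#' Median intensity over pixels not claimed by any segment mask — a robust
#' estimate of the camera background plus unbound-fluorophore haze, used
#' to background-subtract channel means before forming ratios.
#'
#' @param image Numeric matrix.
#' @param masks Label image (nonzero = inside a segment mask).
#' @return Scalar background estimate.
#' @export
estimate_background <- function(image, masks) {
  if (!all(dim(image) == dim(masks)))
    stopf("image and masks must share the same shape")
  out <- image[masks == 0]
  if (!length(out)) return(0)
  stats::median(out)
}

#' Simulate, segment and measure a batch of scenes
#'
#' The workhorse for validation experiments: draws `n_scenes` ground-truth
#' scenes, renders each, runs the automated segmentation on the F-actin
#' channel, measures per-segment intensities and ratios
#' (background-subtracted), and annotates every recovered segment with the
#' ground-truth filament count and tension of its best-matching true prong
#' (greedy IoU matching against the rasterized truth at mask width).
#'
#' @param pattern A [make_stripe_pattern()] object.
#' @param net A [network_config()].
#' @param optics A [render_params()]; its seed is re-derived per scene.
#' @param n_scenes Number of independent scenes.
#' @param seed Base seed; scene s uses `seed + s` (network) and
#'   `seed + 100000 + s` (rendering).
#' @param seg A [segment_config()].
#' @param subtract_background Estimate and subtract per-channel background
#'   before forming ratios?
#' @param min_iou Minimum IoU for truth matching.
#' @return Data frame: one row per recovered segment with measurement
#'   columns (see [measure()]) plus `scene`, `n_true`, `F_true`, `iou`
#'   (`NA` when unmatched), and attribute `recovery` (data frame per scene:
#'   `n_truth`, `n_found`).
#' @export
simulate_measurements <- function(pattern, net = network_config(),
                                  optics = render_params(), n_scenes = 20,
                                  seed = 1L, seg = segment_config(),
                                  subtract_background = TRUE, min_iou = 0.3) {
  rows <- vector("list", n_scenes)
  rec <- data.frame(scene = seq_len(n_scenes), n_truth = 0L, n_found = 0L)
  for (s in seq_len(n_scenes)) {
    scene <- sample_network(pattern, net, seed = seed + s)
    optics$seed <- seed + 100000L + s
    stack <- render(scene, optics)
    actin <- get_channel(stack, "actin")
    abp <- get_channel(stack, "abp")
    sg <- segment_pipeline(actin, seg)
    rec$n_truth[s] <- nrow(scene$segments)
    rec$n_found[s] <- sg$metadata$n_segments
    if (sg$metadata$n_segments == 0L) next
    bg <- if (subtract_background)
      c(estimate_background(actin, sg$masks),
        estimate_background(abp, sg$masks)) else c(0, 0)
    m <- measure(sg$masks, actin, abp, state_id = 1L, region_id = NA,
                 background = bg)
    truth <- rasterize_scene(scene, width_px = seg$target_width_px)
    mm <- match_segments(sg$masks, truth, min_iou = min_iou)
    m$scene <- s
    m$n_true <- NA_real_; m$F_true <- NA_real_; m$iou <- NA_real_
    if (nrow(mm)) {
      m$n_true[mm$label_a] <- scene$segments$n[mm$label_b]
      m$F_true[mm$label_a] <- scene$segments$F_seg[mm$label_b]
      m$iou[mm$label_a] <- mm$iou
    }
    rows[[s]] <- m
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  structure(out, recovery = rec)
}

#' Fit the load-sharing binding law to segment ratios
#'
#' Under the generative law the per-segment ABP : F-actin ratio is
#' `rho(n) / a0 = k0/a0 + (k0 * beta * F / a0) / n`, linear in `1/n`.
#' Regressing measured ratios on the reciprocal ground-truth (or
#' intensity-estimated) bundle size therefore recovers the force-coupled
#' amplitude `k0 * beta * F / a0` as the slope and the mass-action
#' baseline `k0 / a0` as the intercept.
#'
#' @param table Output of [simulate_measurements()] (uses rows with
#'   `valid` and a matched `n_true`).
#' @return The [linfit()] list for ratio ~ 1/n.
#' @export
fit_ratio_vs_inverse_n <- function(table) {
  ok <- table$valid & is.finite(table$ratio) & is.finite(table$n_true)
  linfit(1 / table$n_true[ok], table$ratio[ok])
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate (optional) -> segment -> quantify -> compare for each
#' configured condition and writes all outputs: per-condition segment
#' tables (CSV), an example label image and ratio heatmap (TIFF), a JSON
#' report of headline statistics (quadrant fractions, regressions, Welch
#' comparison of the first two conditions), and the resolved configuration.
#' Identical configurations produce identical outputs.
#'
#' @param config Nested list (see [read_run_config()]) with elements
#'   `seed`, `pattern` (arguments of [make_stripe_pattern()]),
#'   `simulate` (arguments of [render_params()] plus `n_scenes`),
#'   `segmentation` (arguments of [segment_config()]), and `conditions`:
#'   a named list, each entry either simulation overrides for
#'   [network_config()] (e.g. `beta`, `k0`, `F_seg`, `F_dist`) or
#'   `stack` (TIFF path read with [read_stack()]) with optional `frame`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  pat_args <- config$pattern %||% list(stripe_width = 2.5, gap_width = 17.5,
                                       pixel_size = 0.25, shape = c(160, 160))
  pattern <- do.call(make_stripe_pattern, pat_args)
  seg_cfg <- do.call(segment_config, config$segmentation %||% list())
  sim <- config$simulate %||% list()
  n_scenes <- sim$n_scenes %||% 10L
  sim$n_scenes <- NULL
  optics <- do.call(render_params, sim)

  if (is.null(config$conditions) || !length(config$conditions))
    stopf("config needs a named `conditions` list")
  report <- list(seed = seed, conditions = list())
  tables <- list()
  for (cname in names(config$conditions)) {
    cond <- config$conditions[[cname]]
    if (!is.null(cond$stack)) {
      stack <- read_stack(cond$stack,
                          channel_map = unlist(cond$channel_map %||%
                                                 c(actin = 1L, abp = 2L)))
      frame <- cond$frame %||% 1L
      actin <- get_channel(stack, "actin", frame)
      abp <- get_channel(stack, "abp", frame)
      sg <- segment_pipeline(actin, seg_cfg)
      bg <- c(estimate_background(actin, sg$masks),
              estimate_background(abp, sg$masks))
      tab <- measure(sg$masks, actin, abp, state_id = frame,
                     region_id = NA, background = bg)
      tab$scene <- 1L
    } else {
      net_args <- cond
      net_args$binding <- binding_params(k0 = cond$k0 %||% 1,
                                         beta = cond$beta %||% 0)
      net_args$k0 <- NULL; net_args$beta <- NULL
      net <- do.call(network_config, net_args)
      tab <- simulate_measurements(pattern, net, optics,
                                   n_scenes = n_scenes, seed = seed,
                                   seg = seg_cfg)
    }
    tables[[cname]] <- tab
    write_table_csv(tab, file.path(out_dir, sprintf("segments_%s.csv", cname)),
                    schema = "segment_measurements")
    ok <- tab$valid & is.finite(tab$ratio)
    qf <- if (sum(ok) >= 2L) quadrant_fraction(tab[ok, ]) else NULL
    lf <- if (sum(ok) >= 3L)
      linfit(tab$mean_actin[ok], tab$mean_abp[ok]) else NULL
    report$conditions[[cname]] <- list(
      n_segments = nrow(tab),
      mean_ratio = mean(tab$ratio[ok]),
      quadrant_fraction = qf$fraction,
      regression = lf)
  }
  if (length(tables) >= 2L) {
    nm <- names(tables)[1:2]
    ra <- tables[[nm[1L]]]; rb <- tables[[nm[2L]]]
    report$welch_ratio <- c(list(conditions = nm),
      welch_test(ra$ratio[ra$valid], rb$ratio[rb$valid]))
  }
  resolved <- config
  resolved$pattern <- pat_args
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
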