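#' Rendering parameters for the synthetic TIRF acquisition
#'
#' Controls how a ground-truth scene is turned into a noisy two-channel
#' image stack: Gaussian point-spread blur, camera gain, constant
#' background, Poisson shot noise followed by additive Gaussian read noise,
#' and per-frame geometric photobleaching. Frames are acquired every
#' `frame_interval` seconds (2 s by default, the acquisition cadence the
#' simulator emulates).
#'
#' @param psf_sigma PSF standard deviation in pixels (>= 0; 0 disables
#'   blurring).
#' @param background Background level in photons per pixel.
#' @param gain Photons per intensity unit of the ground-truth densities.
#' @param read_noise_sigma Gaussian read noise sd in photons (0 disables).
#' @param bleach_rate_per_frame Per-frame bleached fraction, one value per
#'   channel (recycled); signal in frame t is scaled by
#'   `(1 - rate)^(t - 1)`.
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param shot_noise Apply Poisson shot noise? Set `FALSE` (with
#'   `read_noise_sigma = 0`) for noiseless expected images.
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical stack.
#' @return An object of class `render_params`.
#' @export
render_params <- function(psf_sigma = 1, background = 10, gain = 2,
                          read_noise_sigma = 2,
                          bleach_rate_per_frame = c(actin = 0, abp = 0),
                          frame_interval = 2, n_frames = 1,
                          shot_noise = TRUE, seed = 1L) {
  check_scalar(psf_sigma, "psf_sigma", lower = 0)
  check_scalar(background, "background", lower = 0)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar(read_noise_sigma, "read_noise_sigma", lower = 0)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", lower = 1)
  bl <- rep_len(bleach_rate_per_frame, 2L)
  if (any(bl < 0) || any(bl >= 1))
    stopf("`bleach_rate_per_frame` must be in [0, 1)")
  structure(list(psf_sigma = psf_sigma, background = background, gain = gain,
                 read_noise_sigma = read_noise_sigma,
                 bleach_rate_per_frame = bl,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 shot_noise = isTRUE(shot_noise), seed = as.integer(seed)),
            class = "render_params")
}

#' Construct an image stack container
#'
#' @param data Numeric array with dimensions (frames, rows, cols, channels).
#' @param channels Channel names, e.g. `c("actin", "abp")`.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval Seconds between frames.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channels = c("actin", "abp"),
                        pixel_size = 1, frame_interval = 2) {
  if (length(dim(data)) != 4L)
    stopf("`data` must be a 4-D array (frames, rows, cols, channels)")
  if (dim(data)[4L] != length(channels))
    stopf("channel names do not match the 4th array dimension")
  structure(list(data = data, channels = channels,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frame(s), %d x %d px, channels [%s], %g um/px, dt = %g s\n",
              d[1L], d[2L], d[3L], paste(x$channels, collapse = ", "),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Extract one channel frame from a stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index.
#' @param frame Frame index (1-based).
#' @return A numeric matrix.
#' @export
get_channel <- function(stack, channel, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ci <- if (is.character(channel)) match(channel, stack$channels)
        else as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > length(stack$channels))
    stopf("unknown channel '%s'", as.character(channel))
  if (frame < 1L || frame > dim(stack$data)[1L]) stopf("frame out of range")
  stack$data[frame, , , ci]
}

# Noiseless expected photon densities (before gain/background), one matrix
# per channel. Actin density on a segment path is n * a0; ABP density is
# n * rho(n); overlapping segments add.
scene_expected_densities <- function(scene) {
  nr <- scene$shape[1L]; nc <- scene$shape[2L]
  e_actin <- matrix(0, nr, nc)
  e_abp <- matrix(0, nr, nc)
  for (i in seq_along(scene$paths)) {
    path <- scene$paths[[i]]
    px <- do.call(rbind, lapply(seq_len(nrow(path) - 1L), function(k)
      raster_line(path[k, ], path[k + 1L, ])))
    px <- px[!duplicated(px), , drop = FALSE]
    ok <- px[, 1L] >= 1 & px[, 1L] <= nr & px[, 2L] >= 1 & px[, 2L] <= nc
    px <- px[ok, , drop = FALSE]
    n <- scene$segments$n[i]
    e_actin[px] <- e_actin[px] + n * scene$segments$a0[i]
    e_abp[px] <- e_abp[px] + n * scene$segments$rho[i]
  }
  list(actin = e_actin, abp = e_abp)
}

#' Render a scene to a two-channel image stack
#'
#' Produces the simulated acquisition of a ground-truth scene. Segment
#' paths are rasterized at constant per-pixel density (`n * a0` for the
#' F-actin channel, `n * rho(n)` for the ABP channel; overlaps add), then
#' per frame: Gaussian PSF blur, multiplication by gain and the cumulative
#' bleaching factor, background addition, Poisson shot noise, and Gaussian
#' read noise. With blurring and noise disabled, on-path pixel values equal
#' `density * gain + background` exactly.
#'
#' @param scene A [sample_network()] scene (non-empty).
#' @param render A [render_params()] object.
#' @return An [image_stack()] with channels `c("actin", "abp")`.
#' @export
render <- function(scene, render = render_params()) {
  stopifnot(inherits(scene, "scene_ground_truth"),
            inherits(render, "render_params"))
  if (nrow(scene$segments) == 0L) stopf("scene has no segments")
  dens <- scene_expected_densities(scene)
  nr <- scene$shape[1L]; nc <- scene$shape[2L]
  base <- lapply(dens, function(e) {
    if (render$psf_sigma > 0) e <- ebi_gblur(e, render$psf_sigma)
    e * render$gain
  })
  out <- array(0, dim = c(render$n_frames, nr, nc, 2L))
  with_seed(render$seed, {
    for (t in seq_len(render$n_frames)) {
      for (ci in 1:2) {
        fade <- (1 - render$bleach_rate_per_frame[ci])^(t - 1)
        img <- base[[ci]] * fade + render$background
        if (render$shot_noise)
          img <- matrix(stats::rpois(length(img), lambda = pmax(img, 0)),
                        nr, nc)
        if (render$read_noise_sigma > 0)
          img <- img + matrix(stats::rnorm(length(img), 0,
                                           render$read_noise_sigma), nr, nc)
        out[t, , , ci] <- img
      }
    }
  })
  image_stack(out, channels = c("actin", "abp"),
              pixel_size = scene$pattern$pixel_size,
              frame_interval = render$frame_interval)
}

# Separable Gaussian blur with circular (mass-preserving) boundaries,
# as cached band-matrix products: B_rows %*% m %*% B_cols. Much faster
# than FFT filtering at these image sizes when called thousands of times.
blur_cache <- new.env(parent = emptyenv())

gauss_band <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(blur_cache[[key]])) return(blur_cache[[key]])
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- ((seq_len(n) - 1L + off) %% n) + 1L
    B[cbind(seq_len(n), idx)] <- B[cbind(seq_len(n), idx)] + k[j]
  }
  blur_cache[[key]] <- B
  B
}

ebi_gblur <- function(m, sigma) {
  gauss_band(nrow(m), sigma) %*% m %*% t(gauss_band(ncol(m), sigma))
}
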