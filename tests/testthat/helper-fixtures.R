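# Shared fixtures: small patterns, configurations and toy images built in
# code at test time.

test_pattern <- function(shape = c(160, 192)) {
  make_stripe_pattern(2.5, 17.5, pixel_size = 0.25, shape = shape)
}

test_net <- function(beta = 0.5, ...) {
  network_config(n_stars = 2, prongs_per_star = 3,
                 binding = binding_params(k0 = 1, beta = beta), ...)
}

# compact pattern/network pair for cheap IO and smoke tests: 80 x 80 px
# with two full gaps
small_pattern <- function(shape = c(80, 80)) {
  make_stripe_pattern(2.5, 12.5, pixel_size = 0.5, shape = shape)
}

small_net <- function(...) {
  network_config(n_stars = 1, prongs_per_star = 3, margin_px = 6,
                 min_separation_px = 10, min_prong_px = 6, ...)
}

noiseless_optics <- function(...) {
  render_params(psf_sigma = 1, background = 0, gain = 2,
                read_noise_sigma = 0, shot_noise = FALSE, ...)
}

noisy_optics <- function(...) {
  render_params(psf_sigma = 1, background = 10, gain = 2,
                read_noise_sigma = 2, shot_noise = TRUE, ...)
}

# a hand-built scene: one knot with straight prongs, bypassing the sampler
manual_scene <- function(paths, n, pattern, F_seg = 6,
                         binding = binding_params(k0 = 1, beta = 0.5),
                         a0 = 30) {
  rho <- binding_density(binding, n, F_seg)
  structure(list(
    segments = data.frame(segment_id = seq_along(paths), star_id = 1L,
                          n = n, F_seg = F_seg, rho = rho, a0 = a0),
    paths = paths,
    knots = matrix(paths[[1]][1, ], nrow = 1),
    shape = pattern$shape, pattern = pattern,
    config = NULL, seed = NA_integer_),
    class = "scene_ground_truth")
}

# random blob mask: union of a few filled rectangles and discs
random_blob_mask <- function(nr = 40, nc = 40, n_shapes = 3) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_shapes)) {
    if (stats::runif(1) < 0.5) {
      r0 <- sample(5:(nr - 10), 1); c0 <- sample(5:(nc - 10), 1)
      m[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- TRUE
    } else {
      rc <- sample(8:(nr - 8), 1); cc <- sample(8:(nc - 8), 1)
      rad <- sample(2:5, 1)
      d <- outer(seq_len(nr), seq_len(nc),
                 function(a, b) (a - rc)^2 + (b - cc)^2)
      m[d <= rad^2] <- TRUE
    }
  }
  m
}

# independent nested-loop oracle for junction detection
brute_branch_points <- function(skel, method = c("crossing", "count")) {
  method <- match.arg(method)
  nr <- nrow(skel); nc <- ncol(skel)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && skel[r, c]
  out <- matrix(FALSE, nr, nc)
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    vals <- vapply(ring, function(d) at(r + d[1], c + d[2]), logical(1))
    if (method == "count") {
      out[r, c] <- sum(vals) >= 3
    } else {
      trans <- sum(!vals & vals[c(2:8, 1)])
      out[r, c] <- trans >= 3
    }
  }
  out
}
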