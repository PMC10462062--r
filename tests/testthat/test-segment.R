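test_that("thresholding separates well-separated intensity classes", {
  img <- matrix(0, 20, 20); img[5:10, 5:15] <- 100
  m <- binarize(img, "otsu")
  expect_identical(m[, ], img == 100)
  expect_true(attr(m, "threshold") > 0 && attr(m, "threshold") < 100)

  img2 <- matrix(c(40, 60), 10, 10)
  m2 <- binarize(img2, "fixed", threshold = 50)
  expect_identical(m2[, ], img2 > 50)
})

test_that("otsu threshold matches a brute-force between-class-variance scan", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(c(rnorm(300, 10, 2), rnorm(100, 40, 4)), 20, 20)
    m <- binarize(x, "otsu")
    t_pkg <- attr(m, "threshold")
    # oracle: scan every midpoint between consecutive sorted values
    v <- sort(as.vector(x)); n <- length(v)
    best <- -Inf; t_best <- NA
    for (k in 1:(n - 1)) {
      if (v[k] == v[k + 1]) next
      w0 <- k / n
      bcv <- w0 * (1 - w0) * (mean(v[1:k]) - mean(v[(k + 1):n]))^2
      if (bcv > best) { best <- bcv; t_best <- (v[k] + v[k + 1]) / 2 }
    }
    expect_equal(t_pkg, t_best, tolerance = 1e-12)
    # threshold falls strictly between the two mode means
    expect_gt(t_pkg, 10); expect_lt(t_pkg, 40)
  }
})

test_that("automatic thresholds are shift-equivariant so masks are offset-invariant", {
  set.seed(33)
  x <- matrix(c(rnorm(300, 5, 1), rnorm(100, 25, 2)), 20, 20)
  for (method in c("otsu", "li", "robust")) {
    m0 <- binarize(x, method)
    m1 <- binarize(x + 137.5, method)
    expect_identical(m0[, ], m1[, ])
    expect_equal(attr(m1, "threshold") - attr(m0, "threshold"), 137.5,
                 tolerance = 1e-6)
  }
})

test_that("a constant image yields an empty mask with a warning flag", {
  img <- matrix(3, 10, 10)
  expect_warning(m <- binarize(img, "otsu"), "constant")
  expect_false(any(m))
  expect_true(attr(m, "constant"))
})

test_that("robust threshold keeps dim bundles over a dominant dark background", {
  # dominant dark background; bundle brightnesses span a 4-fold range,
  # as they do when sizes run 1-4 filaments
  img <- matrix(0, 60, 60)
  img[20, 10:50] <- 25    # dim bundle
  img[40, 10:50] <- 100   # bright bundle
  set.seed(7)
  img <- img + matrix(rnorm(3600, 0, 0.2), 60, 60)
  mr <- binarize(img, "robust")
  expect_true(all(mr[20, 10:50]))
  expect_true(all(mr[40, 10:50]))
  expect_lt(mean(mr), 0.05)  # background stays background
})

test_that("thinning reduces a ribbon to its one-pixel centreline", {
  bar <- matrix(FALSE, 11, 24); bar[4:8, 3:22] <- TRUE
  sk <- skeletonize_mask(bar)
  px <- which(sk, arr.ind = TRUE)
  expect_identical(unique(px[, 1]), 6L)          # middle row only
  expect_true(all(sk <= bar))                    # skeleton within mask
  expect_identical(skeletonize_mask(matrix(FALSE, 5, 5)),
                   matrix(FALSE, 5, 5))
})

test_that("thinning preserves the component structure of random blobs", {
  set.seed(99)
  for (i in 1:15) {
    m <- random_blob_mask()
    sk <- skeletonize_mask(m)
    expect_true(all(sk <= m))
    n_before <- max(bundlemech:::label_components8(m))
    n_after <- max(bundlemech:::label_components8(sk))
    expect_equal(n_after, n_before)
  }
})

test_that("junction detection matches the nested-loop oracle on random skeletons", {
  set.seed(12)
  for (i in 1:200) {
    sk <- skeletonize_mask(random_blob_mask(30, 30, sample(2:4, 1)))
    for (method in c("crossing", "count")) {
      got <- attr(branch_points(sk, method = method), "image")
      expect_identical(got, brute_branch_points(sk, method = method))
    }
  }
})

test_that("a plus-shaped skeleton has exactly one junction, a line none", {
  p <- matrix(FALSE, 9, 9); p[5, 2:8] <- TRUE; p[2:8, 5] <- TRUE
  bp <- branch_points(p)
  expect_equal(nrow(bp), 1)
  expect_equal(as.vector(bp), c(5, 5))
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_equal(nrow(branch_points(line)), 0)
})

test_that("debranching splits the canonical shapes into their arms", {
  # Y: three arms meeting at (10, 10)
  y <- matrix(FALSE, 20, 20)
  for (d in 0:8) { y[10 - d, 10] <- TRUE; y[10 + d, 10 - d] <- TRUE
                   y[10 + d, 10 + d] <- TRUE }
  lab <- split_segments(y, branch_points(y), min_segment_px = 1)
  expect_equal(max(lab), 3)

  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_equal(max(split_segments(line, branch_points(line), 1)), 1)

  p <- matrix(FALSE, 11, 11); p[6, 2:10] <- TRUE; p[2:10, 6] <- TRUE
  expect_equal(max(split_segments(p, branch_points(p), 1)), 4)
})

test_that("labels partition the guarded skeleton and order by size", {
  set.seed(61)
  for (i in 1:10) {
    sk <- skeletonize_mask(random_blob_mask(35, 35))
    bp <- branch_points(sk)
    lab <- split_segments(sk, bp, min_segment_px = 1)
    # no pixel outside the skeleton; labels contiguous from 1
    expect_true(all(sk[lab > 0]))
    K <- max(lab)
    if (K > 0) {
      sizes <- tabulate(lab[lab > 0], K)
      expect_true(all(diff(sizes) <= 0))   # descending
      expect_identical(sort(unique(as.vector(lab))), c(0L, seq_len(K)))
      # removed area is exactly the guard neighbourhood of branch points
      bpim <- attr(bp, "image")
      guard <- EBImage::dilate(bpim + 0, matrix(1, 3, 3)) > 0
      expect_identical(lab > 0, sk & !guard)
    }
  }
})

test_that("size filtering discards components below the minimum", {
  m <- matrix(FALSE, 20, 20)
  m[3, 3:12] <- TRUE          # 10 px
  m[10, 3:5] <- TRUE          # 3 px
  lab <- split_segments(m, branch_points(m), min_segment_px = 5)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 10)
})

test_that("widening produces fixed-width masks split at the midline", {
  line <- matrix(0L, 15, 30); line[8, 4:27] <- 1L
  w <- widen(line, 5)
  counts <- colSums(w[, 6:25] == 1L)
  expect_true(all(counts == 5))

  expect_identical(widen(line, 1), line + 0L)
  expect_error(widen(line, 4), "odd")

  # two parallel skeletons 3 px apart share the midline by proximity
  two <- matrix(0L, 15, 30); two[7, 4:27] <- 1L; two[10, 4:27] <- 2L
  w2 <- widen(two, 5)
  expect_true(all(w2[8, 6:25] == 1L))   # nearer to label 1
  expect_true(all(w2[9, 6:25] == 2L))   # nearer to label 2
  expect_false(any(w2 == 1L & w2 == 2L))
  expect_true(all(w2[5:6, 6:25] == 1L) && all(w2[11:12, 6:25] == 2L))
})

test_that("widening ties go to the lower label", {
  two <- matrix(0L, 11, 20); two[4, 3:18] <- 1L; two[8, 3:18] <- 2L
  w <- widen(two, 5)
  expect_true(all(w[6, 5:16] == 1L))  # equidistant row
})

test_that("the full pipeline recovers a rendered star and is deterministic", {
  pat <- test_pattern()
  net <- network_config(n_stars = 1, prongs_per_star = 3)
  sc <- sample_network(pat, net, seed = 23)
  img <- get_channel(render(sc, noiseless_optics()), "actin")
  sg1 <- segment_pipeline(img)
  sg2 <- segment_pipeline(img)
  expect_identical(sg1$masks, sg2$masks)
  expect_equal(sg1$metadata$n_segments, 3)
  truth <- rasterize_scene(sc, 5)
  mm <- match_segments(sg1$masks, truth, min_iou = 0.5)
  expect_equal(nrow(mm), 3)
})

test_that("a blank image passes through the pipeline with a warning flag", {
  expect_warning(sg <- segment_pipeline(matrix(0, 30, 30)), "constant")
  expect_equal(sg$metadata$n_segments, 0)
  expect_true(sg$metadata$empty)
  expect_equal(nrow(measure(sg$masks, matrix(0, 30, 30), matrix(0, 30, 30))), 0)
})
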