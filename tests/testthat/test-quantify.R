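make_stack <- function(frames_actin, frames_abp = frames_actin) {
  T_ <- length(frames_actin)
  d <- dim(frames_actin[[1]])
  arr <- array(0, c(T_, d[1], d[2], 2))
  for (t in seq_len(T_)) {
    arr[t, , , 1] <- frames_actin[[t]]
    arr[t, , , 2] <- frames_abp[[t]]
  }
  image_stack(arr)
}

test_that("time averaging is the per-pixel mean over the half-open window", {
  f1 <- matrix(1, 5, 5); f3 <- matrix(3, 5, 5)
  st <- make_stack(list(f1, f3))
  avg <- time_average(st, list(start = 1, stop = 3))
  expect_equal(avg[, , "actin"], matrix(2, 5, 5))
  one <- time_average(st, list(start = 2, stop = 3))
  expect_equal(one[, , "actin"], f3)
  expect_error(time_average(st, list(start = 2, stop = 2)), "stop > start")
  expect_error(time_average(st, list(start = 1, stop = 9)), "outside")
})

test_that("mean of the average equals the mean of per-frame means", {
  set.seed(3)
  fr <- lapply(1:4, function(i) matrix(runif(36), 6, 6))
  st <- make_stack(fr)
  avg <- time_average(st, list(start = 1, stop = 5))
  expect_equal(mean(avg[, , "actin"]), mean(vapply(fr, mean, 1)))
})

test_that("transition detection finds an abrupt scene change", {
  set.seed(8)
  a <- matrix(runif(100), 10, 10)
  b <- matrix(runif(100) + 5, 10, 10)
  frames <- c(replicate(4, a + matrix(rnorm(100, 0, 0.01), 10, 10),
                        simplify = FALSE),
              replicate(4, b + matrix(rnorm(100, 0, 0.01), 10, 10),
                        simplify = FALSE))
  st <- make_stack(frames)
  w <- detect_transitions(st, z_threshold = 1.5)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(1L, 5L))
  # windows tile the stack
  expect_equal(w$stop[nrow(w)], 9L)
  expect_true(all(w$start[-1] == w$stop[-nrow(w)]))
})

test_that("a constant stack yields a single all-covering window", {
  st <- make_stack(replicate(5, matrix(1, 4, 4), simplify = FALSE))
  w <- detect_transitions(st)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$stop), c(1L, 6L))
})

test_that("per-segment measurement forms the ratio of channel means", {
  masks <- matrix(0L, 10, 10); masks[2:4, 2:8] <- 1L; masks[7:9, 2:8] <- 2L
  actin <- matrix(10, 10, 10); abp <- matrix(5, 10, 10)
  tab <- measure(masks, actin, abp)
  expect_equal(tab$ratio, c(0.5, 0.5))
  expect_equal(tab$area_px, c(21L, 21L))

  # proportional channels give the proportionality constant everywhere
  set.seed(4)
  a2 <- matrix(runif(100, 1, 5), 10, 10)
  tab2 <- measure(masks, a2, 2 * a2)
  expect_equal(tab2$ratio, c(2, 2))

  expect_error(measure(masks, actin, matrix(0, 9, 9)), "shape")
})

test_that("non-positive actin means are flagged and carry no ratio", {
  masks <- matrix(0L, 6, 6); masks[2, 2:4] <- 1L; masks[5, 2:4] <- 2L
  actin <- matrix(0, 6, 6); actin[5, ] <- 10
  abp <- matrix(1, 6, 6)
  tab <- measure(masks, actin, abp)
  expect_false(tab$valid[1]); expect_true(is.na(tab$ratio[1]))
  expect_true(tab$valid[2]); expect_equal(tab$ratio[2], 0.1)
})

test_that("segment ratios order by bundle size under force-activated binding", {
  pat <- test_pattern(c(100, 80))
  bind <- binding_params(k0 = 1, beta = 0.5)
  sc <- manual_scene(list(rbind(c(30, 30), c(30, 55)),
                          rbind(c(70, 30), c(70, 55))),
                     n = c(1, 4), pat, F_seg = 8, binding = bind)
  st <- render(sc, noiseless_optics())
  actin <- get_channel(st, "actin"); abp <- get_channel(st, "abp")
  sg <- segment_pipeline(actin)
  tab <- measure(sg$masks, actin, abp)
  truth <- rasterize_scene(sc, 5)
  mm <- match_segments(sg$masks, truth, 0.5)
  r1 <- tab$ratio[mm$label_a[mm$label_b == 1]]
  r4 <- tab$ratio[mm$label_a[mm$label_b == 2]]
  expect_gt(r1, r4)
  expect_equal(r1 / r4, binding_density(bind, 1, 8) /
                 binding_density(bind, 4, 8), tolerance = 0.05)
})

test_that("ratio heatmaps match a per-pixel loop oracle", {
  set.seed(9)
  actin <- matrix(runif(64, 0.5, 2), 8, 8)
  abp <- matrix(runif(64), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[2:6, 3:7] <- TRUE
  h <- ratio_image(actin, abp, mask)
  oracle <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8)
    if (mask[i, j] && actin[i, j] > 0) oracle[i, j] <- abp[i, j] / actin[i, j]
  expect_equal(h, oracle)
  expect_equal(mean(h, na.rm = TRUE), mean(oracle, na.rm = TRUE))

  expect_equal(ratio_image(actin, 2 * actin, mask)[mask],
               rep(2, sum(mask)))
  empty <- ratio_image(actin, abp, matrix(FALSE, 8, 8))
  expect_true(all(is.na(empty)))
})

test_that("the actin floor masks unreliable ratio pixels", {
  actin <- matrix(c(0.01, 10), 4, 4)
  abp <- matrix(1, 4, 4)
  h <- ratio_image(actin, abp, matrix(TRUE, 4, 4), actin_floor = 1)
  expect_true(all(is.na(h[actin <= 1])))
  expect_true(all(is.finite(h[actin > 1])))
})

test_that("segment matching is greedy on IoU and one-to-one", {
  lab <- matrix(0L, 12, 20); lab[3:7, 4:13] <- 1L
  mm <- match_segments(lab, lab)
  expect_equal(mm$iou, 1)
  shifted <- matrix(0L, 12, 20); shifted[3:7, 5:14] <- 1L
  mm2 <- match_segments(lab, shifted, min_iou = 0.5)
  expect_equal(nrow(mm2), 1)
  expect_equal(mm2$iou, 45 / 55)  # 5x9 overlap over 2*50 - 45 union
  disjoint <- matrix(0L, 12, 20); disjoint[9:11, 15:19] <- 1L
  expect_equal(nrow(match_segments(lab, disjoint)), 0)
})

test_that("fold change is measured against the first state", {
  expect_equal(max_fold_change(c(1, 2, 3)), 3)
  expect_equal(max_fold_change(c(4, 4, 4)), 1)
  expect_equal(max_fold_change(c(2, 1, 5, 4)), 2.5)
  expect_warning(fc <- max_fold_change(c(0, 2)), "baseline")
  expect_true(is.na(fc))
})

test_that("per-trial normalization is scale-invariant with unit medians", {
  set.seed(14)
  tab <- data.frame(trial = rep(c("a", "b"), each = 30),
                    mean_actin = c(runif(30, 10, 50), runif(30, 30, 150)),
                    mean_abp = c(runif(30, 1, 5), runif(30, 3, 15)))
  norm <- normalize_per_trial(tab)
  med <- tapply(norm$mean_actin, norm$trial, median)
  expect_equal(as.vector(med), c(1, 1))
  scaled <- tab
  scaled$mean_actin <- scaled$mean_actin * 7
  expect_equal(normalize_per_trial(scaled)$mean_actin, norm$mean_actin)
  bad <- data.frame(trial = "a", mean_actin = c(0, 0, 0), mean_abp = 1)
  expect_error(normalize_per_trial(bad), "median")
})

test_that("quadrant fraction counts discordant segments against the medians", {
  tab <- data.frame(mean_actin = 1:4, mean_abp = 4:1)
  q <- quadrant_fraction(tab)
  expect_equal(q$fraction, 0.5)
  expect_equal(sum(q$in_quadrant), 2)
  conc <- data.frame(mean_actin = 1:10, mean_abp = (1:10)^2)
  expect_equal(quadrant_fraction(conc)$fraction, 0)
  expect_error(quadrant_fraction(tab[1, , drop = FALSE]), "2 rows")
})

test_that("quadrant fraction sits near independence for force-blind binding", {
  # equal bundle sizes, beta = 0: channels differ only by symmetric noise
  set.seed(30)
  fr <- replicate(40, {
    n <- 60
    actin <- rnorm(n, 100, 10)
    abp <- 0.1 * 100 + rnorm(n, 0, 1)  # independent of actin's noise
    quadrant_fraction(data.frame(mean_actin = actin, mean_abp = abp))$fraction
  })
  expect_equal(mean(fr), 0.25, tolerance = 0.03)
})
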