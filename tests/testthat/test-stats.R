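test_that("line fits recover exact linear relationships", {
  x <- c(0, 1, 2, 3, 4.5)
  f <- linfit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r, 1, tolerance = 1e-12)

  fc <- linfit(x, rep(3, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r, 0)

  expect_error(linfit(rep(1, 5), 1:5), "variance")
  expect_error(linfit(1:2, 1:2), "3 finite points")
})

test_that("line fit matches the normal-equation closed form", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(0.7, 2.1, 1.9, 3.2, 3.0)
  f <- linfit(x, y)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(f$slope, sl, tolerance = 1e-12)
  expect_equal(f$intercept, ic, tolerance = 1e-12)
  expect_equal(f$r, r, tolerance = 1e-12)
})

test_that("welch statistic matches the closed-form hand computation", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_test(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(t_hand, df_hand), tolerance = 1e-12)

  set.seed(2)
  x <- rnorm(20); y <- rnorm(15, 1, 2)
  w2 <- welch_test(x, y)
  se2 <- var(x) / 20 + var(y) / 15
  expect_equal(w2$t, (mean(x) - mean(y)) / sqrt(se2), tolerance = 1e-12)
  expect_equal(w2$df,
               se2^2 / ((var(x) / 20)^2 / 19 + (var(y) / 15)^2 / 14),
               tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1; degenerate groups error", {
  g <- c(1, 2, 3, 4)
  w <- welch_test(g, g)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welch_test(c(1, 1), c(1, 1)), "variance")
  expect_error(welch_test(1, c(1, 2)), "2 finite values")
})

test_that("paired region comparison reports deltas and excludes unmatched keys", {
  pre <- data.frame(region_id = rep(1:3, each = 4),
                    ratio = rep(c(0.2, 0.3, 0.4), each = 4),
                    mean_actin = rep(c(10, 20, 30), each = 4))
  post <- pre
  pc0 <- paired_compare(pre, post)
  expect_equal(pc0$deltas$d_ratio, rep(0, 3))
  expect_equal(pc0$deltas$d_actin, rep(0, 3))

  post$ratio <- post$ratio + 0.1
  pc1 <- paired_compare(pre, post)
  expect_equal(pc1$deltas$d_ratio, rep(0.1, 3), tolerance = 1e-12)

  post2 <- post[post$region_id != 3, ]
  post2$region_id[post2$region_id == 2] <- 9
  pc2 <- paired_compare(pre, post2)
  expect_setequal(pc2$unmatched, c("2", "3", "9"))
  expect_equal(nrow(pc2$deltas), 1)
})

test_that("force-activated binding raises the ratio after ATP more than a dead mutant", {
  # paired fields: pre = no force (beta irrelevant), post = motors on.
  # FL responds to load; the force-blind variant does not.
  k0 <- 1; beta_fl <- 0.5; a0 <- 30
  sim_table <- function(beta, seed) {
    set.seed(seed)
    do.call(rbind, lapply(1:6, function(reg) {
      n <- sample(1:4, 8, replace = TRUE)
      F_seg <- rlnorm(8, log(6) - 0.18, 0.6)
      rho <- binding_density(binding_params(k0 = k0, beta = beta), n, F_seg)
      actin <- n * a0 * (1 + rnorm(8, 0, 0.05))
      abp <- n * rho * (1 + rnorm(8, 0, 0.05))
      data.frame(region_id = reg, ratio = abp / actin, mean_actin = actin)
    }))
  }
  wins <- 0
  for (r in 1:40) {
    pre_fl <- sim_table(0, 100 + r); post_fl <- sim_table(beta_fl, 200 + r)
    pre_dc <- sim_table(0, 300 + r); post_dc <- sim_table(0, 400 + r)
    d_fl <- paired_compare(pre_fl, post_fl)$summary$mean_d_ratio
    d_dc <- paired_compare(pre_dc, post_dc)$summary$mean_d_ratio
    if (d_fl > d_dc) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})
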