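test_that("RGB track speed is mean frame-to-frame displacement over time", {
  tr <- data.frame(timestamp = c(0, 1), x_m = c(0, 3), y_m = c(0, 4))
  expect_equal(rgb_track_speed(tr)$mean_speed, 5)
  tr <- data.frame(timestamp = 0:5, x_m = rep(1, 6), y_m = rep(2, 6))
  expect_equal(rgb_track_speed(tr)$mean_speed, 0)
  # constant 4.1 m/s straight track, zero noise: exact recovery
  ts <- seq(0, 2, by = 1 / 30)
  tr <- data.frame(timestamp = ts, x_m = 4.1 * ts, y_m = 0)
  expect_equal(rgb_track_speed(tr)$mean_speed, 4.1, tolerance = 1e-12)
  expect_equal(rgb_track_speed(tr, stride = 5)$mean_speed, 4.1,
               tolerance = 1e-12)
  expect_error(rgb_track_speed(tr[1, ]), "insufficient")
  tr$timestamp[2] <- 0
  expect_error(rgb_track_speed(tr), "strictly increasing")
})

test_that("TIR spacing speed averages per-increment spacing over time", {
  pr <- data.frame(print_id = 1:2, timestamp = c(0, 5),
                   x_m = c(0, 10), y_m = 0)
  est <- tir_spacing_speed(pr)
  expect_equal(est$mean_speed, 2)
  expect_equal(est$mean_spacing, 10)
  pr <- data.frame(print_id = 1:3, timestamp = c(0, 5, 10),
                   x_m = c(0, 8, 20), y_m = 0)
  est <- tir_spacing_speed(pr)
  expect_equal(est$mean_speed, 2) # (8/5 + 12/5) / 2
  expect_equal(est$mean_spacing, 10)
  expect_equal(est$n_increments, 2)
  expect_error(tir_spacing_speed(pr[1, ]), "insufficient")
  pr$timestamp[2] <- 0
  expect_error(tir_spacing_speed(pr), "strictly increasing")
})

test_that("increments spanning a print_id gap are excluded", {
  pr <- data.frame(print_id = c(1L, 2L, 4L), timestamp = c(0, 5, 15),
                   x_m = c(0, 10, 40), y_m = 0)
  est <- tir_spacing_speed(pr)
  expect_equal(est$n_increments, 1)
  expect_equal(est$mean_speed, 2)
})

test_that("event pairing is an inner join with duplicate keys rejected", {
  rgb <- data.frame(whale_id = "W1", event_id = paste0("E", 1:5),
                    mean_speed = 1:5)
  tir <- data.frame(whale_id = "W1", event_id = paste0("E", 3:7),
                    mean_speed = 6:10, mean_spacing = 2)
  expect_message(p <- pair_events(rgb, tir), "unpaired")
  expect_equal(nrow(p), 3)
  expect_equal(p$event_id, paste0("E", 3:5))
  expect_true("mean_spacing" %in% names(p))
  expect_error(pair_events(rbind(rgb, rgb[1, ]), tir), "duplicate")
  tir2 <- tir; tir2$event_id <- paste0("X", 1:5)
  expect_warning(p2 <- pair_events(rgb, tir2), "no shared")
  expect_equal(nrow(p2), 0)
})

test_that("agreement statistics handle perfect and offset agreement", {
  p <- data.frame(rgb_speed = c(1, 1.5, 2, 2.5), tir_speed = c(1, 1.5, 2, 2.5))
  a <- agreement_stats(p)
  expect_equal(a$bias, 0)
  expect_equal(c(a$loa_low, a$loa_high), c(0, 0))
  expect_equal(a$rmse, 0)
  expect_equal(a$mae, 0)
  expect_equal(a$icc_a1, 1)
  expect_equal(a$pct_within_half, 100)
  expect_equal(a$pct_within_one, 100)

  p$tir_speed <- p$rgb_speed - 0.5 # constant RGB - TIR offset of +0.5
  a <- agreement_stats(p)
  expect_equal(a$bias, 0.5)
  expect_equal(a$sd_differences, 0)
  expect_lt(a$icc_a1, 1) # absolute agreement penalises the offset
})

test_that("agreement battery matches a spreadsheet-style recomputation", {
  p <- data.frame(rgb_speed = c(1, 2, 1.5), tir_speed = c(1.2, 1.9, 1.4))
  a <- agreement_stats(p)
  d <- p$rgb_speed - p$tir_speed
  expect_equal(a$bias, mean(d))
  expect_equal(a$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(a$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(a$rmse, sqrt(mean(d^2)))
  expect_equal(a$mae, mean(abs(d)))
  expect_equal(a$nrmse, sqrt(mean(d^2)) / mean(p$rgb_speed))
  expect_equal(a$mape, mean(abs(d / p$rgb_speed)) * 100)
  expect_equal(a$median_mape, median(abs(d / p$rgb_speed)) * 100)
  tt <- t.test(p$rgb_speed, p$tir_speed, paired = TRUE)
  expect_equal(a$paired_t, unname(tt$statistic))
  expect_equal(a$paired_t_p, tt$p.value)
  pb <- lm(d ~ I((p$rgb_speed + p$tir_speed) / 2))
  expect_equal(a$prop_bias_slope, unname(coef(pb)[2]))
  expect_true(a$mae <= a$rmse)
})

test_that("ICC(A,1) reproduces a hand-computed two-way ANOVA on five pairs", {
  x <- c(1.0, 1.4, 2.0, 2.6, 3.0)
  y <- c(1.2, 1.3, 2.2, 2.4, 3.3)
  a <- agreement_stats(data.frame(rgb_speed = x, tir_speed = y))
  # two-way ANOVA by explicit sums of squares: 5 subjects x 2 raters
  dat <- c(x, y)
  subj <- rep(1:5, 2); rater <- rep(1:2, each = 5)
  grand <- mean(dat)
  ssr <- 2 * sum((tapply(dat, subj, mean) - grand)^2)
  ssc <- 5 * sum((tapply(dat, rater, mean) - grand)^2)
  sse <- sum((dat - grand)^2) - ssr - ssc
  msr <- ssr / 4; msc <- ssc / 1; mse <- sse / 4
  icc_hand <- (msr - mse) / (msr + mse + (2 / 5) * (msc - mse))
  expect_equal(a$icc_a1, icc_hand, tolerance = 1e-12)
})

test_that("Deming regression recovers exact lines and matches a grid search", {
  x <- c(1, 2, 3, 4, 5)
  f <- deming_regression(x, x)
  expect_equal(f$slope, 1, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  f <- deming_regression(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_error(deming_regression(x, rep(2, 5)), "degenerate")

  set.seed(17)
  xs <- runif(40, 0.5, 3); ys <- 0.8 * xs + 0.3 + rnorm(40, 0, 0.15)
  xo <- xs + rnorm(40, 0, 0.15)
  fit <- deming_regression(xo, ys, lambda = 1)
  # independent oracle: grid search over (slope, intercept) minimising
  # lambda-weighted orthogonal squared distance
  obj <- function(b) {
    sum((ys - b[2] - b[1] * xo)^2 / (1 + b[1]^2))
  }
  grid <- expand.grid(slope = seq(fit$slope - 0.1, fit$slope + 0.1, 5e-4),
                      intercept = seq(fit$intercept - 0.1,
                                      fit$intercept + 0.1, 5e-4))
  vals <- apply(grid, 1, obj)
  best <- grid[which.min(vals), ]
  expect_equal(fit$slope, best$slope, tolerance = 1e-3)
  expect_equal(fit$intercept, best$intercept, tolerance = 1e-3)
})

test_that("speed estimates are invariant to rigid motions of the world frame", {
  set.seed(23)
  ts <- seq(0, 3, by = 0.2)
  tr <- data.frame(timestamp = ts, x_m = 1.2 * ts + rnorm(length(ts), 0, 0.05),
                   y_m = 0.5 * ts + rnorm(length(ts), 0, 0.05))
  base <- rgb_track_speed(tr)$mean_speed
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(tr[c("x_m", "y_m")]) %*% R
  tr2 <- data.frame(timestamp = ts, x_m = xy[, 1] + 50, y_m = xy[, 2] - 20)
  expect_equal(rgb_track_speed(tr2)$mean_speed, base, tolerance = 1e-12)

  pr <- data.frame(print_id = 1:4, timestamp = c(0, 4, 8, 12),
                   x_m = c(0, 5, 11, 16), y_m = c(0, 1, 1.5, 2.5))
  base <- tir_spacing_speed(pr)$mean_speed
  xy <- as.matrix(pr[c("x_m", "y_m")]) %*% R
  pr2 <- pr; pr2$x_m <- xy[, 1] - 7; pr2$y_m <- xy[, 2] + 3
  expect_equal(tir_spacing_speed(pr2)$mean_speed, base, tolerance = 1e-12)
})

test_that("swapping sensor roles negates bias but preserves error magnitudes", {
  set.seed(29)
  p <- data.frame(rgb_speed = runif(20, 0.8, 1.6))
  p$tir_speed <- p$rgb_speed + rnorm(20, 0.1, 0.2)
  a <- agreement_stats(p)
  b <- agreement_stats(data.frame(rgb_speed = p$tir_speed,
                                  tir_speed = p$rgb_speed))
  expect_equal(b$bias, -a$bias)
  expect_equal(b$prop_bias_slope, -a$prop_bias_slope)
  expect_equal(b$rmse, a$rmse)
  expect_equal(b$mae, a$mae)
  expect_equal(b$icc_a1, a$icc_a1)
})
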