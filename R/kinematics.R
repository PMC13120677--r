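#' Mean swimming speed from an RGB rostrum track
#'
#' Frame-to-frame Euclidean displacement of the rostrum landmark divided by
#' elapsed time, averaged over consecutive frame pairs within a surfacing
#' event. A frame stride > 1 computes displacements over every `stride`-th
#' frame, trading temporal resolution for annotation-noise suppression.
#'
#' @param track Data frame with columns `timestamp` (seconds, strictly
#'   increasing), `x_m`, `y_m` (world metres), and optionally `whale_id`,
#'   `event_id`.
#' @param stride Positive integer frame stride (default 1, i.e. native
#'   frame rate).
#' @return An object of class `speed_estimate` with fields `whale_id`,
#'   `event_id`, `method = "rgb_track"`, `mean_speed`, `n_increments`,
#'   `stride`.
#' @export
rgb_track_speed <- function(track, stride = 1L) {
  track <- as.data.frame(track)
  stopifnot(all(c("timestamp", "x_m", "y_m") %in% names(track)))
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  o <- order(track$timestamp)
  track <- track[o, ]
  if (nrow(track) < stride + 1) {
    stop("insufficient data: need at least stride + 1 tracked positions",
         call. = FALSE)
  }
  if (any(diff(track$timestamp) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  i <- seq(1, nrow(track) - stride, by = stride)
  j <- i + stride
  dt <- track$timestamp[j] - track$timestamp[i]
  dd <- sqrt((track$x_m[j] - track$x_m[i])^2 + (track$y_m[j] - track$y_m[i])^2)
  speeds <- dd / dt
  structure(
    list(whale_id = track$whale_id[1] %||% NA,
         event_id = track$event_id[1] %||% NA,
         method = "rgb_track",
         mean_speed = mean(speeds),
         n_increments = length(speeds),
         stride = stride),
    class = "speed_estimate")
}

#' Mean swimming speed from thermal flukeprint spacing
#'
#' Distance between centroids of successive flukeprints along a linear
#' trajectory divided by the corresponding time interval; increment speeds
#' are averaged per event, and the mean inter-centroid spacing is recorded
#' for the spacing-to-speed model. Degraded prints are retained (movement
#' analysis keeps them); increments spanning a gap in the sequential
#' `print_id` are excluded because only successive prints define spacing.
#'
#' @param prints Data frame with columns `print_id` (sequential integers),
#'   `timestamp` (seconds), `x_m`, `y_m`, and optionally `whale_id`,
#'   `event_id`, `degraded`.
#' @return A `speed_estimate` with `method = "tir_spacing"`, `mean_speed`,
#'   `mean_spacing`, `n_increments`.
#' @export
tir_spacing_speed <- function(prints) {
  prints <- as.data.frame(prints)
  stopifnot(all(c("print_id", "timestamp", "x_m", "y_m") %in% names(prints)))
  prints <- prints[order(prints$print_id), ]
  if (nrow(prints) < 2) {
    stop("insufficient data: need at least 2 flukeprints", call. = FALSE)
  }
  if (any(diff(prints$timestamp) <= 0)) {
    stop("print timestamps must be strictly increasing", call. = FALSE)
  }
  consecutive <- diff(prints$print_id) == 1
  if (!any(consecutive)) {
    stop("insufficient data: no consecutive print pairs", call. = FALSE)
  }
  i <- which(consecutive); j <- i + 1
  sp <- sqrt((prints$x_m[j] - prints$x_m[i])^2 +
             (prints$y_m[j] - prints$y_m[i])^2)
  dt <- prints$timestamp[j] - prints$timestamp[i]
  structure(
    list(whale_id = prints$whale_id[1] %||% NA,
         event_id = prints$event_id[1] %||% NA,
         method = "tir_spacing",
         mean_speed = mean(sp / dt),
         mean_spacing = mean(sp),
         n_increments = length(sp)),
    class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("Speed estimate [%s] whale %s event %s: %.3f m/s over %d increments\n",
              x$method, x$whale_id, x$event_id, x$mean_speed, x$n_increments))
  if (!is.null(x$mean_spacing)) {
    cat(sprintf("  mean flukeprint spacing: %.3f m\n", x$mean_spacing))
  }
  invisible(x)
}

#' Pair per-event speed estimates across sensors
#'
#' Inner join of RGB and TIR event tables on `(whale_id, event_id)`;
#' unpaired events are dropped with a message. Duplicate keys in either
#' table are an error because an event must contribute one estimate per
#' sensor.
#'
#' @param rgb,tir Data frames with columns `whale_id`, `event_id`,
#'   `mean_speed` (TIR may carry `mean_spacing`).
#' @return Data frame with columns `whale_id`, `event_id`, `rgb_speed`,
#'   `tir_speed`, and `mean_spacing` when available.
#' @export
pair_events <- function(rgb, tir) {
  rgb <- as.data.frame(rgb); tir <- as.data.frame(tir)
  stopifnot(all(c("whale_id", "event_id", "mean_speed") %in% names(rgb)),
            all(c("whale_id", "event_id", "mean_speed") %in% names(tir)))
  krgb <- paste(rgb$whale_id, rgb$event_id, sep = "\r")
  ktir <- paste(tir$whale_id, tir$event_id, sep = "\r")
  if (anyDuplicated(krgb) || anyDuplicated(ktir)) {
    stop("duplicate (whale_id, event_id) keys in speed tables", call. = FALSE)
  }
  shared <- intersect(krgb, ktir)
  if (length(shared) == 0) {
    warning("no shared surfacing events between RGB and TIR tables")
  }
  n_un <- (length(krgb) - length(shared)) + (length(ktir) - length(shared))
  if (n_un > 0) message(n_un, " unpaired event(s) dropped")
  i <- match(shared, krgb); j <- match(shared, ktir)
  out <- data.frame(whale_id = rgb$whale_id[i], event_id = rgb$event_id[i],
                    rgb_speed = rgb$mean_speed[i], tir_speed = tir$mean_speed[j],
                    stringsAsFactors = FALSE)
  if ("mean_spacing" %in% names(tir)) out$mean_spacing <- tir$mean_spacing[j]
  out
}

#' Method-agreement battery for paired speed estimates
#'
#' Bland--Altman bias and 95% limits of agreement, RMSE, MAE, normalised
#' RMSE (scaled by the mean RGB speed), MAPE and median MAPE (relative to
#' RGB), ICC(A,1) (two-way random effects, absolute agreement, single
#' measure, with its 95% CI), a paired t-test, proportional bias
#' (regression of differences on pair means), and the percentage of pairs
#' within 0.5 and 1.0 m/s. Differences are oriented RGB - TIR, the RGB
#' channel being the visual reference.
#'
#' @param pairs Paired table from [pair_events()] (columns `rgb_speed`,
#'   `tir_speed`).
#' @return An object of class `agreement_report`.
#' @export
agreement_stats <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("rgb_speed", "tir_speed") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 paired events", call. = FALSE)
  x <- pairs$rgb_speed; y <- pairs$tir_speed
  d <- x - y
  bias <- mean(d); sdd <- stats::sd(d)
  ci <- bias + c(-1, 1) * stats::qt(0.975, n - 1) * sdd / sqrt(n)
  rmse <- sqrt(mean(d^2)); mae <- mean(abs(d))
  nz <- x != 0
  if (any(!nz)) warning(sum(!nz), " pair(s) with zero RGB speed excluded from MAPE")
  ape <- abs(d[nz] / x[nz]) * 100
  # paired t is undefined for constant differences (zero variance)
  tt <- tryCatch(stats::t.test(x, y, paired = TRUE),
                 error = function(e) list(statistic = NA_real_,
                                          parameter = n - 1,
                                          p.value = NA_real_))
  means <- (x + y) / 2
  pb <- stats::lm(d ~ means)
  pb_sum <- suppressWarnings(summary(pb))$coefficients
  pb_slope <- if ("means" %in% rownames(pb_sum)) {
    c(pb_sum["means", "Estimate"], pb_sum["means", "Pr(>|t|)"])
  } else c(NA_real_, NA_real_)
  icc <- icc_a1(x, y)
  structure(
    list(n_pairs = n,
         bias = bias, bias_ci = ci,
         loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
         sd_differences = sdd,
         rmse = rmse, mae = mae,
         nrmse = rmse / mean(x),
         mape = mean(ape), median_mape = stats::median(ape),
         n_mape = sum(nz),
         icc_a1 = icc$icc, icc_ci = icc$ci,
         paired_t = unname(tt$statistic), paired_t_df = unname(tt$parameter),
         paired_t_p = tt$p.value,
         prop_bias_slope = unname(pb_slope[1]),
         prop_bias_p = unname(pb_slope[2]),
         pct_within_half = 100 * mean(abs(d) <= 0.5),
         pct_within_one = 100 * mean(abs(d) <= 1.0)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Speed agreement over %d paired surfacing events (RGB - TIR)\n",
              x$n_pairs))
  cat(sprintf("  bias %.3f m/s (95%% CI %.3f to %.3f), LoA [%.3f, %.3f]\n",
              x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high))
  cat(sprintf("  RMSE %.3f, MAE %.3f, nRMSE %.3f, MAPE %.1f%%, median MAPE %.1f%%\n",
              x$rmse, x$mae, x$nrmse, x$mape, x$median_mape))
  cat(sprintf("  ICC(A,1) %.3f (95%% CI %.3f-%.3f)\n",
              x$icc_a1, x$icc_ci[1], x$icc_ci[2]))
  cat(sprintf("  paired t = %.3f (df %d, p = %.3g); proportional bias slope %.3f (p = %.3g)\n",
              x$paired_t, x$paired_t_df, x$paired_t_p,
              x$prop_bias_slope, x$prop_bias_p))
  cat(sprintf("  %.1f%% within 0.5 m/s, %.1f%% within 1.0 m/s\n",
              x$pct_within_half, x$pct_within_one))
  invisible(x)
}

# ICC(A,1): two-way random effects, absolute agreement, single measure
# (McGraw & Wong). k = 2 raters (sensors), n subjects (events).
icc_a1 <- function(x, y) {
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # CI by the McGraw-Wong F-based interval
  a <- (k * icc) / (n * (1 - icc)); b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(0.975, n - 1, v)
  f_u <- stats::qf(0.975, v, n - 1)
  lo <- (n * (msr - f_l * mse)) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- (n * (f_u * msr - mse)) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (!is.finite(lo)) lo <- NA_real_
  if (!is.finite(hi)) hi <- NA_real_
  list(icc = icc, ci = c(lo, hi),
       ms = c(rows = msr, cols = msc, error = mse))
}

#' Deming (errors-in-variables) regression
#'
#' Closed-form Deming fit assuming a known ratio `lambda` of the y to x
#' error variances (default 1, equal variances):
#' \deqn{\hat\beta_1 = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}}}
#' with intercept \eqn{\bar y - \hat\beta_1 \bar x}. Standard errors are
#' leave-one-out jackknife; Wald tests compare the slope with 1 and the
#' intercept with 0, the calibration hypotheses for method comparison.
#'
#' @param x,y Paired measurements, length >= 3.
#' @param lambda Error variance ratio (> 0).
#' @return An object of class `deming_fit` with slope, intercept, their
#'   jackknife SEs, and `slope_test` / `intercept_test` (z, p).
#' @export
deming_regression <- function(x, y, lambda = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired samples of equal length >= 3", call. = FALSE)
  }
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  est <- unname(deming_coefficients(x, y, lambda))
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) {
    deming_coefficients(x[-i], y[-i], lambda)
  }, numeric(2))
  se <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  z_slope <- (est[1] - 1) / se[1]
  z_int <- est[2] / se[2]
  structure(
    list(slope = est[1], intercept = est[2],
         slope_se = se[1], intercept_se = se[2],
         lambda = lambda, n = n,
         slope_test = list(z = z_slope, p = 2 * stats::pnorm(-abs(z_slope)),
                           null = 1),
         intercept_test = list(z = z_int, p = 2 * stats::pnorm(-abs(z_int)),
                               null = 0)),
    class = "deming_fit")
}

deming_coefficients <- function(x, y, lambda) {
  sxx <- mean((x - mean(x))^2)
  syy <- mean((y - mean(y))^2)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  if (sxy == 0) {
    stop("degenerate Deming fit: zero covariance between methods", call. = FALSE)
  }
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g, n = %d)\n", x$lambda, x$n))
  cat(sprintf("  slope %.4f +/- %.4f (H0 slope = 1: z = %.3f, p = %.3g)\n",
              x$slope, x$slope_se, x$slope_test$z, x$slope_test$p))
  cat(sprintf("  intercept %.4f +/- %.4f (H0 intercept = 0: z = %.3f, p = %.3g)\n",
              x$intercept, x$intercept_se, x$intercept_test$z,
              x$intercept_test$p))
  invisible(x)
}

#' Per-event speed tables from an annotation table
#'
#' Convenience extraction: runs [rgb_track_speed()] on each event's RGB
#' rostrum track and [tir_spacing_speed()] on each event's TIR print
#' centroid sequence, returning one-row-per-event data frames suitable for
#' [pair_events()]. Events with too few positions or prints are skipped
#' with a message.
#'
#' @param annotations Annotation table.
#' @param stride Frame stride for the RGB track speeds.
#' @return List with data frames `rgb` and `tir`.
#' @export
event_speeds <- function(annotations, stride = 1L) {
  an <- as.data.frame(annotations)
  ros <- an[an$record_type == "rostrum" & an$sensor == "RGB", ]
  rgb <- est_by_event(ros, function(d) rgb_track_speed(d, stride = stride))
  cen <- an[an$record_type == "print_centroid" & an$sensor == "TIR", ]
  tir <- est_by_event(cen, tir_spacing_speed)
  list(rgb = rgb, tir = tir)
}

est_by_event <- function(d, f) {
  if (nrow(d) == 0) {
    return(data.frame(whale_id = character(), event_id = character(),
                      mean_speed = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(d, paste(d$whale_id, d$event_id, sep = "\r")), function(g) {
    est <- tryCatch(f(g), error = function(e) {
      message("event skipped (", g$whale_id[1], "/", g$event_id[1], "): ",
              conditionMessage(e))
      NULL
    })
    if (is.null(est)) return(NULL)
    row <- data.frame(whale_id = est$whale_id, event_id = est$event_id,
                      mean_speed = est$mean_speed,
                      n_increments = est$n_increments,
                      stringsAsFactors = FALSE)
    if (!is.null(est$mean_spacing)) row$mean_spacing <- est$mean_spacing
    row
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
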