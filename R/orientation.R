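#' Compass bearing between two world points
#'
#' Bearing of the vector `from -> to` on the 0--360 degree geographic
#' compass scale (0 = north, 90 = east), with world coordinates in local
#' east-north metres. This is the bearing of a flukeprint's
#' posterior-to-anterior axis (thermal channel) or of a whale's
#' tail-to-rostrum body axis (RGB channel).
#'
#' @param from,to Numeric length-2 world points (east, north) in metres.
#' @return Bearing in degrees, in `[0, 360)`.
#' @examples
#' bearing_from_points(c(0, 0), c(1, 0)) # due east: 90
#' @export
bearing_from_points <- function(from, to) {
  from <- as.numeric(from); to <- as.numeric(to)
  if (length(from) != 2 || length(to) != 2 ||
      !all(is.finite(c(from, to)))) {
    stop("points must be finite length-2 coordinates", call. = FALSE)
  }
  d <- to - from
  if (all(d == 0)) {
    stop("undefined bearing: points are coincident", call. = FALSE)
  }
  deg <- atan2(d[1], d[2]) * 180 / pi # atan2(east, north)
  (deg + 360) %% 360
}

#' Wrapped angular difference
#'
#' Difference `a - b` wrapped to the half-open interval `(-180, 180]`
#' degrees, the convention used for paired heading differences. The
#' antipodal case maps to +180.
#'
#' @param a,b Angles in degrees (vectorised).
#' @return Wrapped differences in degrees.
#' @export
wrap_difference <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("angles must be finite", call. = FALSE)
  }
  d <- ((a - b + 180) %% 360) - 180
  d[d == -180] <- 180
  d
}

#' Circular summary of a sample of angles
#'
#' Resultant-vector summary statistics for directional data: circular mean,
#' mean resultant length \eqn{\bar{R}}, circular standard deviation
#' \eqn{\sqrt{-2\ln\bar{R}}} (reported in both radians and degrees), and
#' the Rayleigh test of uniformity. The Rayleigh p-value uses Zar's
#' small-sample refinement
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R_v^2)} - (1 + 2n))} with
#' \eqn{R_v = n\bar{R}}; the large-sample \eqn{e^{-Z}} value is also
#' reported for comparison.
#'
#' @param angles Angles in degrees, length >= 1 (Rayleigh test needs >= 2).
#' @return An object of class `circular_summary` with fields `n`,
#'   `circ_mean` (degrees, `NA` and `mean_defined = FALSE` when the
#'   resultant vanishes), `resultant_length`, `circ_sd_rad`, `circ_sd_deg`,
#'   `rayleigh_Z`, `rayleigh_p` (Zar), `rayleigh_p_asymptotic`.
#' @export
circular_summary <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 1 || !all(is.finite(angles))) {
    stop("need at least one finite angle", call. = FALSE)
  }
  n <- length(angles)
  rad <- angles * pi / 180
  C <- mean(cos(rad)); S <- mean(sin(rad))
  rbar <- sqrt(C^2 + S^2)
  mean_defined <- rbar > .Machine$double.eps^0.5
  circ_mean <- if (mean_defined) (atan2(S, C) * 180 / pi + 360) %% 360 else NA_real_
  sd_rad <- if (rbar > 0) sqrt(-2 * log(min(rbar, 1))) else Inf
  Z <- n * rbar^2
  Rv <- n * rbar
  p_zar <- if (n >= 2) {
    exp(sqrt(1 + 4 * n + 4 * (n^2 - Rv^2)) - (1 + 2 * n))
  } else NA_real_
  structure(
    list(n = n, circ_mean = circ_mean, mean_defined = mean_defined,
         resultant_length = rbar,
         circ_sd_rad = sd_rad, circ_sd_deg = sd_rad * 180 / pi,
         rayleigh_Z = Z,
         rayleigh_p = min(1, p_zar),
         rayleigh_p_asymptotic = exp(-Z)),
    class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d)\n", x$n))
  cat(sprintf("  mean %.2f deg, Rbar %.4f, SD %.2f deg (%.4f rad)\n",
              x$circ_mean, x$resultant_length, x$circ_sd_deg, x$circ_sd_rad))
  cat(sprintf("  Rayleigh Z = %.3f, p = %.4g\n", x$rayleigh_Z, x$rayleigh_p))
  invisible(x)
}

#' Fisher--Lee circular correlation between paired angle samples
#'
#' \deqn{r = \frac{\sum \sin(a_i - \bar a)\sin(b_i - \bar b)}
#'   {\sqrt{\sum \sin^2(a_i - \bar a)\sum \sin^2(b_i - \bar b)}}}
#' with \eqn{\bar a, \bar b} the circular means. Significance uses the
#' standard asymptotic normal test (Jammalamadaka--SenGupta form).
#'
#' @param a,b Paired angles in degrees, equal lengths >= 3.
#' @return List with `r`, `test_statistic`, `p_value`, `n`.
#' @export
circular_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3) {
    stop("need paired samples of equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("angles must be finite", call. = FALSE)
  }
  n <- length(a)
  ar <- a * pi / 180; br <- b * pi / 180
  abar <- atan2(mean(sin(ar)), mean(cos(ar)))
  bbar <- atan2(mean(sin(br)), mean(cos(br)))
  sa <- sin(ar - abar); sb <- sin(br - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) {
    warning("zero circular variance in one series; correlation undefined")
    return(list(r = NA_real_, test_statistic = NA_real_,
                p_value = NA_real_, n = n, defined = FALSE))
  }
  r <- sum(sa * sb) / den
  # asymptotic test: sqrt(n * lam22 / (lam02 * lam20)) * r ~ N(0,1)
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  stat <- if (l22 > 0) sqrt(n * l20 * l02 / l22) * r else NA_real_
  p <- if (is.finite(stat)) 2 * stats::pnorm(-abs(stat)) else NA_real_
  list(r = r, test_statistic = stat, p_value = p, n = n, defined = TRUE)
}

#' Build the paired-heading table from an annotation table
#'
#' Extracts thermal flukeprint headings (posterior -> anterior edge vectors
#' from the TIR sensor) and RGB body-axis headings (tail -> rostrum),
#' pairs them by whale, surfacing event and flukeprint id, and computes
#' wrapped TIR - RGB differences. RGB body-axis records without a
#' `print_id` are paired with every print of the same event (the body axis
#' is one reference per event); per-print RGB tail records take precedence
#' when present.
#'
#' @param annotations Annotation table as returned by [read_annotations()]
#'   or [simulate_tracks_and_prints()].
#' @return Data frame with columns `whale_id`, `event_id`, `print_id`,
#'   `tir_heading`, `rgb_heading`, `difference` (degrees, `(-180, 180]`).
#' @export
heading_pairs <- function(annotations) {
  an <- as.data.frame(annotations)
  need <- c("record_type", "whale_id", "event_id", "sensor")
  if (!all(need %in% names(an))) {
    stop("annotation table lacks required columns: ",
         paste(setdiff(need, names(an)), collapse = ", "), call. = FALSE)
  }
  post <- an[an$record_type == "print_posterior" & an$sensor == "TIR", ]
  ant  <- an[an$record_type == "print_anterior" & an$sensor == "TIR", ]
  key <- function(d) paste(d$whale_id, d$event_id, d$print_id, sep = "\r")
  m <- match(key(post), key(ant))
  post <- post[!is.na(m), ]; ant <- ant[m[!is.na(m)], ]
  if (nrow(post) == 0) return(empty_heading_pairs())
  tir_heading <- vapply(seq_len(nrow(post)), function(i) {
    bearing_from_points(c(post$x_m[i], post$y_m[i]),
                        c(ant$x_m[i], ant$y_m[i]))
  }, numeric(1))
  tir <- data.frame(whale_id = post$whale_id, event_id = post$event_id,
                    print_id = post$print_id, tir_heading = tir_heading,
                    stringsAsFactors = FALSE)

  tail_r <- an[an$record_type == "tail" & an$sensor == "RGB", ]
  rost <- an[an$record_type == "rostrum" & an$sensor == "RGB", ]
  ekey <- function(d, ts = TRUE) {
    k <- paste(d$whale_id, d$event_id, sep = "\r")
    if (ts && "timestamp" %in% names(d)) paste(k, d$timestamp, sep = "\r") else k
  }
  m <- match(ekey(tail_r), ekey(rost))
  tail_r <- tail_r[!is.na(m), ]; rost <- rost[m[!is.na(m)], ]
  if (nrow(tail_r) == 0) return(empty_heading_pairs())
  rgb_heading <- vapply(seq_len(nrow(tail_r)), function(i) {
    bearing_from_points(c(tail_r$x_m[i], tail_r$y_m[i]),
                        c(rost$x_m[i], rost$y_m[i]))
  }, numeric(1))
  # one RGB reference heading per event: circular mean over frames
  rgb_ev <- data.frame(whale_id = tail_r$whale_id, event_id = tail_r$event_id,
                       rgb_heading = rgb_heading, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(rgb_ev, paste(rgb_ev$whale_id, rgb_ev$event_id, sep = "\r")),
    function(d) {
      data.frame(whale_id = d$whale_id[1], event_id = d$event_id[1],
                 rgb_heading = circular_summary(d$rgb_heading)$circ_mean,
                 stringsAsFactors = FALSE)
    }))
  m <- match(paste(tir$whale_id, tir$event_id, sep = "\r"),
             paste(agg$whale_id, agg$event_id, sep = "\r"))
  tir$rgb_heading <- agg$rgb_heading[m]
  out <- tir[!is.na(tir$rgb_heading), ]
  out$difference <- wrap_difference(out$tir_heading, out$rgb_heading)
  rownames(out) <- NULL
  out
}

empty_heading_pairs <- function() {
  data.frame(whale_id = character(), event_id = character(),
             print_id = integer(), tir_heading = numeric(),
             rgb_heading = numeric(), difference = numeric(),
             stringsAsFactors = FALSE)
}

#' Heading agreement report between thermal and RGB headings
#'
#' Per-sensor circular summaries, the Fisher--Lee circular correlation,
#' a circular summary of the wrapped TIR - RGB differences (mean offset,
#' circular SD, Rayleigh test of clustering), agreement-category
#' proportions (Excellent <= 5 deg, Good <= 15 deg, Acceptable <= 20 deg,
#' Discrepant > 20 deg, inclusive upper bounds), the mean absolute heading
#' error and the percentage of estimates with error under 20 degrees.
#' Per-whale summaries of the differences accompany the pooled report.
#'
#' @param pairs Heading-pair table from [heading_pairs()] (columns
#'   `tir_heading`, `rgb_heading`, `difference`, `whale_id`).
#' @return An object of class `heading_agreement`.
#' @export
heading_agreement_report <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 heading pairs", call. = FALSE)
  diffs <- pairs$difference
  absd <- abs(diffs)
  cats <- cut(absd, breaks = c(-Inf, 5, 15, 20, Inf),
              labels = c("Excellent", "Good", "Acceptable", "Discrepant"))
  prop <- as.list(table(cats) / length(cats))
  per_whale <- NULL
  if ("whale_id" %in% names(pairs)) {
    per_whale <- do.call(rbind, lapply(split(pairs, pairs$whale_id), function(d) {
      cs <- circular_summary(d$difference)
      data.frame(whale_id = d$whale_id[1], n = nrow(d),
                 mean_difference = cs$circ_mean,
                 circ_sd_deg = cs$circ_sd_deg, stringsAsFactors = FALSE)
    }))
    rownames(per_whale) <- NULL
  }
  structure(
    list(n_pairs = nrow(pairs),
         tir_summary = circular_summary(pairs$tir_heading),
         rgb_summary = circular_summary(pairs$rgb_heading),
         correlation = circular_correlation(pairs$tir_heading,
                                            pairs$rgb_heading),
         difference_summary = circular_summary(diffs),
         category_proportions = lapply(prop, as.numeric),
         mean_abs_error = mean(absd),
         pct_under_20deg = 100 * mean(absd < 20),
         per_whale = per_whale),
    class = "heading_agreement")
}

#' @export
print.heading_agreement <- function(x, ...) {
  ds <- x$difference_summary
  cat(sprintf("Heading agreement over %d TIR/RGB pairs\n", x$n_pairs))
  cat(sprintf("  mean offset (TIR - RGB): %.2f deg, circular SD %.2f deg\n",
              wrap_difference(ds$circ_mean, 0), ds$circ_sd_deg))
  cat(sprintf("  circular correlation r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p_value))
  cat(sprintf("  Rayleigh test on differences: Z = %.3f, p = %.3g\n",
              ds$rayleigh_Z, ds$rayleigh_p))
  p <- x$category_proportions
  cat(sprintf("  Excellent %.1f%% | Good %.1f%% | Acceptable %.1f%% | Discrepant %.1f%%\n",
              100 * p$Excellent, 100 * p$Good, 100 * p$Acceptable,
              100 * p$Discrepant))
  invisible(x)
}
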