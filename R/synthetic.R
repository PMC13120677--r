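#' Configuration for the synthetic dual-sensor survey generator
#'
#' Defines the study conditions emulated by the simulator: two age classes
#' whose calf body lengths are at most half of an accompanying adult's,
#' flukeprint widths forming two separable clusters, tailbeat-driven print
#' deposition along linear tracks at humpback-typical breeding-ground
#' speeds, dual-sensor sampling at 30 Hz from 90 m altitude with about
#' half a metre of barometric jitter, pixel annotation noise, and heading
#' noise concentrated on the thermal channel.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param n_adults,n_calves Whale counts per class (defaults 80 and 12,
#'   the sampling frame of a typical breeding-ground survey season).
#' @param adult_length_mean,adult_length_sd Adult body length distribution,
#'   metres.
#' @param calf_length_fraction_range Calf length as a fraction of the
#'   accompanying adult's; the upper bound may not exceed 0.5.
#' @param flukespan_to_length_ratio Fluke span relative to body length.
#' @param width_model List with `slope` (width per metre of fluke span)
#'   and class-specific noise SDs `adult_noise_sd`, `calf_noise_sd`
#'   (metres). Calf noise is larger than adult noise, reflecting the
#'   greater fluke compliance of young animals.
#' @param speed_range Per-event true swimming speed range, m/s.
#' @param tailbeat_freq_range Tailbeat frequency range, Hz (print period
#'   is its reciprocal).
#' @param lmm_params List `beta0`, `beta1`, `sigma_u`, `sigma_e`: natural-log
#'   scale parameters of the generative spacing-to-speed model
#'   `log(speed) = beta0 + beta1 log(spacing) + u_i + e_ij`.
#' @param spacing_meanlog,spacing_sdlog Log-normal distribution of event
#'   mean spacing (metres) used by [generate_speed_observations()].
#' @param rgb_speed_noise_sd Tracking noise SD on the RGB "observed"
#'   speed, m/s.
#' @param heading_noise_sd_tir,heading_noise_sd_rgb Heading noise SDs per
#'   sensor, degrees.
#' @param pixel_noise_sd Annotation jitter in pixels.
#' @param altitude,altitude_sd Flight altitude and per-frame barometric
#'   jitter SD, metres (jitter truncated at 3 SD).
#' @param frame_rate Video frame rate, Hz.
#' @param events_per_whale,prints_per_event Surfacing events per whale and
#'   flukeprints per event.
#' @param degraded_fraction Fraction of prints flagged as visibly degraded
#'   (excluded from width measurement, retained for movement analysis).
#' @param rgb_camera,tir_camera [camera_model()]s for the two sensors.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_adults = 80L, n_calves = 12L,
                       adult_length_mean = 12, adult_length_sd = 1,
                       calf_length_fraction_range = c(0.30, 0.50),
                       flukespan_to_length_ratio = 0.30,
                       width_model = list(slope = 0.9,
                                          adult_noise_sd = 0.15,
                                          calf_noise_sd = 0.35),
                       speed_range = c(0.8, 1.6),
                       tailbeat_freq_range = c(0.20, 1 / 3),
                       lmm_params = list(beta0 = -0.39, beta1 = 0.33,
                                         sigma_u = 0.09, sigma_e = 0.18),
                       spacing_meanlog = log(5), spacing_sdlog = 0.5,
                       rgb_speed_noise_sd = 0.05,
                       heading_noise_sd_tir = 6,
                       heading_noise_sd_rgb = 1,
                       pixel_noise_sd = 1,
                       altitude = 90, altitude_sd = 0.5,
                       frame_rate = 30,
                       events_per_whale = 2L, prints_per_event = 4L,
                       degraded_fraction = 0.1,
                       rgb_camera = NULL, tir_camera = NULL) {
  if (calf_length_fraction_range[2] > 0.5) {
    stop("calf length fraction upper bound may not exceed 0.5", call. = FALSE)
  }
  sds <- c(adult_length_sd, width_model$adult_noise_sd,
           width_model$calf_noise_sd, rgb_speed_noise_sd,
           heading_noise_sd_tir, heading_noise_sd_rgb, pixel_noise_sd,
           altitude_sd, lmm_params$sigma_u, lmm_params$sigma_e)
  if (any(sds < 0)) stop("all noise SDs must be >= 0", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  if (is.null(rgb_camera)) {
    rgb_camera <- camera_model("RGB", 8000, 6000, focal_length = 6000)
  }
  if (is.null(tir_camera)) {
    tir_camera <- camera_model("TIR", 640, 512, focal_length = 1000)
  }
  structure(
    list(seed = as.integer(seed),
         n_adults = as.integer(n_adults), n_calves = as.integer(n_calves),
         adult_length_mean = adult_length_mean,
         adult_length_sd = adult_length_sd,
         calf_length_fraction_range = calf_length_fraction_range,
         flukespan_to_length_ratio = flukespan_to_length_ratio,
         width_model = width_model,
         speed_range = speed_range,
         tailbeat_freq_range = tailbeat_freq_range,
         lmm_params = lmm_params,
         spacing_meanlog = spacing_meanlog, spacing_sdlog = spacing_sdlog,
         rgb_speed_noise_sd = rgb_speed_noise_sd,
         heading_noise_sd_tir = heading_noise_sd_tir,
         heading_noise_sd_rgb = heading_noise_sd_rgb,
         pixel_noise_sd = pixel_noise_sd,
         altitude = altitude, altitude_sd = altitude_sd,
         frame_rate = frame_rate,
         events_per_whale = as.integer(events_per_whale),
         prints_per_event = as.integer(prints_per_event),
         degraded_fraction = degraded_fraction,
         rgb_camera = rgb_camera, tir_camera = tir_camera),
    class = "sim_config")
}

# heading in compass degrees -> unit (east, north) direction
heading_dir <- function(deg) {
  rad <- deg * pi / 180
  cbind(east = sin(rad), north = cos(rad))
}

#' Simulate a whale population with known ground truth
#'
#' Draws per-whale morphometry (body length, fluke span, mean flukeprint
#' width) for two age classes and per-event kinematic truth (speed,
#' heading, tailbeat period, random whale intercept of the
#' spacing-to-speed model). Calf lengths are a uniform fraction (bounded
#' at 0.5) of a drawn adult length; flukeprint width is a class-dependent
#' linear function of fluke span with class-specific noise.
#'
#' @param cfg A [sim_config()].
#' @return List with `states` (one row per whale-event: `whale_id`,
#'   `age_class`, `body_length`, `fluke_span`, `width`, `event_id`,
#'   `speed`, `heading`, `tailbeat_period`, `u_i`) and `whales` (one row
#'   per whale in the [summarize_individuals()] schema, holding true
#'   means).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_adults + cfg$n_calves
  if (n == 0) stop("no whales configured", call. = FALSE)
  age <- rep(c("adult", "calf"), c(cfg$n_adults, cfg$n_calves))
  len <- numeric(n)
  len[age == "adult"] <- stats::rnorm(cfg$n_adults, cfg$adult_length_mean,
                                      cfg$adult_length_sd)
  if (cfg$n_calves > 0) {
    companion <- stats::rnorm(cfg$n_calves, cfg$adult_length_mean,
                              cfg$adult_length_sd)
    frac <- stats::runif(cfg$n_calves, cfg$calf_length_fraction_range[1],
                         cfg$calf_length_fraction_range[2])
    len[age == "calf"] <- companion * frac
  }
  span <- cfg$flukespan_to_length_ratio * len
  noise_sd <- ifelse(age == "adult", cfg$width_model$adult_noise_sd,
                     cfg$width_model$calf_noise_sd)
  width <- cfg$width_model$slope * span + stats::rnorm(n, 0, noise_sd)
  whale_id <- sprintf("W%03d", seq_len(n))
  u_i <- stats::rnorm(n, 0, cfg$lmm_params$sigma_u)

  ne <- cfg$events_per_whale
  idx <- rep(seq_len(n), each = ne)
  states <- data.frame(
    whale_id = whale_id[idx],
    age_class = age[idx],
    body_length = len[idx],
    fluke_span = span[idx],
    width = width[idx],
    event_id = sprintf("E%02d", rep(seq_len(ne), n)),
    speed = stats::runif(n * ne, cfg$speed_range[1], cfg$speed_range[2]),
    heading = stats::runif(n * ne, 0, 360),
    tailbeat_period = 1 / stats::runif(n * ne, cfg$tailbeat_freq_range[1],
                                       cfg$tailbeat_freq_range[2]),
    u_i = u_i[idx],
    stringsAsFactors = FALSE)
  whales <- data.frame(
    whale_id = whale_id, age_class = age,
    mean_flukeprint_width = width,
    mean_body_length = len, mean_fluke_span = span,
    n_measurements = ne * cfg$prints_per_event,
    stringsAsFactors = FALSE)
  list(states = states, whales = whales)
}

#' Simulate annotated tracks and flukeprints for both sensors
#'
#' For every whale-event, lays a linear track at the event's true speed
#' and heading, samples RGB body landmarks (rostrum, fluke notch, tail,
#' fluke tips) at the frame rate, and deposits thermal flukeprint records
#' (centroid, width endpoints, posterior/anterior edges) once per tailbeat
#' period, so consecutive centroids are `speed x period` apart. World
#' coordinates are projected to pixels through the sensor's ground sample
#' distance at a per-frame jittered altitude, pixel annotation noise is
#' added, and the emitted world coordinates are back-projected from the
#' noisy pixels so both coordinate systems stay consistent. Heading noise
#' rotates the print axis (TIR) and the body axis (RGB) record-by-record.
#'
#' @param cfg A [sim_config()].
#' @param states The `states` table from [simulate_population()].
#' @return Annotation table in the [read_annotations()] schema, with the
#'   extra provenance column `age_class`.
#' @export
simulate_tracks_and_prints <- function(cfg, states) {
  stopifnot(inherits(cfg, "sim_config"))
  states <- as.data.frame(states)
  if (nrow(states) == 0) stop("states table is empty", call. = FALSE)
  set.seed(cfg$seed + 1L)
  rows <- lapply(seq_len(nrow(states)), function(i) {
    simulate_event(cfg, states[i, ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_event <- function(cfg, st) {
  v <- st$speed; T <- st$tailbeat_period
  duration <- cfg$prints_per_event * T
  dir <- heading_dir(st$heading)[1, ]
  track_len <- v * duration
  start <- -dir * track_len / 2   # centre the track on the image footprint

  ts_frames <- seq(0, duration, by = 1 / cfg$frame_rate)
  pos <- cbind(start[1] + v * ts_frames * dir[1],
               start[2] + v * ts_frames * dir[2])

  # RGB body axis per frame, rotated by per-frame heading noise about rostrum
  hd_rgb <- st$heading + stats::rnorm(length(ts_frames), 0,
                                      cfg$heading_noise_sd_rgb)
  bdir <- heading_dir(hd_rgb)
  notch <- pos - bdir * st$body_length
  rgb <- rbind(
    ann_rows(cfg, "rostrum", st, NA, ts_frames, pos, "RGB"),
    ann_rows(cfg, "fluke_notch", st, NA, ts_frames, notch, "RGB"),
    ann_rows(cfg, "tail", st, NA, ts_frames, notch, "RGB"))
  # fluke tips at the first frame only (pre-dive fluke extension)
  tip_perp <- cbind(bdir[1, 2], -bdir[1, 1])
  tips <- rbind(notch[1, ] + tip_perp[1, ] * st$fluke_span / 2,
                notch[1, ] - tip_perp[1, ] * st$fluke_span / 2)
  rgb <- rbind(rgb,
               ann_rows(cfg, "fluke_tip_left", st, NA, ts_frames[1],
                        tips[1, , drop = FALSE], "RGB"),
               ann_rows(cfg, "fluke_tip_right", st, NA, ts_frames[1],
                        tips[2, , drop = FALSE], "RGB"))

  # thermal flukeprints: one per tailbeat period
  k <- seq_len(cfg$prints_per_event)
  t_k <- k * T
  cen <- cbind(start[1] + v * t_k * dir[1], start[2] + v * t_k * dir[2])
  hd_tir <- st$heading + stats::rnorm(length(k), 0, cfg$heading_noise_sd_tir)
  pdir <- heading_dir(hd_tir)
  pperp <- cbind(pdir[, 2], -pdir[, 1])
  w <- st$width
  ax <- 0.8 * w  # along-axis print extent; only its direction is analysed
  degraded <- stats::runif(length(k)) < cfg$degraded_fraction
  emergence <- stats::runif(length(k), 0, 4)
  tir <- rbind(
    ann_rows(cfg, "print_centroid", st, k, t_k, cen, "TIR",
             degraded = degraded, emergence = emergence),
    ann_rows(cfg, "print_width_left", st, k, t_k,
             cen + pperp * w / 2, "TIR", degraded = degraded,
             emergence = emergence),
    ann_rows(cfg, "print_width_right", st, k, t_k,
             cen - pperp * w / 2, "TIR", degraded = degraded,
             emergence = emergence),
    ann_rows(cfg, "print_posterior", st, k, t_k,
             cen - pdir * ax / 2, "TIR", degraded = degraded,
             emergence = emergence),
    ann_rows(cfg, "print_anterior", st, k, t_k,
             cen + pdir * ax / 2, "TIR", degraded = degraded,
             emergence = emergence))
  rbind(rgb, tir)
}

# Build annotation rows: project world -> pixel at jittered altitude,
# add pixel noise, back-project to world.
ann_rows <- function(cfg, type, st, print_id, ts, world, sensor,
                     degraded = FALSE, emergence = NA_real_) {
  n <- nrow(world)
  cam <- if (sensor == "RGB") cfg$rgb_camera else cfg$tir_camera
  jit <- stats::rnorm(n, 0, cfg$altitude_sd)
  if (cfg$altitude_sd > 0) {
    jit <- pmin(pmax(jit, -3 * cfg$altitude_sd), 3 * cfg$altitude_sd)
  }
  alt <- cfg$altitude + jit
  gsd <- alt / cam$focal_length
  px <- cbind(cam$principal_point[1] + world[, 1] / gsd,
              cam$principal_point[2] - world[, 2] / gsd)
  px <- px + matrix(stats::rnorm(2 * n, 0, cfg$pixel_noise_sd), ncol = 2)
  wxy <- cbind((px[, 1] - cam$principal_point[1]) * gsd,
               -(px[, 2] - cam$principal_point[2]) * gsd)
  data.frame(
    record_type = type,
    whale_id = st$whale_id, event_id = st$event_id,
    print_id = if (all(is.na(print_id))) NA_integer_ else as.integer(print_id),
    timestamp = ts, sensor = sensor,
    x_px = px[, 1], y_px = px[, 2],
    x_m = wxy[, 1], y_m = wxy[, 2],
    altitude_m = alt, yaw_deg = 0,
    degraded = degraded,
    emergence_offset_s = emergence,
    age_class = st$age_class,
    stringsAsFactors = FALSE)
}

#' Generate paired spacing/speed observations from the generative model
#'
#' The generative inverse of the spacing-to-speed mixed model: per event,
#' mean flukeprint spacing is drawn log-normally and
#' `log(speed) = beta0 + beta1 log(spacing) + u_i + e_ij` with the
#' configured whale intercepts `u_i` and residual SD. The RGB "observed"
#' speed is the true speed plus small Gaussian tracking noise.
#'
#' @param cfg A [sim_config()].
#' @param states The `states` table from [simulate_population()] (supplies
#'   `whale_id`, `event_id`, `u_i`).
#' @return Data frame with `whale_id`, `event_id`, `mean_spacing`,
#'   `speed` (TIR/model truth), `rgb_speed`.
#' @export
generate_speed_observations <- function(cfg, states) {
  stopifnot(inherits(cfg, "sim_config"))
  states <- as.data.frame(states)
  if (is.null(cfg$lmm_params)) stop("lmm_params not set", call. = FALSE)
  set.seed(cfg$seed + 2L)
  p <- cfg$lmm_params
  n <- nrow(states)
  spacing <- stats::rlnorm(n, cfg$spacing_meanlog, cfg$spacing_sdlog)
  eps <- stats::rnorm(n, 0, p$sigma_e)
  log_speed <- p$beta0 + p$beta1 * log(spacing) + states$u_i + eps
  speed <- exp(log_speed)
  rgb_speed <- pmax(speed + stats::rnorm(n, 0, cfg$rgb_speed_noise_sd), 1e-6)
  data.frame(whale_id = states$whale_id, event_id = states$event_id,
             mean_spacing = spacing, speed = speed, rgb_speed = rgb_speed,
             stringsAsFactors = FALSE)
}

#' Render a demonstration thermal frame of flukeprints
#'
#' Draws flukeprints as Gaussian temperature-contrast blobs on the thermal
#' sensor's raster, with intensity decaying exponentially with print age.
#' This is a visual demonstration of what the annotation tables describe,
#' not a physical wake model.
#'
#' @param prints Data frame with columns `x_px`, `y_px` (blob centres),
#'   `width_px` (Gaussian full width), and optionally `age_s`.
#' @param cfg A [sim_config()] (supplies the TIR raster size).
#' @param decay_rate Intensity decay constant per second (0 = no decay).
#' @return Numeric matrix (rows = image height, columns = width) in
#'   `[0, 1]`.
#' @export
render_thermal_frame <- function(prints, cfg = sim_config(),
                                 decay_rate = 0.1) {
  prints <- as.data.frame(prints)
  stopifnot(all(c("x_px", "y_px", "width_px") %in% names(prints)))
  cam <- cfg$tir_camera
  img <- matrix(0, nrow = cam$image_height, ncol = cam$image_width)
  xs <- matrix(seq_len(cam$image_width), nrow = cam$image_height,
               ncol = cam$image_width, byrow = TRUE)
  ys <- matrix(seq_len(cam$image_height), nrow = cam$image_height,
               ncol = cam$image_width)
  age <- if ("age_s" %in% names(prints)) prints$age_s else rep(0, nrow(prints))
  for (i in seq_len(nrow(prints))) {
    sigma <- prints$width_px[i] / 4
    blob <- exp(-((xs - prints$x_px[i])^2 + (ys - prints$y_px[i])^2) /
                  (2 * sigma^2)) * exp(-decay_rate * age[i])
    img <- img + blob
  }
  if (max(img) > 0) img <- img / max(img)
  img
}

#' Extract blob centroids from a rendered thermal frame
#'
#' Finds local maxima above a threshold (non-maximum suppression over a
#' square neighbourhood) and refines each to an intensity-weighted
#' centroid over a window, mirroring how flukeprint centroids are clicked
#' in annotation software.
#'
#' @param img Matrix from [render_thermal_frame()].
#' @param threshold Minimum peak intensity (fraction of maximum).
#' @param window Half-width in pixels of the suppression/centroid window.
#' @return Data frame with `x_px`, `y_px`, `intensity`.
#' @export
find_blob_centroids <- function(img, threshold = 0.2, window = 10L) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  peaks <- NULL
  cand <- which(img >= threshold * max(img), arr.ind = TRUE)
  ord <- order(img[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  taken <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (taken[r, c]) next
    rr <- max(1, r - window):min(h, r + window)
    cc <- max(1, c - window):min(w, c + window)
    if (img[r, c] < max(img[rr, cc])) next
    taken[rr, cc] <- TRUE
    patch <- img[rr, cc]
    x <- sum(patch * matrix(cc, length(rr), length(cc), byrow = TRUE)) / sum(patch)
    y <- sum(patch * matrix(rr, length(rr), length(cc))) / sum(patch)
    peaks <- rbind(peaks, data.frame(x_px = x, y_px = y,
                                     intensity = img[r, c]))
  }
  peaks[order(-peaks$intensity), , drop = FALSE]
}
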