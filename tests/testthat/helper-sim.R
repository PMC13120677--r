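# Simulation config with every noise channel silenced, for exact
# round-trip checks; overrides are passed straight to sim_config().
zero_noise_config <- function(...) {
  args <- list(...)
  defaults <- list(pixel_noise_sd = 0, heading_noise_sd_tir = 0,
                   heading_noise_sd_rgb = 0, altitude_sd = 0,
                   rgb_speed_noise_sd = 0, degraded_fraction = 0)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(sim_config, args)
}

# Tiny hand-built annotation table: one whale, one event, world coords.
# Widths at given emergence offsets/degraded flags; a 2-print centroid
# sequence; a 3-frame rostrum track.
toy_annotations <- function() {
  w <- function(type, pid, ts, x, y, degraded = FALSE, off = 1) {
    data.frame(record_type = type, whale_id = "W1", event_id = "E1",
               print_id = pid, timestamp = ts, sensor = "TIR",
               x_px = NA_real_, y_px = NA_real_, x_m = x, y_m = y,
               altitude_m = 90, yaw_deg = 0, degraded = degraded,
               emergence_offset_s = off, age_class = "adult",
               stringsAsFactors = FALSE)
  }
  r <- function(type, ts, x, y) {
    data.frame(record_type = type, whale_id = "W1", event_id = "E1",
               print_id = NA_integer_, timestamp = ts, sensor = "RGB",
               x_px = NA_real_, y_px = NA_real_, x_m = x, y_m = y,
               altitude_m = 90, yaw_deg = 0, degraded = FALSE,
               emergence_offset_s = NA_real_, age_class = "adult",
               stringsAsFactors = FALSE)
  }
  rbind(
    w("print_width_left", 1L, 4, 0, 0), w("print_width_right", 1L, 4, 2, 0),
    w("print_width_left", 2L, 8, 0, 1), w("print_width_right", 2L, 8, 3, 1),
    w("print_centroid", 1L, 4, 0, 0), w("print_centroid", 2L, 8, 0, 10),
    r("rostrum", 0, 0, 0), r("rostrum", 1, 3, 4), r("rostrum", 2, 6, 8),
    r("fluke_notch", 0, 0, -12), r("fluke_notch", 1, 3, -8),
    r("fluke_notch", 2, 6, -4),
    r("fluke_tip_left", 0, -1.8, -12), r("fluke_tip_right", 0, 1.8, -12))
}
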