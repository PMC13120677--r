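test_that("population counts, class structure and determinism hold", {
  cfg <- sim_config(seed = 1, n_adults = 80, n_calves = 12)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$whales), 92)
  expect_equal(sum(pop$whales$age_class == "adult"), 80)
  expect_equal(sum(pop$whales$age_class == "calf"), 12)
  expect_equal(nrow(pop$states), 92 * cfg$events_per_whale)
  # calves are at most half an adult-scale body length by construction
  expect_true(all(pop$whales$mean_body_length[pop$whales$age_class == "calf"] <
                    0.5 * max(pop$whales$mean_body_length)))
  pop2 <- simulate_population(sim_config(seed = 1, n_adults = 80,
                                         n_calves = 12))
  expect_identical(pop, pop2)
  pop3 <- simulate_population(sim_config(seed = 2, n_adults = 80,
                                         n_calves = 12))
  expect_false(identical(pop$whales, pop3$whales))
})

test_that("widths are deterministic given span when width noise is zero", {
  cfg <- sim_config(seed = 5,
                    width_model = list(slope = 0.9, adult_noise_sd = 0,
                                       calf_noise_sd = 0))
  pop <- simulate_population(cfg)
  expect_equal(pop$whales$mean_flukeprint_width,
               0.9 * pop$whales$mean_fluke_span)
})

test_that("calf and adult width clusters are disjoint under defaults", {
  pop <- simulate_population(sim_config(seed = 11))
  w <- pop$whales
  expect_true(max(w$mean_flukeprint_width[w$age_class == "calf"]) <
                min(w$mean_flukeprint_width[w$age_class == "adult"]))
})

test_that("noiseless prints sit exactly speed x period apart along the heading", {
  cfg <- zero_noise_config(seed = 3, n_adults = 1, n_calves = 0,
                           events_per_whale = 1, prints_per_event = 4,
                           speed_range = c(1.4, 1.4),
                           tailbeat_freq_range = c(0.25, 0.25))
  pop <- simulate_population(cfg)
  pop$states$heading <- 90 # due east
  ann <- simulate_tracks_and_prints(cfg, pop$states)
  cen <- ann[ann$record_type == "print_centroid", ]
  cen <- cen[order(cen$print_id), ]
  d <- sqrt(diff(cen$x_m)^2 + diff(cen$y_m)^2)
  expect_equal(d, rep(1.4 * 4, 3), tolerance = 1e-9)
  # displacements due east: no northward component
  expect_equal(diff(cen$y_m), rep(0, 3), tolerance = 1e-9)
  expect_true(all(diff(cen$x_m) > 0))
})

test_that("centroid scatter matches the configured pixel noise", {
  # stationary track: every print lands on the same true point, so the
  # world-coordinate scatter is exactly pixel noise times the GSD
  cfg <- sim_config(seed = 8, n_adults = 1, n_calves = 0,
                    events_per_whale = 1, prints_per_event = 1200,
                    speed_range = c(0, 0), pixel_noise_sd = 2,
                    altitude_sd = 0, heading_noise_sd_tir = 0,
                    heading_noise_sd_rgb = 0, degraded_fraction = 0)
  pop <- simulate_population(cfg)
  ann <- simulate_tracks_and_prints(cfg, pop$states)
  cen <- ann[ann$record_type == "print_centroid", ]
  gsd <- cfg$altitude / cfg$tir_camera$focal_length
  expect_gt(nrow(cen), 1000)
  expect_equal(sd(cen$x_m), 2 * gsd, tolerance = 0.1)
  expect_equal(sd(cen$y_m), 2 * gsd, tolerance = 0.1)
})

test_that("annotation output is reproducible under a fixed seed", {
  cfg <- sim_config(seed = 21, n_adults = 3, n_calves = 2)
  pop <- simulate_population(cfg)
  a1 <- simulate_tracks_and_prints(cfg, pop$states)
  a2 <- simulate_tracks_and_prints(cfg, pop$states)
  expect_identical(a1, a2)
  o1 <- generate_speed_observations(cfg, pop$states)
  o2 <- generate_speed_observations(cfg, pop$states)
  expect_identical(o1, o2)
})

test_that("speed observations follow the generative spacing model", {
  # zero variance: speed is an exact deterministic function of spacing
  cfg <- sim_config(seed = 2, n_adults = 10, n_calves = 0,
                    lmm_params = list(beta0 = -0.39, beta1 = 0.33,
                                      sigma_u = 0, sigma_e = 0))
  pop <- simulate_population(cfg)
  obs <- generate_speed_observations(cfg, pop$states)
  expect_equal(obs$speed, exp(-0.39) * obs$mean_spacing^0.33,
               tolerance = 1e-12)
  # beta1 = 1, beta0 = log f: pure kinematics, speed = f x spacing
  f <- 0.25
  cfg <- sim_config(seed = 2, n_adults = 10, n_calves = 0,
                    lmm_params = list(beta0 = log(f), beta1 = 1,
                                      sigma_u = 0, sigma_e = 0))
  pop <- simulate_population(cfg)
  obs <- generate_speed_observations(cfg, pop$states)
  expect_equal(obs$speed, f * obs$mean_spacing, tolerance = 1e-12)
})

test_that("OLS on a large simulated sample recovers the generative slope", {
  cfg <- sim_config(seed = 42, n_adults = 2500, n_calves = 0,
                    events_per_whale = 2,
                    lmm_params = list(beta0 = -0.39, beta1 = 0.33,
                                      sigma_u = 0.09, sigma_e = 0.18))
  pop <- simulate_population(cfg)
  obs <- generate_speed_observations(cfg, pop$states)
  fit <- summary(lm(log(speed) ~ log(mean_spacing), data = obs))
  est <- fit$coefficients["log(mean_spacing)", ]
  expect_lt(abs(est["Estimate"] - 0.33), 3 * est["Std. Error"])
})

test_that("rendered thermal blobs are recovered by the centroid extractor", {
  cfg <- sim_config(seed = 1)
  one <- data.frame(x_px = 320, y_px = 256, width_px = 30)
  img <- render_thermal_frame(one, cfg)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(256, 320))
  # zero decay keeps intensity constant over print age
  old <- data.frame(x_px = 320, y_px = 256, width_px = 30, age_s = 100)
  expect_equal(render_thermal_frame(old, cfg, decay_rate = 0), img)
  two <- data.frame(x_px = c(300, 350), y_px = c(250, 250),
                    width_px = c(24, 24))
  found <- find_blob_centroids(render_thermal_frame(two, cfg), window = 12)
  expect_equal(nrow(found), 2)
  found <- found[order(found$x_px), ]
  expect_equal(found$x_px, c(300, 350), tolerance = 0.5)
  expect_equal(found$y_px, c(250, 250), tolerance = 0.5)
})
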