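test_that("release trains obey rate, locking and determinism", {
  expect_length(simulate_release_train(0, 100, seed = 1), 0)

  # Poisson count within 3 SD of rate * duration
  ev <- simulate_release_train(2, 1000, seed = 2)
  expect_gt(length(ev), 2000 - 3 * sqrt(2000))
  expect_lt(length(ev), 2000 + 3 * sqrt(2000))
  expect_false(is.unsorted(ev))
  expect_true(all(ev >= 0 & ev < 1000))

  expect_identical(simulate_release_train(0, 10, locked_times = c(1, 2, 3),
                                          p_release = 1, seed = 3),
                   c(1, 2, 3))
  expect_identical(simulate_release_train(5, 50, seed = 7),
                   simulate_release_train(5, 50, seed = 7))

  expect_error(simulate_release_train(-1, 10), "rate")
  expect_error(simulate_release_train(1, -10), "duration")
  expect_error(simulate_release_train(1, 10, p_release = 2), "p_release")
})

test_that("indicator kernel matches the transient model's closed forms", {
  p <- kinetic_params(A = 0.7, t0 = 0, tau_rise = 0.002, tau_decay = 0.03)
  k <- indicator_kernel(p, 500, 0.3)
  expect_identical(k[1], 0)                 # rise term vanishes at t = 0
  tpk <- transient_time_to_peak(p)
  expect_lt(abs(attr(k, "t")[which.max(k)] - tpk), 1 / 500 + 1e-12)

  # tau_rise -> 0 limit: pure exponential decay with peak ~ A (the first
  # nonzero sample sits one frame past the instantaneous peak)
  p0 <- kinetic_params(A = 1, t0 = 0, tau_rise = 1e-7, tau_decay = 0.05)
  k0 <- indicator_kernel(p0, 1000, 0.25)
  expect_equal(max(k0), 1, tolerance = 0.03)
  expect_equal(as.numeric(k0[-1]),
               exp(-attr(k0, "t")[-1] / 0.05), tolerance = 1e-3)

  expect_error(kinetic_params(tau_rise = -1), "tau_rise")
  expect_error(kinetic_params(tau_decay = 0), "tau_decay")
})

test_that("rendered movies are Poisson-limited, faithful and reproducible", {
  kin <- kinetic_params(A = 1, t0 = 0, tau_rise = 0.002, tau_decay = 0.05)

  # shot-noise-only movie: per-pixel variance ~ mean over >= 1e5 px-frames
  cfg0 <- sim_config(frame_rate = 100, duration = 10, image_shape = c(16, 16),
                     n_sites = 0, baseline_photon_rate = 20, seed = 8)
  m0 <- render_movie(cfg0, list(), kin)
  mm <- glusense:::movie_as_matrix(m0$frames)
  expect_gt(length(mm), 1e5)
  vm <- mean(apply(mm, 2, stats::var) / colMeans(mm))
  expect_gt(vm, 0.95)
  expect_lt(vm, 1.05)

  # single event at one site: peak dF/F at the footprint centre recovers
  # the transient amplitude diluted by the baseline, within shot noise
  cfg <- sim_config(frame_rate = 200, duration = 3, image_shape = c(24, 24),
                    n_sites = 1, footprint_sigma = 1.5,
                    baseline_photon_rate = 5, site_brightness = 2000,
                    seed = 7)
  mv <- render_movie(cfg, list(1.0), kin,
                     site_centers = matrix(c(12, 12), 1))
  px <- mv$frames[, 12, 12]
  f0 <- mean(px[1:150])
  expected <- transient_amplitude(kin) * 2000 / (2000 + 5)
  expect_equal(max(px / f0 - 1), expected, tolerance = 0.12)

  expect_identical(render_movie(cfg, list(1.0), kin,
                                site_centers = matrix(c(12, 12), 1))$frames,
                   mv$frames)
  expect_error(render_movie(cfg, rep(list(1), 5), kin), "trains")
})

test_that("sparse-noise stimulus has the stated non-gray statistics", {
  st <- sparse_noise_stimulus(600, c(8, 8), refresh_rate = 5,
                              p_nongray = 0.02, seed = 5)
  expect_true(all(st$frames %in% c(-1L, 0L, 1L)))
  frac <- mean(st$frames != 0)
  expect_gt(frac, 0.018)
  expect_lt(frac, 0.022)
  # black and white equiprobable given non-gray
  bw <- mean(st$frames[st$frames != 0] == 1)
  expect_equal(bw, 0.5, tolerance = 0.05)
  expect_error(sparse_noise_stimulus(10, c(4, 4), p_nongray = 2), "p_nongray")
})

test_that("tuned sessions follow the 8-direction design", {
  cfg <- sim_config(frame_rate = 30, duration = 1, image_shape = c(16, 16),
                    n_sites = 1, baseline_photon_rate = 10,
                    site_brightness = 40, seed = 21)
  tun <- tuning_ground_truth(preferred = 90, kappa = 3, base_rate = 6)
  kin <- kinetic_params(A = 1, t0 = 0, tau_rise = 0.002, tau_decay = 0.1)
  ses <- simulate_tuned_session(cfg, tun, kin, trials_per_direction = 15)
  expect_identical(nrow(ses$stim_log), 120L)   # 8 directions x 15 trials
  expect_setequal(unique(ses$stim_log$direction_deg), seq(0, 315, by = 45))

  # responses largest at the preferred direction, by construction
  tr <- ses$movie$ground_truth$trains[[1]]
  counts <- vapply(seq(0, 315, by = 45), function(d) {
    on <- ses$stim_log$onset_s[ses$stim_log$direction_deg == d]
    sum(vapply(on, function(o) sum(tr >= o & tr < o + 2), numeric(1)))
  }, numeric(1))
  # orientation tuning: 90 and 270 share the preferred orientation
  expect_identical(seq(0, 315, by = 45)[which.max(counts)] %% 180, 90)

  expect_error(simulate_tuned_session(cfg, tun, kin, directions = c(10, 20)),
               "45")
  expect_error(tuning_ground_truth(preferred = 30, kappa = 1), "45")
})

test_that("sparse-noise sessions apply the linear RF forward model", {
  gd <- c(4, 4)
  st <- sparse_noise_stimulus(60, gd, seed = 6)
  zero_rf <- list(on = array(0, c(gd, 3)), off = array(0, c(gd, 3)))
  ses <- simulate_sparse_noise_session(st, zero_rf, noise_sd = 1,
                                       response_rate = 10, seed = 9)
  expect_equal(stats::sd(ses$response), 1, tolerance = 0.1)
  expect_equal(mean(ses$response), 0, tolerance = 0.15)

  bad_rf <- list(on = array(0, c(5, 5, 3)), off = array(0, c(5, 5, 3)))
  expect_error(simulate_sparse_noise_session(st, bad_rf), "grid")
  long_rf <- list(on = array(0, c(gd, 40)), off = array(0, c(gd, 40)))
  expect_error(simulate_sparse_noise_session(st, long_rf,
                                             response_rate = 10), "1.4")
})

test_that("photometry simulation composes drift, bleach and transients", {
  tr <- simulate_photometry(100, numeric(0),
                            kinetic_params(A = 1, tau_rise = 0.1,
                                           tau_decay = 1),
                            drift_poly_coeffs = c(10, 0.01, -1e-4),
                            bleach_tau = 500, noise_sd = 0, rate_hz = 20)
  t <- (seq_along(tr$values) - 1) / 20
  expect_equal(tr$values, (10 + 0.01 * t - 1e-4 * t^2) * exp(-t / 500),
               tolerance = 1e-12)
  a <- simulate_photometry(50, c(10, 30),
                           kinetic_params(A = 0.2, tau_rise = 0.1,
                                          tau_decay = 1),
                           noise_sd = 0.1, rate_hz = 20, seed = 4)
  b <- simulate_photometry(50, c(10, 30),
                           kinetic_params(A = 0.2, tau_rise = 0.1,
                                          tau_decay = 1),
                           noise_sd = 0.1, rate_hz = 20, seed = 4)
  expect_identical(a$values, b$values)
  expect_error(simulate_photometry(10, 20, kinetic_params()), "within")
})
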