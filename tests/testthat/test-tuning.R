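test_that("time-resolved tuning averages trials per direction", {
  fx <- tuned_trial_structure(trials_per_direction = 6, seed = 71)
  trt <- time_resolved_tuning(fx$src, fx$frame_rate, fx$onsets,
                              fx$directions)
  expect_identical(dim(trt$curves)[1], 8L)
  # identical trials within direction (noiseless source): the mean equals
  # any single trial
  i1 <- which(fx$directions == 0)[1]
  f0 <- round(fx$onsets[i1] * fx$frame_rate) + 1
  rel <- (-round(0.5 * fx$frame_rate)):(round(2 * fx$frame_rate) - 1)
  expect_equal(as.numeric(trt$curves[match(0, trt$directions), , 1]),
               fx$src[f0 + rel])

  # trial-order permutation invariance
  set.seed(1)
  perm <- sample(length(fx$onsets))
  trt2 <- time_resolved_tuning(fx$src, fx$frame_rate, fx$onsets[perm],
                               fx$directions[perm])
  expect_equal(trt2$curves, trt$curves)

  # missing directions are flagged, not zero-filled
  keep <- fx$directions != 90
  trt3 <- time_resolved_tuning(fx$src, fx$frame_rate, fx$onsets[keep],
                               fx$directions[keep])
  expect_identical(trt3$missing, numeric(0))
  expect_false(90 %in% trt3$directions)
  expect_identical(dim(trt3$curves)[1], 7L)
})

test_that("eight-point tuning subtracts the pre-stimulus baseline", {
  fx <- tuned_trial_structure(trials_per_direction = 6, seed = 72)
  flat <- time_resolved_tuning(rep(3.5, fx$n), fx$frame_rate, fx$onsets,
                               fx$directions)
  expect_equal(unname(eight_point_tuning(flat)), rep(0, 8))

  trt <- time_resolved_tuning(fx$src, fx$frame_rate, fx$onsets,
                              fx$directions)
  ep <- eight_point_tuning(trt)
  # additive offsets cancel
  trt_off <- time_resolved_tuning(fx$src + 11, fx$frame_rate, fx$onsets,
                                  fx$directions)
  expect_equal(eight_point_tuning(trt_off), ep)
  # noiseless source: responses proportional to the generating gain
  expect_equal(unname(ep) / max(ep), fx$gain / max(fx$gain),
               tolerance = 1e-6)
})

test_that("eight-point responses track event-rate ratios", {
  # preferred rate 2 ev/s vs orthogonal 0.5 ev/s -> response ratio ~ 4
  fr <- 50
  dirs8 <- seq(0, 315, by = 45)
  set.seed(73)
  directions <- sample(rep(dirs8, 30))
  onsets <- 1 + (seq_along(directions) - 1) * 3
  n <- round((max(onsets) + 3) * fr)
  kin <- kinetic_params(A = 1, tau_rise = 0.002, tau_decay = 0.08)
  rate_of <- function(d) ifelse(d %% 180 == 0, 2, ifelse(d %% 90 == 0, 0.5, 1))
  ev <- unlist(lapply(seq_along(onsets), function(i) {
    nkt <- stats::rpois(1, rate_of(directions[i]) * 2)
    if (nkt > 0) onsets[i] + stats::runif(nkt, 0, 2) else numeric(0)
  }))
  dff <- ideal_trace(sort(ev), n / fr, fr, kin)
  trt <- time_resolved_tuning(dff, fr, onsets, directions)
  ep <- eight_point_tuning(trt)
  pref <- mean(ep[as.character(c(0, 180))])
  orth <- mean(ep[as.character(c(90, 270))])
  expect_equal(pref / orth, 4, tolerance = 0.35)
})

test_that("orientation statistics match hand-computed vector sums", {
  dirs8 <- seq(0, 315, by = 45)
  # responses {0: 2, 90: 1}: doubled angles put them antiparallel
  s <- orientation_stats(c(2, 0, 1, 0, 0, 0, 0, 0), dirs8)
  expect_equal(s$preferred_orientation, 0, tolerance = 1e-9)
  expect_equal(s$osi, 1 / 3)
  expect_equal(s$osi_raw, 1)
  expect_equal(s$tuning_magnitude, sqrt(5))
  expect_equal(s$response_amplitude, 3 / 8)

  # equal responses at all directions cancel
  expect_equal(orientation_stats(rep(1, 8), dirs8)$osi, 0, tolerance = 1e-12)

  # single orientation at 0/180
  s2 <- orientation_stats(c(1, 0, 0, 0, 1, 0, 0, 0), dirs8)
  expect_equal(s2$preferred_orientation, 0, tolerance = 1e-9)
  expect_equal(s2$osi, 1)

  # all-zero: undefined orientation, osi 0
  s3 <- orientation_stats(rep(0, 8), dirs8)
  expect_true(is.na(s3$preferred_orientation))
  expect_identical(s3$osi, 0)

  # rotating all labels by 45 deg shifts preferred by 45 mod 180, osi fixed
  set.seed(74)
  for (i in 1:50) {
    r <- runif(8)
    a <- orientation_stats(r, dirs8)
    b <- orientation_stats(r, (dirs8 + 45) %% 360)
    expect_equal((a$preferred_orientation + 45) %% 180,
                 b$preferred_orientation %% 180, tolerance = 1e-9)
    expect_equal(a$osi, b$osi, tolerance = 1e-12)
  }

  # normalized OSI always in [0, 1] for nonnegative curves
  set.seed(75)
  osis <- vapply(1:10000, function(i)
    orientation_stats(runif(8), dirs8)$osi, numeric(1))
  expect_true(all(osis >= 0 & osis <= 1))

  expect_error(orientation_stats(1:3, dirs8), "length")
})

test_that("tuning maps encode orientation/OSI/amplitude as HSV", {
  pref <- matrix(c(0, 90, NA, 45), 2)
  osi <- matrix(c(1, 1, 0, 0.5), 2)
  amp <- matrix(c(1, 2, 0.5, 1), 2)
  img <- tuning_map(pref, osi, amp)
  expect_identical(dim(img), c(2L, 2L, 3L))
  expect_equal(max(img), 1)            # value channel normalized to FOV max
  # untuned pixel is gray (R = G = B)
  expect_equal(img[1, 2, 1], img[1, 2, 2])
  expect_equal(img[1, 2, 2], img[1, 2, 3])
  # orientations 90 deg apart get opposite hues: 0 -> red (value 1/2 from
  # the amplitude channel), 90 -> cyan; colours are 8-bit quantized
  expect_equal(img[1, 1, ], c(0.5, 0, 0), tolerance = 0.01)
  expect_equal(img[2, 1, ], c(0, 1, 1), tolerance = 0.01)
})

test_that("cross-validated covariance estimates shared-signal covariance", {
  fx <- tuned_trial_structure(trials_per_direction = 12, seed = 76)
  n <- fx$n
  # truth: variance of the source's trial-mean tuning curve
  trts <- time_resolved_tuning(fx$src, fx$frame_rate, fx$onsets,
                               fx$directions)
  true_cov <- stats::var(as.vector(t(trts$curves[, , 1])))

  reps <- 30
  cvs <- naive <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(400 + r)
    shared <- rnorm(n)
    p1 <- fx$src + shared + rnorm(n, 0, 0.3)
    p2 <- fx$src + shared + rnorm(n, 0, 0.3)
    sc <- crossval_spread(cbind(p1, p2), fx$frame_rate, fx$onsets,
                          fx$directions, coords = rbind(c(1, 1), c(1, 2)),
                          mask = c(TRUE, TRUE), n_splits = 20, seed = r)
    cvs[r] <- sc$curve$cov_labeled[1]
    t1 <- time_resolved_tuning(p1, fx$frame_rate, fx$onsets, fx$directions)
    t2 <- time_resolved_tuning(p2, fx$frame_rate, fx$onsets, fx$directions)
    naive[r] <- stats::cov(as.vector(t(t1$curves[, , 1])),
                           as.vector(t(t2$curves[, , 1])))
  }
  sem <- stats::sd(cvs) / sqrt(reps)
  # CV estimate unbiased despite shared noise; naive covariance inflated
  expect_lt(abs(mean(cvs) - true_cov), 3 * sem + 0.02 * true_cov)
  expect_gt(mean(naive), mean(cvs) * 1.2)

  # independent pixels: covariance ~ 0
  set.seed(77)
  q1 <- rnorm(n)
  q2 <- rnorm(n)
  sc0 <- crossval_spread(cbind(q1, q2), fx$frame_rate, fx$onsets,
                         fx$directions, coords = rbind(c(1, 1), c(1, 2)),
                         mask = c(TRUE, TRUE), n_splits = 20, seed = 5)
  expect_lt(abs(sc0$curve$cov_labeled[1]), 0.02)

  expect_error(crossval_spread(cbind(q1, q2), fx$frame_rate,
                               fx$onsets[1:8], fx$directions[1:8],
                               coords = rbind(c(1, 1), c(1, 2)),
                               mask = c(TRUE, TRUE)),
               "4 trials")
})

test_that("spread curves widen with the synthetic footprint size", {
  d2s <- vapply(c(1, 2.5), function(sg) {
    cfg <- sim_config(frame_rate = 30, duration = 1, image_shape = c(20, 20),
                      n_sites = 1, footprint_sigma = sg,
                      baseline_photon_rate = 10, site_brightness = 80,
                      seed = 78)
    tun <- tuning_ground_truth(preferred = 0, kappa = 3, base_rate = 6)
    kin <- kinetic_params(A = 1.5, tau_rise = 0.002, tau_decay = 0.12)
    ses <- simulate_tuned_session(cfg, tun, kin, trials_per_direction = 8)
    mv <- ses$movie
    pm <- glusense:::movie_as_matrix(mv$frames)
    coords <- cbind((seq_len(400) - 1) %% 20 + 1,
                    (seq_len(400) - 1) %/% 20 + 1)
    # wide mask so pair distances span well past the 1/e^2 crossing
    msk <- as.vector(labeled_mask(matrix(colMeans(pm), 20, 20), q = 0.3))
    sc <- crossval_spread(pm, 30, ses$stim_log$onset_s,
                          ses$stim_log$direction_deg, coords, msk,
                          n_splits = 10, max_dist = 20, seed = 6)
    sc$cov_crossings$d_1e2
  }, numeric(1))
  expect_false(any(is.na(d2s)))
  expect_gt(d2s[2], d2s[1])
})

test_that("spread aggregation bootstraps recordings deterministically", {
  # three synthetic "recordings" whose curves decay exponentially
  mk <- function(scale) {
    cu <- data.frame(distance = 0:12,
                     cov_labeled = scale * exp(-(0:12) / 3),
                     cor_labeled = exp(-(0:12) / 3))
    structure(list(curve = cu), class = "spread_curve")
  }
  curves <- list(mk(1), mk(1.4), mk(0.8))
  ag <- aggregate_spread(curves, "cov", n_boot = 200, seed = 9)
  expect_equal(ag$mean[1], mean(c(1, 1.4, 0.8)))
  expect_equal(ag$crossings$d_1e, 3, tolerance = 0.1)
  expect_true(all(ag$ci_lo <= ag$mean & ag$mean <= ag$ci_hi))
  ag2 <- aggregate_spread(curves, "cov", n_boot = 200, seed = 9)
  expect_identical(ag, ag2)

  # clearly separated conditions are flagged significant
  wide <- list(mk(1), mk(1.05), mk(0.95))
  wide <- lapply(wide, function(cu) {
    cu$curve$cov_labeled <- cu$curve$cov_labeled[1] * exp(-(0:12) / 6)
    cu
  })
  dd <- spread_difference(wide, curves, "cov", which = "d_1e2",
                          n_boot = 200, seed = 10)
  expect_gt(dd$difference, 0)
  expect_true(dd$significant)
})

test_that("crossing distances interpolate and order correctly", {
  d <- 0:20
  v <- exp(-d / 4)
  cr <- spread_distances(d, v)
  expect_equal(cr$max, 1)
  expect_equal(cr$d_1e, 4, tolerance = 0.1)
  expect_equal(cr$d_1e2, 8, tolerance = 0.2)
  expect_lte(cr$d_1e, cr$d_1e2)
  # never crossing: flagged NA
  expect_true(is.na(spread_distances(0:3, rep(1, 4))$d_1e))
})
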