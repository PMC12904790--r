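test_that("design matrix has the Toeplitz impulse structure", {
  gd <- c(3, 3)
  n_stim <- 20
  frames <- array(0L, c(n_stim, gd))
  frames[5, 2, 2] <- 1L                       # single white flash
  st <- structure(list(frames = frames, refresh_rate = 5,
                       p_nongray = 0, grid_dim = gd),
                  class = "sparse_noise_stimulus")
  x <- build_design(st, response_rate = 5, max_lag = 0.6)
  n_lags <- attr(x, "n_lags")
  expect_identical(ncol(x), 2L * 9L * n_lags)  # shape contract
  p_idx <- 2 + (2 - 1) * 3                     # pixel (2,2), column-major
  xm <- as.matrix(x)
  for (l in seq_len(n_lags)) {
    col <- (l - 1) * 9 + p_idx
    expect_equal(which(xm[, col] != 0), 5 + (l - 1))  # diagonal streak
  }
  expect_true(all(xm[, 9 * n_lags + seq_len(9 * n_lags)] == 0))  # OFF empty

  # all-gray stimulus: all-zero design
  st0 <- structure(list(frames = array(0L, c(10, gd)), refresh_rate = 5,
                        p_nongray = 0, grid_dim = gd),
                   class = "sparse_noise_stimulus")
  expect_equal(sum(abs(build_design(st0, 5, 0.4))), 0)
  expect_error(build_design(st, 5, max_lag = -1), "max_lag")
})

test_that("explained variance follows its definition", {
  expect_equal(explained_variance(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(explained_variance(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(explained_variance(c(1, 2, 3), c(1, 1, 1)), -1.5)
  expect_error(explained_variance(1, 1), "test samples")
  expect_warning(ev <- explained_variance(c(2, 2), c(1, 2)), "variance")
  expect_true(is.na(ev))
})

test_that("ridge fits invert the forward model and shrink sensibly", {
  gd <- c(5, 5)
  rate <- 10
  stim <- sparse_noise_stimulus(180, gd, refresh_rate = 5, p_nongray = 0.05,
                                seed = 3)
  rf <- make_rf(gd, 5, 3, 3, off_scale = 0.4)
  ses <- simulate_sparse_noise_session(stim, rf, noise_sd = 0,
                                       response_rate = rate)
  x <- build_design(stim, rate, max_lag = 0.4,
                    n_samples = length(ses$response))
  w_true <- c(as.numeric(rf$on), as.numeric(rf$off))
  # forward model consistency between simulator and design matrix
  expect_equal(as.numeric(x %*% w_true), ses$response, tolerance = 1e-10)

  fit <- fit_strf(x, ses$response, lambda = 1e-8)
  expect_gt(stats::cor(fit$w, w_true), 0.99)
  expect_equal(explained_variance(ses$response, fit$fitted), 1,
               tolerance = 1e-6)

  # very large lambda: weights spatially constant per lag (Laplacian null
  # space), shrunken norm
  big <- fit_strf(x, ses$response, lambda = 1e10)
  arr <- glusense:::strf_weight_arrays(big$w, gd, attr(x, "n_lags"))
  per_lag_sd <- apply(arr$on, 3, stats::sd)
  expect_lt(max(per_lag_sd), 1e-4 * max(abs(big$w)) + 1e-12)
  expect_lt(sum(big$w^2), sum(fit$w^2))
})

test_that("cross-validation picks sensible lambdas", {
  gd <- c(4, 4)
  rate <- 10
  stim <- sparse_noise_stimulus(150, gd, refresh_rate = 5, p_nongray = 0.06,
                                seed = 8)
  rf <- make_rf(gd, 4, 2, 3)
  lams <- 10^seq(-4, 4, by = 1)
  ses0 <- simulate_sparse_noise_session(stim, rf, noise_sd = 0,
                                        response_rate = rate)
  cv0 <- crossval_lambda(build_design(stim, rate, 0.3,
                                      n_samples = length(ses0$response)),
                         ses0$response, lams, k = 3)
  expect_equal(cv0$lambda, min(lams))        # no-noise limit
  expect_equal(cv0$ev_cv, 1, tolerance = 1e-6)

  # pure-noise response: all EV <= ~0, but a lambda is still returned
  set.seed(9)
  yn <- rnorm(length(ses0$response))
  cvn <- crossval_lambda(build_design(stim, rate, 0.3,
                                      n_samples = length(yn)),
                         yn, lams, k = 3)
  expect_lt(cvn$ev_cv, 0.05)
  expect_true(cvn$lambda %in% lams)

  # noisy signal: EV(lambda) rises then falls (unimodal in practice)
  ses <- simulate_sparse_noise_session(stim, rf,
                                       noise_sd = stats::sd(ses0$response),
                                       response_rate = rate, seed = 10)
  cv <- crossval_lambda(build_design(stim, rate, 0.3,
                                     n_samples = length(ses$response)),
                        ses$response, lams, k = 3)
  ev <- cv$ev_by_lambda$ev
  expect_gt(which.max(ev), 1)
  expect_lt(which.max(ev), length(ev))
  signs <- sign(diff(ev))
  expect_lte(sum(diff(signs[signs != 0]) != 0), 1)

  expect_error(crossval_lambda(matrix(1, 5, 2), rnorm(5), 1, k = 3), "folds")
})

test_that("circular-shift test is significant only for real structure", {
  gd <- c(4, 4)
  rate <- 10
  stim <- sparse_noise_stimulus(120, gd, refresh_rate = 5, p_nongray = 0.06,
                                seed = 11)
  rf <- make_rf(gd, 4, 2, 2)
  ses <- simulate_sparse_noise_session(stim, rf, noise_sd = 0,
                                       response_rate = rate)
  x <- build_design(stim, rate, 0.3, n_samples = length(ses$response))
  st <- circular_shift_test(x, ses$response, lambda = 0.01,
                            n_shifts = 200, min_shift = 5, seed = 1)
  expect_equal(st$p, 1 / 200)               # floor; no null exceedance
  st2 <- circular_shift_test(x, ses$response, lambda = 0.01,
                             n_shifts = 200, min_shift = 5, seed = 1)
  expect_identical(st$p, st2$p)             # seed determinism
  expect_error(circular_shift_test(x, ses$response, 0.01, n_shifts = 1),
               "n_shifts")
  expect_warning(circular_shift_test(x, ses$response, 0.01, n_shifts = 50,
                                     seed = 2), "coarse")
})

test_that("responsiveness combines the EV and p thresholds", {
  expect_true(classify_responsive(0.15, 0.001))
  expect_false(classify_responsive(0.15, 0.02))
  expect_false(classify_responsive(0.09, 0.0001))
  expect_false(classify_responsive(0.1, 0.001))   # must exceed 0.1
  expect_error(classify_responsive(NA, 0.1), "defined")
})

test_that("spatial RF extraction and Gaussian fits localize subfields", {
  gd <- c(9, 9)
  n_lags <- 4
  on <- array(0, c(gd, n_lags))
  on[, , 3] <- glusense:::gaussian_footprint(gd, 5.3, 4.2, 1.5)
  obj <- list(on_weights = on, off_weights = array(0, c(gd, n_lags)),
              lags = (0:3) / 10)
  sp <- spatial_rf(obj)
  expect_equal(sp$best_lag, 0.2)
  # pure ON RF: combined map equals ON / 2 (signed-average convention)
  expect_equal(sp$map, on[, , 3] / 2)
  expect_true(sp$gaussian$converged)
  expect_lt(max(abs(sp$gaussian$center - c(5.3, 4.2))), 0.3)
  # rotationally symmetric truth: sigma_x ~ sigma_y
  expect_equal(sp$gaussian$sigma[1], sp$gaussian$sigma[2], tolerance = 0.05)
})

test_that("full fit EV exceeds cross-validated EV in expectation", {
  gd <- c(4, 4)
  rate <- 10
  stim <- sparse_noise_stimulus(100, gd, refresh_rate = 5, p_nongray = 0.06,
                                seed = 12)
  rf <- make_rf(gd, 4, 3, 2)
  base <- simulate_sparse_noise_session(stim, rf, noise_sd = 0,
                                        response_rate = rate)
  sig_sd <- stats::sd(base$response)
  diffs <- vapply(1:12, function(i) {
    ses <- simulate_sparse_noise_session(stim, rf, noise_sd = sig_sd,
                                         response_rate = rate, seed = 100 + i)
    x <- build_design(stim, rate, 0.3, n_samples = length(ses$response))
    cv <- crossval_lambda(x, ses$response, 10^seq(-2, 4, by = 1), k = 3)
    explained_variance(ses$response, cv$fit$fitted) - cv$ev_cv
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("stRF estimation recovers a known RF end to end", {
  gd <- c(6, 6)
  rate <- 15
  stim <- sparse_noise_stimulus(300, gd, refresh_rate = 5, p_nongray = 0.02,
                                seed = 2)
  rf <- make_rf(gd, floor(1.4 * rate) + 1, 3, 4)
  clean <- simulate_sparse_noise_session(stim, rf, noise_sd = 0,
                                         response_rate = rate)
  sig_sd <- stats::sd(clean$response)
  ses <- simulate_sparse_noise_session(stim, rf, noise_sd = sig_sd / 5,
                                       response_rate = rate, seed = 3)
  fit <- estimate_strf(stim, ses$response, rate,
                       lambdas = 10^seq(-1, 5, by = 0.5),
                       n_shifts = 400, min_shift = 5, seed = 4)
  expect_gt(fit$ev_cv, 0.3)
  expect_true(fit$responsive)
  expect_lt(max(abs(fit$spatial$gaussian$center - c(3, 4))), 1)

  # shuffled responses: never responsive (fixed seeds, deterministic)
  for (i in 1:5) {
    set.seed(200 + i)
    yshuf <- sample(ses$response)
    fs <- estimate_strf(stim, yshuf, rate, lambdas = 10^seq(1, 5, by = 1),
                        n_shifts = 400, min_shift = 5, seed = 300 + i)
    expect_false(fs$responsive)
  }
})
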