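# Shared fixture builders; everything is generated in code under fixed
# seeds, no data files.

# Ideal (noise-free) trace of kernel-convolved events on the frame grid.
ideal_trace <- function(event_times, duration, frame_rate, kinetics) {
  glusense:::event_trace(event_times, round(duration * frame_rate),
                         frame_rate, kinetics)
}

# Small movie with sites on a fixed grid of well-separated centres.
separated_movie <- function(n_sites = 5, duration = 30, seed = 11,
                            brightness = 60, rate = 0.8) {
  cfg <- sim_config(frame_rate = 100, duration = duration,
                    image_shape = c(48, 48), n_sites = n_sites,
                    footprint_sigma = 1.5, baseline_photon_rate = 20,
                    site_brightness = brightness, seed = seed)
  kin <- kinetic_params(A = 1.5, t0 = 0, tau_rise = 0.002, tau_decay = 0.05)
  centers <- cbind(c(10, 10, 24, 38, 38), c(10, 38, 24, 10, 38))
  centers <- centers[seq_len(n_sites), , drop = FALSE]
  trains <- lapply(seq_len(n_sites), function(s)
    simulate_release_train(rate, duration, seed = seed + 100 + s))
  list(movie = render_movie(cfg, trains, kin, site_centers = centers),
       centers = centers, trains = trains, kinetics = kin, config = cfg)
}

# Grating-session trial structure without imaging: a shared source trace
# modulated by an orientation tuning curve, for tuning-statistics tests.
tuned_trial_structure <- function(trials_per_direction = 12, frame_rate = 20,
                                  kappa = 2, pref = 0, seed = 31) {
  dirs8 <- seq(0, 315, by = 45)
  withr_seed <- function(expr) glusense:::with_seed(seed, expr)
  directions <- withr_seed(sample(rep(dirs8, trials_per_direction)))
  onsets <- 1 + (seq_along(directions) - 1) * 3
  duration <- max(onsets) + 3
  n <- round(duration * frame_rate)
  gain <- exp(kappa * (cos(2 * (dirs8 - pref) * pi / 180) - 1))
  src <- numeric(n)
  for (i in seq_along(onsets)) {
    g <- gain[match(directions[i], dirs8)]
    i0 <- round(onsets[i] * frame_rate) + 1
    idx <- i0:(i0 + round(2 * frame_rate) - 1)
    src[idx] <- src[idx] + g
  }
  list(src = src, onsets = onsets, directions = directions,
       frame_rate = frame_rate, n = n, gain = gain, dirs8 = dirs8)
}

# Separable ON-dominated spatiotemporal RF on a given grid.
make_rf <- function(gd, n_lags, cy, cx, sigma = 1.2, off_scale = 0) {
  prof <- exp(-((seq_len(n_lags) - 4)^2) / 8)
  prof[1:2] <- 0
  on <- array(0, c(gd, n_lags))
  for (l in seq_len(n_lags))
    on[, , l] <- glusense:::gaussian_footprint(gd, cy, cx, sigma) * prof[l]
  list(on = on, off = off_scale * on)
}
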