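#' Indicator kinetic parameters
#'
#' Bundle of the four parameters of the rise/decay transient model
#' \deqn{f(t) = A (1 - e^{-(t-t_0)/\tau_{rise}}) e^{-(t-t_0)/\tau_{decay}}}
#' used throughout the package to describe single-release glutamate
#' transients.
#'
#' @param A amplitude factor (dimensionless, \eqn{\Delta F/F_0} units).
#'   The realised peak of the curve is smaller than `A` (see
#'   [transient_amplitude()]).
#' @param t0 onset time of the transient (s); the time of the action
#'   potential or release event.
#' @param tau_rise activation time constant (s), must be positive.
#' @param tau_decay deactivation time constant (s), must be positive.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(A = 1, t0 = 0, tau_rise = 0.002, tau_decay = 0.03) {
  if (!is.finite(A) || A < 0) stopf("A must be >= 0")
  if (!is.finite(tau_rise) || tau_rise <= 0) stopf("tau_rise must be > 0")
  if (!is.finite(tau_decay) || tau_decay <= 0) stopf("tau_decay must be > 0")
  structure(list(A = A, t0 = t0, tau_rise = tau_rise, tau_decay = tau_decay),
            class = "kinetic_params")
}

#' Peak time and peak value of the transient model
#'
#' Closed forms derived by setting the derivative of the transient equation
#' to zero: the peak occurs at
#' \eqn{t^* = \tau_{rise} \ln(1 + \tau_{decay}/\tau_{rise})} after onset.
#'
#' @param params a [kinetic_params()] object.
#' @return `transient_time_to_peak`: seconds from onset to peak.
#'   `transient_amplitude`: peak value of the fitted curve.
#' @export
transient_time_to_peak <- function(params) {
  with(params, tau_rise * log(1 + tau_decay / tau_rise))
}

#' @rdname transient_time_to_peak
#' @export
transient_amplitude <- function(params) {
  with(params, {
    A * tau_decay / (tau_rise + tau_decay) *
      (1 + tau_decay / tau_rise)^(-tau_rise / tau_decay)
  })
}

#' Evaluate the transient model on a time grid
#'
#' @param params a [kinetic_params()] object.
#' @param t times (s). Values before `t0` map to 0.
#' @return numeric vector of \eqn{\Delta F/F_0} values.
#' @export
transient_model <- function(params, t) {
  dt <- t - params$t0
  ifelse(dt > 0,
         params$A * (1 - exp(-dt / params$tau_rise)) * exp(-dt / params$tau_decay),
         0)
}

#' Sample the indicator impulse-response kernel at the frame grid
#'
#' The kernel is the transient model with `t0 = 0`, sampled at
#' `0, 1/frame_rate, 2/frame_rate, ...` up to `support` seconds.
#'
#' @param params a [kinetic_params()] object (its `t0` is ignored).
#' @param frame_rate sampling rate (Hz).
#' @param support kernel duration (s); at least `5 * tau_decay` recommended.
#' @return numeric vector with attribute `t` holding the sample times.
#' @export
indicator_kernel <- function(params, frame_rate, support = 5 * params$tau_decay) {
  if (!is.finite(frame_rate) || frame_rate <= 0) stopf("frame_rate must be > 0")
  if (support <= 0) stopf("support must be > 0")
  t <- seq(0, support, by = 1 / frame_rate)
  p0 <- params
  p0$t0 <- 0
  structure(transient_model(p0, t), t = t)
}

#' Simulation configuration for synthetic movies
#'
#' @param frame_rate imaging frame rate (Hz).
#' @param duration recording duration (s).
#' @param image_shape integer c(rows, cols) in pixels.
#' @param n_sites number of point-source synaptic sites.
#' @param footprint_sigma isotropic Gaussian footprint sigma (px).
#' @param baseline_photon_rate static background expectation
#'   (photons/frame/pixel).
#' @param site_brightness photons/frame contributed by a site at its
#'   footprint peak at baseline (the event transient multiplies this).
#' @param bleach_tau optional photobleaching time constant (s); `NULL`
#'   disables bleaching.
#' @param seed integer seed; identical seeds give bit-identical movies.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(frame_rate = 100, duration = 30,
                       image_shape = c(64, 64), n_sites = 5,
                       footprint_sigma = 1.5, baseline_photon_rate = 20,
                       site_brightness = 30, bleach_tau = NULL, seed = 1L) {
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (duration <= 0) stopf("duration must be > 0")
  if (any(image_shape < 1)) stopf("image_shape must be positive")
  if (!is_count(n_sites)) stopf("n_sites must be a nonnegative count")
  if (baseline_photon_rate < 0 || site_brightness < 0)
    stopf("photon rates must be >= 0")
  structure(list(frame_rate = frame_rate, duration = duration,
                 image_shape = as.integer(image_shape),
                 n_sites = as.integer(n_sites),
                 footprint_sigma = footprint_sigma,
                 baseline_photon_rate = baseline_photon_rate,
                 site_brightness = site_brightness,
                 bleach_tau = bleach_tau, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a release-event train
#'
#' Homogeneous-Poisson spontaneous events merged with Bernoulli-thinned
#' events at supplied locked times (stimulus- or spike-locked release).
#'
#' @param rate spontaneous event rate (events/s), >= 0.
#' @param duration train duration (s).
#' @param locked_times optional times (s) at which release occurs with
#'   probability `p_release`.
#' @param p_release release probability at each locked time.
#' @param seed optional integer seed.
#' @return sorted numeric vector of event times in `[0, duration)`.
#' @export
simulate_release_train <- function(rate, duration, locked_times = NULL,
                                   p_release = 1, seed = NULL) {
  if (!is.finite(rate) || rate < 0) stopf("rate must be >= 0")
  if (!is.finite(duration) || duration < 0) stopf("duration must be >= 0")
  if (p_release < 0 || p_release > 1) stopf("p_release must be in [0, 1]")
  with_seed(seed, {
    n <- stats::rpois(1L, rate * duration)
    ev <- if (n > 0) stats::runif(n, 0, duration) else numeric(0)
    if (length(locked_times)) {
      locked_times <- locked_times[locked_times >= 0 & locked_times < duration]
      keep <- stats::runif(length(locked_times)) < p_release
      ev <- c(ev, locked_times[keep])
    }
    sort(ev)
  })
}

# Unit-peak isotropic Gaussian footprint truncated at 4 sigma, as a
# rows x cols matrix centred at (cy, cx) in pixel coordinates.
gaussian_footprint <- function(shape, cy, cx, sigma) {
  fp <- matrix(0, shape[1L], shape[2L])
  r <- ceiling(4 * sigma)
  ys <- max(1L, floor(cy - r)):min(shape[1L], ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(shape[2L], ceiling(cx + r))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  v <- exp(-d2 / (2 * sigma^2))
  v[d2 > (4 * sigma)^2] <- 0
  fp[ys, xs] <- v
  fp
}

#' Ideal indicator trace for an event train
#'
#' Convolves release-event impulses with the indicator kernel on the frame
#' grid: the noise-free dF/F trace a site with these kinetics would show.
#' Each event contributes one impulse in the frame containing it.
#'
#' @param event_times event times (s).
#' @param duration trace duration (s).
#' @param frame_rate sampling rate (Hz).
#' @param kinetics a [kinetic_params()].
#' @return numeric trace of length `round(duration * frame_rate)`.
#' @export
release_trace <- function(event_times, duration, frame_rate, kinetics) {
  event_trace(event_times, round(duration * frame_rate), frame_rate,
              kinetics)
}

event_trace <- function(event_times, n_frames, frame_rate, kinetics) {
  imp <- numeric(n_frames)
  if (length(event_times)) {
    idx <- floor(event_times * frame_rate) + 1L
    idx <- idx[idx >= 1L & idx <= n_frames]
    for (i in idx) imp[i] <- imp[i] + 1
  }
  k <- indicator_kernel(kinetics, frame_rate)
  if (!any(imp > 0)) return(imp)
  full <- stats::convolve(imp, rev(k), type = "open")
  full[seq_len(n_frames)]
}

#' Render a synthetic photon-count movie
#'
#' Pixel expectations are
#' `baseline + bleach(t) * sum_site footprint * (1 + trace) * site_brightness`
#' where each site trace is its event train convolved with the indicator
#' kernel; every pixel-frame is then drawn independently Poisson. The static
#' baseline models unlabelled background and is not bleached.
#'
#' @param config a [sim_config()].
#' @param trains list of event-time vectors, one per site (recycled empty
#'   when shorter than `n_sites`).
#' @param kinetics a [kinetic_params()] shared by all sites.
#' @param site_centers optional n_sites x 2 matrix (row, col); randomly
#'   placed with a 4-sigma margin when `NULL`.
#' @param tuning optional [tuning_ground_truth()], stored with the output.
#' @return list of class `synthetic_movie`: `frames` (T x rows x cols
#'   integer array), `frame_rate`, and `ground_truth` (footprints, centers,
#'   trains, kinetics, tuning).
#' @export
render_movie <- function(config, trains, kinetics, site_centers = NULL,
                         tuning = NULL) {
  sh <- config$image_shape
  n_frames <- round(config$frame_rate * config$duration)
  n_px <- prod(sh)
  k <- config$n_sites
  if (length(trains) > k) stopf("more trains (%d) than sites (%d)",
                                length(trains), k)
  length(trains) <- k
  trains <- lapply(trains, function(x) if (is.null(x)) numeric(0) else x)
  with_seed(config$seed, {
    if (is.null(site_centers)) {
      m <- min(4 * config$footprint_sigma, min(sh) / 4)
      site_centers <- cbind(stats::runif(k, 1 + m, sh[1L] - m),
                            stats::runif(k, 1 + m, sh[2L] - m))
    }
    fps <- array(0, dim = c(k, sh[1L], sh[2L]))
    expectation <- matrix(config$baseline_photon_rate, n_frames, n_px)
    site_sum <- matrix(0, n_frames, n_px)
    for (s in seq_len(k)) {
      fp <- gaussian_footprint(sh, site_centers[s, 1L], site_centers[s, 2L],
                               config$footprint_sigma)
      fps[s, , ] <- fp
      tr <- event_trace(trains[[s]], n_frames, config$frame_rate, kinetics)
      site_sum <- site_sum +
        outer(1 + tr, as.vector(fp)) * config$site_brightness
    }
    if (!is.null(config$bleach_tau)) {
      t <- (seq_len(n_frames) - 1L) / config$frame_rate
      site_sum <- site_sum * exp(-t / config$bleach_tau)
    }
    expectation <- expectation + site_sum
    if (any(!is.finite(expectation)) || any(expectation < 0))
      stopf("pixel expectation overflow or negative", class = "glusense_generation_error")
    frames <- stats::rpois(length(expectation), expectation)
    dim(frames) <- c(n_frames, sh[1L], sh[2L])
    structure(list(frames = frames, frame_rate = config$frame_rate,
                   ground_truth = list(footprints = fps,
                                       centers = site_centers,
                                       trains = trains, kinetics = kinetics,
                                       tuning = tuning, config = config)),
              class = "synthetic_movie")
  })
}

#' Orientation-tuning ground truth for synthetic sites
#'
#' Sites follow a von-Mises-style orientation tuning curve on doubled
#' angles: the event-rate multiplier for a grating moving in direction
#' \eqn{\theta} is \eqn{\exp(\kappa(\cos 2(\theta - \theta_{pref}) - 1))},
#' which is 1 at the preferred orientation and flat for `kappa = 0`.
#'
#' @param preferred per-site preferred direction (deg), each a multiple
#'   of 45 in 0..315.
#' @param kappa per-site concentration (>= 0; 0 means untuned).
#' @param base_rate event rate (events/s) at the preferred orientation
#'   during the stimulus.
#' @return object of class `tuning_ground_truth` including the 8-direction
#'   rate-multiplier matrix (`site x direction`).
#' @export
tuning_ground_truth <- function(preferred, kappa, base_rate = 4) {
  if (any(preferred %% 45 != 0) || any(preferred < 0) || any(preferred >= 360))
    stopf("preferred directions must be multiples of 45 deg in [0, 315]")
  if (any(kappa < 0)) stopf("kappa must be >= 0")
  dirs <- seq(0, 315, by = 45)
  gain <- t(vapply(seq_along(preferred), function(s) {
    exp(kappa[s] * (cos(2 * (dirs - preferred[s]) * pi / 180) - 1))
  }, numeric(8L)))
  structure(list(preferred = preferred, kappa = kappa, base_rate = base_rate,
                 directions = dirs, gain = gain),
            class = "tuning_ground_truth")
}

#' Simulate a drifting-grating tuned imaging session
#'
#' Eight grating directions (45-degree increments) presented in randomized
#' order, `stim_dur` s of stimulus after `gray_dur` s of mean luminance,
#' each direction shown `trials_per_direction` times. Site event rates
#' during a stimulus are `base_rate * gain(direction)`; between stimuli a
#' low spontaneous rate applies.
#'
#' @param config a [sim_config()]; its `duration` is overridden by the
#'   trial schedule.
#' @param tuning a [tuning_ground_truth()] with one entry per site.
#' @param kinetics a [kinetic_params()].
#' @param trials_per_direction trials per direction (paper design: 15).
#' @param directions stimulus directions (deg), multiples of 45.
#' @param stim_dur,gray_dur stimulus-on and preceding gray durations (s).
#' @param spont_rate spontaneous event rate between stimuli (events/s).
#' @return list: `movie` ([render_movie()] output) and `stim_log`
#'   (data.frame onset_s, direction_deg).
#' @export
simulate_tuned_session <- function(config, tuning, kinetics,
                                   trials_per_direction = 15,
                                   directions = seq(0, 315, by = 45),
                                   stim_dur = 2, gray_dur = 1,
                                   spont_rate = 0.1) {
  if (any(directions %% 45 != 0))
    stopf("directions must be multiples of 45 deg")
  if (trials_per_direction < 1) stopf("trials_per_direction must be >= 1")
  n_sites <- length(tuning$preferred)
  if (n_sites != config$n_sites) stopf("tuning must describe n_sites sites")
  with_seed(derive_seed(config$seed, "tuned_session"), {
    trial_dirs <- sample(rep(directions, trials_per_direction))
    n_trials <- length(trial_dirs)
    onsets <- gray_dur + (seq_len(n_trials) - 1L) * (gray_dur + stim_dur)
    duration <- n_trials * (gray_dur + stim_dur)
    trains <- lapply(seq_len(n_sites), function(s) {
      ev <- simulate_release_train(spont_rate, duration)
      for (i in seq_len(n_trials)) {
        rate <- tuning$base_rate *
          tuning$gain[s, match(trial_dirs[i], tuning$directions)]
        n <- stats::rpois(1L, rate * stim_dur)
        if (n > 0) ev <- c(ev, onsets[i] + stats::runif(n, 0, stim_dur))
      }
      sort(ev)
    })
    cfg <- config
    cfg$duration <- duration
    movie <- render_movie(cfg, trains, kinetics, tuning = tuning)
    list(movie = movie,
         stim_log = data.frame(onset_s = onsets, direction_deg = trial_dirs))
  })
}

#' Generate a sparse-noise stimulus
#'
#' Each grid cell is independently non-gray with probability `p_nongray`
#' in every frame (black/white equiprobable given non-gray), matching the
#' retinotopic-mapping stimulus design (2% non-gray, 5 Hz refresh).
#'
#' @param duration stimulus duration (s).
#' @param grid_dim integer c(gridY, gridX).
#' @param refresh_rate stimulus refresh rate (Hz).
#' @param p_nongray per-cell probability of being non-gray.
#' @param seed integer seed.
#' @return object of class `sparse_noise_stimulus`: `frames`
#'   (T_stim x gridY x gridX array of -1/0/+1), `refresh_rate`, `p_nongray`.
#' @export
sparse_noise_stimulus <- function(duration, grid_dim = c(8, 8),
                                  refresh_rate = 5, p_nongray = 0.02,
                                  seed = 1L) {
  if (p_nongray < 0 || p_nongray > 1) stopf("p_nongray must be in [0, 1]")
  n <- round(duration * refresh_rate)
  with_seed(seed, {
    u <- stats::runif(n * prod(grid_dim))
    f <- integer(length(u))
    f[u < p_nongray / 2] <- 1L
    f[u >= p_nongray / 2 & u < p_nongray] <- -1L
    dim(f) <- c(n, grid_dim[1L], grid_dim[2L])
    structure(list(frames = f, refresh_rate = refresh_rate,
                   p_nongray = p_nongray, grid_dim = as.integer(grid_dim)),
              class = "sparse_noise_stimulus")
  })
}

# Sample-and-hold upsampling: stimulus frame index for each response sample.
stim_frame_at <- function(n_resp, response_rate, refresh_rate, n_stim) {
  t <- (seq_len(n_resp) - 1L) / response_rate
  pmin(n_stim, floor(t * refresh_rate) + 1L)
}

#' Simulate responses of linear receptive fields to sparse noise
#'
#' The response is the stimulus history weighted by ON and OFF
#' spatiotemporal receptive fields plus white Gaussian noise:
#' `r(t) = sum_lags sum_px RF_ON * max(S, 0) + RF_OFF * max(-S, 0) + noise`.
#' The stimulus is upsampled to the response rate by sample-and-hold. The
#' forward model here is computed by direct convolution, independently of
#' the Toeplitz design matrix used for fitting.
#'
#' @param stimulus a [sparse_noise_stimulus()].
#' @param true_rf list with arrays `on` and `off`, each
#'   gridY x gridX x n_lags, lags at the response sampling grid from 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param response_rate response sampling rate (Hz).
#' @param seed optional integer seed for the noise.
#' @return list: `response` (numeric), `response_rate`, `stimulus`,
#'   `true_rf`.
#' @export
simulate_sparse_noise_session <- function(stimulus, true_rf, noise_sd = 0,
                                          response_rate = 30, seed = NULL) {
  gd <- stimulus$grid_dim
  don <- dim(true_rf$on)
  if (!identical(don[1:2], gd) || !identical(dim(true_rf$off), don))
    stopf("RF grid does not match the stimulus grid")
  n_lags <- don[3L]
  if ((n_lags - 1) / response_rate > 1.4 + 1e-9)
    stopf("RF lag span exceeds 1.4 s")
  n_stim <- dim(stimulus$frames)[1L]
  n <- floor(n_stim / stimulus$refresh_rate * response_rate)
  idx <- stim_frame_at(n, response_rate, stimulus$refresh_rate, n_stim)
  s <- matrix(stimulus$frames, nrow = n_stim)[idx, , drop = FALSE]
  on <- pmax(s, 0)
  off <- pmax(-s, 0)
  w_on <- matrix(true_rf$on, ncol = n_lags)    # px x lag
  w_off <- matrix(true_rf$off, ncol = n_lags)
  resp <- numeric(n)
  for (l in seq_len(n_lags)) {
    d <- l - 1L
    rows <- seq_len(n - d)
    resp[rows + d] <- resp[rows + d] +
      on[rows, , drop = FALSE] %*% w_on[, l] +
      off[rows, , drop = FALSE] %*% w_off[, l]
  }
  if (noise_sd > 0)
    resp <- resp + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  list(response = as.numeric(resp), response_rate = response_rate,
       stimulus = stimulus, true_rf = true_rf)
}

#' Simulate a fiber-photometry trace
#'
#' `trace = drift(t) * exp(-t/bleach_tau) * (1 + sum kernels at rewards)
#' + noise`, where `drift` is a polynomial in `t` (coefficients in
#' increasing order: c0 + c1 t + ...).
#'
#' @param duration trace duration (s).
#' @param reward_times reward delivery times (s), within the trace.
#' @param kinetics a [kinetic_params()] for the reward transient (use slow
#'   time constants for bulk photometry signals).
#' @param drift_poly_coeffs polynomial drift coefficients (increasing order).
#' @param bleach_tau photobleaching time constant (s); `Inf` disables.
#' @param noise_sd additive Gaussian noise sd.
#' @param rate_hz sampling rate (Hz).
#' @param seed optional integer seed.
#' @return list of class `photometry_trace`: `values`, `rate_hz`,
#'   `events` (data.frame time_s, label).
#' @export
simulate_photometry <- function(duration, reward_times, kinetics,
                                drift_poly_coeffs = c(1, 0, 0, 0, 0),
                                bleach_tau = Inf, noise_sd = 0,
                                rate_hz = 20, seed = NULL) {
  if (any(reward_times < 0 | reward_times > duration))
    stopf("reward_times must lie within the trace")
  n <- round(duration * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  drift <- rowSums(outer(t, seq_along(drift_poly_coeffs) - 1, "^") *
                     rep(drift_poly_coeffs, each = n))
  sig <- event_trace(reward_times, n, rate_hz, kinetics)
  vals <- drift * exp(-t / bleach_tau) * (1 + sig)
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  structure(list(values = vals, rate_hz = rate_hz,
                 events = data.frame(time_s = reward_times,
                                     label = rep("reward",
                                                 length(reward_times)))),
            class = "photometry_trace")
}
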