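#' Fractional fluorescence change (dF/F0)
#'
#' Computes `(F - F0) / F0`. In `moving_median` mode `F0` is a per-frame
#' moving median of `F` (default window 10,001 frames, the convention used
#' for in vivo gratings recordings); windows shrink (truncate) at the trace
#' edges. In `baseline_mean` mode `F0` is the mean of the first
#' `baseline_span` seconds.
#'
#' @param values raw fluorescence trace.
#' @param frame_rate sampling rate (Hz); only needed for `baseline_mean`.
#' @param mode baseline mode.
#' @param window_frames odd moving-median window length (frames).
#' @param baseline_span baseline duration (s) for `baseline_mean`.
#' @return numeric dF/F0 trace of the same length.
#' @export
compute_dff <- function(values, frame_rate = NULL,
                        mode = c("moving_median", "baseline_mean"),
                        window_frames = 10001L, baseline_span = 1) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 3L) stopf("trace must have length >= 3")
  if (mode == "moving_median") {
    if (window_frames %% 2L == 0L) stopf("window_frames must be odd")
    f0 <- moving_median(values, as.integer(window_frames))
  } else {
    if (is.null(frame_rate)) stopf("frame_rate required for baseline_mean")
    nb <- max(1L, min(n, round(baseline_span * frame_rate)))
    f0 <- rep(mean(values[seq_len(nb)]), n)
  }
  if (any(f0 <= 0))
    stopf("baseline F0 <= 0; cannot form dF/F0",
          class = "glusense_degenerate_baseline")
  (values - f0) / f0
}

# Moving median with edge-truncated (shrinking) windows:
# out[i] = median(x[max(1, i-h) : min(n, i+h)]). Interior values come from
# stats::runmed (Turlach algorithm); edges are computed directly.
moving_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(x)
  out <- numeric(n)
  if (n >= w) {
    out <- as.numeric(stats::runmed(x, w, endrule = "keep"))
    edge <- c(seq_len(h), (n - h + 1L):n)
  } else {
    edge <- seq_len(n)
  }
  for (i in edge)
    out[i] <- stats::median(x[max(1L, i - h):min(n, i + h)])
  out
}

#' Spike-triggered average of a fluorescence trace
#'
#' Averages trace snippets aligned to isolated spikes. A spike qualifies
#' only if no other spike falls within `isolation` seconds on either side
#' (the slow iGluSnFR4s decay makes closely spaced APs overlap, so the
#' reference analysis used 500 ms).
#'
#' @param values dF/F0 trace.
#' @param frame_rate sampling rate (Hz).
#' @param spike_times spike times (s) relative to trace start.
#' @param pre,post snippet extent before/after the spike (s).
#' @param isolation minimum separation from neighbouring spikes (s).
#' @return list of class `sta`: `mean`, `sem`, `t` (s relative to spike),
#'   `n_used`, `empty` flag. When no spike qualifies, `empty = TRUE` and
#'   the traces are `NULL` (not an error).
#' @export
spike_triggered_average <- function(values, frame_rate, spike_times,
                                    pre = 0.02, post = 0.4,
                                    isolation = 0.5) {
  if (pre < 0 || post < 0) stopf("pre and post must be >= 0")
  st <- sort(spike_times)
  iso <- rep(TRUE, length(st))
  if (length(st) > 1L) {
    gaps <- diff(st)
    iso[-length(st)] <- iso[-length(st)] & gaps > isolation
    iso[-1L] <- iso[-1L] & gaps > isolation
  }
  st <- st[iso]
  npre <- round(pre * frame_rate)
  npost <- round(post * frame_rate)
  n <- length(values)
  snips <- list()
  for (ts in st) {
    i0 <- round(ts * frame_rate) + 1L
    idx <- (i0 - npre):(i0 + npost)
    if (idx[1L] >= 1L && idx[length(idx)] <= n)
      snips[[length(snips) + 1L]] <- values[idx]
  }
  tt <- ((-npre):npost) / frame_rate
  if (!length(snips))
    return(structure(list(mean = NULL, sem = NULL, t = tt, n_used = 0L,
                          empty = TRUE), class = "sta"))
  m <- do.call(rbind, snips)
  structure(list(mean = colMeans(m),
                 sem = if (nrow(m) > 1L)
                   apply(m, 2L, stats::sd) / sqrt(nrow(m))
                 else rep(0, ncol(m)),
                 t = tt, n_used = nrow(m), empty = FALSE),
            class = "sta")
}

#' Fit the rise/decay transient model to a trace
#'
#' Nonlinear least squares fit of
#' \eqn{A(1-e^{-(t-t_0)/\tau_{rise}})e^{-(t-t_0)/\tau_{decay}}}, zero
#' before \eqn{t_0}. Default initialization: `t0` at the 10%-rise crossing
#' before the peak, `tau_rise` = 2 frames, `tau_decay` from the 1/e point
#' after the peak, `A` = peak value. Taus are optimized on a log scale so
#' they stay positive. Non-convergence is reported via `converged`, never
#' silently.
#'
#' @param values trace to fit (e.g. an STA mean); peak must be positive.
#' @param frame_rate sampling rate (Hz).
#' @param t_start time of the first sample (s).
#' @param t0_known optional fixed onset time (s); fitted when `NULL`.
#' @return object of class `transient_fit`: `params` ([kinetic_params()]),
#'   `amplitude` (peak of the fitted curve), `time_to_peak`, `rss`,
#'   `converged`, `fitted`.
#' @export
fit_transient <- function(values, frame_rate, t_start = 0, t0_known = NULL) {
  n <- length(values)
  t <- t_start + (seq_len(n) - 1L) / frame_rate
  pk <- max(values)
  if (!is.finite(pk) || pk <= 0) stopf("trace peak must be > 0")
  ipk <- which.max(values)
  # initialization (documented defaults)
  pre <- which(values[seq_len(ipk)] < 0.1 * pk)
  t0_init <- if (!is.null(t0_known)) t0_known
             else if (length(pre)) t[max(pre)] else t[1L]
  tr_init <- 2 / frame_rate
  post <- which(values[ipk:n] < pk / exp(1))
  td_init <- if (length(post)) max(t[ipk + post[1L] - 1L] - t[ipk], 2 / frame_rate)
             else max(t[n] - t[ipk], 2 / frame_rate)
  obj <- function(par, t0) {
    p <- list(A = exp(par[1L]), t0 = t0, tau_rise = exp(par[2L]),
              tau_decay = exp(par[3L]))
    sum((values - transient_model(p, t))^2)
  }
  fit_at <- function(t0) {
    par0 <- log(c(pk, tr_init, td_init))
    o <- stats::optim(par0, obj, t0 = t0, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    # BFGS polish on the smooth (A, log tau) surface for a clean
    # convergence diagnostic at machine precision
    o2 <- tryCatch(stats::optim(o$par, obj, t0 = t0, method = "BFGS",
                                control = list(maxit = 500,
                                               reltol = 1e-14)),
                   error = function(e) NULL)
    if (!is.null(o2) && o2$value <= o$value) o2 else o
  }
  if (is.null(t0_known)) {
    opt_t0 <- stats::optimize(function(t0) fit_at(t0)$value,
                              interval = c(t0_init - 3 / frame_rate,
                                           t0_init + 3 / frame_rate),
                              tol = 1e-6 / frame_rate)
    t0_hat <- opt_t0$minimum
  } else {
    t0_hat <- t0_known
  }
  o <- fit_at(t0_hat)
  params <- kinetic_params(A = exp(o$par[1L]), t0 = t0_hat,
                           tau_rise = exp(o$par[2L]),
                           tau_decay = exp(o$par[3L]))
  structure(list(params = params,
                 amplitude = transient_amplitude(params),
                 time_to_peak = transient_time_to_peak(params),
                 rss = o$value,
                 converged = o$convergence == 0L,
                 diagnostics = if (o$convergence != 0L) o else NULL,
                 fitted = transient_model(params, t), t = t),
            class = "transient_fit")
}

# Huber-weighted iteratively reweighted least-squares line fit; the robust
# linear model used for log-autocorrelation decay slopes. Returns slope,
# intercept, slope standard error and two-sided slope p-value (t-test).
huber_line <- function(x, y, k = 1.345, max_iter = 50L) {
  w <- rep(1, length(x))
  a <- b <- 0
  for (i in seq_len(max_iter)) {
    sw <- sum(w)
    xm <- sum(w * x) / sw
    ym <- sum(w * y) / sw
    sxx <- sum(w * (x - xm)^2)
    if (sxx <= 0) return(NULL)
    b <- sum(w * (x - xm) * (y - ym)) / sxx
    a <- ym - b * xm
    r <- y - a - b * x
    s <- stats::median(abs(r)) / 0.6745
    if (s <= .Machine$double.eps) break
    w_new <- pmin(1, k * s / abs(r))
    if (max(abs(w_new - w)) < 1e-10) {
      w <- w_new
      break
    }
    w <- w_new
  }
  m <- length(x)
  if (m < 3L) return(NULL)
  sw <- sum(w)
  xm <- sum(w * x) / sw
  sxx <- sum(w * (x - xm)^2)
  r <- y - a - b * x
  s2 <- sum(w * r^2) / (sw - 2)
  se <- sqrt(s2 / sxx)
  p <- 2 * stats::pt(-abs(b / se), df = m - 2)
  list(slope = b, intercept = a, se = se, p = p)
}

#' Estimate the indicator decay constant from trace autocorrelation
#'
#' The trace is cut into windows (default 10 s). Within each window the
#' autocorrelation at incremental time lags is computed, a robust
#' (Huber IRLS) line is fitted to `log(autocorrelation)` versus lag, and
#' windows whose slope is significantly negative (`p < alpha`) contribute
#' `tau = |1 / slope|`. The trace-level tau summarizes the window taus
#' (default: minimum, mirroring the branch-level convention that bursts
#' bias slower).
#'
#' @param values dF/F-like trace.
#' @param frame_rate sampling rate (Hz).
#' @param window window length (s).
#' @param max_lag maximum lag (s); default `min(1, window / 4)`.
#' @param alpha significance threshold for the slope fit.
#' @param summary `"min"` (default) or `"median"` over window taus.
#' @return list of class `decay_estimate`: `tau` (s, `NA` when no window
#'   is significant), `defined`, `window_taus`, `n_windows_used`,
#'   `p_values`.
#' @export
decay_from_autocorrelation <- function(values, frame_rate, window = 10,
                                       max_lag = NULL, alpha = 0.001,
                                       summary = c("min", "median")) {
  summary <- match.arg(summary)
  if (is.null(max_lag)) max_lag <- min(1, window / 4)
  if (max_lag >= window) stopf("max_lag must be < window")
  wlen <- round(window * frame_rate)
  nlag <- max(3L, round(max_lag * frame_rate))
  n <- length(values)
  n_win <- max(1L, floor(n / wlen))
  taus <- pvals <- rep(NA_real_, n_win)
  for (wi in seq_len(n_win)) {
    seg <- values[((wi - 1L) * wlen + 1L):min(n, wi * wlen)]
    if (length(seg) < 3L * nlag || stats::sd(seg) == 0) next
    ac <- stats::acf(seg, lag.max = nlag, plot = FALSE,
                     demean = TRUE)$acf[-1L]
    # beyond the first nonpositive autocorrelation the log-decay is pure
    # noise; truncate there
    zero <- which(ac <= 0)
    if (length(zero)) ac <- ac[seq_len(zero[1L] - 1L)]
    lags <- seq_along(ac) / frame_rate
    if (length(ac) < 3L) next
    fit <- huber_line(lags, log(ac))
    if (is.null(fit) || !is.finite(fit$p)) next
    pvals[wi] <- fit$p
    if (fit$p < alpha && fit$slope < 0) taus[wi] <- abs(1 / fit$slope)
  }
  ok <- !is.na(taus)
  tau <- if (!any(ok)) NA_real_
         else if (summary == "min") min(taus[ok]) else stats::median(taus[ok])
  structure(list(tau = tau, defined = any(ok), window_taus = taus,
                 n_windows_used = sum(ok), p_values = pvals),
            class = "decay_estimate")
}

#' Branch-level decay constant
#'
#' Minimum defined decay time across release sites on the same dendritic
#' branch (single-event decays are the fastest credible estimate; bursts
#' and overlap only slow apparent decay).
#'
#' @param estimates list of [decay_from_autocorrelation()] results, or a
#'   numeric vector of taus (s) possibly containing `NA`.
#' @return minimum defined tau (s), or `NA` when all are undefined.
#' @export
branch_decay <- function(estimates) {
  taus <- if (is.numeric(estimates)) estimates
          else vapply(estimates, function(e) e$tau, numeric(1L))
  ok <- !is.na(taus)
  if (!any(ok)) return(NA_real_)
  min(taus[ok])
}

#' Detect glutamate transients by modified z-score threshold crossing
#'
#' The baseline is the `baseline_span`-second window with the lowest
#' standard deviation anywhere in the trace; the z-trace uses that
#' window's mean and sd. One event is reported per contiguous
#' supra-threshold run, timed at the run's first frame.
#'
#' @param values dF/F0 trace.
#' @param frame_rate sampling rate (Hz).
#' @param baseline_span baseline window length (s).
#' @param threshold_sd detection threshold in baseline sd units.
#' @return list: `event_times` (s), `z` (z-score trace), `baseline`
#'   (mean, sd, window start index).
#' @export
detect_events_zscore <- function(values, frame_rate, baseline_span = 0.5,
                                 threshold_sd = 8) {
  n <- length(values)
  w <- round(baseline_span * frame_rate)
  if (n <= w) stopf("trace must be longer than baseline_span")
  cs <- cumsum(c(0, values))
  cs2 <- cumsum(c(0, values^2))
  starts <- seq_len(n - w + 1L)
  sums <- cs[starts + w] - cs[starts]
  sq <- cs2[starts + w] - cs2[starts]
  vars <- pmax(0, (sq - sums^2 / w) / (w - 1))
  i0 <- which.min(vars)
  mu <- sums[i0] / w
  sdv <- sqrt(vars[i0])
  if (sdv <= .Machine$double.eps)
    stopf("baseline sd is zero", class = "glusense_degenerate_baseline")
  z <- (values - mu) / sdv
  above <- z >= threshold_sd
  onsets <- which(above & !c(FALSE, above[-n]))
  list(event_times = (onsets - 1L) / frame_rate, z = z,
       baseline = list(mean = mu, sd = sdv, start = i0))
}
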