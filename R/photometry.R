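#' Detrend a photometry trace
#'
#' Slow baseline drift from photobleaching is modelled by a 4th-order
#' polynomial fitted to the raw trace; the trace is converted to
#' dF/F-like units against that polynomial and the residual slow
#' modulation is removed with a mild Gaussian low-cut filter (default
#' cutoff period 3 min, the midpoint of the 2-4 min range). A trace that
#' is exactly a 4th-order polynomial therefore maps to (numerically) zero.
#'
#' @param values raw sensor trace.
#' @param rate_hz sampling rate (Hz).
#' @param lowcut_period low-cut cutoff period (s), nominally 120-240.
#' @param poly_order bleach polynomial order.
#' @return detrended dF/F-like trace (zero-mean at slow timescales).
#' @export
photometry_detrend <- function(values, rate_hz, lowcut_period = 180,
                               poly_order = 4L) {
  n <- length(values)
  if (n / rate_hz <= lowcut_period)
    stopf("trace shorter than the low-cut period")
  t <- (seq_len(n) - 1L) / rate_hz
  pf <- tryCatch(stats::lm(values ~ stats::poly(t, poly_order, raw = FALSE)),
                 error = function(e) stopf("polynomial fit failed: %s",
                                           conditionMessage(e)))
  base <- stats::fitted(pf)
  if (any(base <= 0)) stopf("fitted bleach baseline nonpositive",
                            class = "glusense_degenerate_baseline")
  dff <- (values - base) / base
  # half-amplitude at 1/lowcut_period Hz
  sigma <- sqrt(2 * log(2)) / (2 * pi / lowcut_period) * rate_hz
  dff - gauss_lowpass(dff, sigma)
}

#' Peri-event time histogram with local baseline subtraction
#'
#' Extracts per-event trace snippets over `window` seconds around each
#' event, subtracts each trial's mean over the `baseline` seconds
#' preceding the event, and averages across trials. Events too close to
#' the trace edges are dropped (reported in `n_dropped`).
#'
#' @param values trace (typically [photometry_detrend()] output).
#' @param rate_hz sampling rate (Hz).
#' @param event_times event (e.g. reward) times (s).
#' @param window c(before, after) extent (s) relative to the event.
#' @param baseline pre-event baseline duration (s).
#' @return list of class `peth`: `t` (s relative to event), `mean`,
#'   `sem`, `trials` (matrix), `n_trials`, `n_dropped`.
#' @export
peth <- function(values, rate_hz, event_times, window = c(-2, 4),
                 baseline = 2) {
  if (window[1L] > -baseline)
    window[1L] <- -baseline
  n <- length(values)
  i_rel <- round(window[1L] * rate_hz):round(window[2L] * rate_hz)
  tt <- i_rel / rate_hz
  base_idx <- tt >= -baseline & tt < 0
  rows <- list()
  dropped <- 0L
  for (ev in event_times) {
    i0 <- round(ev * rate_hz) + 1L
    idx <- i0 + i_rel
    if (idx[1L] < 1L || idx[length(idx)] > n) {
      dropped <- dropped + 1L
      next
    }
    snip <- values[idx]
    rows[[length(rows) + 1L]] <- snip - mean(snip[base_idx])
  }
  if (dropped > 0L) message(dropped, " events dropped near trace edges")
  if (!length(rows))
    return(structure(list(t = tt, mean = NULL, sem = NULL, trials = NULL,
                          n_trials = 0L, n_dropped = dropped),
                     class = "peth"))
  m <- do.call(rbind, rows)
  structure(list(t = tt, mean = colMeans(m),
                 sem = if (nrow(m) > 1L)
                   apply(m, 2L, stats::sd) / sqrt(nrow(m))
                 else rep(0, ncol(m)),
                 trials = m, n_trials = nrow(m), n_dropped = dropped),
            class = "peth")
}
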