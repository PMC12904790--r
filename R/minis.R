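#' Pixelwise activity statistic calibrated to photon shot noise
#'
#' For each pixel, the time series is temporally highpass filtered (raw
#' minus a Gaussian low-pass, default 4 Hz cutoff) and its sample skewness
#' is referenced to the skewness that pure photon shot noise of the same
#' mean would produce after the identical filter. For a Poisson series
#' with mean \eqn{\lambda}, standardized skewness is
#' \eqn{\kappa_f / \sqrt{\lambda}} where \eqn{\kappa_f} is the cumulant
#' factor \eqn{\sum c^3 / (\sum c^2)^{3/2}} of the filter impulse response
#' `c`, so the reported statistic
#' `skewness * sqrt(mean) / kappa_f` has expectation exactly 1 on
#' shot-noise-only input; values above 1 flag event-driven positive
#' skewness in excess of shot noise. Constant or nonpositive-mean pixels
#' return 0.
#'
#' @param movie T x rows x cols array (or T x pixels matrix) of
#'   photon-count-like intensities.
#' @param frame_rate acquisition rate (Hz).
#' @param highpass_cutoff low-pass subtraction cutoff (Hz, half-amplitude).
#' @return matrix (rows x cols) of the statistic, class `activity_image`,
#'   with attributes `highpass_cutoff` and `kappa`.
#' @export
activity_image <- function(movie, frame_rate, highpass_cutoff = 4) {
  shape <- if (length(dim(movie)) == 3L) dim(movie)[2:3] else NULL
  m <- if (length(dim(movie)) == 3L) movie_as_matrix(movie) else movie
  n <- nrow(m)
  if (n < 100L) stopf("movie must have >= 100 frames")
  sigma <- sqrt(2 * log(2)) / (2 * pi * highpass_cutoff) * frame_rate
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  ceff <- -k
  ceff[r + 1L] <- ceff[r + 1L] + 1
  kappa <- sum(ceff^3) / sum(ceff^2)^1.5
  mu <- colMeans(m)
  stat <- numeric(ncol(m))
  valid <- mu > 0
  if (!all(valid)) warnf("%d pixels with nonpositive mean set to 0",
                         sum(!valid))
  # process pixels in blocks to bound the filter working memory
  block <- max(1L, floor(2e6 / n))
  for (b in split(which(valid), ceiling(seq_along(which(valid)) / block))) {
    hp <- m[, b, drop = FALSE] - gauss_lowpass(m[, b, drop = FALSE], sigma)
    # drop half-kernel edges where the reflection-padded filter is biased
    hp <- hp[(r + 1L):(n - r), , drop = FALSE]
    stat[b] <- col_skewness(hp) * sqrt(mu[b]) / kappa
  }
  stat[!is.finite(stat)] <- 0
  out <- if (!is.null(shape)) matrix(stat, shape[1L], shape[2L]) else stat
  structure(out, class = "activity_image",
            highpass_cutoff = highpass_cutoff, kappa = kappa)
}

#' Detect spontaneous release sites by seeded non-negative factorization
#'
#' A simplified stand-in for constrained matrix factorization source
#' extraction: seeds are local maxima of the [activity_image()], each site
#' gets a spatial support disk (radius `3 * footprint_sigma`) around its
#' seed, and footprints/traces are refined by multiplicative non-negative
#' updates of `dF ~ footprints x traces` with a fixed iteration cap.
#' Initialization is deterministic (seed-ordered), so results are
#' reproducible.
#'
#' @param movie T x rows x cols array.
#' @param frame_rate acquisition rate (Hz).
#' @param footprint_sigma expected site radius scale (px).
#' @param max_sites maximum number of sites.
#' @param min_activity activity-statistic threshold for seeds (shot noise
#'   alone gives values near 1).
#' @param min_separation minimum seed separation (px); defaults to
#'   `2 * footprint_sigma`.
#' @param n_iter multiplicative update iterations.
#' @return list of class `site_map`: `footprints` (n_sites x rows x cols,
#'   unit peak), `traces` (n_sites x T, dF-scaled), `centroids`
#'   (n_sites x 2, row/col), `activity` (the seed image). Zero sites gives
#'   empty components.
#' @export
detect_sites <- function(movie, frame_rate, footprint_sigma = 1.5,
                         max_sites = 20L, min_activity = 2,
                         min_separation = NULL, n_iter = 30L) {
  d <- dim(movie)
  act <- activity_image(movie, frame_rate)
  sh <- d[2:3]
  if (is.null(min_separation)) min_separation <- 2 * footprint_sigma
  seeds <- local_maxima_2d(unclass(act), min_activity, min_separation)
  empty <- list(footprints = array(0, c(0L, sh[1L], sh[2L])),
                traces = matrix(0, 0L, d[1L]),
                centroids = matrix(0, 0L, 2L), activity = act)
  if (nrow(seeds) == 0L) return(structure(empty, class = "site_map"))
  if (nrow(seeds) > max_sites) seeds <- seeds[seq_len(max_sites), , drop = FALSE]
  m <- movie_as_matrix(movie)
  f0 <- apply(m, 2L, stats::median)
  v <- t(pmax(sweep(m, 2L, f0), 0))            # pixels x time, nonnegative
  n_px <- nrow(v)
  k <- nrow(seeds)
  supp <- matrix(FALSE, n_px, k)
  w <- matrix(0, n_px, k)
  rows <- (seq_len(n_px) - 1L) %% sh[1L] + 1L
  cols <- (seq_len(n_px) - 1L) %/% sh[1L] + 1L
  for (s in seq_len(k)) {
    d2 <- (rows - seeds[s, 1L])^2 + (cols - seeds[s, 2L])^2
    supp[, s] <- d2 <= (3 * footprint_sigma)^2
    w[, s] <- exp(-d2 / (2 * footprint_sigma^2)) * supp[, s]
  }
  h <- pmax(crossprod(w, v) / pmax(colSums(w^2), 1e-12), 1e-12)
  eps <- 1e-12
  for (it in seq_len(n_iter)) {
    h <- h * (crossprod(w, v) / (crossprod(w, w) %*% h + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    w[!supp] <- 0
  }
  peak <- apply(w, 2L, max)
  keep <- peak > 0
  w <- w[, keep, drop = FALSE]
  h <- h[keep, , drop = FALSE]
  peak <- peak[keep]
  if (!ncol(w)) return(structure(empty, class = "site_map"))
  h <- h * peak                                 # unit-peak footprints
  w <- sweep(w, 2L, peak, "/")
  cent <- t(vapply(seq_len(ncol(w)), function(s) {
    c(sum(rows * w[, s]), sum(cols * w[, s])) / sum(w[, s])
  }, numeric(2L)))
  fps <- array(0, c(ncol(w), sh[1L], sh[2L]))
  for (s in seq_len(ncol(w))) fps[s, , ] <- matrix(w[, s], sh[1L], sh[2L])
  structure(list(footprints = fps, traces = h, centroids = cent,
                 activity = act), class = "site_map")
}

# 2D local maxima (8-neighbourhood) above a threshold with greedy
# minimum-separation suppression; returns a matrix of (row, col) sorted by
# decreasing value.
local_maxima_2d <- function(img, min_value, min_sep) {
  nr <- nrow(img)
  nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  ismax <- ctr >= min_value
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ismax <- ismax & ctr >= pad[2:(nr + 1L) + dy, 2:(nc + 1L) + dx]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  idx <- idx[order(ctr[ismax], decreasing = TRUE), , drop = FALSE]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    dd <- sqrt((idx[keep, 1L] - idx[i, 1L])^2 + (idx[keep, 2L] - idx[i, 2L])^2)
    keep[i] <- all(dd >= min_sep)
  }
  idx[keep, , drop = FALSE]
}

# Spectral noise-amplitude estimate: the white-noise sd implied by the
# median periodogram level over the upper third of the one-sided spectrum
# (median of an exponential with mean sigma^2 is sigma^2 * log 2).
spectral_noise_sd <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n
  half <- p[2:floor(n / 2)]
  hi <- half[ceiling(2 * length(half) / 3):length(half)]
  sqrt(stats::median(hi) / log(2))
}

#' Event SNR of a release-site trace
#'
#' The amplitude of the third-largest detected peak divided by a spectral
#' estimate of the noise amplitude. Peaks are local maxima above
#' `3 * noise` with a 50-ms minimum separation; with fewer than three
#' peaks, the smallest available peak is used.
#'
#' @param trace site activity trace (dF-like).
#' @param frame_rate sampling rate (Hz).
#' @return list: `snr` (`NA` when no peaks or zero noise), `noise_sd`,
#'   `n_peaks`, `peak_times`.
#' @export
site_snr <- function(trace, frame_rate) {
  noise <- spectral_noise_sd(trace)
  if (!is.finite(noise) || noise <= 0)
    return(list(snr = NA_real_, noise_sd = noise, n_peaks = 0L,
                peak_times = numeric(0)))
  pk <- find_peaks(trace, min_height = 3 * noise,
                   min_sep = max(1L, round(0.05 * frame_rate)))
  if (!length(pk))
    return(list(snr = NA_real_, noise_sd = noise, n_peaks = 0L,
                peak_times = numeric(0)))
  amps <- sort(trace[pk], decreasing = TRUE)
  amp <- if (length(amps) >= 3L) amps[3L] else amps[length(amps)]
  list(snr = amp / noise, noise_sd = noise, n_peaks = length(pk),
       peak_times = (pk - 1L) / frame_rate)
}

#' Decay constant of a release-site trace
#'
#' Detects isolated peaks (no neighbouring peak within `isolation`,
#' bootstrapped from a first pass assuming a 150-ms decay), averages the
#' peak-triggered post-peak traces, and fits a single exponential
#' `A * exp(-t / tau) + C` to the mean decay.
#'
#' @param trace site activity trace.
#' @param frame_rate sampling rate (Hz).
#' @param isolation required clearance around a peak (s); default
#'   `5 * tau` from the two-pass bootstrap starting at 150 ms.
#' @return list: `decay_tau` (s, `NA` when undefined), `n_peaks_used`.
#' @export
site_decay <- function(trace, frame_rate, isolation = NULL) {
  noise <- spectral_noise_sd(trace)
  min_sep <- max(1L, round(0.05 * frame_rate))
  # decay fitting wants prominent, event-sized peaks: small decay-phase
  # bumps above the bare noise floor would otherwise veto isolation
  pk <- find_peaks(trace, min_height = max(3 * noise, 0.25 * max(trace)),
                   min_sep = min_sep)
  if (!length(pk)) return(list(decay_tau = NA_real_, n_peaks_used = 0L))
  pass <- function(iso_s) {
    iso <- round(iso_s * frame_rate)
    ok <- vapply(seq_along(pk), function(i) {
      others <- pk[-i]
      !length(others) || all(abs(others - pk[i]) > iso)
    }, logical(1L))
    use <- pk[ok]
    win <- max(3L, round(3 * iso_s * frame_rate))
    snips <- list()
    for (p in use) {
      idx <- p:min(length(trace), p + win)
      if (length(idx) >= 4L)
        snips[[length(snips) + 1L]] <- trace[idx[seq_len(min(length(idx), win + 1L))]]
    }
    if (!length(snips)) return(NULL)
    len <- min(lengths(snips))
    m <- colMeans(do.call(rbind, lapply(snips, function(s) s[seq_len(len)])))
    tt <- (seq_along(m) - 1L) / frame_rate
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-tt / tau) + c0,
                 data = list(y = m, tt = tt),
                 start = list(a = m[1L], tau = max(iso_s / 5, 2 / frame_rate),
                              c0 = 0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tau <- stats::coef(fit)[["tau"]]
    if (!is.finite(tau) || tau <= 0) return(NULL)
    list(tau = tau, n = length(snips))
  }
  if (is.null(isolation)) {
    p1 <- pass(5 * 0.150)
    if (is.null(p1)) return(list(decay_tau = NA_real_, n_peaks_used = 0L))
    p2 <- pass(5 * p1$tau)
    if (is.null(p2)) p2 <- p1
  } else {
    p2 <- pass(isolation)
    if (is.null(p2)) return(list(decay_tau = NA_real_, n_peaks_used = 0L))
  }
  list(decay_tau = p2$tau, n_peaks_used = p2$n)
}

#' Aggregate site scores to wells and variants
#'
#' Two-level aggregation: the median of each statistic across detected
#' sites per well, then the mean and SEM of the well medians per variant.
#' Wells without sites are excluded (with a message).
#'
#' @param scores data.frame with columns `well`, `variant`, and one or
#'   more numeric statistic columns (e.g. `snr`, `decay_tau`).
#' @param stats_cols names of the statistic columns; defaults to all
#'   numeric columns other than identifiers.
#' @return list: `well_medians` (one row per well) and `variant_summary`
#'   (mean, sem, n_wells per variant and statistic).
#' @export
aggregate_wells <- function(scores, stats_cols = NULL) {
  if (!all(c("well", "variant") %in% names(scores)))
    stopf("scores needs 'well' and 'variant' columns")
  if (is.null(stats_cols))
    stats_cols <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)],
                          c("well", "variant", "site_id"))
  wells <- split(scores, scores$well)
  wm <- do.call(rbind, lapply(names(wells), function(wn) {
    d <- wells[[wn]]
    if (!nrow(d)) return(NULL)
    out <- data.frame(well = wn, variant = d$variant[1L], n_sites = nrow(d))
    for (sc in stats_cols)
      out[[sc]] <- stats::median(d[[sc]], na.rm = TRUE)
    out
  }))
  dropped <- setdiff(unique(scores$well), wm$well)
  if (length(dropped))
    message("excluded empty wells: ", paste(dropped, collapse = ", "))
  vs <- do.call(rbind, lapply(split(wm, wm$variant), function(d) {
    out <- data.frame(variant = d$variant[1L], n_wells = nrow(d))
    for (sc in stats_cols) {
      x <- d[[sc]]
      out[[paste0(sc, "_mean")]] <- mean(x, na.rm = TRUE)
      out[[paste0(sc, "_sem")]] <- if (sum(!is.na(x)) > 1L)
        stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))) else NA_real_
    }
    out
  }))
  rownames(wm) <- rownames(vs) <- NULL
  list(well_medians = wm, variant_summary = vs)
}
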