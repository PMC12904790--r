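#' Time-resolved tuning curves
#'
#' Per-direction trial-mean traces over a window spanning `pre` seconds
#' before stimulus onset to `stim_dur` seconds after. Directions with no
#' trials are flagged absent rather than zero-filled.
#'
#' @param dff dF/F trace (vector) or T x n_roi matrix.
#' @param frame_rate sampling rate (Hz).
#' @param onsets stimulus onset times (s), one per trial.
#' @param directions direction label (deg) per trial.
#' @param stim_dur stimulus duration (s).
#' @param pre pre-stimulus window retained for baseline subtraction (s).
#' @return list of class `time_resolved_tuning`: `curves` (array
#'   n_directions x n_window x n_roi), `directions` (those present),
#'   `missing` (requested but absent), `t_rel` (s relative to onset),
#'   `n_trials` per direction.
#' @export
time_resolved_tuning <- function(dff, frame_rate, onsets, directions,
                                 stim_dur = 2, pre = 0.5) {
  if (is.null(dim(dff))) dff <- matrix(dff, ncol = 1L)
  n <- nrow(dff)
  npre <- round(pre * frame_rate)
  ndur <- round(stim_dur * frame_rate)
  rel <- (-npre):(ndur - 1L)
  all_dirs <- sort(unique(directions))
  keep_trial <- rep(TRUE, length(onsets))
  trials <- lapply(seq_along(onsets), function(i) {
    i0 <- round(onsets[i] * frame_rate) + 1L
    idx <- i0 + rel
    if (idx[1L] < 1L || idx[length(idx)] > n) return(NULL)
    dff[idx, , drop = FALSE]
  })
  ok <- !vapply(trials, is.null, logical(1L))
  curves <- array(NA_real_, c(length(all_dirs), length(rel), ncol(dff)))
  n_trials <- integer(length(all_dirs))
  for (di in seq_along(all_dirs)) {
    sel <- which(ok & directions == all_dirs[di])
    n_trials[di] <- length(sel)
    if (!length(sel)) next
    acc <- Reduce(`+`, trials[sel])
    curves[di, , ] <- acc / length(sel)
  }
  present <- n_trials > 0L
  structure(list(curves = curves[present, , , drop = FALSE],
                 directions = all_dirs[present],
                 missing = all_dirs[!present],
                 t_rel = rel / frame_rate,
                 n_trials = n_trials[present]),
            class = "time_resolved_tuning")
}

#' Eight-point tuning curve
#'
#' Per-direction scalar response: mean over the stimulus-on period minus
#' the mean over the `pre_window` seconds before onset (local baseline
#' subtraction makes the result invariant to additive offsets).
#'
#' @param trt a [time_resolved_tuning()] result.
#' @param pre_window baseline window before onset (s).
#' @return matrix n_directions x n_roi (dropped to a vector for one ROI)
#'   with the directions as row names.
#' @export
eight_point_tuning <- function(trt, pre_window = 0.5) {
  pre_idx <- trt$t_rel < 0 & trt$t_rel >= -pre_window
  if (!any(pre_idx)) stopf("no pre-stimulus samples available")
  on_idx <- trt$t_rel >= 0
  resp <- apply(trt$curves[, on_idx, , drop = FALSE], c(1L, 3L), mean) -
    apply(trt$curves[, pre_idx, , drop = FALSE], c(1L, 3L), mean)
  rownames(resp) <- trt$directions
  if (ncol(resp) == 1L) resp[, 1L] else resp
}

#' Orientation statistics from an eight-point tuning curve
#'
#' Responses are treated as vectors at doubled orientation angles
#' (direction mod 180, angle x2); negatives are rectified to 0 before
#' summation. Both published OSI variants are returned: `osi` is the
#' resultant length divided by the summed responses (normalized, in
#' `[0, 1]`); `osi_raw` is the raw resultant magnitude.
#'
#' @param responses per-direction responses.
#' @param directions stimulus directions (deg), same length.
#' @return list: `preferred_orientation` (deg in `[0, 180)`; `NA` when all
#'   responses are zero), `osi`, `osi_raw`, `tuning_magnitude` (2-norm of
#'   the tuning curve), `response_amplitude` (mean response magnitude),
#'   `n_rectified`.
#' @export
orientation_stats <- function(responses, directions) {
  if (length(responses) != length(directions))
    stopf("responses and directions differ in length")
  n_neg <- sum(responses < 0)
  r <- pmax(responses, 0)
  th <- 2 * (directions %% 180) * pi / 180
  z <- sum(r * exp(1i * th))
  tot <- sum(r)
  if (tot == 0)
    return(list(preferred_orientation = NA_real_, osi = 0, osi_raw = 0,
                tuning_magnitude = 0, response_amplitude = 0,
                n_rectified = n_neg))
  pref <- (Arg(z) / 2 * 180 / pi) %% 180
  list(preferred_orientation = pref,
       osi = Mod(z) / tot,
       osi_raw = Mod(z),
       tuning_magnitude = sqrt(sum(r^2)),
       response_amplitude = mean(r),
       n_rectified = n_neg)
}

#' Pixelwise HSV tuning map
#'
#' Hue encodes preferred orientation (`pref / 180`), saturation the
#' normalized OSI (clipped to `[0, 1]`), and value the response amplitude
#' normalized to the field-of-view maximum, matching the published map
#' convention. Untuned pixels come out desaturated.
#'
#' @param preferred matrix of preferred orientations (deg; `NA` allowed).
#' @param osi matrix of normalized OSI values.
#' @param amplitude matrix of response amplitudes.
#' @return rows x cols x 3 RGB array in `[0, 1]`.
#' @export
tuning_map <- function(preferred, osi, amplitude) {
  h <- (preferred %% 180) / 180
  h[is.na(h)] <- 0
  s <- pmin(pmax(osi, 0), 1)
  s[is.na(s)] <- 0
  vmax <- max(amplitude, na.rm = TRUE)
  v <- if (vmax > 0) pmin(pmax(amplitude / vmax, 0), 1)
       else amplitude * 0
  v[is.na(v)] <- 0
  cols <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(v))
  rgb <- grDevices::col2rgb(cols) / 255
  array(t(rgb), dim = c(dim(preferred), 3L))
}

#' Labeled-pixel mask from a mean image
#'
#' Pixels at or near the brightest pixels: the top `q` quantile of the
#' mean image, dilated by one pixel.
#'
#' @param mean_img rows x cols mean-intensity image.
#' @param q fraction of brightest pixels to seed the mask.
#' @return logical matrix of the same shape.
#' @export
labeled_mask <- function(mean_img, q = 0.05) {
  thr <- stats::quantile(mean_img, 1 - q)
  m <- mean_img >= thr
  out <- m
  nr <- nrow(m)
  nc <- ncol(m)
  for (dy in -1:1) for (dx in -1:1) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    out <- out | m[ys, xs]
  }
  out
}

#' Cross-validated pixel-pair tuning covariance versus distance
#'
#' For each pixel pair, the time-resolved tuning curve is computed twice
#' from mutually exclusive random halves of the trials, and the covariance
#' (and correlation) between the two pixels' half-split curves is averaged
#' over `n_splits` random splits. Because the two halves share no trials,
#' independent noise cancels in expectation and the statistic estimates
#' shared-signal tuning covariance; it is binned by pairwise distance
#' separately for labeled and background pixels.
#'
#' @param pixmat T x n_pixels dF matrix.
#' @param frame_rate sampling rate (Hz).
#' @param onsets,directions trial structure as in
#'   [time_resolved_tuning()].
#' @param coords n_pixels x 2 matrix of pixel (row, col) positions.
#' @param mask logical vector: labeled pixels.
#' @param n_splits number of random half-splits.
#' @param max_dist maximum pair distance (px).
#' @param max_pairs subsampling cap per pixel class.
#' @param stim_dur,pre trial window (s).
#' @param seed integer seed (splits and pair subsampling).
#' @return list of class `spread_curve`: `curve` (data.frame distance,
#'   cov_labeled, cov_background, cor_labeled, cor_background, n_pairs_*),
#'   plus 1/e and 1/e^2 crossing distances for the labeled covariance and
#'   correlation (see [spread_distances()]).
#' @export
crossval_spread <- function(pixmat, frame_rate, onsets, directions, coords,
                            mask, n_splits = 20L, max_dist = 30,
                            max_pairs = 1e5, stim_dur = 2, pre = 0.5,
                            seed = 1L) {
  tab <- table(directions)
  if (any(tab < 4L)) stopf("need >= 4 trials per direction to split")
  npre <- round(pre * frame_rate)
  ndur <- round(stim_dur * frame_rate)
  rel <- (-npre):(ndur - 1L)
  n <- nrow(pixmat)
  np <- ncol(pixmat)
  ok <- vapply(onsets, function(o) {
    i0 <- round(o * frame_rate) + 1L
    i0 + rel[1L] >= 1L && i0 + rel[length(rel)] <= n
  }, logical(1L))
  onsets <- onsets[ok]
  directions <- directions[ok]
  trial_resp <- lapply(seq_along(onsets), function(i) {
    i0 <- round(onsets[i] * frame_rate) + 1L
    pixmat[i0 + rel, , drop = FALSE]        # n_win x np
  })
  dirs <- sort(unique(directions))
  with_seed(seed, {
    pairs_of <- function(which_px) {
      if (length(which_px) < 2L)
        return(matrix(integer(0), 0L, 2L))
      cmb <- utils::combn(which_px, 2L)
      d <- sqrt((coords[cmb[1L, ], 1L] - coords[cmb[2L, ], 1L])^2 +
                  (coords[cmb[1L, ], 2L] - coords[cmb[2L, ], 2L])^2)
      sel <- which(d <= max_dist)
      if (length(sel) > max_pairs) sel <- sample(sel, max_pairs)
      cbind(t(cmb[, sel, drop = FALSE]), d[sel])
    }
    lp <- pairs_of(which(mask))
    bp <- pairs_of(which(!mask))
    d_all <- length(rel) * length(dirs)
    acc <- function(pairs) list(cv = numeric(nrow(pairs)),
                                cr = numeric(nrow(pairs)))
    al <- acc(lp)
    ab <- acc(bp)
    for (s in seq_len(n_splits)) {
      h1 <- h2 <- vector("list", length(dirs))
      for (di in seq_along(dirs)) {
        tr <- which(directions == dirs[di])
        tr <- sample(tr)
        half <- floor(length(tr) / 2L)
        h1[[di]] <- tr[seq_len(half)]
        h2[[di]] <- tr[half + seq_len(half)]
      }
      curve_of <- function(halves) {
        do.call(rbind, lapply(halves, function(ix) {
          Reduce(`+`, trial_resp[ix]) / length(ix)
        }))                                  # d_all x np
      }
      c1 <- curve_of(h1)
      c2 <- curve_of(h2)
      a1 <- sweep(c1, 2L, colMeans(c1))
      a2 <- sweep(c2, 2L, colMeans(c2))
      s1 <- sqrt(colSums(a1^2) / (d_all - 1))
      s2 <- sqrt(colSums(a2^2) / (d_all - 1))
      upd <- function(a, pairs) {
        if (!nrow(pairs)) return(a)
        i <- pairs[, 1L]
        j <- pairs[, 2L]
        cv <- (colSums(a1[, i, drop = FALSE] * a2[, j, drop = FALSE]) +
                 colSums(a1[, j, drop = FALSE] * a2[, i, drop = FALSE])) /
          (2 * (d_all - 1))
        den <- (s1[i] * s2[j] + s1[j] * s2[i]) / 2
        a$cv <- a$cv + cv
        a$cr <- a$cr + ifelse(den > 0, cv / den, 0)
        a
      }
      al <- upd(al, lp)
      ab <- upd(ab, bp)
    }
    bin_curve <- function(pairs, a) {
      if (!nrow(pairs))
        return(data.frame(distance = numeric(0), cov = numeric(0),
                          cor = numeric(0), n_pairs = integer(0)))
      b <- round(pairs[, 3L])
      data.frame(distance = as.numeric(names(tapply(a$cv, b, mean))),
                 cov = as.numeric(tapply(a$cv / n_splits, b, mean)),
                 cor = as.numeric(tapply(a$cr / n_splits, b, mean)),
                 n_pairs = as.integer(table(b)))
    }
    cl <- bin_curve(lp, al)
    cb <- bin_curve(bp, ab)
    curve <- merge(stats::setNames(cl, c("distance", "cov_labeled",
                                         "cor_labeled", "n_pairs_labeled")),
                   stats::setNames(cb, c("distance", "cov_background",
                                         "cor_background",
                                         "n_pairs_background")),
                   by = "distance", all = TRUE)
    structure(list(curve = curve,
                   cov_crossings = spread_distances(cl$distance, cl$cov),
                   cor_crossings = spread_distances(cl$distance, cl$cor)),
              class = "spread_curve")
  })
}

#' Distances at which a spread curve falls to 1/e and 1/e^2 of its maximum
#'
#' Crossing distances are found by linear interpolation; `NA` when the
#' curve never drops below the threshold within range. By construction
#' `d_1e <= d_1e2` whenever both are defined.
#'
#' @param distance increasing distance bins.
#' @param value curve values per bin.
#' @return list: `max`, `d_1e`, `d_1e2`.
#' @export
spread_distances <- function(distance, value) {
  if (!length(value)) return(list(max = NA_real_, d_1e = NA_real_,
                                  d_1e2 = NA_real_))
  mx <- max(value, na.rm = TRUE)
  cross <- function(thr) {
    below <- which(value <= thr)
    below <- below[below > which.max(value)]
    if (!length(below)) return(NA_real_)
    i <- below[1L]
    if (i == 1L) return(distance[1L])
    x0 <- distance[i - 1L]
    x1 <- distance[i]
    y0 <- value[i - 1L]
    y1 <- value[i]
    x0 + (y0 - thr) / (y0 - y1) * (x1 - x0)
  }
  list(max = mx, d_1e = cross(mx / exp(1)), d_1e2 = cross(mx / exp(2)))
}

#' Average spread curves across recordings with bootstrap CIs
#'
#' Averages per-recording spread curves on their common distance bins and
#' bootstraps recordings (1,000 samples, percentile 2.5/97.5) to attach
#' confidence intervals to the mean curve and to the 1/e and 1/e^2
#' crossing distances. Two conditions differ significantly when the
#' bootstrap CI of their crossing-distance difference excludes 0 (see
#' `spread_difference`).
#'
#' @param curves list of [crossval_spread()] results.
#' @param statistic `"cov"` or `"cor"` column family to aggregate.
#' @param n_boot bootstrap samples.
#' @param seed integer seed.
#' @return list: `distance`, `mean`, `ci_lo`, `ci_hi`, `crossings`
#'   (with CI bounds for `d_1e`, `d_1e2`).
#' @export
aggregate_spread <- function(curves, statistic = c("cov", "cor"),
                             n_boot = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_labeled")
  dists <- Reduce(intersect, lapply(curves, function(cu) cu$curve$distance))
  m <- vapply(curves, function(cu) {
    cu$curve[[col]][match(dists, cu$curve$distance)]
  }, numeric(length(dists)))
  m <- matrix(m, nrow = length(dists))
  mean_curve <- rowMeans(m)
  with_seed(seed, {
    bs <- replicate(n_boot, {
      pick <- sample(ncol(m), replace = TRUE)
      mc <- rowMeans(m[, pick, drop = FALSE])
      cr <- spread_distances(dists, mc)
      c(mc, cr$d_1e, cr$d_1e2)
    })
    nd <- length(dists)
    ci <- apply(bs[seq_len(nd), , drop = FALSE], 1L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
    cr <- spread_distances(dists, mean_curve)
    qd <- function(row) stats::quantile(bs[row, ], c(0.025, 0.975),
                                        na.rm = TRUE)
    list(distance = dists, mean = mean_curve,
         ci_lo = ci[1L, ], ci_hi = ci[2L, ],
         crossings = list(d_1e = cr$d_1e, d_1e_ci = qd(nd + 1L),
                          d_1e2 = cr$d_1e2, d_1e2_ci = qd(nd + 2L)))
  })
}

#' @rdname aggregate_spread
#' @param curves_a,curves_b two recording sets to compare.
#' @param which crossing distance to compare (`"d_1e2"` or `"d_1e"`).
#' @return `spread_difference`: list with the observed difference
#'   (a minus b), its bootstrap CI, and `significant`.
#' @export
spread_difference <- function(curves_a, curves_b, statistic = c("cov", "cor"),
                              which = "d_1e2", n_boot = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_labeled")
  pull <- function(curves) {
    dists <- Reduce(intersect, lapply(curves, function(cu) cu$curve$distance))
    m <- vapply(curves, function(cu) {
      cu$curve[[col]][match(dists, cu$curve$distance)]
    }, numeric(length(dists)))
    list(d = dists, m = matrix(m, nrow = length(dists)))
  }
  a <- pull(curves_a)
  b <- pull(curves_b)
  stat_of <- function(p, pick) {
    cr <- spread_distances(p$d, rowMeans(p$m[, pick, drop = FALSE]))
    cr[[which]]
  }
  obs <- stat_of(a, seq_len(ncol(a$m))) - stat_of(b, seq_len(ncol(b$m)))
  with_seed(seed, {
    diffs <- replicate(n_boot, {
      stat_of(a, sample(ncol(a$m), replace = TRUE)) -
        stat_of(b, sample(ncol(b$m), replace = TRUE))
    })
    ci <- stats::quantile(diffs, c(0.025, 0.975), na.rm = TRUE)
    list(difference = obs, ci = ci,
         significant = is.finite(ci[1L]) && (ci[1L] > 0 || ci[2L] < 0))
  })
}
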