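#' Build the lagged sparse-noise design matrix
#'
#' Toeplitz-style design containing the stimulus history at lags from 0 to
#' `max_lag` seconds (at the response sampling grid), with separate ON
#' (`max(S, 0)`) and OFF (`max(-S, 0)`) predictor blocks so luminance
#' increments and decrements at the same screen position get independent
#' weights. The stimulus is upsampled to the response rate by
#' sample-and-hold; rows with incomplete history are zero-padded, and row
#' `t` references only stimulus at times `<= t`.
#'
#' Column order: ON block then OFF block; within a block, lag-major with
#' pixels fastest (column = `(block-1)*P*L + (lag-1)*P + pixel`).
#'
#' @param stimulus a [sparse_noise_stimulus()].
#' @param response_rate response sampling rate (Hz).
#' @param max_lag maximum lag (s).
#' @param n_samples optional number of response samples (defaults to the
#'   stimulus duration at `response_rate`).
#' @return sparse `dgCMatrix` with attributes `grid_dim`, `n_lags`,
#'   `lags` (s), `response_rate`.
#' @export
build_design <- function(stimulus, response_rate, max_lag = 1.4,
                         n_samples = NULL) {
  if (max_lag <= 0) stopf("max_lag must be > 0")
  gd <- stimulus$grid_dim
  n_stim <- dim(stimulus$frames)[1L]
  n <- if (is.null(n_samples))
    floor(n_stim / stimulus$refresh_rate * response_rate) else n_samples
  idx <- stim_frame_at(n, response_rate, stimulus$refresh_rate, n_stim)
  s <- matrix(stimulus$frames, nrow = n_stim)[idx, , drop = FALSE]
  p <- ncol(s)
  n_lags <- as.integer(floor(max_lag * response_rate)) + 1L
  blocks <- list(methods::as(Matrix::Matrix(pmax(s, 0), sparse = TRUE),
                             "TsparseMatrix"),
                 methods::as(Matrix::Matrix(pmax(-s, 0), sparse = TRUE),
                             "TsparseMatrix"))
  ii <- jj <- vv <- list()
  for (b in 1:2) {
    tb <- blocks[[b]]
    for (l in seq_len(n_lags)) {
      d <- l - 1L
      keep <- tb@i + 1L + d <= n
      off <- (b - 1L) * p * n_lags + (l - 1L) * p
      ii[[length(ii) + 1L]] <- tb@i[keep] + 1L + d
      jj[[length(jj) + 1L]] <- tb@j[keep] + 1L + off
      vv[[length(vv) + 1L]] <- tb@x[keep]
    }
  }
  x <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, 2L * p * n_lags))
  attr(x, "grid_dim") <- gd
  attr(x, "n_lags") <- n_lags
  attr(x, "lags") <- (seq_len(n_lags) - 1L) / response_rate
  attr(x, "response_rate") <- response_rate
  x
}

# Discrete 2D Laplacian (4-neighbour, replicate/Neumann boundaries) for a
# gy x gx grid, as a sparse matrix acting on column-major flattened pixels.
laplacian_2d <- function(gd) {
  gy <- gd[1L]
  gx <- gd[2L]
  p <- gy * gx
  id <- function(y, x) y + (x - 1L) * gy
  ii <- jj <- vv <- list()
  push <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    vv[[length(vv) + 1L]] <<- v
  }
  for (x in seq_len(gx)) for (y in seq_len(gy)) {
    ctr <- id(y, x)
    nbr <- c(if (y > 1L) id(y - 1L, x), if (y < gy) id(y + 1L, x),
             if (x > 1L) id(y, x - 1L), if (x < gx) id(y, x + 1L))
    push(ctr, ctr, length(nbr))
    for (nb in nbr) push(ctr, nb, -1)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(p, p))
}

# Penalty crossproduct t(L) %*% L replicated over every lag of both the ON
# and OFF blocks (spatial smoothing only; no temporal term).
laplacian_penalty <- function(design) {
  gd <- attr(design, "grid_dim")
  n_lags <- attr(design, "n_lags")
  ltl <- Matrix::crossprod(laplacian_2d(gd))
  Matrix::bdiag(rep(list(ltl), 2L * n_lags))
}

#' Fit stRF weights by Laplacian-regularized ridge regression
#'
#' Minimizes `||y - Xw||^2 + lambda * ||L w||^2` where `L` applies the 2D
#' spatial Laplacian independently at each lag and each ON/OFF block,
#' solved through the normal equations. The response is centred
#' internally; predictions add the training mean back.
#'
#' @param design matrix from [build_design()].
#' @param response numeric response vector.
#' @param lambda regularization weight (>= 0).
#' @param xtx,xty,xcm,n_train,penalty optional precomputed pieces
#'   (uncentred X'X, X'(y - ybar), column means, training rows; used by
#'   the cross-validation and permutation loops). An implicit unpenalized
#'   intercept is handled by centring through a rank-1 update of X'X.
#' @return list of class `strf_fit`: `w`, `offset`, `lambda`, `fitted`.
#' @export
fit_strf <- function(design, response, lambda, xtx = NULL, xty = NULL,
                     xcm = NULL, n_train = NULL, penalty = NULL) {
  if (lambda < 0) stopf("lambda must be >= 0")
  if (any(!is.finite(response))) stopf("response must be finite")
  if (is.null(penalty)) penalty <- laplacian_penalty(design)
  off <- mean(response)
  yc <- response - off
  if (is.null(xtx)) xtx <- Matrix::crossprod(design)
  if (is.null(xty)) xty <- Matrix::crossprod(design, yc)
  if (is.null(xcm)) xcm <- Matrix::colMeans(design)
  if (is.null(n_train)) n_train <- nrow(design)
  a <- as.matrix(xtx + lambda * penalty) - n_train * tcrossprod(xcm)
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch))
    stopf("normal equations singular; increase lambda")
  w <- backsolve(ch, backsolve(ch, as.numeric(xty), transpose = TRUE))
  b0 <- off - sum(xcm * w)
  structure(list(w = w, offset = b0, lambda = lambda,
                 fitted = as.numeric(design %*% w) + b0),
            class = "strf_fit")
}

#' Explained variance on held-out data
#'
#' `EV = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with the mean taken
#' over the test set itself. Perfect prediction gives 1; predicting the
#' test mean gives 0; worse-than-mean predictions go negative.
#'
#' @param y_test observed responses (>= 2 values, nonzero variance).
#' @param y_hat predictions.
#' @return scalar EV (`NA` with a warning when test variance is zero).
#' @export
explained_variance <- function(y_test, y_hat) {
  if (length(y_test) < 2L) stopf("need >= 2 test samples")
  sst <- sum((y_test - mean(y_test))^2)
  if (sst == 0) {
    warnf("zero test variance; EV undefined")
    return(NA_real_)
  }
  1 - sum((y_test - y_hat)^2) / sst
}

#' Choose the regularization weight by contiguous k-fold cross-validation
#'
#' Folds are contiguous time blocks (respecting temporal autocorrelation).
#' For each lambda the fold-mean EV is computed; the final stRF is refit
#' on the full recording at the best lambda.
#'
#' @param design,response as in [fit_strf()].
#' @param lambdas candidate grid; default is logarithmic, 10 points per
#'   decade over 6 decades centred on the design's spectral scale
#'   (`mean(diag(X'X))`).
#' @param k number of folds.
#' @return list: `lambda`, `ev_cv` (best fold-mean EV), `ev_by_lambda`,
#'   `fit` (full-data [fit_strf()] at the best lambda), `penalty`.
#' @export
crossval_lambda <- function(design, response, lambdas = NULL, k = 3L) {
  n <- nrow(design)
  if (k < 2L || n < 3L * k) stopf("cannot build %d contiguous folds", k)
  penalty <- laplacian_penalty(design)
  xtx_all <- Matrix::crossprod(design)
  if (is.null(lambdas)) {
    s <- mean(Matrix::diag(xtx_all))
    if (s <= 0) s <- 1
    lambdas <- 10^seq(log10(s) - 3, log10(s) + 3, by = 0.1)
  }
  bounds <- floor(seq(0, n, length.out = k + 1L))
  folds <- lapply(seq_len(k), function(i) (bounds[i] + 1L):bounds[i + 1L])
  csum_all <- Matrix::colSums(design)
  pre <- lapply(folds, function(f) {
    xf <- design[f, , drop = FALSE]
    xt <- design[-f, , drop = FALSE]
    yt <- response[-f]
    list(xtx = xtx_all - Matrix::crossprod(xf),
         xty = Matrix::crossprod(xt, yt - mean(yt)),
         xcm = as.numeric(csum_all - Matrix::colSums(xf)) / (n - length(f)),
         n_train = n - length(f),
         off = mean(yt), x_test = xf, y_test = response[f])
  })
  ev <- vapply(lambdas, function(lam) {
    mean(vapply(pre, function(p) {
      fit <- fit_strf(p$x_test, p$y_test, lam, xtx = p$xtx, xty = p$xty,
                      xcm = p$xcm, n_train = p$n_train, penalty = penalty)
      # weights come from the training normal equations supplied above;
      # the training intercept is rebuilt from the training means.
      yhat <- as.numeric(p$x_test %*% fit$w) + p$off - sum(p$xcm * fit$w)
      explained_variance(p$y_test, yhat)
    }, numeric(1L)), na.rm = TRUE)
  }, numeric(1L))
  if (all(is.na(ev))) stopf("explained variance undefined for all lambdas")
  best <- which.max(ev)
  fit <- fit_strf(design, response, lambdas[best], xtx = xtx_all,
                  penalty = penalty)
  list(lambda = lambdas[best], ev_cv = ev[best],
       ev_by_lambda = data.frame(lambda = lambdas, ev = ev),
       fit = fit, penalty = penalty)
}

#' Circular-shift permutation test for stRF significance
#'
#' Refits the receptive field after circularly shifting the response in
#' time relative to the stimulus (equivalent to shifting the stimulus
#' predictor, and preserving autocorrelation), building a null
#' distribution of explained variances. `p` is the fraction of null EVs
#' exceeding the real EV, floored at `1/n_shifts` so it is never 0.
#' Shifts are drawn uniformly outside `±min_shift` seconds.
#'
#' @param design,response as in [fit_strf()].
#' @param lambda regularization weight (use the cross-validated choice).
#' @param n_shifts number of random shifts (>= 2; < 100 warns).
#' @param min_shift minimum shift magnitude (s).
#' @param seed integer seed.
#' @param xtx,penalty optional precomputed pieces.
#' @return list: `p`, `ev_real`, `ev_null` (vector).
#' @export
circular_shift_test <- function(design, response, lambda, n_shifts = 1000L,
                                min_shift = 5, seed = 1L, xtx = NULL,
                                penalty = NULL) {
  if (n_shifts < 2L) stopf("n_shifts must be >= 2")
  if (n_shifts < 100L) warnf("n_shifts < 100 gives a coarse p-value")
  n <- nrow(design)
  rate <- attr(design, "response_rate")
  ms <- max(1L, round(min_shift * rate))
  if (ms >= n - ms) stopf("trace too short for min_shift")
  if (is.null(penalty)) penalty <- laplacian_penalty(design)
  if (is.null(xtx)) xtx <- Matrix::crossprod(design)
  xcm <- Matrix::colMeans(design)
  a <- as.matrix(xtx + lambda * penalty) - n * tcrossprod(xcm)
  ch <- chol(a)
  ev_of <- function(y) {
    yc <- y - mean(y)
    xty <- as.numeric(Matrix::crossprod(design, yc))
    w <- backsolve(ch, backsolve(ch, xty, transpose = TRUE))
    explained_variance(y, as.numeric(design %*% w) + mean(y) - sum(xcm * w))
  }
  ev_real <- ev_of(response)
  with_seed(seed, {
    shifts <- sample(ms:(n - ms), n_shifts, replace = TRUE)
    ev_null <- vapply(shifts, function(s) {
      ev_of(response[(seq_len(n) + s - 1L) %% n + 1L])
    }, numeric(1L))
    list(p = max(mean(ev_null > ev_real), 1 / n_shifts),
         ev_real = ev_real, ev_null = ev_null)
  })
}

#' Responsiveness classification
#'
#' A site is responsive when the full-data explained variance exceeds
#' `ev_threshold` (default 0.1) and the circular-shift p-value is below
#' `p_threshold` (default 0.005).
#'
#' @param ev_full full-data explained variance.
#' @param p circular-shift p-value.
#' @param ev_threshold,p_threshold thresholds.
#' @return logical flag.
#' @export
classify_responsive <- function(ev_full, p, ev_threshold = 0.1,
                                p_threshold = 0.005) {
  if (is.na(ev_full) || is.na(p)) stopf("ev and p must be defined")
  ev_full > ev_threshold && p < p_threshold
}

# Reshape a flat weight vector into ON and OFF gy x gx x n_lags arrays
# (inverse of the build_design column ordering).
strf_weight_arrays <- function(w, grid_dim, n_lags) {
  p <- prod(grid_dim)
  on <- array(w[seq_len(p * n_lags)], c(grid_dim, n_lags))
  off <- array(w[p * n_lags + seq_len(p * n_lags)], c(grid_dim, n_lags))
  list(on = on, off = off)
}

#' Fit a spatiotemporal receptive field end to end
#'
#' Convenience wrapper: builds the design, cross-validates lambda, refits
#' on the full recording, runs the circular-shift test and classifies
#' responsiveness; for responsive sites the spatial RF is extracted and
#' fitted with a 2D Gaussian ([spatial_rf()]).
#'
#' @param stimulus a [sparse_noise_stimulus()].
#' @param response response trace.
#' @param response_rate response sampling rate (Hz).
#' @param max_lag maximum lag (s).
#' @param lambdas optional lambda grid.
#' @param folds CV folds.
#' @param n_shifts circular-shift permutations.
#' @param min_shift minimum shift (s).
#' @param seed integer seed.
#' @return object of class `strf`: `on_weights`, `off_weights`
#'   (gy x gx x n_lags), `lambda`, `ev_cv`, `ev_full`, `p_shift`,
#'   `responsive`, `best_lag`, `spatial` (Gaussian fit or `NULL`), `lags`.
#' @export
estimate_strf <- function(stimulus, response, response_rate, max_lag = 1.4,
                          lambdas = NULL, folds = 3L, n_shifts = 1000L,
                          min_shift = 5, seed = 1L) {
  design <- build_design(stimulus, response_rate, max_lag,
                         n_samples = length(response))
  cv <- crossval_lambda(design, response, lambdas, k = folds)
  ev_full <- explained_variance(response, cv$fit$fitted)
  sh <- circular_shift_test(design, response, cv$lambda,
                            n_shifts = n_shifts, min_shift = min_shift,
                            seed = seed, penalty = cv$penalty)
  arrs <- strf_weight_arrays(cv$fit$w, attr(design, "grid_dim"),
                             attr(design, "n_lags"))
  resp <- classify_responsive(ev_full, sh$p)
  out <- structure(list(on_weights = arrs$on, off_weights = arrs$off,
                        lambda = cv$lambda, ev_cv = cv$ev_cv,
                        ev_full = ev_full, p_shift = sh$p,
                        responsive = resp,
                        lags = attr(design, "lags"),
                        ev_by_lambda = cv$ev_by_lambda,
                        best_lag = NA_real_, spatial = NULL),
                   class = "strf")
  if (resp) {
    sp <- spatial_rf(out)
    out$best_lag <- sp$best_lag
    out$spatial <- sp
  }
  out
}

#' Spatial receptive field and 2D Gaussian subfield fit
#'
#' The combined ON/OFF map is `(ON - OFF) / 2` (OFF weights sign-flipped
#' so suppression by light increments reads negative); the spatial RF is
#' the lag slice with the largest absolute combined response, fitted with
#' an elliptical 2D Gaussian by least squares. A failed fit is flagged and
#' the raw slice still returned.
#'
#' @param strf an `strf` object (from [estimate_strf()]), or a list with
#'   `on_weights`, `off_weights`, `lags`.
#' @return list: `map` (best-lag combined slice), `best_lag` (s),
#'   `gaussian` (amplitude, center (row, col), sigma (row, col), angle,
#'   offset, converged).
#' @export
spatial_rf <- function(strf) {
  comb <- (strf$on_weights - strf$off_weights) / 2
  n_lags <- dim(comb)[3L]
  score <- vapply(seq_len(n_lags), function(l) max(abs(comb[, , l])),
                  numeric(1L))
  best <- which.max(score)
  slice <- comb[, , best]
  g <- fit_gaussian2d(slice)
  list(map = slice, best_lag = strf$lags[best], gaussian = g)
}

#' Least-squares elliptical 2D Gaussian fit
#'
#' @param mat matrix to fit (signed; the dominant-|value| polarity sets
#'   the amplitude sign).
#' @return list: `amplitude`, `center` (row, col), `sigma` (row, col along
#'   the rotated axes), `angle` (rad), `offset`, `converged`, `fitted`.
#' @export
fit_gaussian2d <- function(mat) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sgn <- if (abs(max(mat)) >= abs(min(mat))) 1 else -1
  wts <- pmax(sgn * mat, 0)
  tot <- sum(wts)
  if (tot <= 0) return(list(converged = FALSE))
  cy <- sum(yy * wts) / tot
  cx <- sum(xx * wts) / tot
  sy <- sqrt(sum((yy - cy)^2 * wts) / tot) + 0.3
  sx <- sqrt(sum((xx - cx)^2 * wts) / tot) + 0.3
  par0 <- c(sgn * max(abs(mat)), cy, cx, log(sy), log(sx), 0, 0)
  model <- function(p) {
    a <- p[1L]; y0 <- p[2L]; x0 <- p[3L]
    s1 <- exp(p[4L]); s2 <- exp(p[5L]); th <- p[6L]; c0 <- p[7L]
    u <- (yy - y0) * cos(th) + (xx - x0) * sin(th)
    v <- -(yy - y0) * sin(th) + (xx - x0) * cos(th)
    a * exp(-(u^2 / (2 * s1^2) + v^2 / (2 * s2^2))) + c0
  }
  o <- stats::optim(par0, function(p) sum((mat - model(p))^2),
                    method = "Nelder-Mead",
                    control = list(maxit = 3000, reltol = 1e-12))
  p <- o$par
  list(amplitude = p[1L], center = c(p[2L], p[3L]),
       sigma = exp(p[4:5]), angle = p[6L], offset = p[7L],
       converged = o$convergence == 0L, fitted = model(p))
}
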