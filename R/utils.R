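# Internal helpers shared across modules.

stopf <- function(..., class = "glusense_invalid_parameter") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG stream afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seed below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) %% 100003 * 69069 + h * 7919 + 1) %% 2147483629)
}

# Discrete Gaussian kernel (unit sum) with support truncated at 4 sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian low-pass along time for a vector or the columns of a matrix.
# Edges handled by reflection padding so there are no NA stubs.
gauss_lowpass <- function(x, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  top <- x[pmin(n, (r + 1L):2L), , drop = FALSE]
  bot <- x[pmax(1L, (n - 1L):(n - r)), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- stats::filter(xp, k, sides = 2)
  y <- y[(r + 1L):(r + n), , drop = FALSE]
  if (vec) as.numeric(y) else unclass(y)
}

# Adjusted Fisher-Pearson sample skewness, columnwise.
col_skewness <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  d <- sweep(m, 2L, mu)
  m2 <- colMeans(d^2)
  m3 <- colMeans(d^3)
  g1 <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Local maxima above `min_height`, greedily enforcing a minimum separation
# (in samples); stronger peaks win ties. Returns sorted indices.
find_peaks <- function(x, min_height = -Inf, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand) || min_sep <= 1L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Movie arrays are dim = c(T, rows, cols) so each pixel's time series is
# contiguous; this flattens to a T x (rows*cols) matrix.
movie_as_matrix <- function(movie) {
  d <- dim(movie)
  if (length(d) != 3L) stopf("movie must be a T x rows x cols array")
  dim(movie) <- c(d[1L], d[2L] * d[3L])
  movie
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0
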