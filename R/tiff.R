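# Minimal baseline TIFF support: multi-page, grayscale, uncompressed,
# little-endian, one strip per page; 16-bit unsigned or 32-bit float
# samples. Enough to exchange synthetic movies with standard readers
# (validated against Python tifffile in the test suite) without an
# external imaging dependency.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_entry <- function(tag, type, count, value) {
  list(tag = as.integer(tag), type = as.integer(type),
       count = as.integer(count), value = as.integer(value))
}

write_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                       endian = "little")
write_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4L,
                                       endian = "little")

#' Write a movie as a multi-page TIFF
#'
#' Frames are written in acquisition order as grayscale pages, 16-bit
#' unsigned when all values are integers in `[0, 65535]`, 32-bit float
#' otherwise.
#'
#' @param frames T x rows x cols array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(frames, path) {
  d <- dim(frames)
  if (length(d) != 3L) stopf("frames must be a T x rows x cols array")
  nt <- d[1L]; nr <- d[2L]; nc <- d[3L]
  vals <- as.numeric(frames)
  uint16 <- all(vals >= 0 & vals <= 65535 & vals == round(vals))
  bps <- if (uint16) 16L else 32L
  fmt <- if (uint16) 1L else 3L
  bytes_per_page <- nr * nc * bps / 8L
  n_tags <- 10L
  ifd_size <- 2L + 12L * n_tags + 4L
  data0 <- 8L
  ifd0 <- data0 + nt * bytes_per_page
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u16(con, 42L)
  write_u32(con, ifd0)
  for (t in seq_len(nt)) {
    page <- t(matrix(frames[t, , ], nr, nc))   # row-major pixel order
    if (uint16) writeBin(as.integer(page), con, size = 2L, endian = "little")
    else writeBin(as.numeric(page), con, size = 4L, endian = "little")
  }
  for (t in seq_len(nt)) {
    entries <- list(
      tiff_entry(256L, TIFF_TYPE_LONG, 1L, nc),
      tiff_entry(257L, TIFF_TYPE_LONG, 1L, nr),
      tiff_entry(258L, TIFF_TYPE_SHORT, 1L, bps),
      tiff_entry(259L, TIFF_TYPE_SHORT, 1L, 1L),       # no compression
      tiff_entry(262L, TIFF_TYPE_SHORT, 1L, 1L),       # black is zero
      tiff_entry(273L, TIFF_TYPE_LONG, 1L, data0 + (t - 1L) * bytes_per_page),
      tiff_entry(277L, TIFF_TYPE_SHORT, 1L, 1L),
      tiff_entry(278L, TIFF_TYPE_LONG, 1L, nr),
      tiff_entry(279L, TIFF_TYPE_LONG, 1L, bytes_per_page),
      tiff_entry(339L, TIFF_TYPE_SHORT, 1L, fmt))
    write_u16(con, length(entries))
    for (e in entries) {
      write_u16(con, e$tag)
      write_u16(con, e$type)
      write_u32(con, e$count)
      if (e$type == TIFF_TYPE_SHORT) {
        write_u16(con, e$value)
        write_u16(con, 0L)
      } else {
        write_u32(con, e$value)
      }
    }
    nxt <- if (t < nt) ifd0 + t * ifd_size else 0L
    write_u32(con, nxt)
  }
  invisible(path)
}

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Read a multi-page grayscale TIFF written by [write_movie_tiff()]
#'
#' Supports little-endian, uncompressed, single-sample pages (any strip
#' layout) with 8/16-bit unsigned or 32-bit float samples.
#'
#' @param path TIFF file path.
#' @return T x rows x cols numeric array.
#' @export
read_movie_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stopf("only little-endian TIFF is supported")
  if (read_u16(raw, 2L) != 42L) stopf("not a TIFF file")
  off <- read_u32(raw, 4L)
  pages <- list()
  while (off != 0) {
    n <- read_u16(raw, off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- off + 2L + (i - 1L) * 12L
      tag <- read_u16(raw, e)
      type <- read_u16(raw, e + 2L)
      count <- read_u32(raw, e + 4L)
      size <- c(1L, 1L, 2L, 4L)[min(type, 4L)]
      vals <- if (count * size <= 4L) {
        voff <- e + 8L
        if (type == TIFF_TYPE_SHORT)
          vapply(seq_len(count), function(j) read_u16(raw, voff + 2L * (j - 1L)),
                 numeric(1L))
        else read_u32(raw, voff)
      } else {
        voff <- read_u32(raw, e + 8L)
        vapply(seq_len(count), function(j) {
          if (type == TIFF_TYPE_SHORT) read_u16(raw, voff + 2L * (j - 1L))
          else read_u32(raw, voff + 4L * (j - 1L))
        }, numeric(1L))
      }
      tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    off <- read_u32(raw, off + 2L + n * 12L)
  }
  if (!length(pages)) stopf("empty TIFF")
  nc <- pages[[1L]][["256"]]
  nr <- pages[[1L]][["257"]]
  bps <- pages[[1L]][["258"]]
  fmt <- if (is.null(pages[[1L]][["339"]])) 1L else pages[[1L]][["339"]]
  if (!is.null(pages[[1L]][["259"]]) && pages[[1L]][["259"]] != 1L)
    stopf("compressed TIFF not supported")
  out <- array(0, c(length(pages), nr, nc))
  for (t in seq_along(pages)) {
    tg <- pages[[t]]
    offs <- tg[["273"]]
    cnts <- tg[["279"]]
    buf <- unlist(lapply(seq_along(offs), function(s) {
      raw[(offs[s] + 1L):(offs[s] + cnts[s])]
    }))
    px <- if (bps == 8L) as.numeric(buf)
      else if (bps == 16L)
        readBin(buf, "integer", nr * nc, size = 2L, signed = FALSE,
                endian = "little")
      else if (fmt == 3L)
        readBin(buf, "double", nr * nc, size = 4L, endian = "little")
      else readBin(buf, "integer", nr * nc, size = 4L, endian = "little")
    out[t, , ] <- matrix(px, nr, nc, byrow = TRUE)
  }
  out
}
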