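#' Calibrated multi-channel movie
#'
#' Container for a two (or more) channel 2D time series: a numeric array
#' indexed `[channel, frame, y, x]` plus the physical calibration every
#' downstream stage needs. Single-frame data are stored with one frame
#' and `frame_interval = NA`.
#'
#' @param pixels Numeric array with dimensions (channel, frame, y, x).
#'   A plain matrix is promoted to a single-channel, single-frame stack.
#' @param pixel_size Pixel size in micrometres per pixel (isotropic in
#'   X-Y); must be supplied explicitly.
#' @param frame_interval Seconds per frame; required when there is more
#'   than one frame, `NA` otherwise.
#' @param channel_names Optional character vector of channel labels
#'   (e.g. `c("PI3P", "TGN")`).
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(pixels, pixel_size, frame_interval = NA_real_,
                        channel_names = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, 1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 4L) {
    stop("`pixels` must be a (channel, frame, y, x) array", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  d <- dim(pixels)
  if (d[2] > 1L && (is.na(frame_interval) || frame_interval <= 0)) {
    stop("`frame_interval` must be a positive number of seconds for ",
         "multi-frame data", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(d[1]))
  }
  if (length(channel_names) != d[1]) {
    stop("`channel_names` must have one label per channel", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         frame_interval = as.numeric(frame_interval),
         channel_names = as.character(channel_names)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "movie_stack: %d channel(s) [%s], %d frame(s), %d x %d px\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[4], d[3]))
  cat(sprintf("  pixel size %.4g um/px", x$pixel_size))
  if (!is.na(x$frame_interval)) {
    cat(sprintf(", frame interval %.4g s", x$frame_interval))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$pixels)

n_frames <- function(movie) dim(movie$pixels)[2]
n_channels <- function(movie) dim(movie$pixels)[1]

#' Extract one frame of one channel as a matrix
#'
#' @param movie A [movie_stack()].
#' @param channel Channel index or name.
#' @param frame Frame index (1-based).
#' @return A numeric matrix `[y, x]`.
#' @export
get_frame <- function(movie, channel = 1L, frame = 1L) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.character(channel)) {
    channel <- match(channel, movie$channel_names)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  movie$pixels[channel, frame, , ]
}

#' Read a multi-page TIFF into a calibrated movie
#'
#' Reads 8/16-bit (or float) TIFF data and reshapes the pages into a
#' `(channel, frame, y, x)` stack according to the declared page
#' layout. Calibration is never guessed from file metadata: pixel size
#' (and frame interval for time series) must be given explicitly.
#'
#' @param path Path to a TIFF file, or a character vector of paths (one
#'   single-channel file per channel) with `layout = "split"`.
#' @param pixel_size Pixel size in um/px (required).
#' @param frame_interval Seconds per frame for time series.
#' @param layout Page layout: `"TCYX"` (frame-major: all channels of
#'   frame 1, then frame 2, ...), `"CTYX"` (channel-major: all frames
#'   of channel 1, then channel 2, ...), or `"split"` (one file per
#'   channel).
#' @param n_channels Number of channels interleaved in a single file
#'   (ignored for `"split"`).
#' @param channel_names Optional channel labels.
#' @return A [movie_stack()]. Integer data are preserved exactly.
#' @export
read_movie <- function(path, pixel_size, frame_interval = NA_real_,
                       layout = c("TCYX", "CTYX", "split"),
                       n_channels = 1L, channel_names = NULL) {
  layout <- match.arg(layout)
  if (missing(pixel_size)) {
    stop("calibration error: `pixel_size` must be supplied", call. = FALSE)
  }
  read_pages <- function(p) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # first sample of RGB data
      m
    })
  }
  if (layout == "split") {
    per_channel <- lapply(path, read_pages)
    nf <- vappl_int(per_channel, length)
    if (length(unique(nf)) != 1L) {
      stop("format error: per-channel files have differing frame counts",
           call. = FALSE)
    }
    nc <- length(per_channel)
    nt <- nf[1]
    shp <- dim(per_channel[[1]][[1]])
    pixels <- array(0, c(nc, nt, shp[1], shp[2]))
    for (c in seq_len(nc)) for (t in seq_len(nt)) {
      m <- per_channel[[c]][[t]]
      if (!identical(dim(m), shp)) {
        stop("format error: page shapes differ between channels",
             call. = FALSE)
      }
      pixels[c, t, , ] <- m
    }
  } else {
    pages <- read_pages(path)
    np <- length(pages)
    nc <- as.integer(n_channels)
    if (nc < 1L || np %% nc != 0L) {
      stop("format error: page count ", np,
           " is not a multiple of n_channels = ", nc, call. = FALSE)
    }
    nt <- np %/% nc
    shp <- dim(pages[[1]])
    pixels <- array(0, c(nc, nt, shp[1], shp[2]))
    for (k in seq_len(np)) {
      if (!identical(dim(pages[[k]]), shp)) {
        stop("format error: pages have differing shapes", call. = FALSE)
      }
      if (layout == "TCYX") {
        t <- (k - 1L) %/% nc + 1L
        c <- (k - 1L) %% nc + 1L
      } else {
        c <- (k - 1L) %/% nt + 1L
        t <- (k - 1L) %% nt + 1L
      }
      pixels[c, t, , ] <- pages[[k]]
    }
  }
  movie_stack(pixels, pixel_size = pixel_size,
              frame_interval = frame_interval,
              channel_names = channel_names)
}

#' Write a movie to a multi-page 16-bit TIFF
#'
#' Pages are written frame-major (`TCYX`). Integer intensities in
#' `[0, 65535]` round-trip exactly through [read_movie()].
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$pixels)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[2])) for (c in seq_len(d[1])) {
    m <- movie$pixels[c, t, , ]
    m <- pmin(pmax(round(m), 0), 65535)
    pages[[k]] <- m / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

vappl_int <- function(x, f) vapply(x, f, integer(1))
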