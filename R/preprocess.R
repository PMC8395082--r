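#' Gaussian blur by physical radius
#'
#' Convolves an image with a normalized isotropic Gaussian whose sigma,
#' in pixels, is `radius_um / pixel_size` (the blur parameter is the
#' sigma expressed in physical units, the convention of the ImageJ
#' ecosystem's "Sigma (Radius)" field). The kernel is truncated at
#' 4 sigma and renormalized; borders are handled by mirror reflection
#' so that edge intensities are not dimmed.
#'
#' @param image Numeric matrix `[y, x]`.
#' @param radius_um Blur sigma in micrometres; must be > 0.
#' @param pixel_size Pixel size in um/px.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, radius_um, pixel_size) {
  stopifnot(is.matrix(image))
  if (radius_um <= 0) stop("`radius_um` must be > 0", call. = FALSE)
  check_pixel_size(pixel_size)
  sigma <- radius_um / pixel_size
  if (sigma < 0.1) {
    warning("blur sigma ", signif(sigma, 3),
            " px is below 0.1 px; returning input unchanged")
    return(image)
  }
  k <- gaussian_kernel_1d(sigma)
  cpp_convolve_sep(image, k)
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as
#' the grayscale opening with a ball-shaped (spherical-cap height
#' profile) structuring element of the given radius, and subtracts it,
#' clamping at zero. Structures narrower than the ball (diffraction-
#' limited dots) are preserved; broad gradients are removed. Borders
#' are mirror-reflected.
#'
#' @param image Numeric matrix `[y, x]`.
#' @param ball_radius_px Ball radius in pixels; `>= 1`.
#' @return Background-subtracted matrix, everywhere `>= 0` and
#'   `<= image`.
#' @export
subtract_background <- function(image, ball_radius_px) {
  stopifnot(is.matrix(image))
  if (ball_radius_px < 1) stop("`ball_radius_px` must be >= 1", call. = FALSE)
  se <- ball_element(ball_radius_px)
  bg <- cpp_dilate_nonflat(
    cpp_erode_nonflat(image, se$dx, se$dy, se$h), se$dx, se$dy, se$h)
  pmax(image - bg, 0)
}

# Ball structuring element: support = disc of radius r, heights
# h(d) = sqrt(r^2 - d^2) relative to the ball top.
ball_element <- function(r) {
  ri <- as.integer(ceiling(r))
  off <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  d2 <- off$dx^2 + off$dy^2
  keep <- d2 <= r^2
  list(dx = as.integer(off$dx[keep]), dy = as.integer(off$dy[keep]),
       h = sqrt(r^2 - d2[keep]))
}

#' Apply the standard preprocessing recipe to a movie
#'
#' Gaussian blur followed by rolling-ball background subtraction,
#' applied to every channel and every frame independently (no temporal
#' filtering). Either step can be disabled by passing `NULL`.
#'
#' @param movie A [movie_stack()].
#' @param gaussian_radius_um Blur sigma in um, or `NULL` to skip.
#' @param rolling_ball_px Ball radius in px, or `NULL` to skip.
#' @return A preprocessed [movie_stack()].
#' @export
preprocess_movie <- function(movie, gaussian_radius_um = 0.1,
                             rolling_ball_px = 10) {
  stopifnot(inherits(movie, "movie_stack"))
  out <- movie
  for (c in seq_len(n_channels(movie))) {
    for (t in seq_len(n_frames(movie))) {
      m <- movie$pixels[c, t, , ]
      if (!is.null(gaussian_radius_um)) {
        m <- gaussian_blur(m, gaussian_radius_um, movie$pixel_size)
      }
      if (!is.null(rolling_ball_px)) {
        m <- subtract_background(m, rolling_ball_px)
      }
      out$pixels[c, t, , ] <- m
    }
  }
  out
}
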