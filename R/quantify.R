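#' Per-dot intensity quantification
#'
#' Sums the total intensity of all detected dots of one image/cell and
#' normalizes by the number of dots.
#'
#' @param objects Data frame from [measure_objects()] (after any
#'   filtering), for a single image or cell.
#' @return A list with `n_dots`, `total_intensity` and
#'   `intensity_per_dot`; the per-dot value is `NA` (flagged, not a
#'   silent zero) when there are no dots.
#' @export
quantify_dots <- function(objects) {
  n <- nrow(objects)
  tot <- sum(objects$total_intensity)
  list(n_dots = n,
       total_intensity = tot,
       intensity_per_dot = if (n > 0) tot / n else NA_real_)
}

#' Plasma-membrane band intensity per area
#'
#' Integrates intensity over the pixels that lie inside a hand-drawn
#' cell outline and within `band_um` of the outline, normalized by the
#' band area in um^2. This is the standard read-out for signal at or
#' near the plasma membrane when the outline is drawn just outside it.
#'
#' @param image Numeric matrix `[y, x]`.
#' @param outline An [roi_polygon()] enclosing the cell.
#' @param band_um Band width in micrometres (> 0); default 1.5.
#' @param pixel_size Pixel size in um/px.
#' @return Intensity per um^2. If the band is wider than the cell
#'   inradius the band is the whole polygon and a warning is issued.
#' @export
quantify_pm_band <- function(image, outline, band_um = 1.5, pixel_size) {
  stopifnot(is.matrix(image), inherits(outline, "roi_polygon"))
  if (band_um <= 0) stop("`band_um` must be > 0", call. = FALSE)
  check_pixel_size(pixel_size)
  nr <- nrow(image); nc <- ncol(image)
  xs <- rep(seq_len(nc) - 1L, each = nr)
  ys <- rep(seq_len(nr) - 1L, times = nc)
  inside <- points_in_polygon(xs, ys, outline)
  if (!any(inside)) stop("outline encloses no pixels", call. = FALSE)
  band_px <- um_to_px(band_um, pixel_size)
  d <- dist_to_polygon_boundary(xs[inside], ys[inside], outline)
  in_band <- d <= band_px
  if (all(in_band)) {
    warning("band is wider than the cell inradius; using whole polygon")
  }
  sel <- which(inside)[in_band]
  area_um2 <- length(sel) * pixel_size^2
  sum(image[sel]) / area_um2
}

#' Whole-ROI intensity per area
#'
#' Total intensity of all pixels inside the polygon divided by the ROI
#' area in um^2 (an intensive quantity: independent of ROI size for
#' uniform signal).
#'
#' @param image Numeric matrix `[y, x]`.
#' @param roi An [roi_polygon()].
#' @param pixel_size Pixel size in um/px.
#' @return Intensity per um^2.
#' @export
quantify_roi_per_area <- function(image, roi, pixel_size) {
  stopifnot(is.matrix(image), inherits(roi, "roi_polygon"))
  check_pixel_size(pixel_size)
  mask <- roi_mask(roi, nrow(image), ncol(image))
  n <- sum(mask)
  if (n == 0) stop("zero-area ROI", call. = FALSE)
  sum(image[mask]) / (n * pixel_size^2)
}
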