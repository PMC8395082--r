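#' Optical specification of the imaging setup
#'
#' Bundles the quantities that set the lateral resolution of a confocal
#' acquisition: the emission wavelength of the shorter-wavelength
#' fluorophore, the numerical aperture of the objective, and the
#' resolution-improvement factor of a detector-array (Airyscan-type)
#' mode.
#'
#' @param lambda_em Emission wavelength in nanometres (e.g. 529 for
#'   mCITRINE).
#' @param na Numerical aperture of the objective (e.g. 1.3 for an
#'   oil-immersion 40x lens).
#' @param airyscan_factor Resolution improvement ratio of the detection
#'   mode; 1 for conventional confocal, about 1.7 for Airyscan. Must be
#'   >= 1.
#' @return An object of class `optics_spec`.
#' @examples
#' optics_spec(lambda_em = 529, na = 1.3, airyscan_factor = 1.7)
#' @export
optics_spec <- function(lambda_em, na, airyscan_factor = 1) {
  for (nm in c("lambda_em", "na", "airyscan_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid optics: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (airyscan_factor < 1) {
    stop("invalid optics: `airyscan_factor` must be >= 1", call. = FALSE)
  }
  structure(
    list(lambda_em = as.numeric(lambda_em), na = as.numeric(na),
         airyscan_factor = as.numeric(airyscan_factor)),
    class = "optics_spec"
  )
}

#' Lateral resolution limit of the acquisition
#'
#' Computes the Rayleigh-type lateral resolution limit
#' \eqn{0.61 \lambda / (\mathrm{NA} \cdot X)} in nanometres, where
#' \eqn{X} is the resolution improvement ratio of the detection mode
#' (1 for conventional confocal). With `floor_to_tens = TRUE` the value
#' is floored to the nearest 10 nm, the precision at which such limits
#' are conventionally reported; the default returns the unrounded
#' value.
#'
#' @param optics An [optics_spec()].
#' @param floor_to_tens Floor the result to the nearest 10 nm? Default
#'   `FALSE`.
#' @return Resolution limit in nm.
#' @examples
#' o <- optics_spec(529, 1.3, 1.7)
#' resolution_limit(o)                       # ~146 nm
#' resolution_limit(o, floor_to_tens = TRUE) # 140 nm
#' @export
resolution_limit <- function(optics, floor_to_tens = FALSE) {
  if (!inherits(optics, "optics_spec")) {
    stop("`optics` must be an optics_spec", call. = FALSE)
  }
  r <- 0.61 * optics$lambda_em / optics$na / optics$airyscan_factor
  if (isTRUE(floor_to_tens)) r <- 10 * floor(r / 10)
  r
}

#' Convert between pixels and micrometres
#'
#' Exact linear conversions given an isotropic pixel size. The two
#' functions are inverses of one another.
#'
#' @param px Length in pixels.
#' @param um Length in micrometres.
#' @param pixel_size Pixel size in micrometres per pixel; must be > 0.
#' @return Length in the other unit.
#' @examples
#' px_to_um(5, 0.125)   # 0.625 um
#' um_to_px(1.25, 0.125) # 10 px
#' @export
px_to_um <- function(px, pixel_size) {
  check_pixel_size(pixel_size)
  px * pixel_size
}

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_size) {
  check_pixel_size(pixel_size)
  um / pixel_size
}

check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)",
         call. = FALSE)
  }
  invisible(pixel_size)
}
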