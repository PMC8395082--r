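#' Analysis configuration
#'
#' All tunable parameters of the detection / colocalization / tracking
#' pipeline, with the defaults used throughout: a constant intensity
#' threshold (held fixed across all samples of one comparison), the
#' circularity filter at 0.1, a 1.5 um plasma-membrane band, 0.1 um
#' Gaussian blur, rolling-ball radius 10 px, association window
#' [1, 5] px, maximum tracking displacement 10 px per frame and minimum
#' track length 3 frames.
#'
#' @param threshold Intensity cutoff applied to the preprocessed image,
#'   or the method tag `"otsu"` to derive one via [otsu_threshold()].
#' @param min_circularity Minimum circularity `4*pi*A/P^2` retained by
#'   the dot filter; in `[0, 1]`.
#' @param pm_band_um Width of the plasma-membrane band inside the cell
#'   outline, um.
#' @param gaussian_radius_um Gaussian blur sigma expressed in um.
#' @param rolling_ball_px Rolling-ball background radius in pixels.
#' @param assoc_min_px,assoc_max_px Association window bounds in pixels
#'   (closed interval); `assoc_min_px < assoc_max_px`.
#' @param max_disp_px Maximum frame-to-frame displacement when linking
#'   tracks, pixels.
#' @param min_track_frames Minimum number of frames a track must span;
#'   `>= 1`.
#' @param pixel_size Pixel size in um/px.
#' @param optics An [optics_spec()], or `NULL` if no colocalization
#'   against the resolution limit is needed.
#' @param seed Integer seed for stochastic procedures (Monte-Carlo
#'   statistics); the pipeline itself is deterministic.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(threshold = NULL,
                            min_circularity = 0.1,
                            pm_band_um = 1.5,
                            gaussian_radius_um = 0.1,
                            rolling_ball_px = 10,
                            assoc_min_px = 1,
                            assoc_max_px = 5,
                            max_disp_px = 10,
                            min_track_frames = 3,
                            pixel_size = 0.125,
                            optics = NULL,
                            seed = 1L) {
  if (assoc_min_px >= assoc_max_px) {
    stop("`assoc_min_px` must be < `assoc_max_px`", call. = FALSE)
  }
  if (min_track_frames < 1) {
    stop("`min_track_frames` must be >= 1", call. = FALSE)
  }
  if (min_circularity < 0 || min_circularity > 1) {
    stop("`min_circularity` must lie in [0, 1]", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  if (!is.null(optics) && !inherits(optics, "optics_spec")) {
    optics <- do.call(optics_spec, as.list(optics))
  }
  structure(
    list(threshold = threshold, min_circularity = min_circularity,
         pm_band_um = pm_band_um, gaussian_radius_um = gaussian_radius_um,
         rolling_ball_px = rolling_ball_px, assoc_min_px = assoc_min_px,
         assoc_max_px = assoc_max_px, max_disp_px = max_disp_px,
         min_track_frames = as.integer(min_track_frames),
         pixel_size = pixel_size, optics = optics,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Keys match the arguments of [analysis_config()]; `optics` may be a
#' mapping with `lambda_em`, `na`, `airyscan_factor`.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
    y <- y[intersect(names(y), known)]
  }
  do.call(analysis_config, y)
}
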