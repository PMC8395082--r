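#' Nearest-neighbour centroid distances between two channels
#'
#' For every object of channel A, finds the channel-B object whose
#' centroid minimizes the Euclidean centre-centre distance (same
#' frame, same calibration). Ties are broken towards the lower B
#' label.
#'
#' @param objectsA,objectsB Data frames with columns `label`, `x_px`,
#'   `y_px` (as produced by [measure_objects()]).
#' @param pixel_size Optional pixel size (um/px); when given, distances
#'   are also reported in nm.
#' @return A data frame with one row per A-object: `source_id`,
#'   `target_id` (`NA` when B is empty), `distance_px` and, when
#'   calibrated, `distance_nm`. Empty A gives an empty result.
#' @export
nearest_neighbors <- function(objectsA, objectsB, pixel_size = NULL) {
  nA <- nrow(objectsA)
  out <- data.frame(source_id = c(objectsA$label, integer(0)),
                    target_id = rep(NA_integer_, nA),
                    distance_px = rep(NA_real_, nA))
  if (nA == 0L) {
    if (!is.null(pixel_size)) out$distance_nm <- numeric(0)
    return(out)
  }
  if (nrow(objectsB) > 0L) {
    ordB <- order(objectsB$label)
    bx <- objectsB$x_px[ordB]; by <- objectsB$y_px[ordB]
    blab <- objectsB$label[ordB]
    for (i in seq_len(nA)) {
      d <- sqrt((objectsA$x_px[i] - bx)^2 + (objectsA$y_px[i] - by)^2)
      j <- which.min(d)  # first minimum = lowest label after ordering
      out$target_id[i] <- blab[j]
      out$distance_px[i] <- d[j]
    }
  }
  if (!is.null(pixel_size)) {
    check_pixel_size(pixel_size)
    out$distance_nm <- out$distance_px * pixel_size * 1000
  }
  out
}

#' Object-based colocalization against the resolution limit
#'
#' Counts the channel-A objects whose nearest channel-B centroid lies
#' strictly below the optical resolution limit: below it the two
#' structures cannot be resolved apart and the colocalization is taken
#' as true. The measure is directional (A to B), not symmetric. The
#' limit should come from [resolution_limit()] evaluated at the
#' shorter emission maximum wavelength of the fluorophore pair.
#'
#' @param objectsA,objectsB Object tables of one frame.
#' @param limit_nm Distance threshold in nm.
#' @param pixel_size Pixel size in um/px.
#' @return A list with `n_source`, `n_colocalized`, `fraction` (NA if
#'   A is empty), `limit_nm`, and the per-object `records`.
#' @export
colocalize <- function(objectsA, objectsB, limit_nm, pixel_size) {
  nn <- nearest_neighbors(objectsA, objectsB, pixel_size = pixel_size)
  n_src <- nrow(nn)
  n_col <- sum(nn$distance_nm < limit_nm, na.rm = TRUE)
  list(n_source = n_src, n_colocalized = n_col,
       fraction = if (n_src > 0) n_col / n_src else NA_real_,
       limit_nm = limit_nm, records = nn)
}

#' Single-frame association calls within a pixel-distance window
#'
#' Classifies every channel-A object by the distance to its nearest
#' channel-B object: `colocalized` when the distance is below
#' `assoc_min_px` (the pair is not resolvable as two structures),
#' `associated` when it falls within the closed window
#' `[assoc_min_px, assoc_max_px]` (adjacent but distinguishable
#' compartments), neither otherwise. The two states are mutually
#' exclusive.
#'
#' @param objectsA,objectsB Object tables of one frame.
#' @param assoc_min_px,assoc_max_px Window bounds in pixels; the
#'   default `[1, 5]` px corresponds to ~125-625 nm at 0.125 um/px.
#' @return A data frame with `source_id`, `target_id`, `distance_px`,
#'   `colocalized`, `associated`, plus attribute `n_associated`.
#' @export
call_associations <- function(objectsA, objectsB,
                              assoc_min_px = 1, assoc_max_px = 5) {
  if (assoc_min_px >= assoc_max_px) {
    stop("`assoc_min_px` must be < `assoc_max_px`", call. = FALSE)
  }
  nn <- nearest_neighbors(objectsA, objectsB)
  nn$colocalized <- !is.na(nn$distance_px) & nn$distance_px < assoc_min_px
  nn$associated <- !is.na(nn$distance_px) &
    nn$distance_px >= assoc_min_px & nn$distance_px <= assoc_max_px
  attr(nn, "n_associated") <- sum(nn$associated)
  nn
}
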