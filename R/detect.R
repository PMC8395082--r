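#' Threshold-based dot segmentation
#'
#' Builds a binary mask `image >= threshold` and labels its
#' 8-connected components. The threshold is meant to be held constant
#' across all samples of one comparison; intensity measurements are
#' taken from the un-thresholded image via [measure_objects()].
#'
#' @param image Numeric matrix `[y, x]` (typically preprocessed).
#' @param threshold Intensity cutoff.
#' @return Integer label matrix; 0 is background. An image entirely
#'   below threshold yields zero labels (not an error).
#' @export
segment_dots <- function(image, threshold) {
  stopifnot(is.matrix(image))
  cpp_label8(image >= threshold)
}

#' Otsu threshold on a pooled histogram
#'
#' Helper for choosing the constant threshold of one experiment:
#' maximizes between-class variance over a 256-bin histogram of all
#' supplied intensities (pool every image of the comparison).
#'
#' @param values Numeric vector (or matrix) of intensities.
#' @param n_bins Number of histogram bins.
#' @return A single threshold value on the intensity scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

#' Circularity shape descriptor
#'
#' `4 * pi * A / P^2`: 1.0 for a perfect circle, small for elongated or
#' ragged structures. Values above 1 (possible for tiny digitized
#' shapes) are capped at 1.0, the convention of the tool ecosystem this
#' pipeline mirrors.
#'
#' @param area Area `A`.
#' @param perimeter Perimeter `P` (same length unit squared/linear).
#' @return Circularity in `(0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  c <- 4 * pi * area / perimeter^2
  pmin(c, 1)
}

#' Measure segmented objects
#'
#' Computes, for every labeled region: the geometric (unweighted)
#' centroid in 0-based pixel coordinates, area in px^2 and um^2, the
#' perimeter by Moore boundary tracing with corner-corrected
#' chain-code weights (0.948 per axial step, 0.948*sqrt(2) per
#' diagonal step; the estimator with smallest bias on small discs),
#' circularity `4*pi*A/P^2` (capped at 1), and the total / mean
#' intensity of `original_image` under the mask. Objects touching the
#' image border are retained and flagged. Objects smaller than
#' `min_area_px` (default 2 px^2; a single pixel has an ill-defined
#' perimeter) are dropped.
#'
#' @param labels Integer label matrix from [segment_dots()].
#' @param original_image Intensity image the masks are applied to
#'   (pre-threshold).
#' @param pixel_size Pixel size in um/px.
#' @param min_area_px Minimum object area in px^2.
#' @return A data frame with one row per object: `label`, `x_px`,
#'   `y_px`, `area_px2`, `area_um2`, `perimeter_px`, `circularity`,
#'   `total_intensity`, `mean_intensity`, `touches_border`.
#' @export
measure_objects <- function(labels, original_image, pixel_size,
                            min_area_px = 2) {
  stopifnot(is.matrix(labels), is.matrix(original_image),
            identical(dim(labels), dim(original_image)))
  check_pixel_size(pixel_size)
  nlab <- max(labels)
  empty <- data.frame(
    label = integer(), x_px = numeric(), y_px = numeric(),
    area_px2 = numeric(), area_um2 = numeric(), perimeter_px = numeric(),
    circularity = numeric(), total_intensity = numeric(),
    mean_intensity = numeric(), touches_border = logical())
  if (nlab == 0L) return(empty)
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  inten <- original_image[idx]
  res <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    sel <- lab == l
    a <- sum(sel)
    if (a < min_area_px) next
    r <- rows[sel]; cc <- cols[sel]
    per <- trace_perimeter(r, cc)
    res[[l]] <- data.frame(
      label = l,
      x_px = mean(cc) - 1, y_px = mean(r) - 1,
      area_px2 = a, area_um2 = a * pixel_size^2,
      perimeter_px = per,
      circularity = circularity(a, per),
      total_intensity = sum(inten[sel]),
      mean_intensity = mean(inten[sel]),
      touches_border = any(r == 1L | r == nr | cc == 1L | cc == nc))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Moore-neighbour outer boundary tracing of one object given its pixel
# rows/cols; returns the weighted chain-code perimeter (Kulpa weights).
# Interior holes are ignored (outer boundary only).
trace_perimeter <- function(r, cc) {
  w_ax <- 0.948
  w_di <- 0.948 * sqrt(2)
  n <- length(r)
  if (n == 1L) return(4 * w_ax)
  # local mask with a 1-pixel background pad
  r0 <- min(r) - 1L; c0 <- min(cc) - 1L
  m <- matrix(FALSE, max(r) - r0 + 2L, max(cc) - c0 + 2L)
  m[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
  # start: topmost then leftmost foreground pixel (row-major scan entry)
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # directions 0..7, clockwise order starting at West
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  scan_from <- 0L
  first_move <- NA_integer_
  perim <- 0
  steps <- 0L
  max_steps <- 8L * n + 8L
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- (scan_from + s) %% 8L
      ni <- cur[1] + nb[d + 1L, 1]; nj <- cur[2] + nb[d + 1L, 2]
      if (m[ni, nj]) {
        # Jacob's criterion: back at the start about to repeat the
        # first move -> the boundary is closed
        if (!is.na(first_move) &&
            cur[1] == start[1] && cur[2] == start[2] && d == first_move) {
          return(perim)
        }
        perim <- perim +
          if (nb[d + 1L, 1] != 0 && nb[d + 1L, 2] != 0) w_di else w_ax
        cur <- c(ni, nj)
        if (is.na(first_move)) first_move <- d
        scan_from <- (d + 6L) %% 8L
        found <- TRUE
        break
      }
    }
    if (!found) return(perim)
    steps <- steps + 1L
    if (steps > max_steps) return(perim)
  }
}

#' Filter objects by circularity
#'
#' Keeps only structures with circularity strictly greater than
#' `min_circularity` (default 0.1), removing non-dotty background such
#' as elongated strands.
#'
#' @param objects Data frame from [measure_objects()].
#' @param min_circularity Cutoff in `[0, 1]`.
#' @return The retained subset; never larger than the input.
#' @export
filter_circularity <- function(objects, min_circularity = 0.1) {
  objects[objects$circularity > min_circularity, , drop = FALSE]
}

#' Detect dots in every frame and channel of a movie
#'
#' Runs [segment_dots()], [measure_objects()] and
#' [filter_circularity()] per channel and frame. Intensities are read
#' from the supplied movie itself (preprocess first if the recipe
#' calls for it).
#'
#' @param movie A [movie_stack()].
#' @param threshold Constant intensity threshold.
#' @param min_circularity Circularity cutoff; set to 0 to disable.
#' @param min_area_px Minimum object size in px^2.
#' @return A data frame of objects with `channel` and `frame` columns
#'   prepended.
#' @export
detect_dots <- function(movie, threshold, min_circularity = 0.1,
                        min_area_px = 2) {
  stopifnot(inherits(movie, "movie_stack"))
  out <- list()
  for (c in seq_len(n_channels(movie))) {
    for (t in seq_len(n_frames(movie))) {
      img <- movie$pixels[c, t, , ]
      obj <- measure_objects(segment_dots(img, threshold), img,
                             movie$pixel_size, min_area_px = min_area_px)
      obj <- filter_circularity(obj, min_circularity)
      if (nrow(obj)) {
        obj <- cbind(channel = movie$channel_names[c], frame = t, obj)
        out[[length(out) + 1L]] <- obj
      }
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(channel = character(), frame = integer()),
                 measure_objects(matrix(0L, 2, 2), matrix(0, 2, 2), 1)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
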