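# Shared fixture builders: all synthetic, generated in code.

# Digital disc mask: pixels whose centre lies within `rad` of the centre.
make_disc <- function(rad, size = 2 * rad + 5) {
  ctr <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= rad^2)
}

# Rasterized regular k-gon of circumradius R.
make_kgon <- function(k, R = 60, size = 2 * R + 9) {
  ctr <- (size + 1) / 2
  th <- 2 * pi * (0:(k - 1)) / k + pi / 7
  poly <- roi_polygon(cbind(x = ctr + R * cos(th), y = ctr + R * sin(th)))
  m <- matrix(FALSE, size, size)
  for (j in seq_len(size)) {
    ys <- seq_len(size)
    m[, j] <- dtctrack:::points_in_polygon(rep(j, size), ys, poly)
  }
  m
}

# Measure a logical mask as a single object on a flat intensity image.
measure_mask <- function(mask, intensity = 1, pixel_size = 1) {
  img <- matrix(0, nrow(mask), ncol(mask))
  img[mask] <- intensity
  measure_objects(dtctrack:::cpp_label8(mask), img, pixel_size)
}

# Brute-force nearest-neighbour oracle: plain double loop.
nn_brute <- function(A, B) {
  out <- data.frame(source_id = A$label, target_id = NA_integer_,
                    distance_px = NA_real_)
  for (i in seq_len(nrow(A))) {
    best <- Inf; best_lab <- NA_integer_
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x_px[i] - B$x_px[j])^2 + (A$y_px[i] - B$y_px[j])^2)
      if (d < best || (d == best && B$label[j] < best_lab)) {
        best <- d; best_lab <- B$label[j]
      }
    }
    if (is.finite(best)) {
      out$target_id[i] <- best_lab
      out$distance_px[i] <- best
    }
  }
  out
}

random_objects <- function(n, extent = 50, labels = seq_len(n)) {
  data.frame(label = labels, x_px = runif(n, 0, extent),
             y_px = runif(n, 0, extent))
}

# Detections table for a spot moving along a given path (one per frame).
path_detections <- function(xy, labels = seq_len(nrow(xy)),
                            frames = seq_len(nrow(xy))) {
  data.frame(frame = frames, label = labels,
             x_px = xy[, 1], y_px = xy[, 2])
}

# Grayscale opening oracle: brute-force non-flat erode/dilate in R
# (reflective borders), for cross-checking the compiled kernels.
opening_oracle <- function(img, r) {
  se <- dtctrack:::ball_element(r)
  refl <- function(i, n) {
    if (n == 1) return(1L)
    per <- 2L * n - 2L
    i <- (i - 1L) %% per
    i[i < 0] <- i[i < 0] + per
    ifelse(i < n, i + 1L, per - i + 1L)
  }
  nr <- nrow(img); nc <- ncol(img)
  er <- matrix(Inf, nr, nc)
  for (k in seq_along(se$h)) {
    rows <- refl(seq_len(nr) + se$dy[k], nr)
    cols <- refl(seq_len(nc) + se$dx[k], nc)
    er <- pmin(er, img[rows, cols, drop = FALSE] - se$h[k])
  }
  di <- matrix(-Inf, nr, nc)
  for (k in seq_along(se$h)) {
    rows <- refl(seq_len(nr) - se$dy[k], nr)
    cols <- refl(seq_len(nc) - se$dx[k], nc)
    di <- pmax(di, er[rows, cols, drop = FALSE] + se$h[k])
  }
  di
}
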