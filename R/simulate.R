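#' Configuration of the synthetic two-channel movie simulator
#'
#' The simulator emulates the kind of data the pipeline is built for:
#' two populations of diffraction-limited spots (rendered as 2D
#' Gaussians with sub-pixel positions) undergoing Brownian motion on a
#' noisy background, with a declared number of channel-A/channel-B
#' pairs that move together ("associate") for a planted interval at a
#' tether distance inside the association window. Defaults mirror the
#' acquisition they stand in for: 0.125 um pixels, 2 s frame interval,
#' PSF sigma ~1 px, association lifetimes of mean 6 s.
#'
#' @param image_size Image side length, pixels.
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Seconds per frame.
#' @param n_frames Number of frames.
#' @param n_spots Spots per channel.
#' @param psf_sigma_px Gaussian PSF sigma, pixels.
#' @param amplitude Peak spot amplitude above background, counts.
#' @param background Constant background level, counts.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts;
#'   photon noise is Poisson on `background + signal`. Set `noise =
#'   FALSE` to disable both.
#' @param noise Apply noise at all?
#' @param diffusion_step_sd Brownian step standard deviation per axis,
#'   px/frame.
#' @param n_pairs Number of associated A-B pairs.
#' @param tether_px Tether distance of associated pairs, pixels; must
#'   lie inside `(assoc_min_px, assoc_max_px)`.
#' @param tether_jitter_sd Relative radial jitter of the tether, px.
#' @param lifetime `"exponential"` or `"fixed"` association lifetime.
#' @param lifetime_mean_s Mean (or fixed) association duration,
#'   seconds, on the `(n_frames - 1) * frame_interval` convention.
#' @param assoc_min_px,assoc_max_px The association window the planted
#'   pairs are constructed against.
#' @param exclusion Keep non-associated A-B spot pairs farther apart
#'   than `assoc_max_px` (plus margin)? Keeps the planted association
#'   intervals exactly recoverable; disable to study coincidental
#'   associations of unconstrained random scatter.
#' @param min_separation_px Minimum initial distance between spots of
#'   the same channel.
#' @param margin_px Initial distance of spots from the image border.
#' @param seed Integer seed; the same seed reproduces the movie
#'   bit-identically.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(image_size = 160,
                              pixel_size = 0.125,
                              frame_interval = 2,
                              n_frames = 50,
                              n_spots = 20,
                              psf_sigma_px = 1.0,
                              amplitude = 150,
                              background = 100,
                              read_noise_sd = 3,
                              noise = TRUE,
                              diffusion_step_sd = 0.3,
                              n_pairs = 5,
                              tether_px = 3,
                              tether_jitter_sd = 0.3,
                              lifetime = c("exponential", "fixed"),
                              lifetime_mean_s = 6,
                              assoc_min_px = 1,
                              assoc_max_px = 5,
                              exclusion = TRUE,
                              min_separation_px = 16,
                              margin_px = 10,
                              seed = 1L) {
  lifetime <- match.arg(lifetime)
  stopifnot(image_size > 0, n_frames >= 1, n_spots >= 0,
            psf_sigma_px > 0, amplitude > 0, background >= 0,
            diffusion_step_sd >= 0, n_pairs >= 0, n_pairs <= n_spots,
            lifetime_mean_s > 0, assoc_min_px < assoc_max_px)
  if (n_pairs > 0 &&
      (tether_px <= assoc_min_px || tether_px >= assoc_max_px)) {
    stop("`tether_px` must lie strictly inside the association window",
         call. = FALSE)
  }
  cfg <- list(image_size = as.integer(image_size),
              pixel_size = pixel_size, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              n_spots = as.integer(n_spots),
              psf_sigma_px = psf_sigma_px, amplitude = amplitude,
              background = background, read_noise_sd = read_noise_sd,
              noise = isTRUE(noise),
              diffusion_step_sd = diffusion_step_sd,
              n_pairs = as.integer(n_pairs), tether_px = tether_px,
              tether_jitter_sd = tether_jitter_sd, lifetime = lifetime,
              lifetime_mean_s = lifetime_mean_s,
              assoc_min_px = assoc_min_px, assoc_max_px = assoc_max_px,
              exclusion = isTRUE(exclusion),
              min_separation_px = min_separation_px,
              margin_px = margin_px, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a two-channel movie with ground truth
#'
#' Renders the configured spot populations frame by frame and returns
#' both the calibrated movie and the ground truth needed to score any
#' downstream analysis: exact sub-pixel positions of every spot in
#' every frame and the pair table of planted association intervals.
#' Associated pairs share a common Brownian path during their
#' interval (partner placed at the tether distance with small radial
#' jitter, clamped to stay inside the association window); outside
#' the interval, and for all unpaired combinations when `exclusion`
#' is on, B spots are kept beyond the association window by radial
#' push-out. Borders reflect, so the spot count is conserved.
#'
#' @param config A [simulation_config()].
#' @return A list with `movie` (a [movie_stack()] with channels
#'   `"A"`, `"B"`) and `truth` (class `ground_truth`: `positions`
#'   data frame with `frame`, `channel`, `spot_id`, `x_px`, `y_px`;
#'   `pairs` data frame with `idA`, `idB`, `start_frame`,
#'   `end_frame`, `tether_px`; and the `config`).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_spots > 0 &&
      cfg$image_size / sqrt(cfg$n_spots) < 2 * cfg$psf_sigma_px) {
    warning("overcrowded field: expected spot spacing below 2 x PSF sigma")
  }
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)
  S <- cfg$image_size; TT <- cfg$n_frames; N <- cfg$n_spots
  lo <- cfg$margin_px; hi <- S - 1 - cfg$margin_px
  place <- function(n) {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < n) {
      p <- runif(2, lo, hi)
      if (nrow(pts) == 0L ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >=
            cfg$min_separation_px) {
        pts <- rbind(pts, p)
      }
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place spots at the requested separation",
             call. = FALSE)
      }
    }
    pts
  }
  ax <- place(N)  # channel A positions, frame 1
  bx <- if (N > 0) place(N) else matrix(NA_real_, 0, 2)

  # planted association intervals, fully inside [2, TT-1]
  pairs <- data.frame(idA = integer(), idB = integer(),
                      start_frame = integer(), end_frame = integer(),
                      tether_px = numeric())
  if (cfg$n_pairs > 0) {
    nfr <- vapply(seq_len(cfg$n_pairs), function(i) {
      L <- if (cfg$lifetime == "fixed") cfg$lifetime_mean_s else
        stats::rexp(1, 1 / cfg$lifetime_mean_s)
      max(1L, as.integer(round(L / cfg$frame_interval)) + 1L)
    }, integer(1))
    nfr <- pmin(nfr, TT - 2L)
    start <- vapply(nfr, function(k) {
      if (TT - 1L - k < 2L) 2L else sample(2:(TT - 1L - k + 1L), 1L)
    }, integer(1))
    pairs <- data.frame(idA = seq_len(cfg$n_pairs),
                        idB = seq_len(cfg$n_pairs),
                        start_frame = start,
                        end_frame = start + nfr - 1L,
                        tether_px = cfg$tether_px)
  }
  paired_b <- rep(NA_integer_, N)  # which A each B is tethered to
  if (cfg$n_pairs > 0) paired_b[pairs$idB] <- pairs$idA

  reflect_pos <- function(p) {
    # reflecting walls on [0, S-1]
    w <- S - 1
    p <- abs(p)
    p <- w - abs(w - p %% (2 * w))
    p
  }
  tether_angle <- runif(N, 0, 2 * pi)
  pos <- vector("list", TT)
  A <- ax; B <- bx
  for (t in seq_len(TT)) {
    if (t > 1L) {
      A <- reflect_pos(A + matrix(rnorm(2 * N, 0, cfg$diffusion_step_sd),
                                  N, 2))
      B <- reflect_pos(B + matrix(rnorm(2 * N, 0, cfg$diffusion_step_sd),
                                  N, 2))
    }
    # tethered pairs override B during their interval
    if (nrow(pairs)) {
      for (p in seq_len(nrow(pairs))) {
        if (t >= pairs$start_frame[p] && t <= pairs$end_frame[p]) {
          r <- cfg$tether_px + rnorm(1, 0, cfg$tether_jitter_sd)
          r <- min(max(r, cfg$assoc_min_px + 0.3),
                   cfg$assoc_max_px - 0.3)
          th <- tether_angle[pairs$idB[p]]
          B[pairs$idB[p], ] <- reflect_pos(
            A[pairs$idA[p], ] + r * c(cos(th), sin(th)))
        }
      }
    }
    # exclusion: push non-associated B out of every A's window
    if (cfg$exclusion && N > 0) {
      guard <- cfg$assoc_max_px + 1
      for (j in seq_len(N)) {
        tied_now <- !is.na(paired_b[j]) && nrow(pairs) &&
          t >= pairs$start_frame[match(j, pairs$idB)] &&
          t <= pairs$end_frame[match(j, pairs$idB)]
        if (tied_now) next
        tries <- 0L
        repeat {
          d <- sqrt((A[, 1] - B[j, 1])^2 + (A[, 2] - B[j, 2])^2)
          i <- which.min(d)
          if (d[i] > guard) break
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("cannot keep non-associated spots outside the ",
                 "association window; the field is too crowded for ",
                 "`exclusion = TRUE`", call. = FALSE)
          }
          dir <- B[j, ] - A[i, ]
          nrm <- sqrt(sum(dir^2))
          if (nrm < 1e-9) { dir <- c(1, 0); nrm <- 1 }
          B[j, ] <- reflect_pos(A[i, ] + dir / nrm * (guard + 0.5))
        }
      }
    }
    pos[[t]] <- rbind(
      data.frame(frame = t, channel = "A", spot_id = seq_len(N),
                 x_px = A[, 1], y_px = A[, 2]),
      data.frame(frame = t, channel = "B", spot_id = seq_len(N),
                 x_px = B[, 1], y_px = B[, 2]))
  }
  positions <- do.call(rbind, pos)
  rownames(positions) <- NULL

  pixels <- array(0, c(2L, TT, S, S))
  for (t in seq_len(TT)) {
    for (ch in 1:2) {
      sub <- positions[positions$frame == t &
                         positions$channel == c("A", "B")[ch], ]
      img <- render_spots(sub$x_px, sub$y_px, S,
                          cfg$psf_sigma_px, cfg$amplitude) +
        cfg$background
      if (cfg$noise) {
        img <- matrix(rpois(length(img), img), S, S) +
          matrix(rnorm(length(img), 0, cfg$read_noise_sd), S, S)
        img <- pmax(img, 0)
      }
      pixels[ch, t, , ] <- img
    }
  }
  movie <- movie_stack(pixels, pixel_size = cfg$pixel_size,
                       frame_interval = cfg$frame_interval,
                       channel_names = c("A", "B"))
  truth <- structure(list(positions = positions, pairs = pairs,
                          config = cfg),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

# Render 2D Gaussian spots (sub-pixel centres, 0-based coords) on an
# S x S zero image; each spot only touches a +-4 sigma window.
render_spots <- function(x, y, S, sigma, amplitude) {
  img <- matrix(0, S, S)
  half <- ceiling(4 * sigma)
  for (k in seq_along(x)) {
    cx <- x[k]; cy <- y[k]
    jx <- max(0, floor(cx) - half):min(S - 1, ceiling(cx) + half)
    jy <- max(0, floor(cy) - half):min(S - 1, ceiling(cy) + half)
    gx <- exp(-(jx - cx)^2 / (2 * sigma^2))
    gy <- exp(-(jy - cy)^2 / (2 * sigma^2))
    img[jy + 1, jx + 1] <- img[jy + 1, jx + 1] +
      amplitude * outer(gy, gx)
  }
  img
}

#' True analysis read-outs from simulator ground truth
#'
#' Computes, directly from the exact planted positions and bypassing
#' the images entirely, the values every stage of the image pipeline
#' is supposed to recover: per-frame spot counts, per-frame
#' nearest-neighbour association flags of every channel-A spot,
#' maximal association runs with durations, the per-frame associated
#' count, and (optionally) the colocalization fraction below a
#' distance limit. This is the oracle the image pipeline is scored
#' against.
#'
#' @param truth A `ground_truth` from [simulate_movie()].
#' @param limit_nm Optional colocalization distance limit (nm).
#' @return A list: `n_spots_per_frame` (data frame `frame`,
#'   `channel`, `n`), `assoc_per_frame` (data frame `frame`,
#'   `n_associated`), `profiles` (per A-spot association flags),
#'   `runs` (data frame `spot_id`, `start_frame`, `length_frames`,
#'   `duration_s`, `censored`), `mean_run_duration_s`,
#'   `coloc_fraction` (per-frame mean, if `limit_nm` given).
#' @export
emit_truth_tables <- function(truth, limit_nm = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  p <- truth$positions
  counts <- aggregate(spot_id ~ frame + channel, data = p, FUN = length)
  names(counts)[3] <- "n"
  A <- p[p$channel == "A", ]; B <- p[p$channel == "B", ]
  TT <- cfg$n_frames
  ids <- sort(unique(A$spot_id))
  flags <- matrix(FALSE, length(ids), TT,
                  dimnames = list(ids, NULL))
  dists <- matrix(NA_real_, length(ids), TT)
  for (t in seq_len(TT)) {
    At <- A[A$frame == t, ]; Bt <- B[B$frame == t, ]
    if (nrow(Bt) == 0L) next
    for (k in seq_along(ids)) {
      a <- At[At$spot_id == ids[k], ]
      if (nrow(a) == 0L) next
      d <- min(sqrt((a$x_px - Bt$x_px)^2 + (a$y_px - Bt$y_px)^2))
      dists[k, t] <- d
      flags[k, t] <- d >= cfg$assoc_min_px & d <= cfg$assoc_max_px
    }
  }
  runs <- do.call(rbind, lapply(seq_along(ids), function(k) {
    r <- extract_runs(seq_len(TT), flags[k, ], cfg$frame_interval)
    if (nrow(r) == 0L) return(NULL)
    cbind(spot_id = ids[k], r)
  }))
  if (is.null(runs)) {
    runs <- data.frame(spot_id = integer(), start_frame = integer(),
                       length_frames = integer(), duration_s = numeric(),
                       censored = logical())
  }
  rownames(runs) <- NULL
  out <- list(
    n_spots_per_frame = counts,
    assoc_per_frame = data.frame(frame = seq_len(TT),
                                 n_associated = colSums(flags)),
    profiles = list(spot_ids = ids, flags = flags, nn_dist_px = dists),
    runs = runs,
    mean_run_duration_s = if (nrow(runs)) mean(runs$duration_s)
                          else NA_real_)
  if (!is.null(limit_nm)) {
    lim_px <- limit_nm / (cfg$pixel_size * 1000)
    out$coloc_fraction <- mean(dists < lim_px, na.rm = TRUE)
  }
  out
}
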