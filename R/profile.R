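#' Per-frame association profile of one track
#'
#' For every frame of a channel-A track, measures the distance to the
#' nearest channel-B detection and calls the frame associated when
#' that distance lies within the closed window
#' `[assoc_min_px, assoc_max_px]`. Maximal runs of consecutive
#' associated frames are extracted; the duration of a run of n frames
#' is `(n - 1) * frame_interval` seconds (so a 3-frame run at 2 s
#' spacing lasts 4 s, and an isolated associated frame is a run of
#' duration 0). Frames with no channel-B detections are flagged
#' unknown and break runs. Runs touching the first or last frame of
#' the track are flagged `censored`: their true duration is cut short
#' by the observation window.
#'
#' @param track One track's rows from [link_tracks()] (single
#'   `track_id`).
#' @param detectionsB Data frame of channel-B detections with columns
#'   `frame`, `label`, `x_px`, `y_px`.
#' @param assoc_min_px,assoc_max_px Association window, pixels.
#' @param frame_interval Seconds per frame.
#' @return An object of class `association_profile`: list with
#'   `track_id`, `frames`, `nn_dist_px`, `associated` (logical, `NA`
#'   = unknown), `n_assoc_frames`, `runs` (data frame `start_frame`,
#'   `length_frames`, `duration_s`, `censored`), `n_runs`,
#'   `track_duration_s`.
#' @export
profile_association <- function(track, detectionsB,
                                assoc_min_px = 1, assoc_max_px = 5,
                                frame_interval = 2) {
  stopifnot(length(unique(track$track_id)) == 1L)
  track <- track[order(track$frame), ]
  frames <- track$frame
  nf <- length(frames)
  dist <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    b <- detectionsB[detectionsB$frame == frames[k], , drop = FALSE]
    if (nrow(b) > 0L) {
      dist[k] <- min(sqrt((track$x_px[k] - b$x_px)^2 +
                            (track$y_px[k] - b$y_px)^2))
    }
  }
  assoc <- ifelse(is.na(dist), NA,
                  dist >= assoc_min_px & dist <= assoc_max_px)
  runs <- extract_runs(frames, assoc, frame_interval)
  structure(
    list(track_id = track$track_id[1], frames = frames,
         nn_dist_px = dist, associated = assoc,
         n_assoc_frames = sum(assoc, na.rm = TRUE),
         runs = runs, n_runs = nrow(runs),
         track_duration_s = (nf - 1) * frame_interval),
    class = "association_profile"
  )
}

# Maximal runs of TRUE in `assoc` (NA breaks runs), as a data frame.
extract_runs <- function(frames, assoc, frame_interval) {
  flags <- !is.na(assoc) & assoc
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(
    start_frame = frames[starts[sel]],
    length_frames = r$lengths[sel],
    duration_s = (r$lengths[sel] - 1) * frame_interval,
    censored = starts[sel] == 1L | ends[sel] == length(flags)
  )
}

#' Association profiles for a set of tracks
#'
#' @param tracks Data frame from [link_tracks()] /
#'   [filter_tracks()].
#' @inheritParams profile_association
#' @return A list of [profile_association()] objects, one per track.
#' @export
profile_associations <- function(tracks, detectionsB,
                                 assoc_min_px = 1, assoc_max_px = 5,
                                 frame_interval = 2) {
  lapply(split(tracks, tracks$track_id), profile_association,
         detectionsB = detectionsB, assoc_min_px = assoc_min_px,
         assoc_max_px = assoc_max_px, frame_interval = frame_interval)
}

#' Summarize association dynamics over one condition
#'
#' Aggregates the association-run durations of a set of track
#' profiles. Because runs truncated by the start or end of a track
#' (censored) have an unknown true duration, summaries are reported
#' both over all runs and over complete (uncensored) runs only. The
#' unassociated read-out is the tracked duration of tracks that never
#' associate.
#'
#' @param profiles List from [profile_associations()].
#' @return A list: `n_tracks`, `n_tracks_with_association`,
#'   `n_runs`, `mean_run_duration_s`, `median_run_duration_s`,
#'   `mean_complete_run_duration_s`, `n_complete_runs`,
#'   `runs_per_track`, `mean_unassociated_track_duration_s`,
#'   `n_unassociated_tracks`. Empty input yields an empty summary
#'   with `n_tracks = 0`.
#' @export
summarize_dtc <- function(profiles) {
  if (length(profiles) == 0L) {
    return(list(n_tracks = 0L, n_tracks_with_association = 0L,
                n_runs = 0L, mean_run_duration_s = NA_real_,
                median_run_duration_s = NA_real_,
                mean_complete_run_duration_s = NA_real_,
                n_complete_runs = 0L, runs_per_track = NA_real_,
                mean_unassociated_track_duration_s = NA_real_,
                n_unassociated_tracks = 0L))
  }
  runs <- do.call(rbind, lapply(profiles, `[[`, "runs"))
  n_assoc_frames <- vapply(profiles, `[[`, numeric(1), "n_assoc_frames")
  track_dur <- vapply(profiles, `[[`, numeric(1), "track_duration_s")
  unassoc <- n_assoc_frames == 0
  complete <- runs$duration_s[!runs$censored]
  list(
    n_tracks = length(profiles),
    n_tracks_with_association = sum(!unassoc),
    n_runs = nrow(runs),
    mean_run_duration_s = if (nrow(runs)) mean(runs$duration_s)
                          else NA_real_,
    median_run_duration_s = if (nrow(runs)) median(runs$duration_s)
                            else NA_real_,
    mean_complete_run_duration_s = if (length(complete)) mean(complete)
                                   else NA_real_,
    n_complete_runs = length(complete),
    runs_per_track = nrow(runs) / length(profiles),
    mean_unassociated_track_duration_s =
      if (any(unassoc)) mean(track_dur[unassoc]) else NA_real_,
    n_unassociated_tracks = sum(unassoc)
  )
}

#' Run the full Detect, Track and Colocalize pipeline on a movie
#'
#' Preprocesses both channels (Gaussian blur then rolling-ball
#' background subtraction), detects dots with the constant threshold
#' and circularity filter, links the channel-A dots into tracks under
#' the maximum-displacement constraint, discards tracks shorter than
#' the minimum length, and scores per-track association to the
#' re-detected channel-B dots.
#'
#' @param movie A two-channel [movie_stack()].
#' @param config An [analysis_config()]; `config$threshold` must be
#'   set (or `"otsu"` to pool all preprocessed frames of both
#'   channels).
#' @param channelA,channelB Channel indices or names of the tracked
#'   (source) and reference channel.
#' @return A list with `detections`, `tracks`, `profiles`,
#'   `per_frame` (tidy per-track-frame table), `runs` (tidy run
#'   table), and `summary` ([summarize_dtc()] output).
#' @export
dtc_run <- function(movie, config, channelA = 1L, channelB = 2L) {
  stopifnot(inherits(movie, "movie_stack"),
            inherits(config, "analysis_config"))
  if (is.na(movie$frame_interval)) {
    stop("`movie` needs a frame_interval for tracking", call. = FALSE)
  }
  pp <- preprocess_movie(movie,
                         gaussian_radius_um = config$gaussian_radius_um,
                         rolling_ball_px = config$rolling_ball_px)
  thr <- config$threshold
  if (is.null(thr)) stop("config$threshold is not set", call. = FALSE)
  if (identical(thr, "otsu")) thr <- otsu_threshold(pp$pixels)
  det <- detect_dots(pp, thr, min_circularity = config$min_circularity)
  chn <- function(ch) if (is.character(ch)) ch else movie$channel_names[ch]
  detA <- det[det$channel == chn(channelA), , drop = FALSE]
  detB <- det[det$channel == chn(channelB), , drop = FALSE]
  tracks <- link_tracks(detA, max_disp_px = config$max_disp_px)
  tracks <- filter_tracks(tracks, config$min_track_frames)
  profiles <- profile_associations(
    tracks, detB, assoc_min_px = config$assoc_min_px,
    assoc_max_px = config$assoc_max_px,
    frame_interval = movie$frame_interval)
  per_frame <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(track_id = p$track_id, frame = p$frames,
               nn_dist_px = p$nn_dist_px, associated = p$associated)
  }))
  runs <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$runs) == 0L) return(NULL)
    cbind(track_id = p$track_id, p$runs)
  }))
  if (is.null(runs)) {
    runs <- data.frame(track_id = integer(), start_frame = integer(),
                       length_frames = integer(), duration_s = numeric(),
                       censored = logical())
  }
  rownames(per_frame) <- rownames(runs) <- NULL
  list(detections = det, tracks = tracks, profiles = profiles,
       per_frame = per_frame, runs = runs,
       summary = summarize_dtc(profiles), threshold = thr)
}
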