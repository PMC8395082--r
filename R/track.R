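#' Link per-frame detections into tracks
#'
#' Frame-to-frame nearest-neighbour linking under a maximum
#' displacement constraint. For each consecutive frame pair, candidate
#' links are all (track end, detection) pairs at distance
#' `<= max_disp_px`; the default `"greedy"` method assigns them
#' one-to-one in order of ascending distance (deterministic,
#' order-independent; ties broken by track id then detection label),
#' while `"optimal"` computes the exact assignment that maximizes the
#' number of links and, among those, minimizes the summed distance.
#' Unmatched detections start new tracks; a track ends as soon as no
#' candidate qualifies (no gap closing: frames within a track are
#' strictly consecutive).
#'
#' @param detections Data frame with columns `frame`, `label`, `x_px`,
#'   `y_px` for one channel (e.g. one channel of [detect_dots()]).
#' @param max_disp_px Maximum displacement per frame step, pixels.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A data frame with columns `track_id`, `frame`, `label`,
#'   `x_px`, `y_px`, ordered by track then frame.
#' @export
link_tracks <- function(detections, max_disp_px = 10,
                        method = c("greedy", "optimal")) {
  method <- match.arg(method)
  need <- c("frame", "label", "x_px", "y_px")
  stopifnot(all(need %in% names(detections)))
  det <- detections[order(detections$frame, detections$label), need]
  if (nrow(det) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(),
                      label = integer(), x_px = numeric(),
                      y_px = numeric()))
  }
  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)
  # active track state: id and last position/frame
  det1 <- by_frame[[as.character(frames[1])]]
  n0 <- nrow(det1)
  rows <- list(cbind(track_id = seq_len(n0), det1))
  active <- data.frame(track_id = seq_len(n0), x = det1$x_px,
                       y = det1$y_px, frame = frames[1])
  next_id <- n0 + 1L
  for (fi in seq_along(frames)[-1]) {
    f <- frames[fi]
    d2 <- by_frame[[as.character(f)]]
    cur <- active[active$frame == f - 1L, , drop = FALSE]
    assignment <- rep(NA_integer_, nrow(d2))  # row of cur per detection
    if (nrow(cur) > 0L && nrow(d2) > 0L) {
      dmat <- outer(cur$x, d2$x_px, "-")^2 + outer(cur$y, d2$y_px, "-")^2
      dmat <- sqrt(dmat)
      cand <- which(dmat <= max_disp_px, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        if (method == "greedy") {
          ord <- order(dmat[cand], cur$track_id[cand[, 1]],
                       d2$label[cand[, 2]])
          cand <- cand[ord, , drop = FALSE]
          used_t <- logical(nrow(cur)); used_d <- logical(nrow(d2))
          for (k in seq_len(nrow(cand))) {
            i <- cand[k, 1]; j <- cand[k, 2]
            if (!used_t[i] && !used_d[j]) {
              used_t[i] <- TRUE; used_d[j] <- TRUE
              assignment[j] <- i
            }
          }
        } else {
          assignment <- optimal_assignment(dmat, max_disp_px)
        }
      }
    }
    new_rows <- d2
    tid <- integer(nrow(d2))
    for (j in seq_len(nrow(d2))) {
      if (!is.na(assignment[j])) {
        tid[j] <- cur$track_id[assignment[j]]
      } else {
        tid[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    rows[[length(rows) + 1L]] <- cbind(track_id = tid, new_rows)
    active <- data.frame(track_id = tid, x = d2$x_px, y = d2$y_px,
                         frame = f)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

# Exact assignment: maximize the number of matched pairs with
# cost <= max_disp, then minimize total distance; branch-and-bound over
# track ends. Intended for the small per-frame instances of spot
# movies (exponential in the worst case).
optimal_assignment <- function(dmat, max_disp) {
  nT <- nrow(dmat); nD <- ncol(dmat)
  best <- list(n = -1L, cost = Inf, assign = rep(NA_integer_, nD))
  assign_d <- rep(NA_integer_, nD)  # track row per detection
  feas <- dmat <= max_disp
  max_possible <- function(i) sum(apply(
    feas[i:nT, , drop = FALSE], 1, any))
  rec <- function(i, n_matched, cost) {
    if (i > nT) {
      if (n_matched > best$n ||
          (n_matched == best$n && cost < best$cost)) {
        best <<- list(n = n_matched, cost = cost, assign = assign_d)
      }
      return(invisible())
    }
    # bound: even matching every remaining feasible track can't beat best
    remaining <- sum(vapply(i:nT, function(r) any(feas[r, ] &
                                                    is.na(assign_d)),
                            logical(1)))
    if (n_matched + remaining < best$n) return(invisible())
    # try matching track i to each free feasible detection
    for (j in seq_len(nD)) {
      if (is.na(assign_d[j]) && feas[i, j]) {
        assign_d[j] <<- i
        rec(i + 1L, n_matched + 1L, cost + dmat[i, j])
        assign_d[j] <<- NA_integer_
      }
    }
    # or leave track i unmatched
    rec(i + 1L, n_matched, cost)
  }
  rec(1L, 0L, 0)
  best$assign
}

#' Filter tracks by minimum length
#'
#' Keeps tracks spanning at least `min_track_frames` frames (boundary
#' inclusive). With a 2 s frame interval the default of 3 frames
#' corresponds to a minimum tracked span of 4 s.
#'
#' @param tracks Data frame from [link_tracks()].
#' @param min_track_frames Minimum number of frames; `>= 1`.
#' @return The retained subset.
#' @export
filter_tracks <- function(tracks, min_track_frames = 3) {
  if (min_track_frames < 1) {
    stop("`min_track_frames` must be >= 1", call. = FALSE)
  }
  len <- table(tracks$track_id)
  keep <- names(len)[len >= min_track_frames]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-step displacements of each track
#'
#' @param tracks Data frame from [link_tracks()].
#' @return Data frame `track_id`, `frame` (the later frame of the
#'   step), `disp_px`.
#' @export
track_displacements <- function(tracks) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L) return(NULL)
    data.frame(track_id = tr$track_id[-1], frame = tr$frame[-1],
               disp_px = sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      disp_px = numeric())
  }
  rownames(out) <- NULL
  out
}
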