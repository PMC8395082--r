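test_that("an unambiguous stepping spot forms one track", {
  xy <- cbind(seq(0, 45, by = 5), 10)
  tr <- link_tracks(path_detections(xy), max_disp_px = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  expect_equal(track_displacements(tr)$disp_px, rep(5, 9))
})

test_that("a jump beyond max displacement splits the track", {
  x <- c(0, 5, 10, 15, 26, 31, 36)  # 11 px jump between frames 4 and 5
  tr <- link_tracks(path_detections(cbind(x, 0)), max_disp_px = 10)
  expect_equal(length(unique(tr$track_id)), 2)
  lens <- as.numeric(table(tr$track_id))
  expect_setequal(lens, c(4, 3))
  # frames within each track are strictly consecutive
  for (tid in unique(tr$track_id)) {
    f <- sort(tr$frame[tr$track_id == tid])
    expect_equal(diff(f), rep(1, length(f) - 1))
  }
})

test_that("two passing spots: greedy equals the optimal assignment", {
  frames <- 0:20
  det <- rbind(
    data.frame(frame = frames + 1, label = 1L,
               x_px = frames * 2, y_px = 0),
    data.frame(frame = frames + 1, label = 2L,
               x_px = 40 - frames * 2, y_px = 8))
  g <- link_tracks(det, max_disp_px = 10, method = "greedy")
  o <- link_tracks(det, max_disp_px = 10, method = "optimal")
  expect_equal(length(unique(g$track_id)), 2)
  expect_identical(g, o)
  # each track stays on its own y-lane (no identity switch)
  for (tid in unique(g$track_id)) {
    expect_equal(length(unique(g$y_px[g$track_id == tid])), 1)
  }
})

test_that("greedy equals optimal whenever candidates are unique", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    base <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    # well-separated spots, small steps: unique candidates guaranteed
    det <- do.call(rbind, lapply(1:5, function(f) {
      data.frame(frame = f, label = seq_len(n),
                 x_px = base[, 1] + rnorm(n, 0, 1.5),
                 y_px = base[, 2] + rnorm(n, 0, 1.5))
    }))
    g <- link_tracks(det, max_disp_px = 10, method = "greedy")
    o <- link_tracks(det, max_disp_px = 10, method = "optimal")
    expect_identical(g, o)
  }
})

test_that("linking is injective frame to frame", {
  set.seed(72)
  det <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, label = 1:15,
               x_px = runif(15, 0, 60), y_px = runif(15, 0, 60))))
  tr <- link_tracks(det, max_disp_px = 10)
  per <- split(tr, tr$frame)
  for (p in per) expect_false(anyDuplicated(p$track_id) > 0)
  # every detection is carried into exactly one track row
  expect_equal(nrow(tr), nrow(det))
})

test_that("track filtering keeps boundary-inclusive lengths", {
  det <- rbind(
    path_detections(cbind(0:1 * 2, 0), frames = 1:2),
    path_detections(cbind(0:2 * 2, 100), frames = 1:3),
    path_detections(cbind(0:6 * 2, 200), frames = 1:7))
  tr <- link_tracks(det, max_disp_px = 10)
  expect_equal(sort(as.numeric(table(tr$track_id))), c(2, 3, 7))
  kept <- filter_tracks(tr, 3)
  expect_setequal(as.numeric(table(kept$track_id)), c(3, 7))
  expect_identical(filter_tracks(tr, 1), tr)
  expect_error(filter_tracks(tr, 0), ">= 1")
})

test_that("planted lengths 2..10 survive the 3-frame minimum exactly", {
  det <- do.call(rbind, lapply(2:10, function(L)
    path_detections(cbind(seq_len(L) * 3, L * 50), frames = seq_len(L))))
  tr <- filter_tracks(link_tracks(det, max_disp_px = 10), 3)
  expect_setequal(as.numeric(table(tr$track_id)), 3:10)
})

test_that("well-separated simulated spots are tracked without identity switches", {
  sim <- simulate_movie(simulation_config(
    image_size = 200, n_frames = 30, n_spots = 12, n_pairs = 0,
    noise = FALSE, diffusion_step_sd = 0.5, min_separation_px = 25,
    seed = 73))
  truth <- sim$truth$positions
  det <- truth[truth$channel == "A", c("frame", "spot_id", "x_px", "y_px")]
  names(det)[2] <- "label"
  tr <- link_tracks(det, max_disp_px = 10)
  expect_equal(length(unique(tr$track_id)), 12)
  # each recovered track carries a single true spot id (the label
  # column is passed through from the detections)
  tab <- table(tr$track_id, tr$label)
  expect_true(all(rowSums(tab > 0) == 1))
  # time reversal yields the same partition
  det_rev <- det; det_rev$frame <- max(det$frame) + 1 - det$frame
  tr_rev <- link_tracks(det_rev, max_disp_px = 10)
  expect_equal(length(unique(tr_rev$track_id)), 12)
  sig <- function(t) sort(vapply(split(paste(t$x_px, t$y_px), t$track_id),
                                 function(s) paste(sort(s), collapse = "|"),
                                 character(1)), method = "radix")
  expect_identical(unname(sig(tr)), unname(sig(tr_rev)))
})
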