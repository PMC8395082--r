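test_that("the same seed reproduces a movie bit-identically", {
  cfg <- simulation_config(image_size = 64, n_frames = 4, n_spots = 6,
                           n_pairs = 2, min_separation_px = 10, seed = 5)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movie$pixels, b$movie$pixels)
  expect_identical(a$truth$positions, b$truth$positions)
  cfg2 <- simulation_config(image_size = 64, n_frames = 4, n_spots = 6,
                            n_pairs = 2, min_separation_px = 10, seed = 6)
  expect_false(identical(simulate_movie(cfg2)$movie$pixels,
                         a$movie$pixels))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(runif(1))
  invisible(simulate_movie(simulation_config(
    image_size = 48, n_frames = 2, n_spots = 3, n_pairs = 0,
    min_separation_px = 8, seed = 5)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("noise-free static spots give identical frames", {
  sim <- simulate_movie(simulation_config(
    image_size = 96, n_frames = 5, n_spots = 8, n_pairs = 0,
    noise = FALSE, diffusion_step_sd = 0, min_separation_px = 12,
    seed = 7))
  for (t in 2:5) {
    expect_identical(sim$movie$pixels[1, t, , ], sim$movie$pixels[1, 1, , ])
    expect_identical(sim$movie$pixels[2, t, , ], sim$movie$pixels[2, 1, , ])
  }
})

test_that("Brownian steps have the prescribed mean squared displacement", {
  sd_step <- 2
  sim <- simulate_movie(simulation_config(
    image_size = 600, margin_px = 120, n_frames = 50, n_spots = 100,
    n_pairs = 0, noise = FALSE, diffusion_step_sd = sd_step,
    min_separation_px = 5, exclusion = FALSE, seed = 8))
  p <- sim$truth$positions
  p <- p[p$channel == "A", ]
  p <- p[order(p$spot_id, p$frame), ]
  msd <- tapply(seq_len(nrow(p)), p$spot_id, function(i) {
    mean(diff(p$x_px[i])^2 + diff(p$y_px[i])^2)
  })
  expect_equal(mean(msd), 2 * sd_step^2, tolerance = 0.1)
})

test_that("ground-truth pairs respect the association window in and out of their interval", {
  sim <- simulate_movie(simulation_config(
    image_size = 160, n_frames = 40, n_spots = 15, n_pairs = 5,
    seed = 9))
  cfg <- sim$truth$config
  p <- sim$truth$positions
  A <- p[p$channel == "A", ]; B <- p[p$channel == "B", ]
  for (k in seq_len(nrow(sim$truth$pairs))) {
    pr <- sim$truth$pairs[k, ]
    for (t in seq_len(cfg$n_frames)) {
      a <- A[A$spot_id == pr$idA & A$frame == t, ]
      b <- B[B$spot_id == pr$idB & B$frame == t, ]
      d <- sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2)
      if (t >= pr$start_frame && t <= pr$end_frame) {
        expect_gte(d, cfg$assoc_min_px)
        expect_lte(d, cfg$assoc_max_px)
      } else {
        expect_gt(d, cfg$assoc_max_px)
      }
    }
  }
})

test_that("truth tables invert the planted intervals exactly", {
  sim <- simulate_movie(simulation_config(
    image_size = 160, n_frames = 40, n_spots = 15, n_pairs = 4,
    lifetime = "fixed", lifetime_mean_s = 6, seed = 10))
  tt <- emit_truth_tables(sim$truth)
  # fixed 6 s at 2 s per frame -> 4-frame runs
  expect_equal(nrow(tt$runs), 4)
  expect_equal(tt$runs$length_frames, rep(4, 4))
  expect_equal(tt$runs$duration_s, rep(6, 4))
  expect_equal(tt$mean_run_duration_s, 6)
  ord <- order(tt$runs$spot_id)
  expect_equal(tt$runs$start_frame[ord], sim$truth$pairs$start_frame)
  # per-frame associated counts match interval membership
  expected <- vapply(seq_len(40), function(t)
    sum(sim$truth$pairs$start_frame <= t & sim$truth$pairs$end_frame >= t),
    numeric(1))
  expect_equal(tt$assoc_per_frame$n_associated, expected)
  # spot counts per frame and channel
  expect_true(all(tt$n_spots_per_frame$n == 15))
})

test_that("coincidental associations of random scatter follow the spatial-Poisson law", {
  n_sim <- 40; n_spots <- 30; S <- 200; margin <- 10
  hits <- 0L; total <- 0L
  for (s in seq_len(n_sim)) {
    sim <- simulate_movie(simulation_config(
      image_size = S, margin_px = margin, n_frames = 1,
      n_spots = n_spots, n_pairs = 0, noise = FALSE,
      min_separation_px = 2, exclusion = FALSE, seed = 1000 + s))
    tt <- emit_truth_tables(sim$truth)
    hits <- hits + sum(tt$assoc_per_frame$n_associated)
    total <- total + n_spots
  }
  p_hat <- hits / total
  side <- S - 1 - 2 * margin
  rho <- n_spots / side^2
  p_exp <- exp(-rho * pi * 1^2) * (1 - exp(-rho * pi * (5^2 - 1^2)))
  se <- sqrt(p_exp * (1 - p_exp) / total)
  # 99%+ band (plus slack for edge effects of the finite placement box)
  expect_lt(abs(p_hat - p_exp), 3.5 * se + 0.01)
})

test_that("overcrowding and invalid tethers are rejected or flagged", {
  expect_warning(simulate_movie(simulation_config(
    image_size = 12, n_frames = 1, n_spots = 60, n_pairs = 0,
    margin_px = 1, min_separation_px = 0.5, psf_sigma_px = 2,
    exclusion = FALSE, seed = 11)), "overcrowded")
  # with exclusion on, an infeasibly crowded field errors instead of
  # looping forever
  expect_error(suppressWarnings(simulate_movie(simulation_config(
    image_size = 12, n_frames = 1, n_spots = 60, n_pairs = 0,
    margin_px = 1, min_separation_px = 0.5, psf_sigma_px = 2,
    seed = 11))), "too crowded")
  expect_error(simulation_config(tether_px = 6), "tether_px")
  expect_error(simulation_config(tether_px = 0.5), "tether_px")
})
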