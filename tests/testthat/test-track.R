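det_df <- function(x, y, z = 0, class = "small", score = 1) {
  if (!length(x))
    return(data.frame(class = character(), x_px = numeric(),
                      y_px = numeric(), z_um = numeric(), score = numeric()))
  data.frame(class = class, x_px = x, y_px = y, z_um = z, score = score)
}

test_that("a slowly drifting particle yields one full-length track", {
  tr <- new_tracker(max_disp = 3)
  for (f in 1:20) tr <- link_frames(tr, det_df(10 + f, 50), f)
  df <- tracks_to_df(tr)
  expect_equal(length(unique(df$track_id)), 1)
  expect_equal(nrow(df), 20)
  expect_equal(df$frame, 1:20)
})

test_that("stationary well-separated particles keep separate identities", {
  tr <- new_tracker(max_disp = 5)
  for (f in 1:10)
    tr <- link_frames(tr, det_df(c(20, 120), c(20, 120),
                                 class = c("small", "big")), f)
  df <- tracks_to_df(tr)
  expect_equal(length(unique(df$track_id)), 2)
  expect_equal(as.vector(table(df$track_id)), c(10L, 10L))
})

test_that("global linking equals the per-frame brute-force assignment", {
  # two particles crossing within max_disp
  pos_a <- cbind(seq(10, 40, length.out = 7), 25)
  pos_b <- cbind(seq(40, 10, length.out = 7), 26)
  tr <- new_tracker(max_disp = 10, global = TRUE)
  last <- NULL
  for (f in 1:7) {
    dets <- det_df(c(pos_a[f, 1], pos_b[f, 1]), c(pos_a[f, 2], pos_b[f, 2]))
    if (!is.null(last)) {
      cost <- sqrt(outer(last$x, dets$x_px, "-")^2 +
                   outer(last$y, dets$y_px, "-")^2)
      bf <- brute_force_assignment(cost)
      tr2 <- link_frames(tr, dets, f)
      # the tracker's pairing must equal the brute-force optimum
      for (k in 1:2) {
        trk <- tr2$tracks[[k]]
        newest <- trk$points[nrow(trk$points), ]
        expect_equal(newest$x_px, dets$x_px[bf$assignment[k]])
      }
      tr <- tr2
    } else tr <- link_frames(tr, dets, f)
    df <- tracks_to_df(tr)
    last <- list(x = vapply(tr$tracks, function(t) t$last_x, 0),
                 y = vapply(tr$tracks, function(t) t$last_y, 0))
  }
  expect_equal(length(tr$tracks), 2)
})

test_that("each detection belongs to exactly one track", {
  tr <- new_tracker(max_disp = 30)
  set.seed(17)
  total <- 0
  for (f in 1:15) {
    n <- sample(1:4, 1)
    dets <- det_df(runif(n, 0, 200), runif(n, 0, 200))
    total <- total + n
    tr <- link_frames(tr, dets, f)
  }
  df <- tracks_to_df(tr)
  expect_equal(nrow(df), total)          # conservation
  expect_false(any(duplicated(df[, c("frame", "x_px", "y_px")])))
})

test_that("tracks lapse to lost after the miss budget", {
  tr <- new_tracker(max_disp = 5, max_misses = 2)
  tr <- link_frames(tr, det_df(10, 10), 1)
  for (f in 2:5) tr <- link_frames(tr, det_df(numeric(0), numeric(0)), f)
  expect_equal(tr$tracks[[1]]$state, "lost")
})

test_that("sub-half-gate motion never switches identities", {
  lib <- mini_library()
  grid <- lib$z_grid
  # synthetic truth trajectories: 3 particles, displacement < max_disp/2
  starts <- data.frame(class = c("small", "big", "small"),
                       x_px = c(60, 180, 60), y_px = c(60, 60, 190),
                       z_um = grid[c(2, 5, 7)])
  tr <- new_tracker(max_disp = 8)
  for (f in 1:12) {
    dets <- starts
    dets$x_px <- dets$x_px + f * 1.5
    dets$y_px <- dets$y_px + f * 1.0
    dets$score <- 1
    tr <- link_frames(tr, dets, f)
  }
  df <- tracks_to_df(tr)
  expect_equal(length(unique(df$track_id)), 3)
  # no identity switches: each track's class is constant and rows = frames
  for (id in unique(df$track_id)) {
    sub <- df[df$track_id == id, ]
    expect_equal(nrow(sub), 12)
    expect_equal(length(unique(sub$class)), 1)
  }
})

test_that("z trace residuals vanish for exact traces and expose bias", {
  prof <- stage_profile(c(-5, -1, 0, 1, 5, 10), frames_per_level = 5)
  expect_equal(prof$frame_start, c(1, 6, 11, 16, 21, 26))
  expect_equal(prof$frame_end, c(5, 10, 15, 20, 25, 30))
  track <- data.frame(frame = 1:30,
                      z_um = prof$offset_um[rep(1:6, each = 5)] + 2)
  res <- z_trace_vs_stage(track, prof, baseline_z_um = 2)
  expect_equal(res$residual_um, rep(0, 6))

  biased <- track; biased$z_um <- biased$z_um + 0.1
  res2 <- z_trace_vs_stage(biased, prof, baseline_z_um = 2)
  expect_equal(res2$residual_um, rep(0.1, 6), tolerance = 1e-12)

  # unknown baseline: estimated from the whole trace, bias absorbed
  res3 <- z_trace_vs_stage(biased, prof)
  expect_equal(res3$residual_um, rep(0, 6), tolerance = 1e-12)
})

test_that("noisy stage steps recover within the generative noise", {
  prof <- stage_profile(c(-2, -1, 0, 1, 2), frames_per_level = 50)
  zs <- with_seed(99, prof$offset_um[rep(1:5, each = 50)] +
                    rnorm(250, sd = 0.05))
  res <- z_trace_vs_stage(data.frame(frame = 1:250, z_um = zs), prof,
                          baseline_z_um = 0)
  expect_true(all(abs(res$residual_um) < 0.05))
})

test_that("missing levels are flagged absent", {
  prof <- stage_profile(c(0, 1, 2), frames_per_level = 5)
  track <- data.frame(frame = 1:10, z_um = c(rep(0, 5), rep(1, 5)))
  res <- z_trace_vs_stage(track, prof, baseline_z_um = 0)
  expect_true(res$absent[3])
  expect_true(is.na(res$median_z_um[3]))
})

test_that("MSD is zero for stationary and exactly quadratic for ballistic", {
  still <- data.frame(frame = 1:40, x_px = 5, y_px = 9)
  m <- msd(still, pixel_scale_um = 0.0233, frame_interval_s = 0.1)
  expect_true(all(m$msd_um2 == 0))

  v <- 0.7  # um per frame along x
  bal <- data.frame(frame = 1:40, x_px = (1:40) * v / 0.1, y_px = 0)
  m2 <- msd(bal, pixel_scale_um = 0.1, frame_interval_s = 0.05)
  expect_equal(m2$msd_um2, (v * m2$lag_frames)^2, tolerance = 1e-9)

  expect_error(msd(still[1, ], 0.1, 0.1), "short")
})

test_that("random-walk MSD slope matches the diffusion closed form", {
  s <- 0.4  # px per-axis step sd
  n <- 10000
  steps_x <- with_seed(123, rnorm(n, sd = s))
  steps_y <- with_seed(124, rnorm(n, sd = s))
  walk <- data.frame(frame = 1:n, x_px = cumsum(steps_x),
                     y_px = cumsum(steps_y))
  m <- msd(walk, pixel_scale_um = 1, frame_interval_s = 1)
  sub <- m[m$lag_frames <= 20, ]
  slope <- sum(sub$msd_um2 * sub$lag_frames) / sum(sub$lag_frames^2)
  expect_lt(abs(slope - 2 * s^2) / (2 * s^2), 0.1)  # MSD = 4 D tau, D = s^2/2
})

test_that("stage profiles round-trip through YAML", {
  dir <- withr::local_tempdir()
  lib <- mini_library()
  prof <- stage_profile(c(-2, -1, -0.5, 0, 0.5, 1), frames_per_level = 5)
  render_stepped_video(lib, prof, dir, seed = 7)
  back <- read_stage_profile(file.path(dir, "stage_profile.yaml"))
  expect_equal(as.data.frame(back), as.data.frame(prof))
  frames <- read_video_frames(file.path(dir, "frames.tiff"))
  expect_length(frames, 30)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 60)  # two beads per frame
})
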