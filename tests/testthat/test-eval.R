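test_that("assignment solver equals the permutation oracle", {
  for (i in 1:25) {
    n <- with_seed(i, sample(1:5, 1))
    m <- with_seed(i + 100, n + sample.int(6 - n, 1) - 1L)
    cost <- with_seed(i + 200, matrix(runif(n * m), n, m))
    a <- solve_assignment(cost)
    bf <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), bf$cost, tolerance = 1e-12)
  }
  # rectangular with more rows than columns leaves rows unmatched
  cost <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  a <- solve_assignment(cost)
  expect_equal(sum(is.na(a)), 1)
})

test_that("perfect predictions match at distance zero", {
  truths <- data.frame(class = c("small", "big"), x_px = c(10, 60),
                       y_px = c(20, 70), z_um = c(0, 1))
  m <- match_detections(truths, truths, gate = 5)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$dist_px, c(0, 0))
  expect_length(m$missed, 0)
  expect_length(m$spurious, 0)
})

test_that("a prediction beyond the gate is both missed and spurious", {
  truths <- data.frame(class = "small", x_px = 0, y_px = 0, z_um = 0)
  preds <- data.frame(class = "small", x_px = 10, y_px = 0, z_um = 0)
  m <- match_detections(preds, truths, gate = 5)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$missed, 1L)
  expect_equal(m$spurious, 1L)
})

test_that("crossing patterns resolve to the optimal assignment", {
  # 4 preds / 4 truths arranged so greedy nearest-neighbour would err
  truths <- data.frame(class = "small", x_px = c(0, 10, 20, 30),
                       y_px = 0, z_um = 0)
  preds <- data.frame(class = "small", x_px = c(9, 19, 29, 2),
                      y_px = 0.5, z_um = 0)
  m <- match_detections(preds, truths, gate = 50)
  cost <- sqrt(outer(preds$x_px, truths$x_px, "-")^2 +
               outer(preds$y_px, truths$y_px, "-")^2)
  bf <- brute_force_assignment(cost)
  expect_equal(sum(m$pairs$dist_px), bf$cost, tolerance = 1e-12)
  expect_equal(nrow(m$pairs), 4)
})

test_that("matching is invariant under prediction order", {
  grid <- make_z_grid(-2, 2, 0.5)
  for (i in 1:10) {
    truths <- with_seed(i, random_annotations(5, 400, mini_classes, grid))
    preds <- truths
    preds$x_px <- preds$x_px + with_seed(i + 50, rnorm(5, sd = 2))
    preds$y_px <- preds$y_px + with_seed(i + 60, rnorm(5, sd = 2))
    perm <- with_seed(i + 70, sample(5))
    m1 <- match_detections(preds, truths, gate = 20)
    m2 <- match_detections(preds[perm, ], truths, gate = 20)
    expect_equal(sort(m1$pairs$truth), sort(m2$pairs$truth))
    expect_equal(sum(m1$pairs$dist_px), sum(m2$pairs$dist_px),
                 tolerance = 1e-12)
    # accounting: every truth is matched or missed, exactly once
    expect_equal(sort(c(m1$pairs$truth, m1$missed)), 1:5)
  }
})

test_that("class mismatches are recorded but not blocking", {
  truths <- data.frame(class = "small", x_px = 5, y_px = 5, z_um = 0)
  preds <- data.frame(class = "big", x_px = 5.5, y_px = 5, z_um = 0.2)
  m <- match_detections(preds, truths, gate = 5)
  expect_equal(nrow(m$pairs), 1)
  expect_false(m$pairs$class_match)
})

test_that("error report converts a 3-4-5 offset to micrometres", {
  truths <- data.frame(class = "small", x_px = 100, y_px = 100, z_um = 1)
  preds <- data.frame(class = "small", x_px = 103, y_px = 104, z_um = 1)
  m <- match_detections(preds, truths, gate = 50)
  rep <- compute_errors(m, truths, pixel_scale_um = 0.0233)
  expect_equal(rep$horizontal_mae_um, 5 * 0.0233, tolerance = 1e-12)
  expect_equal(rep$vertical_mae_um, 0)
})

test_that("MAE equals the hand-summed mean over random pairs", {
  grid <- make_z_grid(-2, 2, 0.5)
  truths <- with_seed(5, random_annotations(10, 600, mini_classes, grid,
                                            min_sep = 100))
  dx <- with_seed(6, rnorm(10)); dy <- with_seed(7, rnorm(10))
  dz <- with_seed(8, rnorm(10, sd = 0.3))
  preds <- truths
  preds$x_px <- preds$x_px + dx; preds$y_px <- preds$y_px + dy
  preds$z_um <- preds$z_um + dz
  m <- match_detections(preds, truths, gate = 20)
  rep <- compute_errors(m, truths, 0.0233, z_min = -2, z_max = 2)
  expect_equal(rep$horizontal_mae_um, mean(sqrt(dx^2 + dy^2)) * 0.0233,
               tolerance = 1e-9)
  expect_equal(rep$vertical_mae_um, mean(abs(dz)), tolerance = 1e-9)
  # overall MAE is the match-count-weighted mean of per-class MAEs
  pc <- rep$per_class
  expect_equal(sum(pc$n * pc$horizontal_mae_um) / sum(pc$n),
               rep$horizontal_mae_um, tolerance = 1e-12)
  expect_equal(sum(pc$n), rep$n_matched)
})

test_that("empty matchings are flagged undefined, not zero", {
  m <- match_detections(data.frame(class = character(), x_px = numeric(),
                                   y_px = numeric(), z_um = numeric()),
                        data.frame(class = "small", x_px = 1, y_px = 1,
                                   z_um = 0), gate = 5)
  rep <- compute_errors(m, data.frame(class = "small", x_px = 1, y_px = 1,
                                      z_um = 0), 0.0233)
  expect_true(rep$undefined)
  expect_true(is.na(rep$horizontal_mae_um))
  expect_equal(rep$n_missed, 1)
})
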