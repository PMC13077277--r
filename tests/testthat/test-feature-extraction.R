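test_that("pixel scale is the direct ratio with guarded inputs", {
  expect_equal(pixel_scale(1, 200), 0.005)
  expect_equal(pixel_scale(1, 1), 1)
  expect_error(pixel_scale(1, 0), class = "gait_validation_error")
})

test_that("frame distances are scaled Euclidean lengths", {
  nf <- 1L
  xs <- matrix(0, nf, 33); ys <- matrix(0, nf, 33)
  # left_shoulder at (0,0), right_shoulder at (3,4)
  i_rs <- 12 + 1
  xs[, i_rs] <- 3; ys[, i_rs] <- 4
  s <- seq_from_coords(xs, ys)
  d <- frame_distances(s, meters_per_pixel = 0.01)
  expect_equal(d$d_left_shoulder_right_shoulder, 0.05)
  expect_equal(d$d_left_hip_right_hip, 0)          # coincident pair
  # scale covariance: double pixels, halve scale -> unchanged
  s2 <- seq_from_coords(xs * 2, ys * 2)
  d2 <- frame_distances(s2, meters_per_pixel = 0.005)
  expect_equal(as.numeric(d2[1, -1]), as.numeric(d[1, -1]))
})

test_that("frame angles hit the textbook cases", {
  xs <- matrix(0, 1, 33); ys <- matrix(0, 1, 33)
  # left_hip (23) at origin vertex, left_shoulder (11) at (1,0),
  # left_knee (25) at (0,1) -> right angle at the left hip
  xs[, 11 + 1] <- 1; ys[, 11 + 1] <- 0
  xs[, 25 + 1] <- 0; ys[, 25 + 1] <- 1
  xs[, 23 + 1] <- 0; ys[, 23 + 1] <- 0
  trip <- default_angle_triplets()
  a <- frame_angles(seq_from_coords(xs, ys), trip)
  expect_equal(a$ang_left_hip, pi / 2)
  # collinear with vertex between -> straight angle
  xs2 <- xs; ys2 <- ys
  xs2[, 11 + 1] <- -2; ys2[, 11 + 1] <- 0
  xs2[, 25 + 1] <- 3;  ys2[, 25 + 1] <- 0
  a2 <- frame_angles(seq_from_coords(xs2, ys2), trip)
  expect_equal(a2$ang_left_hip, pi)
})

test_that("angles are invariant under similarity transforms of the frame", {
  set.seed(77)
  for (i in 1:100) {
    xs <- matrix(runif(33, -5, 5), 1); ys <- matrix(runif(33, -5, 5), 1)
    a0 <- as.numeric(frame_angles(seq_from_coords(xs, ys))[1, -1])
    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.1, 10)
    tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    xr <- sc * (cos(th) * xs - sin(th) * ys) + tx
    yr <- sc * (sin(th) * xs + cos(th) * ys) + ty
    a1 <- as.numeric(frame_angles(seq_from_coords(xr, yr))[1, -1])
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("moment summaries use population formulas and the constant rule", {
  expect_equal(moment_summary(c(2, 2, 2))[1:4],
               list(mean = 2, sd = 0, skew = 0, kurt = 0))
  expect_true(moment_summary(c(2, 2, 2))$degenerate)
  m <- moment_summary(c(0, 1))
  expect_equal(unlist(m[1:4]), c(mean = 0.5, sd = 0.5, skew = 0, kurt = -2))
  set.seed(5)
  z <- rnorm(1e5)
  mz <- moment_summary(z)
  expect_lt(abs(mz$skew), 3 * sqrt(6 / 1e5))
  expect_lt(abs(mz$kurt), 3 * sqrt(24 / 1e5))
})

test_that("moment summaries match the two-pass oracle on random series", {
  set.seed(31)
  for (i in 1:1000) {
    x <- rnorm(sample(2:60, 1), sd = runif(1, 0.1, 10))
    m <- moment_summary(x)
    expect_equal(unlist(m[1:4]), oracle_moments(x), tolerance = 1e-10)
  }
})

test_that("feature vectors carry exactly 109 named values in frozen order", {
  w <- fixture_walk(seed = 12)
  seg <- extract_second_cycle(w)
  fv <- extract_features(w, seg, meters_per_pixel = 0.005)
  expect_identical(ncol(fv), 109L)
  expect_identical(names(fv), feature_names())
  expect_false(anyNA(fv))
  expect_equal(fv$cycle_n_frames, as.double(seg$n_frames))
  # failed segment refused
  g <- generate_garbage(120, rng_seed = 3)
  expect_error(extract_features(g, extract_second_cycle(g)),
               class = "gait_segment_error")
})

test_that("a frozen walker yields zero spread in every summarised series", {
  xs <- matrix(runif(33, 0, 100), 1)[rep(1, 30), ]
  ys <- matrix(runif(33, 0, 100), 1)[rep(1, 30), ]
  s <- seq_from_coords(xs, ys)
  fv <- extract_features(s, manual_segment(0L, 30L), meters_per_pixel = 0.01)
  spread <- dplyr::select(fv, dplyr::matches("_(sd|skew|kurt)$"))
  expect_true(all(as.numeric(spread[1, ]) == 0))
})

test_that("zoom with compensating scale leaves the feature vector unchanged", {
  w <- fixture_walk(seed = 44)
  seg <- extract_second_cycle(w)
  fv1 <- extract_features(w, seg, meters_per_pixel = 0.005)
  z <- tibble::as_tibble(w)
  z$x <- z$x * 2; z$y <- z$y * 2
  wz <- pose_sequence(z, frame_rate_hz = frame_rate(w))
  segz <- extract_second_cycle(wz)
  expect_identical(segz$minima_indices, seg$minima_indices)
  fv2 <- extract_features(wz, segz, meters_per_pixel = 0.0025)
  expect_equal(as.numeric(fv2[1, ]), as.numeric(fv1[1, ]), tolerance = 1e-9)
})

test_that("reference-length rescaling touches distances only", {
  w <- fixture_walk(seed = 13)
  seg <- extract_second_cycle(w)
  f1 <- extract_features(w, seg, meters_per_pixel = 0.005)
  f3 <- extract_features(w, seg, meters_per_pixel = 0.015)
  dist_cols <- grep("^d_.*_(mean|sd)$", names(f1), value = TRUE)
  ang_cols <- grep("^ang_", names(f1), value = TRUE)
  expect_equal(as.numeric(f3[1, dist_cols]), 3 * as.numeric(f1[1, dist_cols]))
  expect_equal(as.numeric(f3[1, ang_cols]), as.numeric(f1[1, ang_cols]))
  expect_equal(f3$cycle_n_frames, f1$cycle_n_frames)
})

test_that("pair and triplet sets are validated against the landmark enum", {
  bad_pairs <- default_distance_pairs()[-1, ]
  expect_error(validate_pair_set(bad_pairs), class = "gait_config_error")
  p <- default_distance_pairs(); p$a[2] <- "left_hib"
  expect_error(validate_pair_set(p), class = "gait_validation_error")
  t <- default_angle_triplets(); t$vertex[1] <- t$a[1]
  expect_error(validate_triplet_set(t), class = "gait_config_error")
})
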