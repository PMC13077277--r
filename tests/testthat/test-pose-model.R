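test_that("pose sequences round-trip through both file schemas exactly", {
  w <- fixture_walk(seed = 3)
  for (schema in c("csv_long", "jsonl_frames")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_pose_sequence(w, path, schema)
    back <- read_pose_sequence(path, schema, frame_rate_hz = frame_rate(w),
                               coordinate_space = "pixel")
    expect_equal(back$x, w$x, tolerance = 0)
    expect_equal(back$y, w$y, tolerance = 0)
    expect_equal(back$visibility, w$visibility, tolerance = 0)
    expect_identical(back$frame, w$frame)
    expect_identical(back$landmark, w$landmark)
    # determinism: a second write is byte-identical
    path2 <- withr::local_tempfile(fileext = ".txt")
    write_pose_sequence(w, path2, schema)
    expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
  }
})

test_that("single-frame csv_long input reconstructs the frame it encodes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,landmark,x,y,visibility",
               sprintf("0,%d,0.5,0.5,1", 0:32)), path)
  s <- read_pose_sequence(path, "csv_long", coordinate_space = "normalized",
                          image_width_px = 100, image_height_px = 100)
  expect_equal(n_frames(s), 1L)
  expect_true(all(s$x == 0.5) && all(s$y == 0.5))
})

test_that("frames with the wrong landmark count are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,landmark,x,y,visibility",
               sprintf("0,%d,0.5,0.5,1", 0:31)), path)   # 32 landmarks only
  expect_error(read_pose_sequence(path, "csv_long"), class = "gait_schema_error")
  expect_error(pose_sequence(tibble::tibble(frame = 0, landmark = 0,
                                            x = 1, y = 1)),
               class = "gait_schema_error")
  expect_error(pose_sequence(tibble::tibble(frame = integer(),
                                            landmark = integer(),
                                            x = numeric(), y = numeric())),
               class = "gait_validation_error")
})

test_that("pixel-space conversion scales, is idempotent, and demands dimensions", {
  nf <- 2L
  df <- tibble::tibble(frame = rep(0:(nf - 1L), each = 33L),
                       landmark = rep(0:32, nf), x = 0.5, y = 0.5,
                       visibility = 1)
  s <- pose_sequence(df, coordinate_space = "normalized",
                     image_width_px = 1280, image_height_px = 720)
  px <- to_pixel_space(s)
  expect_equal(unique(px$x), 640)
  expect_equal(unique(px$y), 360)
  expect_identical(to_pixel_space(px), px)    # idempotent
  expect_equal(n_frames(px), n_frames(s))     # landmark/frame conservation
  s_nodim <- pose_sequence(df, coordinate_space = "normalized")
  expect_error(to_pixel_space(s_nodim), class = "gait_config_error")
})

test_that("normalized coordinates outside [0,1] are clipped with a warning", {
  df <- tibble::tibble(frame = rep(0L, 33L), landmark = 0:32,
                       x = c(1.2, rep(0.5, 32)), y = 0.5, visibility = 1)
  expect_warning(s <- pose_sequence(df, coordinate_space = "normalized"),
                 "clipped")
  expect_equal(max(s$x), 1)
})

test_that("recording metadata derives and checks the age-group rule", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recording_id,sex,age_years,bmi,site,reference_length_m,reference_length_px",
               "r1,female,64.9,22,thailand,1,200",
               "r2,male,65,27,india,0.75,150"), path)
  meta <- read_recording_meta(path)
  expect_identical(meta$age_group, c("under65", "over65eq"))
  bad <- meta
  bad$age_group <- c("over65eq", "over65eq")
  expect_error(validate_recording_meta(bad), class = "gait_validation_error")
  bad2 <- meta; bad2$sex[1] <- "other"
  expect_error(validate_recording_meta(bad2), class = "gait_validation_error")
})
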