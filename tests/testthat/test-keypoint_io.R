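test_that("joint catalog matches the depth/rgb correspondence table", {
  cat <- joint_catalog()
  expect_equal(nrow(cat), 12)
  expect_false(anyDuplicated(cat$joint) > 0)
  expect_false(anyDuplicated(cat$depth_index) > 0)
  expect_false(anyDuplicated(cat$rgb_index) > 0)
  expect_equal(cat$depth_index[cat$joint == "Left Shoulder"], 4)
  expect_equal(cat$rgb_index[cat$joint == "Left Shoulder"], 11)
  expect_equal(cat$depth_index[cat$joint == "Right Ankle"], 18)
  expect_equal(cat$rgb_index[cat$joint == "Right Ankle"], 28)
  expect_equal(cat$depth_index[cat$joint == "Left Knee"], 13)
  expect_equal(cat$rgb_index[cat$joint == "Right Hip"], 24)
})

test_that("harmonize_joints relabels catalog indices and drops the rest", {
  p <- c(0.1, 0.2, 0.3)
  out <- harmonize_joints(matrix(p, 1, 3, dimnames = list("4", NULL)), "depth")
  expect_equal(rownames(out), "Left Shoulder")
  expect_equal(unname(out[1, ]), p)
  out <- harmonize_joints(matrix(p, 1, 3, dimnames = list("28", NULL)), "rgb")
  expect_equal(rownames(out), "Right Ankle")
  # index 0 is the rgb scheme's nose: not a limb joint, dropped
  out <- harmonize_joints(matrix(p, 1, 3, dimnames = list("0", NULL)), "rgb")
  expect_equal(nrow(out), 0)
  expect_error(harmonize_joints(matrix(p, 1, 3), "thermal"), "arg")
})

test_that("harmonized depth and rgb streams share the canonical key set", {
  cat <- joint_catalog()
  coords <- matrix(seq_len(36), 12, 3)
  depth_raw <- coords
  rownames(depth_raw) <- as.character(cat$depth_index)
  rgb_raw <- coords
  rownames(rgb_raw) <- as.character(cat$rgb_index)
  hd <- harmonize_joints(depth_raw, "depth")
  hr <- harmonize_joints(rgb_raw, "rgb")
  expect_identical(rownames(hd), rownames(hr))
  expect_identical(sort(rownames(hd)), sort(cat$joint))
})

test_that("keypoint CSV round trip is lossless and byte-stable", {
  seq <- toy_sequence(n = 3, seed = 42)
  seq$valid[2, 5] <- FALSE
  seq$coords[2, 5, ] <- NA_real_
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(seq, f1)
  back <- read_keypoint_csv(f1)
  expect_equal(back$coords, seq$coords)
  expect_identical(back$valid, seq$valid)
  expect_equal(back$time, seq$time)
  expect_identical(back$frames, seq$frames)
  expect_equal(back$rate, seq$rate)
  expect_identical(back$source, seq$source)
  expect_identical(back$unit, seq$unit)
  write_keypoint_csv(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a 1-frame sequence serializes to 12 data rows plus header", {
  seq <- toy_sequence(n = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(seq, f)
  lines <- readLines(f)
  data_lines <- grep("^[^#]", lines, value = TRUE)
  expect_length(data_lines, 13)  # header + 12 joints
  expect_equal(data_lines[1], "frame,time_s,joint,x,y,z,valid")
})

test_that("malformed keypoint CSVs are rejected with descriptive errors", {
  seq <- toy_sequence(n = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(seq, f)
  lines <- readLines(f)

  # timestamp going backwards
  bad <- sub("^1,[0-9.eE+-]+,", "1,-0.01,", lines)
  writeLines(bad, f)
  expect_error(read_keypoint_csv(f), "non-monotone timestamps")

  # drop one joint from frame 1 -> error names the joint
  writeLines(lines[!grepl("^1,.*Right Ankle", lines)], f)
  expect_error(read_keypoint_csv(f), "Right Ankle")

  # duplicate (frame, joint) row
  dup_row <- grep("^0,.*Left Knee", lines, value = TRUE)
  writeLines(c(lines, dup_row), f)
  expect_error(read_keypoint_csv(f), "duplicate \\(frame, joint\\)")

  # unknown joint label
  writeLines(sub("Left Knee", "Left Patella", lines), f)
  expect_error(read_keypoint_csv(f), "unknown joint label 'Left Patella'")

  expect_error(read_keypoint_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("empty sequences are rejected at construction and serialization", {
  expect_error(keypoint_sequence(array(0, c(0, 12, 3)), numeric(0),
                                 joint_catalog()$joint),
               "at least one frame")
})

test_that("resample_to_rate picks nearest frames on the target grid", {
  cat <- joint_catalog()
  n <- 10
  coords <- array(rep(seq_len(n), 12 * 3), c(n, 12, 3))  # frame index encoded
  seq <- keypoint_sequence(coords, (seq_len(n) - 1) / 100, cat$joint,
                           rate = 100, source = "reference")
  out <- resample_to_rate(seq, 30)
  # hand-derived nearest frames for grid {0, 1/30, 2/30}: sources 0, 3, 7
  expect_equal(n_frames(out), 3)
  expect_equal(out$coords[, 1, 1], c(1, 4, 8))  # 1-based rows of sources 0,3,7
  expect_equal(out$time, c(0, 1, 2) / 30)
  expect_equal(out$rate, 30)
})

test_that("resampling at the native rate is the identity on frame content", {
  seq <- toy_sequence(n = 12, rate = 30)
  out <- resample_to_rate(seq, 30)
  expect_equal(out$coords, seq$coords)
  expect_equal(out$time, seq$time, tolerance = 1e-12)
})

test_that("resample_to_rate is idempotent and refuses upsampling", {
  seq <- toy_sequence(n = 50, rate = 100)
  once <- resample_to_rate(seq, 30)
  twice <- resample_to_rate(once, 30)
  expect_equal(twice$coords, once$coords)
  expect_equal(twice$time, once$time)
  expect_error(resample_to_rate(seq, 200), "upsampling")
  expect_error(resample_to_rate(seq, -1), "positive")
})
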