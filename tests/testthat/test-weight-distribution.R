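test_that("segmentation orders feet by column centroid and recovers the generator's masks", {
  # two blobs centred at columns 10 and 34: the column-10 blob is the left foot
  m <- matrix(0, 20, 44)
  m[8:12, 8:12] <- 1
  m[8:12, 32:36] <- 2
  reg <- segment_feet(m)
  expect_true(all(which(colSums(reg$left_mask) > 0) %in% 8:12))
  expect_true(all(which(colSums(reg$right_mask) > 0) %in% 32:36))

  rec <- generate_recording("S1", "RES",
                            effect = condition_effect(noise_sd = 0.05),
                            n_frames = 4, seed = 9)
  truth <- attr(rec, "truth")
  reg <- segment_feet(mean_frame(rec))
  expect_identical(unname(reg$left_mask), unname(truth$left_mask))
  expect_identical(unname(reg$right_mask), unname(truth$right_mask))
  expect_identical(reg$ap_boundary_row_left, truth$ap_boundary_row_left)
  expect_identical(reg$ap_boundary_row_right, truth$ap_boundary_row_right)
})

test_that("degenerate frames raise segmentation errors", {
  single <- matrix(0, 20, 20)
  single[5:15, 12:15] <- 1  # one blob, entirely right of the midline
  expect_error(segment_feet(single), "segmentation error")
  expect_error(segment_feet(matrix(0, 5, 5)), "no load")
})

test_that("uniform symmetric load gives a 50/50 split everywhere", {
  m <- matrix(0, 20, 20)
  m[5:14, 3:8] <- 1
  m[5:14, 13:18] <- 1
  rec <- new_recording(array(m, c(20, 20, 3)), "S", "RES")
  d <- compute_distribution(rec)
  expect_equal(d$left_pct, 50)
  expect_equal(d$ant_left_pct, 50)
  expect_equal(d$ant_right_pct, 50)
})

test_that("an all-right anterior load is an extreme but valid distribution", {
  m <- matrix(0, 20, 20)
  left <- matrix(FALSE, 20, 20); left[5:14, 3:8] <- TRUE
  right <- matrix(FALSE, 20, 20); right[5:14, 13:18] <- TRUE
  m[5:9, 13:18] <- 1  # all load on the right foot's anterior half
  rec <- new_recording(array(m, c(20, 20, 1)), "S", "CL")
  reg <- foot_regions(left, right, 9, 9)
  d <- compute_distribution(rec, reg)
  expect_equal(d$left_pct, 0)
  expect_equal(d$ant_right_pct, 100)
  expect_true(is.na(d$ant_left_pct))
})

test_that("indices follow the 50-minus-percentage definition and sign rules", {
  d <- structure(list(left_pct = 50, right_pct = 50,
                      ant_left_pct = 50, post_left_pct = 50,
                      ant_right_pct = 50, post_right_pct = 50),
                 class = "weight_distribution")
  expect_equal(postural_indices(d)$olwd, 0)

  d$left_pct <- 46
  expect_equal(postural_indices(d)$olwd, 4)   # rightward = positive

  d$post_left_pct <- 60
  expect_equal(postural_indices(d)$apwd_left, -10)  # posterior = negative
})

test_that("mirroring a recording negates OLWD and swaps the per-foot APWDs", {
  for (seed in 1:5) {
    set.seed(seed)
    rec <- generate_recording("S", "CL",
      baseline = list(left_pct = runif(1, 40, 60),
                      post_left_pct = runif(1, 40, 60),
                      post_right_pct = runif(1, 40, 60)),
      effect = condition_effect(lateral_shift_pp = runif(1, -5, 5),
                                noise_sd = 0.1),
      n_frames = 3, shape = sim_shape, seed = seed)
    a <- postural_indices(rec)
    b <- postural_indices(mirror_recording(rec))
    expect_equal(b$olwd, -a$olwd, tolerance = 1e-9)
    expect_equal(b$apwd_left, a$apwd_right, tolerance = 1e-9)
    expect_equal(b$apwd_right, a$apwd_left, tolerance = 1e-9)
  }
})

test_that("indices are invariant to rescaling and to frame order", {
  rec <- generate_recording("S", "CLR",
                            effect = condition_effect(lateral_shift_pp = -2,
                                                      noise_sd = 0.2),
                            n_frames = 6, shape = sim_shape, seed = 4)
  a <- postural_indices(rec)

  scaled <- rec
  scaled$frames <- rec$frames * 37.5
  s <- postural_indices(scaled)
  expect_equal(s$olwd, a$olwd, tolerance = 1e-9)
  expect_equal(s$apwd_left, a$apwd_left, tolerance = 1e-9)

  permuted <- rec
  permuted$frames <- rec$frames[, , c(4, 1, 6, 2, 5, 3)]
  p <- postural_indices(permuted)
  expect_equal(p$olwd, a$olwd, tolerance = 1e-9)
  expect_equal(p$apwd_right, a$apwd_right, tolerance = 1e-9)
})

test_that("zero-load recordings and shape mismatches are errors", {
  rec <- new_recording(array(0, c(6, 6, 1)), "S", "RES")
  expect_error(compute_distribution(rec), "no load")
  good <- generate_recording("S", "RES", n_frames = 1, shape = sim_shape)
  reg_other <- segment_feet(mean_frame(
    generate_recording("S", "RES", n_frames = 1, shape = c(52, 44))))
  expect_error(compute_distribution(good, reg_other), "different grid shape")
})
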