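test_that("noiseless generation hits its load-fraction targets exactly", {
  # balanced baseline, no effect: perfectly symmetric indices
  r0 <- generate_recording("S1", "RES", n_frames = 3)
  idx0 <- postural_indices(r0)
  expect_identical(idx0$olwd, 0)
  expect_identical(idx0$apwd_left, 0)
  expect_identical(idx0$apwd_right, 0)

  # +4 pp rightward shift: measured left share is 46, OLWD +4
  r4 <- generate_recording("S1", "CL",
                           effect = condition_effect(lateral_shift_pp = 4),
                           n_frames = 3)
  d4 <- compute_distribution(r4)
  expect_equal(d4$left_pct, 46, tolerance = 1e-12)
  expect_equal(postural_indices(d4)$olwd, 4, tolerance = 1e-12)

  # AP shifts land on the per-foot indices, not the lateral one
  rap <- generate_recording("S1", "CLL",
                            effect = condition_effect(ap_shift_pp_left = 3,
                                                      ap_shift_pp_right = -2),
                            n_frames = 2)
  iap <- postural_indices(rap)
  expect_equal(iap$olwd, 0, tolerance = 1e-12)
  expect_equal(iap$apwd_left, 3, tolerance = 1e-12)
  expect_equal(iap$apwd_right, -2, tolerance = 1e-12)
})

test_that("effects that push a fraction outside [0, 100] are rejected", {
  expect_error(
    generate_recording("S1", "CL", baseline = list(left_pct = 2,
                                                   post_left_pct = 50,
                                                   post_right_pct = 50),
                       effect = condition_effect(lateral_shift_pp = 5),
                       n_frames = 1),
    "outside \\[0, 100\\]")
})

test_that("generation is seed-deterministic", {
  eff <- condition_effect(lateral_shift_pp = 1, noise_sd = 0.2)
  a <- generate_recording("S1", "CL", effect = eff, n_frames = 4, seed = 42)
  b <- generate_recording("S1", "CL", effect = eff, n_frames = 4, seed = 42)
  c <- generate_recording("S1", "CL", effect = eff, n_frames = 4, seed = 43)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))

  ch1 <- generate_cohort(2, n_frames = 2, shape = sim_shape, seed = 7)
  ch2 <- generate_cohort(2, n_frames = 2, shape = sim_shape, seed = 7)
  expect_identical(lapply(ch1, `[[`, "frames"), lapply(ch2, `[[`, "frames"))
})

test_that("without noise the total load is conserved across frames", {
  r <- generate_recording("S1", "CLR",
                          effect = condition_effect(lateral_shift_pp = -3),
                          n_frames = 6, total_load = 700)
  loads <- apply(r$frames, 3, sum)
  expect_equal(loads, rep(700, 6), tolerance = 1e-9)
})

test_that("the generated map has two disjoint foot regions", {
  r <- generate_recording("S1", "RES", n_frames = 1)
  truth <- attr(r, "truth")
  expect_false(any(truth$left_mask & truth$right_mask))
  # a fully empty column band separates the feet
  m <- mean_frame(r)
  occupied_cols <- which(colSums(m) > 0)
  gap <- setdiff(seq(min(occupied_cols), max(occupied_cols)), occupied_cols)
  expect_gt(length(gap), 0)
})

test_that("cohort structure matches the four-condition design", {
  ch <- generate_cohort(1, n_frames = 1, shape = sim_shape, seed = 5)
  expect_length(ch, 4L)
  expect_setequal(vapply(ch, `[[`, "", "condition"),
                  c("RES", "CL", "CLR", "CLL"))

  ch3 <- generate_cohort(3, n_frames = 1, shape = sim_shape, seed = 5)
  expect_length(ch3, 12L)
  expect_equal(length(unique(vapply(ch3, `[[`, "", "subject_id"))), 3L)
})

test_that("a zero-effect noiseless cohort classifies as all no-change", {
  ch <- generate_cohort(5, null_effect_spec(noise_sd = 0),
                        n_frames = 2, shape = sim_shape, seed = 2)
  labels <- classify_cohort(index_table(ch))
  expect_true(all(labels$lateral$label == "No change"))
  expect_true(all(labels$ap$label == "No change"))
})

test_that("an injected dominant CLL effect is classified as mostly rightward", {
  spec <- null_effect_spec(noise_sd = 0.02)
  spec$CLL$lateral_mean <- 5
  spec$CLL$lateral_sd <- 1
  ch <- generate_cohort(200, spec, n_frames = 2, shape = sim_shape, seed = 31)
  labels <- classify_cohort(index_table(ch), epsilon_pp = 0.5)
  cll <- labels$lateral[labels$lateral$condition == "CLL", ]
  # lateral effect ~ N(5, 1); P(shift <= 0.5) is ~phi(-4.5), so with 200
  # subjects a rightward majority of at least 95% holds by construction
  expect_gte(mean(cll$label == "Right"), 0.95)
})

test_that("injected lateral shifts are recovered by the analysis pipeline", {
  for (delta in c(1, 2, 5)) {
    spec <- null_effect_spec(noise_sd = 0.05)
    for (cond in names(spec)) spec[[cond]]$lateral_mean <- delta
    ch <- generate_cohort(40, spec, n_frames = 2, shape = sim_shape,
                          seed = 100 + delta)
    idx <- index_table(ch)
    rest <- idx[idx$condition == "RES", ]
    est <- sapply(c("CL", "CLR", "CLL"), function(cond) {
      cur <- idx[idx$condition == cond, ]
      cur$olwd[match(rest$subject, cur$subject)] - rest$olwd
    })
    # the three conditions share each subject's rest measurement, so the
    # Monte-Carlo SE must come from independent per-subject means
    subj_mean <- rowMeans(est)
    mc_se <- stats::sd(subj_mean) / sqrt(length(subj_mean))
    expect_lt(abs(mean(subj_mean) - delta), 3 * mc_se + 1e-12)
  }
})
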