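# Synthetic cohort generator: determinism, ground-truth invariants, and
# convergence of the simulated dynamics to the generating parameters.

test_that("generated templates are average-referenced, unit-norm, dissimilar", {
  tpl <- generate_templates(19L, 4L, seed = 1L)
  expect_equal(dim(tpl), c(4L, 19L))
  expect_true(all(abs(rowMeans(tpl)) < 1e-12))
  expect_equal(unname(sqrt(rowSums(tpl^2))), rep(1, 4), tolerance = 1e-12)
  cors <- abs(stats::cor(t(tpl)))
  diag(cors) <- 0
  expect_lt(max(cors), 0.5)
  expect_identical(tpl, generate_templates(19L, 4L, seed = 1L))
  expect_error(generate_templates(3L, 4L), "n_channels")
})

test_that("ground-truth constructor enforces its invariants", {
  tpl <- generate_templates(6L, 3L, seed = 2L)
  tm <- matrix(c(0, .5, .5, .3, 0, .7, .9, .1, 0), 3L, byrow = TRUE)
  gt <- microstate_ground_truth(tpl, tm, c(80, 70, 90), noise_sd = 0.1)
  expect_equal(rowSums(gt$transition_matrix), rep(1, 3))
  expect_error(microstate_ground_truth(tpl, tm, c(80, -1, 90)), "positive")
  tm_bad <- tm
  tm_bad[1L, 1L] <- 0.1
  expect_error(microstate_ground_truth(tpl, tm_bad, c(80, 70, 90)))
})

test_that("state sequences are deterministic and follow the cycle in the degenerate case", {
  tpl <- generate_templates(19L, 4L, seed = 3L)
  cycle <- matrix(0, 4L, 4L)
  cycle[cbind(1:4, c(2L, 3L, 4L, 1L))] <- 1
  gt <- microstate_ground_truth(tpl, cycle, rep(50, 4L), noise_sd = 0)
  lab <- simulate_state_sequence(gt, 5000L, 128, seed = 4L)
  expect_identical(lab, simulate_state_sequence(gt, 5000L, 128, seed = 4L))
  est <- microstate_summary(lab, 128)$transition_matrix
  expect_equal(est, cycle, tolerance = 1e-12)
  expect_length(simulate_state_sequence(gt, 1L, 128, seed = 1L), 1L)
})

test_that("long sequences recover the generating transition matrix and durations", {
  gt <- fix_gt()
  lab <- simulate_state_sequence(gt, 2e5L, 128, seed = 5L)
  est <- microstate_summary(lab, 128)
  exp <- expected_microstate_stats(gt, 128)
  expect_lt(max(abs(est$transition_matrix - exp$transition_matrix)), 0.02)
  expect_lt(max(abs(est$coverage - exp$coverage)), 0.02)
  expect_lt(max(abs(est$duration_ms / exp$duration_ms - 1)), 0.05)
})

test_that("synthesis is the inverse of backfitting at zero noise", {
  gt <- fix_gt(0)
  lab <- simulate_state_sequence(gt, 1280L, 128, seed = 6L)
  rec <- synthesize_eeg(gt, lab, fs_hz = 128, seed = 6L)
  expect_identical(backfit(rec, gt$templates), lab)
  expect_equal(sum(compute_gev(rec, lab, gt$templates)), 1, tolerance = 1e-9)
  # average-reference preserved by construction, also with noise
  gtn <- fix_gt(0.3)
  recn <- synthesize_eeg(gtn, lab, fs_hz = 128, seed = 6L)
  expect_lt(max(abs(colMeans(recn$data))), 1e-12)
  expect_error(synthesize_eeg(gt, lab, amplitudes = rep(1, 10)), "length")
})

test_that("moderate noise degrades backfit agreement but stays above chance", {
  gt <- fix_gt(0.5)
  lab <- simulate_state_sequence(gt, 2560L, 128, seed = 8L)
  rec <- synthesize_eeg(gt, lab, fs_hz = 128, seed = 8L)
  agree <- mean(backfit(rec, gt$templates) == lab)
  expect_gt(agree, 0.25)
  expect_lt(agree, 1)
})

test_that("cohorts are reproducible and encode the case-group effect directions", {
  gt_c <- fix_gt(0.05)
  gt_a <- case_ground_truth(gt_c)
  expect_gt(gt_a$mean_durations_ms[2L], gt_c$mean_durations_ms[2L])  # B up
  expect_lt(gt_a$mean_durations_ms[3L], gt_c$mean_durations_ms[3L])  # C down
  expect_gt(gt_a$transition_matrix[1L, 2L], gt_c$transition_matrix[1L, 2L])
  expect_gt(gt_a$transition_matrix[4L, 2L], gt_c$transition_matrix[4L, 2L])
  expect_lt(gt_a$transition_matrix[1L, 3L], gt_c$transition_matrix[1L, 3L])
  expect_lt(gt_a$transition_matrix[2L, 3L], gt_c$transition_matrix[2L, 3L])
  expect_lt(gt_a$transition_matrix[4L, 3L], gt_c$transition_matrix[4L, 3L])
  expect_equal(rowSums(gt_a$transition_matrix), rep(1, 4), tolerance = 1e-9)
  # expected coverage shifts follow the duration shifts
  exp_c <- expected_microstate_stats(gt_c, 128)
  exp_a <- expected_microstate_stats(gt_a, 128)
  expect_gt(exp_a$coverage[2L], exp_c$coverage[2L])
  expect_lt(exp_a$coverage[3L], exp_c$coverage[3L])

  spec <- cohort_spec(2L, 2, 128)
  c1 <- generate_cohort(spec, gt_c, gt_a, seed = 9L)
  c2 <- generate_cohort(spec, gt_c, gt_a, seed = 9L)
  expect_identical(lapply(c1, `[[`, "data"), lapply(c2, `[[`, "data"))
  expect_length(c1, 4L)
  expect_identical(vapply(c1, `[[`, "", "group_label"),
                   c("control", "control", "case", "case"))
  # boundary: one subject per group
  expect_length(generate_cohort(cohort_spec(1L, 1, 128), gt_c, gt_a, 1L), 2L)
})

test_that("cohort round-trips through the on-disk layout", {
  gt <- fix_gt(0.05)
  recs <- generate_cohort(cohort_spec(1L, 1, 128), gt, gt, seed = 10L)
  dir <- withr::local_tempdir()
  write_cohort(recs, dir, ground_truth = list(control = gt))
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_eeg_csv(file.path(dir, paste0(recs[[1L]]$subject_id, ".csv")),
                       fs_hz = 128)
  expect_equal(back$data, recs[[1L]]$data, tolerance = 1e-12)
})
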