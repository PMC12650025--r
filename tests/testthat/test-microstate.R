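# Microstate pipeline: GFP arithmetic, peak picking, polarity-invariant
# clustering, optimal alignment, backfitting, and the 28-D feature vector.

test_that("GFP is the spatial SD with hand-checkable values", {
  rec <- eeg_record(matrix(c(1, -1, 2, 2, 0, 4), 2L), fs_hz = 10)
  g <- compute_gfp(rec)
  expect_equal(g$values, c(1, 0, 2))   # [1,-1]->1; [2,2]->0; [0,4]->2
  # homogeneity
  rec3 <- rec
  rec3$data <- rec$data * 3
  expect_equal(compute_gfp(rec3)$values, 3 * g$values)
})

test_that("peak detection finds apices, honours separation and tie rules", {
  tri <- c(0, 1, 2, 3, 2, 1, 0)
  expect_identical(detect_gfp_peaks(tri, fs_hz = 1000), 4L)
  # two equal peaks closer than the separation: earlier index wins
  twin <- c(0, 5, 0, 5, 0)
  expect_identical(detect_gfp_peaks(twin, min_separation_ms = 20, fs_hz = 128),
                   2L)
  # oscillating field strength: one GFP peak per modulation cycle
  fs <- 128
  t <- seq(1 / fs, 10, by = 1 / fs)
  env <- 1 + 0.9 * sin(2 * pi * 1 * t)   # 1 Hz modulation, 10 cycles
  rec <- eeg_record(rbind(env, -env), fs_hz = fs)
  peaks <- detect_gfp_peaks(compute_gfp(rec), min_separation_ms = 100)
  expect_gt(length(peaks), 8L)
  expect_lt(length(peaks), 12L)
  expect_identical(detect_gfp_peaks(c(1, 2), fs_hz = 1), integer(0))
})

test_that("clustering recovers exact templates and is polarity invariant", {
  gt <- fix_gt()
  tpl <- gt$templates
  maps <- tpl[rep(1:4, each = 25L), ]
  cl <- cluster_templates(maps, K = 4L, seed = 1L)
  al <- align_to_reference(cl$templates, tpl)
  expect_equal(unname(diag(al$templates %*% t(tpl))), rep(1, 4),
               tolerance = 1e-9)
  expect_gt(cl$gev, 1 - 1e-9)
  # maps plus their negations cluster identically (sign-agnostic metric)
  cl2 <- cluster_templates(rbind(maps, -maps), K = 4L, seed = 1L)
  al2 <- align_to_reference(cl2$templates, tpl)
  expect_equal(abs(unname(diag(al2$templates %*% t(tpl)))), rep(1, 4),
               tolerance = 1e-9)
  expect_error(cluster_templates(maps[1:3, ], K = 4L), "fewer")
})

test_that("noisy cohort clustering stays close to the generating maps", {
  gt <- fix_gt(0.2)
  rec <- fix_record(seconds = 20, noise_sd = 0.2, seed = 11L, gt = gt)
  peaks <- detect_gfp_peaks(compute_gfp(rec))
  cl <- cluster_templates(t(apply(rec$data[, peaks], 2L, function(v) v)),
                          K = 4L, seed = 2L)
  al <- align_to_reference(cl$templates, gt$templates)
  cors <- abs(diag(al$templates %*% t(gt$templates)))
  expect_gt(mean(cors), 0.9)
})

test_that("two-level clustering pools subjects and is idempotent for one", {
  gt <- fix_gt()
  sets <- list(gt$templates, gt$templates[c(2, 1, 4, 3), ])
  gl <- two_level_cluster(sets, K = 4L, seed = 3L)
  al <- align_to_reference(gl$templates, gt$templates)
  expect_equal(abs(unname(diag(al$templates %*% t(gt$templates)))),
               rep(1, 4), tolerance = 1e-6)
  single <- two_level_cluster(list(gt$templates), K = 4L, seed = 3L)
  als <- align_to_reference(single$templates, gt$templates)
  expect_equal(abs(unname(diag(als$templates %*% t(gt$templates)))),
               rep(1, 4), tolerance = 1e-9)
  expect_error(two_level_cluster(list()), "at least one")
})

test_that("alignment recovers shuffles, fixes signs, and beats greedy", {
  ref <- fix_gt()$templates
  perm <- c(3L, 1L, 4L, 2L)
  shuffled <- ref[perm, ]
  al <- align_to_reference(shuffled, ref)
  expect_equal(al$templates, ref, ignore_attr = TRUE, tolerance = 1e-12)
  flipped <- ref * c(-1, 1, -1, 1)
  alf <- align_to_reference(flipped, ref)
  expect_identical(alf$permutation, 1:4)
  expect_equal(alf$templates, ref, ignore_attr = TRUE, tolerance = 1e-12)
  # optimal assignment >= greedy on random instances
  set.seed(12)
  for (k in 1:5) {
    rnd <- t(apply(matrix(rnorm(4L * 19L), 4L), 1L, function(v) {
      v <- v - mean(v)
      v / sqrt(sum(v^2))
    }))
    cors <- abs(rnd %*% t(ref))
    greedy <- 0
    avail <- 1:4
    for (j in 1:4) {
      i <- avail[which.max(cors[avail, j])]
      greedy <- greedy + cors[i, j]
      avail <- setdiff(avail, i)
    }
    expect_gte(align_to_reference(rnd, ref)$total_abs_corr, greedy - 1e-12)
  }
  expect_error(align_to_reference(ref[, 1:10], ref), "channel")
})

test_that("backfitting is scale and polarity invariant with lowest-index ties", {
  gt <- fix_gt()
  rec <- fix_record(seconds = 5, seed = 13L, gt = gt)
  lab <- backfit(rec, gt$templates)
  rec10 <- rec
  rec10$data <- rec$data * 10
  expect_identical(backfit(rec10, gt$templates), lab)
  neg <- rec
  neg$data <- -rec$data
  expect_identical(backfit(neg, gt$templates), lab)
  # a sample equal to -T_2 is labelled state 2
  single <- eeg_record(cbind(-gt$templates[2L, ], -gt$templates[2L, ]),
                       fs_hz = 128)
  expect_identical(backfit(single, gt$templates), c(2L, 2L))
})

test_that("summary reproduces hand-counted durations, coverage, transitions", {
  lab <- c(1L, 1L, 2L, 2L, 2L, 3L)
  s <- microstate_summary(lab, fs_hz = 1000)
  expect_equal(s$coverage, c(2, 3, 1, 0) / 6)
  expect_equal(s$duration_ms[1L], 2)        # 2 samples at 1 kHz
  expect_equal(s$transition_matrix[1L, 2L], 1)
  expect_equal(s$transition_matrix[2L, 3L], 1)
  expect_false(s$present[4L])
  expect_equal(sum(s$coverage), 1, tolerance = 1e-12)
  occurring <- which(rowSums(s$transition_matrix) > 0)
  expect_equal(rowSums(s$transition_matrix)[occurring],
               rep(1, length(occurring)), ignore_attr = TRUE)
  # degenerate: constant labels
  sc <- microstate_summary(rep(2L, 10L), 100)
  expect_equal(sc$coverage, c(0, 1, 0, 0))
  expect_true(all(sc$transition_matrix == 0))
})

test_that("GEV is bounded, exact at zero noise, and rejects flat records", {
  gt <- fix_gt()
  rec <- fix_record(seconds = 5, seed = 14L, gt = gt)
  lab <- backfit(rec, gt$templates)
  gev <- compute_gev(rec, lab, gt$templates)
  expect_equal(sum(gev), 1, tolerance = 1e-9)
  expect_true(all(gev >= 0 & gev <= 1))
  # random labels on noise explain strictly less than everything
  set.seed(15)
  noise <- eeg_record(matrix(rnorm(19L * 500L), 19L), fs_hz = 128)
  rl <- sample.int(4L, 500L, replace = TRUE)
  expect_lt(sum(compute_gev(noise, rl, gt$templates)), 1)
  flat <- eeg_record(matrix(1, 19L, 10L), fs_hz = 128)
  expect_error(compute_gev(flat, rep(1L, 10L), gt$templates), "GFP")
})

test_that("the feature vector is 28-D in fixed block order", {
  s <- microstate_summary(c(1L, 1L, 2L, 3L, 4L, 4L), 128)
  fv <- microstate_features(s, gev = c(0.4, 0.3, 0.2, 0.05))
  expect_length(fv, 28L)
  expect_identical(names(fv)[1:4], paste0("dur_", LETTERS[1:4]))
  expect_identical(names(fv)[13L], "p_AB")
  expect_identical(names(fv)[25:28], paste0("gev_", LETTERS[1:4]))
  expect_equal(sum(fv[paste0("cov_", LETTERS[1:4])]), 1, tolerance = 1e-12)
})

test_that("negating a record changes no labels, features, or GEV", {
  gt <- fix_gt(0.1)
  rec <- fix_record(seconds = 5, noise_sd = 0.1, seed = 16L, gt = gt)
  neg <- rec
  neg$data <- -rec$data
  m1 <- microstate_fit(rec, seed = 4L)
  m2 <- microstate_fit(neg, seed = 4L)
  expect_identical(m1$labels, m2$labels)
  expect_equal(m1$features, m2$features, tolerance = 1e-12)
})

test_that("model fitting recovers the generating dynamics on a cohort", {
  gt <- fix_gt(0.05)
  recs <- generate_cohort(cohort_spec(4L, 60, 128), gt, gt, seed = 17L)
  ms <- microstate_fit(recs, seed = 5L, min_run_ms = 10)
  exp <- expected_microstate_stats(gt, 128)
  est_dur <- colMeans(ms$features[, paste0("dur_", LETTERS[1:4])])
  est_cov <- colMeans(ms$features[, paste0("cov_", LETTERS[1:4])])
  expect_lt(max(abs(est_dur / exp$duration_ms - 1)), 0.1)
  expect_lt(max(abs(est_cov - exp$coverage)), 0.05)
  tm_est <- matrix(0, 4L, 4L)
  tm_est[c(t(diag(4) == 0))] <- 0  # placeholder for clarity
  trans <- colMeans(ms$features[, grep("^p_", colnames(ms$features))])
  k <- 1L
  for (i in 1:4) for (j in setdiff(1:4, i)) {
    tm_est[i, j] <- trans[[paste0("p_", LETTERS[i], LETTERS[j])]]
  }
  expect_lt(max(abs(tm_est - exp$transition_matrix)), 0.05)
  expect_gt(mean(rowSums(ms$gev)), 0.8)   # background rhythm is unexplained variance
})

test_that("windowed fitting yields aligned per-window feature rows", {
  gt <- fix_gt(0.05)
  recs <- generate_cohort(cohort_spec(2L, 9, 128), gt, gt, seed = 18L)
  ms <- microstate_fit(recs, window_s = 3, seed = 6L)
  expect_identical(nrow(ms$features), 4L * 3L)     # 3 windows per record
  expect_identical(ms$feature_subjects,
                   rep(vapply(recs, `[[`, "", "subject_id"), each = 3L))
  # window rows agree with the same windows summarised by hand
  wins <- split_record(recs[[1L]], 3)
  expect_length(wins, 3L)
  lab <- ms$labels[[1L]]
  sl <- 1:(3 * 128)
  hand <- microstate_features(
    microstate_summary(lab[sl], 128),
    compute_gev(wins[[1L]], lab[sl], ms$templates)
  )
  expect_equal(ms$features[1L, ], hand, tolerance = 1e-12)
  # per-record coverage still sums to 1 in every window row
  expect_equal(unname(rowSums(ms$features[, paste0("cov_", LETTERS[1:4])])),
               rep(1, 12L), tolerance = 1e-9)
})
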