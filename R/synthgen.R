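# Synthetic EEG cohorts with known microstate ground truth.
#
# The generator inverts the microstate model: a semi-Markov state sequence
# selects one of K fixed topographic templates at every sample, the template is
# scaled by a slowly varying positive amplitude (so GFP peaks exist), and
# average-referenced Gaussian sensor noise is added. Because the generating
# templates, durations and transition matrix are known exactly, every
# downstream estimator (backfitting, duration/coverage/occurrence statistics,
# transition probabilities, GEV) can be checked against ground truth.

#' Microstate ground truth for the synthetic generator
#'
#' @param templates K x n_channels matrix of topographic maps; each row is
#'   re-centred (zero channel mean) and scaled to unit L2 norm.
#' @param transition_matrix K x K row-stochastic matrix with zero diagonal:
#'   the probability of entering state j when a run of state i ends.
#' @param mean_durations_ms mean run duration of each state, in milliseconds.
#' @param noise_sd standard deviation of i.i.d. Gaussian sensor noise, on the
#'   scale of the unit-norm templates (the signal map at time t has L2 norm
#'   equal to the amplitude series, mean 1).
#' @param seed integer seed stored with the ground truth.
#' @return an object of class `microstate_ground_truth`.
#' @export
microstate_ground_truth <- function(templates, transition_matrix,
                                    mean_durations_ms, noise_sd = 0.05,
                                    seed = 1L) {
  if (!is.matrix(templates)) stop("`templates` must be a matrix", call. = FALSE)
  K <- nrow(templates)
  if (K < 2L) stop("need at least 2 templates", call. = FALSE)
  templates <- t(apply(templates, 1L, normalize_map))
  if (!is.matrix(transition_matrix) || any(dim(transition_matrix) != K)) {
    stop("`transition_matrix` must be K x K", call. = FALSE)
  }
  if (any(diag(transition_matrix) != 0)) {
    stop("`transition_matrix` diagonal must be exactly 0", call. = FALSE)
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("each transition row must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(mean_durations_ms) != K || any(mean_durations_ms <= 0)) {
    stop("`mean_durations_ms` must hold K positive durations", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      templates = templates,
      transition_matrix = transition_matrix,
      mean_durations_ms = as.numeric(mean_durations_ms),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "microstate_ground_truth"
  )
}

#' Generate K mutually dissimilar ground-truth templates
#'
#' Draws Gaussian random maps, orthonormalises them (QR), then mixes a small
#' common component back in so templates are merely low-correlation rather
#' than exactly orthogonal; each is average-referenced and unit-norm.
#'
#' @param n_channels number of electrodes (>= K).
#' @param K number of templates (>= 2).
#' @param seed integer seed; identical seeds give identical templates.
#' @param max_abs_corr upper bound on pairwise |correlation| (draws are
#'   rejected and retried until satisfied).
#' @return K x n_channels matrix of zero-mean unit-norm maps.
#' @export
generate_templates <- function(n_channels, K = 4L, seed = 1L,
                               max_abs_corr = 0.5) {
  if (K < 2L) stop("`K` must be >= 2", call. = FALSE)
  if (K > n_channels) {
    stop("`K` cannot exceed `n_channels`", call. = FALSE)
  }
  with_seed(seed, {
    for (attempt in 1:100) {
      raw <- matrix(stats::rnorm(n_channels * K), nrow = n_channels)
      q <- qr.Q(qr(raw))[, seq_len(K), drop = FALSE]
      tpl <- t(apply(t(q), 1L, normalize_map))
      cors <- abs(stats::cor(t(tpl)))
      diag(cors) <- 0
      if (max(cors) < max_abs_corr) {
        rownames(tpl) <- LETTERS[seq_len(K)]
        return(tpl)
      }
    }
    stop("could not generate templates under the correlation bound", call. = FALSE)
  })
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Run lengths are geometric with mean `mean_durations_ms * fs / 1000` samples
#' (the maximum-entropy run-length law consistent with a first-order Markov
#' chain); successive states are drawn from the ground-truth transition matrix.
#'
#' @param gt a `microstate_ground_truth`.
#' @param n_samples sequence length (>= 1).
#' @param fs_hz sampling rate in Hz.
#' @param seed integer seed.
#' @return integer vector of length `n_samples` with values in 1..K.
#' @export
simulate_state_sequence <- function(gt, n_samples, fs_hz, seed = 1L) {
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  stopifnot_scalar(fs_hz, "fs_hz", positive = TRUE)
  K <- nrow(gt$templates)
  mean_len <- pmax(gt$mean_durations_ms * fs_hz / 1000, 1)
  with_seed(seed, {
    labels <- integer(n_samples)
    state <- sample.int(K, 1L)
    pos <- 1L
    while (pos <= n_samples) {
      # geometric on {1,2,...} with mean mean_len[state]
      run <- stats::rgeom(1L, prob = 1 / mean_len[state]) + 1L
      end <- min(pos + run - 1L, n_samples)
      labels[pos:end] <- state
      pos <- end + 1L
      state <- sample.int(K, 1L, prob = gt$transition_matrix[state, ])
    }
    labels
  })
}

#' Default amplitude series for synthesis
#'
#' A rectified smoothed Gaussian process with mean ~1, so the global field
#' power is nonconstant and GFP peak detection has peaks to find.
#'
#' @param n_samples length.
#' @param fs_hz sampling rate (smoothing kernel is ~50 ms wide).
#' @param seed integer seed.
#' @param rel_sd relative modulation depth before rectification.
#' @return positive numeric vector of length `n_samples`.
#' @export
amplitude_series <- function(n_samples, fs_hz, seed = 1L, rel_sd = 0.35) {
  with_seed(seed, {
    z <- stats::rnorm(n_samples + 64L)
    half <- max(1L, round(0.05 * fs_hz))
    kern <- stats::dnorm(seq(-3, 3, length.out = 2L * half + 1L))
    kern <- kern / sum(kern)
    sm <- stats::filter(z, kern, sides = 2L)
    sm <- sm[!is.na(sm)][seq_len(n_samples)]
    sm <- sm / max(stats::sd(sm), 1e-12) * rel_sd
    pmax(abs(1 + sm), 0.05)
  })
}

#' Synthesize an EEG record from a label sequence
#'
#' V(t) = a(t) * T_label(t) + noise, with noise average-referenced per sample
#' so the record keeps the zero channel-mean convention of the templates.
#'
#' @param gt a `microstate_ground_truth`.
#' @param labels integer label sequence (values 1..K).
#' @param amplitudes positive amplitude series, same length as `labels`; by
#'   default an [amplitude_series()] drawn from `seed`.
#' @param fs_hz sampling rate of the produced record.
#' @param seed integer seed for amplitudes and noise.
#' @param subject_id,group_label metadata stored on the record.
#' @return an `eeg_record` with attribute `"labels"` holding the ground truth.
#' @export
synthesize_eeg <- function(gt, labels, amplitudes = NULL, fs_hz = 128,
                           seed = 1L, subject_id = "synth",
                           group_label = "unknown") {
  n <- length(labels)
  K <- nrow(gt$templates)
  if (any(labels < 1L | labels > K)) stop("labels out of range 1..K", call. = FALSE)
  if (is.null(amplitudes)) {
    amplitudes <- amplitude_series(n, fs_hz, seed = derive_seed(seed, 11L))
  }
  if (length(amplitudes) != n) {
    stop("`amplitudes` must have the same length as `labels`", call. = FALSE)
  }
  if (any(amplitudes <= 0)) stop("`amplitudes` must be positive", call. = FALSE)
  n_ch <- ncol(gt$templates)
  sig <- t(gt$templates[labels, , drop = FALSE]) * rep(amplitudes, each = n_ch)
  if (gt$noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, 13L), {
      white <- matrix(stats::rnorm(n_ch * n, sd = gt$noise_sd), nrow = n_ch)
      # ongoing background rhythm: narrowband (alpha-range) noise with
      # per-subject amplitude and peak frequency, independent per channel --
      # group-irrelevant activity that dominates spectral statistics the way
      # ongoing oscillations dominate real EEG
      f0 <- stats::runif(1L, 8.5, 11.5)
      amp <- 2 * gt$noise_sd * exp(stats::rnorm(1L, sd = 0.4))
      bf <- signal::butter(2L, pmin(c(f0 - 1.5, f0 + 1.5) / (fs_hz / 2),
                                    0.99), type = "pass")
      rhythm <- t(apply(matrix(stats::rnorm(n_ch * n), nrow = n_ch), 1L,
                        function(z) {
                          v <- signal::filtfilt(bf, z)
                          v / max(stats::sd(v), 1e-12) * amp
                        }))
      white + rhythm
    })
    # demean across channels so average reference is preserved by construction
    noise <- sweep(noise, 2L, colMeans(noise))
    sig <- sig + noise
  }
  rec <- eeg_record(sig, fs_hz, colnames(gt$templates),
                    subject_id = subject_id, group_label = group_label)
  attr(rec, "labels") <- as.integer(labels)
  rec
}

#' Default control-group ground truth
#'
#' Study-condition defaults: 19 channels, 4 states with field-typical mean
#' durations (80, 70, 90, 75 ms) and uniform off-diagonal transitions. On
#' the standard 19-channel montage the generating topographies are the
#' packaged canonical A-D maps, so state identities in the generator and in
#' a fitted (canonically aligned) microstate model coincide; on other
#' montages random low-correlation templates are drawn instead.
#'
#' @param n_channels number of electrodes.
#' @param seed template seed (used only when templates are drawn randomly).
#' @param noise_sd sensor noise SD.
#' @return a `microstate_ground_truth`.
#' @export
control_ground_truth <- function(n_channels = 19L, seed = 42L,
                                 noise_sd = 0.05) {
  K <- 4L
  tm <- matrix(1 / 3, K, K)
  diag(tm) <- 0
  tpl <- if (n_channels == 19L) canonical_templates() else
    generate_templates(n_channels, K, seed = seed)
  microstate_ground_truth(
    templates = tpl,
    transition_matrix = tm,
    mean_durations_ms = c(A = 80, B = 70, C = 90, D = 75),
    noise_sd = noise_sd,
    seed = seed
  )
}

#' Case-group ground truth encoding the ADHD-like effect pattern
#'
#' Starting from a control ground truth, lengthens state B and shortens state
#' C (duration and hence coverage), and shifts transition mass toward B and
#' away from C (A->B and D->B increased; A->C, B->C and D->C decreased) --
#' the direction pattern reported for ADHD versus control groups.
#'
#' @param gt_control the control `microstate_ground_truth`.
#' @param b_scale,c_scale multiplicative changes to the B / C mean durations.
#' @param shift transition mass moved toward B and away from C in the A, B
#'   and D rows (rows are renormalised; diagonal stays 0).
#' @return a `microstate_ground_truth` for the case group.
#' @export
case_ground_truth <- function(gt_control, b_scale = 1.5, c_scale = 0.6,
                              shift = 0.15) {
  dur <- gt_control$mean_durations_ms
  dur[2L] <- dur[2L] * b_scale
  dur[3L] <- dur[3L] * c_scale
  tm <- gt_control$transition_matrix
  bump <- function(row, up, down, amount) {
    row[down] <- max(row[down] - amount, 0.02)
    row[up] <- row[up] + amount
    row / sum(row)
  }
  tm[1L, ] <- bump(tm[1L, ], up = 2L, down = 3L, amount = shift)  # A: ->B up, ->C down
  tm[4L, ] <- bump(tm[4L, ], up = 2L, down = 3L, amount = shift)  # D: ->B up, ->C down
  tm[2L, c(1L, 4L)] <- tm[2L, c(1L, 4L)] + shift / 2              # B: ->C down
  tm[2L, 3L] <- max(tm[2L, 3L] - shift, 0.02)
  tm[2L, ] <- tm[2L, ] / sum(tm[2L, ])
  microstate_ground_truth(gt_control$templates, tm, dur,
                          noise_sd = gt_control$noise_sd,
                          seed = gt_control$seed)
}

#' Cohort specification
#'
#' @param n_subjects_per_group subjects per group (>= 1).
#' @param record_seconds record length per subject, in seconds.
#' @param fs_hz sampling rate.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 20L, record_seconds = 60,
                        fs_hz = 128) {
  if (n_subjects_per_group < 1L) {
    stop("`n_subjects_per_group` must be >= 1", call. = FALSE)
  }
  stopifnot_scalar(record_seconds, "record_seconds", positive = TRUE)
  stopifnot_scalar(fs_hz, "fs_hz", positive = TRUE)
  structure(
    list(
      n_subjects_per_group = as.integer(n_subjects_per_group),
      record_seconds = record_seconds,
      fs_hz = fs_hz
    ),
    class = "cohort_spec"
  )
}

#' Generate a two-group synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param gt_control,gt_case ground truths for the two groups (same templates
#'   recommended so group differences are purely dynamic).
#' @param seed integer seed; subject-level seeds are derived from it.
#' @return list of `eeg_record`s (controls first), each carrying its
#'   ground-truth `"labels"` attribute.
#' @export
generate_cohort <- function(spec, gt_control, gt_case, seed = 1L) {
  n_samples <- round(spec$record_seconds * spec$fs_hz)
  recs <- vector("list", 2L * spec$n_subjects_per_group)
  idx <- 1L
  for (grp in c("control", "case")) {
    gt <- if (grp == "control") gt_control else gt_case
    for (i in seq_len(spec$n_subjects_per_group)) {
      s <- derive_seed(seed, idx * 17L)
      labels <- simulate_state_sequence(gt, n_samples, spec$fs_hz, seed = s)
      recs[[idx]] <- synthesize_eeg(
        gt, labels, fs_hz = spec$fs_hz, seed = s,
        subject_id = sprintf("%s_%02d", grp, i), group_label = grp
      )
      idx <- idx + 1L
    }
  }
  recs
}

#' Theoretical microstate statistics implied by a ground truth
#'
#' Long-run expectations of the quantities the microstate summariser
#' estimates: mean durations, coverages (stationary occupancy weighted by
#' duration), occurrence rates, and the run-level transition matrix itself.
#'
#' @param gt a `microstate_ground_truth`.
#' @param fs_hz sampling rate the sequence will be simulated at (geometric
#'   run lengths are discretised at this rate).
#' @return list with `duration_ms`, `coverage`, `occurrence_per_s`,
#'   `transition_matrix`.
#' @export
expected_microstate_stats <- function(gt, fs_hz = 128) {
  K <- nrow(gt$templates)
  # stationary distribution of the run-level (embedded) chain
  e <- eigen(t(gt$transition_matrix))
  i <- which.min(abs(e$values - 1))
  pi_run <- Re(e$vectors[, i])
  pi_run <- pi_run / sum(pi_run)
  mean_len <- pmax(gt$mean_durations_ms * fs_hz / 1000, 1)
  dur_ms <- mean_len / fs_hz * 1000
  cov <- pi_run * mean_len / sum(pi_run * mean_len)
  occ <- cov / (dur_ms / 1000)
  list(
    duration_ms = dur_ms,
    coverage = cov,
    occurrence_per_s = occ,
    transition_matrix = gt$transition_matrix
  )
}

#' Write a cohort to disk
#'
#' One CSV matrix per subject plus a metadata CSV and a JSON ground-truth
#' sidecar (for test oracles).
#'
#' @param records list of `eeg_record`s.
#' @param dir output directory (created if needed).
#' @param ground_truth optional list of `microstate_ground_truth`s to
#'   serialise alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir, ground_truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, ""),
    group = vapply(records, function(r) r$group_label, ""),
    fs_hz = vapply(records, function(r) r$fs_hz, 0),
    n_channels = vapply(records, function(r) nrow(r$data), 0L),
    file = vapply(records, function(r) paste0(r$subject_id, ".csv"), "")
  )
  for (r in records) write_eeg_csv(r, file.path(dir, paste0(r$subject_id, ".csv")))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(ground_truth)) {
    jsonlite::write_json(
      lapply(ground_truth, function(g) {
        list(templates = g$templates, transition_matrix = g$transition_matrix,
             mean_durations_ms = g$mean_durations_ms, noise_sd = g$noise_sd,
             seed = g$seed)
      }),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE
    )
  }
  invisible(dir)
}
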