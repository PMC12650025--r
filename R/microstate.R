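# Microstate pipeline: global field power, GFP peak picking, polarity-
# invariant modified K-means clustering of peak topographies, two-level
# (subject -> group) clustering, optimal alignment to reference maps,
# backfitting, and the 28-dimensional dynamic feature vector
# (duration / coverage / occurrence, 12 off-diagonal transition
# probabilities, 4 global-explained-variance values).

#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp potentials at each
#' sample: sqrt(mean over channels of (V_i(t) - Vbar(t))^2). High GFP marks
#' moments of strong, topographically stable differentiation.
#'
#' @param rec an `eeg_record` (>= 2 channels).
#' @return object of class `gfp_series`: list with `values` (nonnegative,
#'   one per sample) and `fs_hz`.
#' @export
compute_gfp <- function(rec) {
  v <- rec$data
  cm <- colMeans(v)
  g <- sqrt(colMeans(sweep(v, 2L, cm)^2))
  structure(list(values = g, fs_hz = rec$fs_hz), class = "gfp_series")
}

#' Detect GFP peaks
#'
#' Strict local maxima of the GFP series, pruned so retained peaks are at
#' least `min_separation_ms` apart; when two candidates conflict the larger
#' one wins (earlier index on exact ties).
#'
#' @param gfp a `gfp_series` (or plain numeric vector with `fs_hz` given).
#' @param min_separation_ms minimum distance between retained peaks.
#' @param fs_hz required only when `gfp` is a bare numeric vector.
#' @return sorted integer vector of sample indices (possibly empty).
#' @export
detect_gfp_peaks <- function(gfp, min_separation_ms = 10, fs_hz = NULL) {
  if (inherits(gfp, "gfp_series")) {
    v <- gfp$values
    fs <- gfp$fs_hz
  } else {
    v <- gfp
    fs <- fs_hz
    if (is.null(fs)) stop("`fs_hz` required for a bare numeric series", call. = FALSE)
  }
  n <- length(v)
  if (n < 3L) {
    return(integer(0))
  }
  core <- v[2:(n - 1L)]
  is_peak <- core > v[1:(n - 2L)] & core > v[3:n]
  cand <- which(is_peak) + 1L
  if (length(cand) == 0L) {
    return(integer(0))
  }
  min_sep <- min_separation_ms / 1000 * fs
  # greedy by height (stable order => earlier index wins ties)
  ord <- cand[order(-v[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Extract unit-norm zero-mean peak topographies (channels x n_peaks -> rows).
peak_maps <- function(rec, peaks) {
  t(apply(rec$data[, peaks, drop = FALSE], 2L, normalize_map))
}

# Polarity-invariant goodness of a labelled set of maps: GFP^2-weighted mean
# squared spatial correlation (the GEV of the peak set).
peak_gev <- function(maps, gfp2, templates, assign) {
  c2 <- vapply(seq_len(nrow(maps)), function(i) {
    spatial_corr(maps[i, ], templates[assign[i], ])^2
  }, 0)
  sum(c2 * gfp2) / sum(gfp2)
}

#' Polarity-invariant modified K-means clustering of topographies
#'
#' Assigns each map to the template maximising the squared spatial
#' correlation (sign-agnostic), then recomputes each template as the
#' normalised sign-aligned mean of its assigned maps; iterates to
#' convergence, keeping the best of `n_init` seeded restarts by GEV.
#'
#' @param maps n_maps x n_channels matrix of topographies (e.g. GFP peak
#'   maps); rows are re-normalised internally.
#' @param K number of clusters.
#' @param n_init random restarts.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @param gfp_weights optional per-map GFP values used in the GEV restart
#'   criterion (default: equal weights).
#' @return object of class `microstate_templates`: list with `templates`
#'   (K x n_channels, zero-mean unit-norm rows), `assignment`, `gev`.
#' @export
cluster_templates <- function(maps, K = 4L, n_init = 10L, max_iter = 100L,
                              seed = 1L, gfp_weights = NULL) {
  if (!is.matrix(maps)) maps <- matrix(maps, ncol = length(maps))
  n <- nrow(maps)
  if (n < K) stop("fewer maps than clusters", call. = FALSE)
  maps <- t(apply(maps, 1L, normalize_map))
  gfp2 <- if (is.null(gfp_weights)) rep(1, n) else gfp_weights^2

  run_once <- function() {
    centers <- maps[sample.int(n, K), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      # squared correlation of unit-norm zero-mean rows = squared dot product
      sim <- (maps %*% t(centers))^2
      assign_new <- max.col(sim, ties.method = "first")
      if (all(assign_new == assign_old)) break
      assign_old <- assign_new
      for (k in seq_len(K)) {
        members <- which(assign_new == k)
        if (length(members) == 0L) {
          centers[k, ] <- maps[sample.int(n, 1L), ]
          next
        }
        signs <- sign(maps[members, , drop = FALSE] %*% centers[k, ])
        signs[signs == 0] <- 1
        centers[k, ] <- normalize_map(
          colSums(maps[members, , drop = FALSE] * as.numeric(signs)) /
            length(members)
        )
      }
    }
    list(templates = centers, assignment = assign_old,
         gev = peak_gev(maps, gfp2, centers, assign_old))
  }

  best <- with_seed(seed, {
    res <- NULL
    for (i in seq_len(n_init)) {
      cand <- run_once()
      if (is.null(res) || cand$gev > res$gev) res <- cand
    }
    res
  })
  class(best) <- "microstate_templates"
  best
}

#' Two-level (subject then group) template clustering
#'
#' Pools all subjects' individual templates and re-clusters the pool to
#' obtain group-level global templates.
#'
#' @param template_sets list of K x n_channels matrices (one per subject).
#' @param K number of global clusters.
#' @param seed integer seed.
#' @param ... passed to [cluster_templates()].
#' @return a `microstate_templates` object.
#' @export
two_level_cluster <- function(template_sets, K = 4L, seed = 1L, ...) {
  if (length(template_sets) == 0L) {
    stop("`template_sets` must contain at least one subject", call. = FALSE)
  }
  pool <- do.call(rbind, template_sets)
  cluster_templates(pool, K = K, seed = seed, ...)
}

#' Align templates to a reference set
#'
#' Finds the one-to-one assignment of templates to reference maps that
#' maximises the total absolute spatial correlation, by exhaustive search
#' over all K! permutations (optimal, not greedy), then flips signs so each
#' aligned template correlates positively with its reference.
#'
#' @param templates K x n_channels matrix.
#' @param reference K x n_channels reference maps (same channel count),
#'   rows in canonical class order (A, B, C, D for K = 4).
#' @return list with `templates` (reordered, sign-corrected, rows named from
#'   the reference), `permutation` (`templates[permutation[k], ]` serves
#'   class k), `signs`, `total_abs_corr`.
#' @export
align_to_reference <- function(templates, reference) {
  if (ncol(templates) != ncol(reference)) {
    stop("channel count mismatch between templates and reference", call. = FALSE)
  }
  K <- nrow(reference)
  if (nrow(templates) != K) stop("template count mismatch", call. = FALSE)
  cors <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) cors[i, j] <- spatial_corr(templates[i, ], reference[j, ])
  }
  perms <- permutations_of(K)
  best_perm <- NULL
  best_total <- -Inf
  for (p in perms) {
    total <- sum(abs(cors[cbind(p, seq_len(K))]))
    if (total > best_total) {
      best_total <- total
      best_perm <- p
    }
  }
  signs <- sign(cors[cbind(best_perm, seq_len(K))])
  signs[signs == 0] <- 1
  aligned <- templates[best_perm, , drop = FALSE] * signs
  rownames(aligned) <- rownames(reference) %||% LETTERS[seq_len(K)]
  list(templates = aligned, permutation = best_perm, signs = signs,
       total_abs_corr = best_total)
}

# All permutations of 1..k as a list (k is small: 4! = 24).
permutations_of <- function(k) {
  if (k == 1L) {
    return(list(1L))
  }
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[i]] <- append(p, k, after = pos - 1L)
      i <- i + 1L
    }
  }
  out
}

#' Backfit templates onto a record
#'
#' Labels every sample with the template of maximal squared spatial
#' correlation (polarity-invariant; ties take the lowest index). Optional
#' minimum-run smoothing merges runs shorter than `min_run_ms` into the
#' neighbouring label with the higher correlation.
#'
#' @param rec an `eeg_record`.
#' @param templates K x n_channels template matrix.
#' @param min_run_ms minimum run length in ms (0 = no smoothing, default).
#' @return integer label vector (1..K), one per sample.
#' @export
backfit <- function(rec, templates, min_run_ms = 0) {
  v <- sweep(rec$data, 2L, colMeans(rec$data))        # spatial demean
  norms <- sqrt(colSums(v^2))
  norms[norms == 0] <- 1
  vn <- sweep(v, 2L, norms, "/")
  tn <- t(apply(templates, 1L, normalize_map))
  sim <- (tn %*% vn)^2                                 # K x n corr^2
  labels <- max.col(t(sim), ties.method = "first")
  if (min_run_ms > 0) {
    min_run <- min_run_ms / 1000 * rec$fs_hz
    labels <- smooth_short_runs(labels, sim, min_run)
  }
  labels
}

# Merge runs shorter than min_run samples into whichever neighbouring label
# fits the run's samples better (mean corr^2).
smooth_short_runs <- function(labels, sim, min_run) {
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_run)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    span <- starts[i]:ends[i]
    cands <- unique(c(if (i > 1L) r$values[i - 1L],
                      if (i < length(r$values)) r$values[i + 1L]))
    fit <- vapply(cands, function(k) mean(sim[k, span]), 0)
    labels[span] <- cands[which.max(fit)]
  }
  labels
}

#' Summarise a microstate label sequence
#'
#' Runs are maximal constant-label segments. Per state: mean run duration
#' (ms), time coverage (fraction of samples), occurrence rate (runs per
#' second); plus the run-boundary transition matrix with structurally zero
#' diagonal and row-normalised off-diagonal counts.
#'
#' @param labels integer label vector (1..K).
#' @param fs_hz sampling rate.
#' @param K number of states (default: max label seen, at least 4).
#' @return list with `duration_ms`, `coverage`, `occurrence_per_s`,
#'   `transition_matrix`, `present` (logical; absent states have duration 0
#'   and an all-zero transition row).
#' @export
microstate_summary <- function(labels, fs_hz, K = max(4L, max(labels))) {
  n <- length(labels)
  if (n < 1L) stop("`labels` must be nonempty", call. = FALSE)
  r <- rle(as.integer(labels))
  duration_ms <- numeric(K)
  occurrence <- numeric(K)
  coverage <- numeric(K)
  for (k in seq_len(K)) {
    runs_k <- r$lengths[r$values == k]
    coverage[k] <- sum(runs_k) / n
    if (length(runs_k) > 0L) {
      duration_ms[k] <- mean(runs_k) / fs_hz * 1000
      occurrence[k] <- length(runs_k) / (n / fs_hz)
    }
  }
  tm <- matrix(0, K, K)
  if (length(r$values) > 1L) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1L]
    for (i in seq_along(from)) tm[from[i], to[i]] <- tm[from[i], to[i]] + 1
    rs <- rowSums(tm)
    nz <- rs > 0
    tm[nz, ] <- tm[nz, , drop = FALSE] / rs[nz]
  }
  list(
    duration_ms = duration_ms,
    coverage = coverage,
    occurrence_per_s = occurrence,
    transition_matrix = tm,
    present = coverage > 0
  )
}

#' Global explained variance per state
#'
#' GEV_k = sum over samples labelled k of corr^2(V(t), T_k) * GFP(t)^2,
#' divided by the total sum of GFP(t)^2. Each value lies in [0, 1] and the
#' values sum to at most 1.
#'
#' @param rec an `eeg_record`.
#' @param labels per-sample state labels (1..K).
#' @param templates K x n_channels template matrix.
#' @param gfp optional precomputed `gfp_series`.
#' @return numeric vector of K GEV values.
#' @export
compute_gev <- function(rec, labels, templates, gfp = NULL) {
  if (is.null(gfp)) gfp <- compute_gfp(rec)
  g2 <- gfp$values^2
  tot <- sum(g2)
  if (tot <= 0) stop("all-zero GFP: record has no spatial variance", call. = FALSE)
  K <- nrow(templates)
  v <- sweep(rec$data, 2L, colMeans(rec$data))
  norms <- sqrt(colSums(v^2))
  norms[norms == 0] <- 1
  vn <- sweep(v, 2L, norms, "/")
  tn <- t(apply(templates, 1L, normalize_map))
  sim <- (tn %*% vn)^2
  gev <- numeric(K)
  for (k in seq_len(K)) {
    sel <- labels == k
    gev[k] <- sum(sim[k, sel] * g2[sel]) / tot
  }
  gev
}

#' Assemble the 28-D microstate feature vector
#'
#' Fixed order: duration (4), coverage (4), occurrence (4), the 12
#' off-diagonal transition probabilities (A->B, A->C, A->D, B->A, ...), and
#' 4 GEV values. States that never occur contribute zeros (see `present` in
#' the summary).
#'
#' @param summary output of [microstate_summary()] (K = 4).
#' @param gev 4 GEV values from [compute_gev()].
#' @return named numeric vector of length 28.
#' @export
microstate_features <- function(summary, gev) {
  K <- length(summary$duration_ms)
  lab <- LETTERS[seq_len(K)]
  tm <- summary$transition_matrix
  trans <- c(t(tm))[c(t(diag(K) == 0))]
  tn <- outer(lab, lab, paste0)
  trans_names <- c(t(tn))[c(t(diag(K) == 0))]
  out <- c(
    stats::setNames(summary$duration_ms, paste0("dur_", lab)),
    stats::setNames(summary$coverage, paste0("cov_", lab)),
    stats::setNames(summary$occurrence_per_s, paste0("occ_", lab)),
    stats::setNames(trans, paste0("p_", trans_names)),
    stats::setNames(gev, paste0("gev_", lab))
  )
  out
}

#' Fit a microstate model to one or more records
#'
#' The full pipeline: GFP peak detection per record, per-record template
#' clustering, pooled second-level clustering (when several records are
#' given), alignment to reference maps, backfitting, and feature
#' computation.
#'
#' @param records one `eeg_record` or a list of them.
#' @param K number of states (default 4).
#' @param reference reference maps for class ordering; defaults to the
#'   packaged canonical 19-channel approximations when the channel count is
#'   19, otherwise alignment is skipped and clusters keep arbitrary order.
#' @param min_separation_ms GFP peak separation.
#' @param n_init,max_iter clustering controls.
#' @param min_run_ms backfit smoothing (0 = off).
#' @param window_s optional epoching: when set, the labelled sequence of
#'   each record is cut into consecutive `window_s`-second windows and one
#'   feature row is produced per window instead of per record (templates
#'   and labels are still estimated from the full records). The
#'   `feature_subjects` field then maps feature rows back to subjects.
#' @param seed integer seed.
#' @return object of class `microstate_model`: global `templates`, per-record
#'   `labels`, `features` (rows x 28 matrix), `gev`, `summaries`,
#'   `feature_subjects`.
#' @export
microstate_fit <- function(records, K = 4L, reference = NULL,
                           min_separation_ms = 10, n_init = 10L,
                           max_iter = 100L, min_run_ms = 0,
                           window_s = NULL, seed = 1L) {
  if (inherits(records, "eeg_record")) records <- list(records)
  n_ch <- nrow(records[[1L]]$data)
  if (is.null(reference) && n_ch == 19L && K == 4L) {
    reference <- canonical_templates()
  }
  indiv <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    gfp <- compute_gfp(rec)
    peaks <- detect_gfp_peaks(gfp, min_separation_ms)
    if (length(peaks) < K) peaks <- order(-gfp$values)[seq_len(min(8L * K, ncol(rec$data)))]
    cl <- cluster_templates(peak_maps(rec, peaks), K = K, n_init = n_init,
                            max_iter = max_iter,
                            seed = derive_seed(seed, i),
                            gfp_weights = gfp$values[peaks])
    indiv[[i]] <- cl$templates
  }
  global <- if (length(indiv) > 1L) {
    two_level_cluster(indiv, K = K, seed = derive_seed(seed, 0L),
                      n_init = n_init, max_iter = max_iter)$templates
  } else {
    indiv[[1L]]
  }
  if (!is.null(reference)) {
    global <- align_to_reference(global, reference)$templates
  } else {
    rownames(global) <- LETTERS[seq_len(K)]
  }
  labels <- vector("list", length(records))
  summaries <- vector("list", length(records))
  gevs <- matrix(0, length(records), K)
  feat_rows <- list()
  feat_subjects <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    lab <- backfit(rec, global, min_run_ms = min_run_ms)
    sm <- microstate_summary(lab, rec$fs_hz, K = K)
    labels[[i]] <- lab
    summaries[[i]] <- sm
    gevs[i, ] <- compute_gev(rec, lab, global)
    if (is.null(window_s)) {
      feat_rows[[length(feat_rows) + 1L]] <-
        microstate_features(sm, gevs[i, ])
      feat_subjects <- c(feat_subjects, rec$subject_id)
    } else {
      ws <- round(window_s * rec$fs_hz)
      nwin <- max(1L, length(lab) %/% ws)
      for (w in seq_len(nwin)) {
        sl <- ((w - 1L) * ws + 1L):min(w * ws, length(lab))
        sub <- rec
        sub$data <- rec$data[, sl, drop = FALSE]
        smw <- microstate_summary(lab[sl], rec$fs_hz, K = K)
        gvw <- compute_gev(sub, lab[sl], global)
        feat_rows[[length(feat_rows) + 1L]] <-
          microstate_features(smw, gvw)
        feat_subjects <- c(feat_subjects, rec$subject_id)
      }
    }
  }
  feats <- do.call(rbind, feat_rows)
  rownames(feats) <- make.unique(feat_subjects)
  structure(
    list(
      templates = global, K = K, labels = labels, features = feats,
      gev = gevs, summaries = summaries,
      subject_ids = vapply(records, function(r) r$subject_id, ""),
      feature_subjects = feat_subjects, seed = seed
    ),
    class = "microstate_model"
  )
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d states, %d record(s), %d channels\n",
              x$K, length(x$labels), ncol(x$templates)))
  cat(sprintf("  mean total GEV: %.3f\n", mean(rowSums(x$gev))))
  invisible(x)
}

#' @export
summary.microstate_model <- function(object, ...) {
  feats <- object$features
  cat(sprintf("Microstate model: %d states over %d record(s)\n",
              object$K, nrow(feats)))
  lab <- LETTERS[seq_len(object$K)]
  tab <- data.frame(
    state = lab,
    duration_ms = colMeans(feats[, paste0("dur_", lab), drop = FALSE]),
    coverage = colMeans(feats[, paste0("cov_", lab), drop = FALSE]),
    occurrence_per_s = colMeans(feats[, paste0("occ_", lab), drop = FALSE]),
    gev = colMeans(feats[, paste0("gev_", lab), drop = FALSE])
  )
  print(tab, row.names = FALSE, digits = 3)
  invisible(tab)
}

#' @export
plot.microstate_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$K), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(x$K)) {
    graphics::barplot(x$templates[k, ], main = rownames(x$templates)[k],
                      col = ifelse(x$templates[k, ] >= 0, "firebrick", "navy"),
                      border = NA, ...)
  }
  invisible(x)
}
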