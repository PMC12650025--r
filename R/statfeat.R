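# Statistical feature block: time-, frequency- and nonlinear-domain
# descriptors (40 scalars per record after cross-channel aggregation), the
# three information-theoretic features (sample entropy, SVD entropy,
# SVD Fisher information), and random-forest Gini-importance selection.

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B), where B counts pairs of length-m templates
#' whose Chebyshev distance is <= r and A the corresponding count at length
#' m + 1; self-matches are excluded. `r` is given as a fraction of the
#' series SD and converted internally.
#'
#' @param x numeric series (length > m + 1).
#' @param m embedding dimension (>= 1).
#' @param r tolerance as a fraction of `sd(x)`.
#' @return nonnegative scalar; `NaN` when no length-(m+1) template pair
#'   matches (no recurrences at tolerance `r`).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short for sample entropy", call. = FALSE)
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  tol <- r * stats::sd(x)
  # both counts range over the same N - m template start positions
  # (standard convention: a constant series gives A = B, SampEn = 0)
  idx <- seq_len(n - m)
  B <- template_match_count(x, idx, m, tol)
  A <- template_match_count(x, idx, m + 1L, tol)
  if (B == 0 || A == 0) {
    return(NaN)
  }
  -log(A / B)
}

# Number of (i < j) pairs among the length-m templates starting at `idx`
# whose Chebyshev distance is <= tol. stats::dist supplies the C-speed
# pairwise maximum-metric kernel.
template_match_count <- function(x, idx, m, tol) {
  emb <- sapply(0:(m - 1L), function(j) x[idx + j])
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = m)
  d <- stats::dist(emb, method = "maximum")
  sum(d <= tol)
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi_m - Phi_(m+1) with Phi_m the mean log fraction of
#' templates within Chebyshev distance r (self-matches included).
#'
#' @inheritParams sample_entropy
#' @return nonnegative scalar (up to estimator bias).
#' @export
approx_entropy <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short for approximate entropy", call. = FALSE)
  tol <- r * stats::sd(x)
  phi <- function(mm) {
    idx <- seq_len(n - mm + 1L)
    counts <- template_neighbour_counts(x, idx, mm, tol)
    mean(log((counts + 1) / length(idx)))  # +1: self-match
  }
  phi(m) - phi(m + 1L)
}

# Per-template neighbour counts (self excluded) under Chebyshev distance,
# without materialising the full distance matrix: pair (i, j), i < j, sits
# at a known offset of the packed dist vector, so matching pairs are mapped
# back to their row/column indices with findInterval().
template_neighbour_counts <- function(x, idx, m, tol) {
  emb <- sapply(0:(m - 1L), function(j) x[idx + j])
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = m)
  n <- nrow(emb)
  ok <- which(unclass(stats::dist(emb, method = "maximum")) <= tol)
  starts <- c(0, cumsum((n - 1L):1L))   # 0-based block start per row i
  i <- findInterval(ok - 0.5, starts)
  j <- ok - starts[i] + i
  tabulate(i, n) + tabulate(j, n)
}

# Normalised singular-value distribution of the delay embedding of x.
svd_probs <- function(x, order = 3L, delay = 1L) {
  n <- length(x)
  if (order < 2L) stop("`order` must be >= 2", call. = FALSE)
  if (n < order * delay + 1L) stop("series too short for SVD embedding", call. = FALSE)
  n_rows <- n - (order - 1L) * delay
  emb <- sapply(0:(order - 1L), function(j) x[seq_len(n_rows) + j * delay])
  s <- svd(emb, nu = 0L, nv = 0L)$d
  s <- s[s >= 1e-12 * max(s, 1e-300)]  # retain the main energy
  if (sum(s) == 0) {
    return(rep(1 / order, order))
  }
  s / sum(s)
}

#' SVD entropy
#'
#' Shannon entropy of the normalised singular values of the delay-embedding
#' matrix of `x`; lies in [0, ln(order)].
#'
#' @param x numeric series.
#' @param order embedding order (>= 2).
#' @param delay embedding delay.
#' @return scalar in [0, ln(order)].
#' @export
svd_entropy <- function(x, order = 3L, delay = 1L) {
  p <- svd_probs(x, order, delay)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' SVD Fisher information
#'
#' Sum over adjacent singular-value probabilities of
#' (p_i - p_(i-1))^2 / (p_i + eps); measures local variation and
#' orderliness of the singular spectrum.
#'
#' @inheritParams svd_entropy
#' @param eps small constant preventing division by zero.
#' @return nonnegative scalar.
#' @export
svd_fisher_info <- function(x, order = 3L, delay = 1L, eps = 1e-8) {
  svd_fisher_from_probs(svd_probs(x, order, delay), eps)
}

#' SVD Fisher information from a probability spectrum
#'
#' The arithmetic core of [svd_fisher_info()], exposed so a known singular
#' spectrum can be evaluated directly.
#'
#' @param p normalised singular-value probabilities.
#' @param eps small constant preventing division by zero.
#' @return nonnegative scalar.
#' @export
svd_fisher_from_probs <- function(p, eps = 1e-8) {
  if (length(p) < 2L) {
    return(0)
  }
  sum(diff(p)^2 / (p[-1L] + eps))
}

# ---- spectral helpers -----------------------------------------------------

# Welch power spectral density: mean periodogram over Hann-windowed 50%-
# overlapping segments. Returns freq (Hz) and power density.
welch_psd <- function(x, fs, nperseg = 256L) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  hop <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1L) / (nperseg - 1L))
  norm <- sum(win^2) * fs
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / norm
    acc <- acc + sp[seq_len(nfreq)]
  }
  p <- acc / length(starts)
  # one-sided correction (all but DC/Nyquist carry doubled power)
  if (nfreq > 2L) p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  list(freq = seq(0, fs / 2, length.out = nfreq), power = p)
}

# db4 (4 vanishing moments, 8 taps) orthonormal wavelet decomposition;
# returns relative energy of detail levels 1..levels. Signal is extended
# periodically; halts early (zero-padding the remaining levels) if the
# approximation becomes shorter than the filter.
db4_energies <- function(x, levels = 6L) {
  h <- c(0.2303778133088964, 0.7148465705529154, 0.6308807679298587,
         -0.02798376941685985, -0.18703481171909309, 0.030841381835560764,
         0.03288301166688520, -0.010597401785069032)
  g <- rev(h) * (-1)^(seq_along(h) - 1L)  # high-pass (quadrature mirror)
  energies <- numeric(levels)
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) < length(h)) break
    n <- length(a)
    ext <- c(a, a[seq_len(length(h))])  # periodic extension
    lo <- stats::filter(ext, rev(h), sides = 1L)
    hi <- stats::filter(ext, rev(g), sides = 1L)
    keep <- seq(length(h), n + length(h) - 1L, by = 2L)
    keep <- keep[keep <= length(lo)]
    d <- hi[keep]
    a <- lo[keep]
    energies[l] <- sum(d^2, na.rm = TRUE)
  }
  tot <- sum(energies) + sum(a^2, na.rm = TRUE)
  if (tot <= 0) {
    return(numeric(levels))
  }
  energies / tot
}

# ---- per-channel feature computation --------------------------------------

#' Names of the default 40-feature statistical manifest
#'
#' @return character vector of length 40, in extraction order.
#' @export
stat_feature_names <- function() {
  c("std", "ptp", "skewness", "kurtosis", "rms",
    "q25", "q50", "q75",
    "hurst", "app_entropy", "samp_entropy", "decorr_time_s",
    "pow_delta", "pow_theta", "pow_alpha", "pow_beta", "pow_gamma",
    "hjorth_mobility", "hjorth_complexity",
    "hjorth_mobility_spec", "hjorth_complexity_spec",
    "higuchi_fd", "katz_fd", "zero_cross_rate", "line_length",
    "spectral_slope", "spectral_entropy", "spectral_edge_hz",
    "svd_entropy", "svd_fisher_info",
    "energy_delta", "energy_theta", "energy_alpha", "energy_beta",
    paste0("wav_db4_d", 1:6))
}

higuchi_fd <- function(x, kmax = 10L) {
  n <- length(x)
  kmax <- min(kmax, n %/% 2L)
  if (kmax < 2L) {
    return(1)
  }
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) {
        lm[m] <- 0
        next
      }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (k * (length(idx) - 1L) * k)
    }
    lk[k] <- mean(lm)
  }
  ok <- lk > 0
  if (sum(ok) < 2L) {
    return(1)
  }
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[ok])), log(lk[ok]))
  unname(fit$coefficients[2L])
}

katz_fd <- function(x) {
  n <- length(x)
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1L])^2))
  if (L <= 0 || d <= 0) {
    return(1)
  }
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

# All 40 manifest features for a single channel.
channel_stat_features <- function(x, fs, entropy_params) {
  nm <- stat_feature_names()
  out <- stats::setNames(numeric(length(nm)), nm)
  n <- length(x)
  sdx <- stats::sd(x)

  out["std"] <- sdx
  out["ptp"] <- max(x) - min(x)
  out["skewness"] <- if (sdx > 0) e1071::skewness(x) else 0
  out["kurtosis"] <- if (sdx > 0) e1071::kurtosis(x) else 0
  out["rms"] <- sqrt(mean(x^2))
  out[c("q25", "q50", "q75")] <- stats::quantile(x, c(0.25, 0.5, 0.75),
                                                 names = FALSE)

  # nonlinear block on a capped prefix (quadratic-cost estimators stabilise
  # well below full record length)
  cap <- min(n, entropy_params$max_samples)
  xe <- x[seq_len(cap)]
  out["hurst"] <- if (sdx > 0 && cap >= 64L) {
    suppressWarnings(
      pracma::hurstexp(xe, display = FALSE)$Hs
    )
  } else 0.5
  m <- entropy_params$m
  r <- entropy_params$r
  if (sdx == 0) {
    out["app_entropy"] <- 0
    out["samp_entropy"] <- 0
  } else {
    out["app_entropy"] <- approx_entropy(xe, m, r)
    se <- sample_entropy(xe, m, r)
    # undefined (no recurrences) -> conservative upper bound for the count
    if (!is.finite(se)) se <- log((cap - m) * (cap - m - 1))
    out["samp_entropy"] <- se
  }

  # decorrelation time: first zero crossing of the autocorrelation (seconds)
  if (sdx > 0) {
    ac <- stats::acf(x, lag.max = min(n - 1L, fs), plot = FALSE)$acf[, 1L, 1L]
    zc <- which(ac <= 0)[1L]
    out["decorr_time_s"] <- if (is.na(zc)) length(ac) / fs else (zc - 1L) / fs
  }

  # spectral block
  psd <- welch_psd(x, fs)
  p <- psd$power
  f <- psd$freq
  tot <- sum(p)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, 45))
  for (b in names(bands)) {
    sel <- f >= bands[[b]][1L] & f < bands[[b]][2L]
    out[paste0("pow_", b)] <- if (tot > 0) sum(p[sel]) / tot else 0
  }
  if (tot > 0) {
    m0 <- tot
    m2 <- sum(f^2 * p)
    m4 <- sum(f^4 * p)
    out["hjorth_mobility_spec"] <- sqrt(m2 / m0)
    out["hjorth_complexity_spec"] <- if (m2 > 0) sqrt(m4 / m2) / sqrt(m2 / m0) else 0
    pn <- p[p > 0] / tot
    out["spectral_entropy"] <- -sum(pn * log(pn))
    cum <- cumsum(p) / tot
    out["spectral_edge_hz"] <- f[which(cum >= 0.95)[1L]]
    sel <- f >= 1 & f <= 40 & p > 0
    if (sum(sel) >= 3L) {
      fit <- stats::lm.fit(cbind(1, log(f[sel])), log(p[sel]))
      out["spectral_slope"] <- unname(fit$coefficients[2L])
    }
  }

  # Hjorth time-domain parameters
  if (sdx > 0) {
    d1 <- diff(x)
    d2 <- diff(d1)
    v0 <- stats::var(x)
    v1 <- stats::var(d1)
    v2 <- stats::var(d2)
    mob <- sqrt(v1 / v0)
    out["hjorth_mobility"] <- mob
    out["hjorth_complexity"] <- if (v1 > 0) sqrt(v2 / v1) / mob else 0
  }

  out["higuchi_fd"] <- if (sdx > 0) higuchi_fd(xe) else 1
  out["katz_fd"] <- if (sdx > 0) katz_fd(x) else 1
  xc <- x - mean(x)
  out["zero_cross_rate"] <- sum(diff(sign(xc[xc != 0])) != 0) / (n / fs)
  out["line_length"] <- sum(abs(diff(x)))

  if (sdx > 0) {
    out["svd_entropy"] <- svd_entropy(xe, entropy_params$svd_order,
                                      entropy_params$svd_delay)
    out["svd_fisher_info"] <- svd_fisher_info(xe, entropy_params$svd_order,
                                              entropy_params$svd_delay,
                                              entropy_params$eps)
  }

  # absolute band energies (band power x total power), delta..beta
  for (b in c("delta", "theta", "alpha", "beta")) {
    sel <- f >= bands[[b]][1L] & f < bands[[b]][2L]
    out[paste0("energy_", b)] <- sum(p[sel])
  }

  out[paste0("wav_db4_d", 1:6)] <- db4_energies(x, 6L)

  out[!is.finite(out)] <- 0
  out
}

#' Entropy / embedding parameter bundle
#'
#' @param m sample/approximate entropy embedding dimension.
#' @param r tolerance as a fraction of the series SD.
#' @param svd_order,svd_delay delay-embedding parameters for the SVD features.
#' @param eps division guard for the Fisher information.
#' @param max_samples cap on series length for the quadratic-cost estimators
#'   (sample/approximate entropy, Hurst).
#' @return a list of parameters.
#' @export
entropy_params <- function(m = 2L, r = 0.2, svd_order = 3L, svd_delay = 1L,
                           eps = 1e-8, max_samples = 1024L) {
  stopifnot(m >= 1L, r > 0, svd_order >= 2L, svd_delay >= 1L)
  list(m = as.integer(m), r = r, svd_order = as.integer(svd_order),
       svd_delay = as.integer(svd_delay), eps = eps,
       max_samples = as.integer(max_samples))
}

#' Extract the statistical feature block from a record
#'
#' Computes the 40-feature manifest (see [stat_feature_names()]) per channel,
#' then aggregates across channels into one named vector per record.
#'
#' @param rec a preprocessed `eeg_record`.
#' @param params an [entropy_params()] bundle.
#' @param aggregate `"mean"` (default), `"median"`, or `"none"` (returns the
#'   channels x features matrix).
#' @return named numeric vector of length 40 (or a matrix when
#'   `aggregate = "none"`).
#' @export
stat_features <- function(rec, params = entropy_params(),
                          aggregate = c("mean", "median", "none")) {
  aggregate <- match.arg(aggregate)
  min_len <- max(params$m + 2L,
                 (params$svd_order - 1L) * params$svd_delay + 2L, 16L)
  if (ncol(rec$data) < min_len) {
    stop(sprintf(
      "record too short (%d samples) for entropy/embedding features (need >= %d)",
      ncol(rec$data), min_len
    ), call. = FALSE)
  }
  per_ch <- t(apply(rec$data, 1L, channel_stat_features, fs = rec$fs_hz,
                    entropy_params = params))
  switch(aggregate,
    mean = colMeans(per_ch),
    median = apply(per_ch, 2L, stats::median),
    none = per_ch
  )
}

#' Gini-importance feature selection
#'
#' Fits a random forest on the training feature matrix, normalises the mean
#' decrease in Gini impurity to sum to 1, and drops features whose normalised
#' importance falls below `threshold`. The three information-theoretic
#' features (sample entropy, SVD entropy, SVD Fisher information) are always
#' retained when present, mirroring their addition after selection.
#'
#' @param feature_matrix numeric matrix, rows = samples, named columns.
#' @param labels class labels (2 classes required).
#' @param threshold importance cutoff (normalised scale).
#' @param seed integer seed (forest fitting is randomised).
#' @param always_keep feature names exempt from the cutoff.
#' @param ntree number of trees.
#' @return list with `selected` (names), `mask` (logical), `importance`
#'   (normalised, sums to 1).
#' @export
gini_select <- function(feature_matrix, labels, threshold = 0.002, seed = 1L,
                        always_keep = c("samp_entropy", "svd_entropy",
                                        "svd_fisher_info"),
                        ntree = 500L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) {
    stop("`labels` must contain at least 2 classes", call. = FALSE)
  }
  if (nrow(feature_matrix) < 10L) {
    stop("need at least 10 samples for importance estimation", call. = FALSE)
  }
  imp <- with_seed(seed, {
    rf <- randomForest::randomForest(x = feature_matrix, y = labels,
                                     ntree = ntree)
    randomForest::importance(rf, type = 2L)[, 1L]
  })
  imp <- imp / max(sum(imp), 1e-300)
  mask <- imp >= threshold
  mask[names(imp) %in% always_keep] <- TRUE
  list(selected = names(imp)[mask], mask = mask, importance = imp)
}
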