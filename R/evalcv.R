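# Subject-independent cross-validation, classification metrics, and
# microstate group comparison.

#' Subject-independent stratified k-fold plan
#'
#' Partitions subjects (not samples) into k disjoint test folds, stratified
#' by group; within each fold the remaining subjects are split 80/20 into
#' training and validation sets, again by subject, so no subject ever
#' appears on both sides of any boundary.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param labels group label per subject (2 classes required).
#' @param k number of folds.
#' @param seed integer seed.
#' @param validation_fraction fraction of non-test subjects used for
#'   validation.
#' @return list of class `fold_plan`; element i has `test`, `train`, `val`
#'   (disjoint subject-id vectors).
#' @export
make_subject_folds <- function(subject_ids, labels, k = 5L, seed = 1L,
                               validation_fraction = 0.2) {
  if (anyDuplicated(subject_ids)) {
    stop("`subject_ids` must be unique (one row per subject)", call. = FALSE)
  }
  if (length(subject_ids) < k) stop("fewer subjects than folds", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  folds <- vector("list", k)
  assign_fold <- with_seed(seed, {
    out <- integer(length(subject_ids))
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      out[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
    }
    out
  })
  for (f in seq_len(k)) {
    test <- subject_ids[assign_fold == f]
    rest <- subject_ids[assign_fold != f]
    rest_lab <- labels[assign_fold != f]
    val <- with_seed(derive_seed(seed, 30L + f), {
      unlist(lapply(unique(rest_lab), function(cl) {
        s <- rest[rest_lab == cl]
        sample(s, max(1L, round(validation_fraction * length(s))))
      }))
    })
    folds[[f]] <- list(test = test, val = val, train = setdiff(rest, val))
  }
  # partition law: every subject in exactly one test fold, never leaked
  stopifnot(setequal(unlist(lapply(folds, `[[`, "test")), subject_ids))
  for (f in folds) {
    stopifnot(length(intersect(f$test, c(f$train, f$val))) == 0L,
              length(intersect(f$train, f$val)) == 0L)
  }
  structure(folds, class = "fold_plan")
}

#' Confusion counts from labels and predictions
#'
#' @param y_true,y_pred 0/1 vectors (1 = case/positive).
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and Cohen's kappa
#' (kappa = (p_o - p_e) / (1 - p_e) with p_e from the marginal products).
#' Ratios with a zero denominator are returned as `NA` (flagged) rather
#' than silently set to 0.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN`.
#' @return named list: accuracy, precision, recall, f1, kappa.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop("empty confusion table", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  acc <- (TP + TN) / n
  prec <- safe_div(TP, TP + FP)
  rec <- safe_div(TP, TP + FN)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  p_o <- acc
  p_e <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1, kappa = kappa)
}

#' RMSE between predicted probabilities and labels
#'
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities in [0, 1].
#' @return sqrt(mean((y - p)^2)).
#' @export
rmse_prob <- function(y_true, y_prob) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_prob)) stop("length mismatch", call. = FALSE)
  if (any(y_prob < 0 | y_prob > 1)) stop("probabilities outside [0,1]", call. = FALSE)
  sqrt(mean((y_true - y_prob)^2))
}

#' Per-feature group comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between the
#' case and control groups, reporting the effect direction (sign of the
#' case-minus-control mean difference) and p-value.
#'
#' @param feature_table numeric matrix, rows = subjects, named columns.
#' @param group_labels `"case"` / `"control"` per row.
#' @param alpha significance level.
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg correction.
#' @return data.frame: feature, direction (+1 case > control / -1 / 0),
#'   p, significant.
#' @export
group_compare <- function(feature_table, group_labels, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  case <- group_labels == "case"
  ctrl <- group_labels == "control"
  if (sum(case) < 2L || sum(ctrl) < 2L) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  p <- numeric(ncol(feature_table))
  dir <- integer(ncol(feature_table))
  for (j in seq_len(ncol(feature_table))) {
    xc <- feature_table[case, j]
    xk <- feature_table[ctrl, j]
    dir[j] <- as.integer(sign(mean(xc) - mean(xk)))
    p[j] <- if (stats::sd(c(xc, xk)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(xc, xk, exact = FALSE)$p.value)
  }
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(
    feature = colnames(feature_table) %||% paste0("f", seq_along(p)),
    direction = dir, p = p, significant = p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Subject-independent cross-validated evaluation
#'
#' The end-to-end evaluation protocol: for each fold a fusion normaliser is
#' fitted on the training subjects only, the training split is augmented
#' 3x, the network is trained with the feedback loop (validation subjects
#' supply the reward signal), and the held-out test subjects are scored.
#'
#' @param micro,stat microstate and statistical feature matrices (rows
#'   aligned with `subject_ids`).
#' @param labels 0/1 (or case/control) label per row.
#' @param subject_ids subject id per row; ids may repeat (one row per
#'   epoch/window), in which case folds are still split by subject and
#'   metrics are computed per row.
#' @param k folds.
#' @param config optional [cnngru_config()] (default: package architecture
#'   at the fused dimension).
#' @param feedback a [feedback_config()].
#' @param augment use the 3x augmentation on training folds.
#' @param seed integer seed.
#' @param verbose print per-fold progress.
#' @return list of class `cv_result`: per-fold metrics data.frame, pooled
#'   confusion counts, aggregate mean/SD metrics, predictions, fold plan.
#' @export
run_cv <- function(micro, stat, labels, subject_ids, k = 5L, config = NULL,
                   feedback = feedback_config(), augment = TRUE, seed = 1L,
                   verbose = FALSE) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.integer(factor(labels, levels = c("control", "case"))) - 1L
  }
  usub <- unique(subject_ids)
  plan <- make_subject_folds(usub, labels[match(usub, subject_ids)], k = k,
                             seed = derive_seed(seed, 20L))
  fold_metrics <- vector("list", k)
  preds <- data.frame(subject_id = character(0), y = integer(0),
                      prob = numeric(0), fold = integer(0))
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k)) {
    fold <- plan[[f]]
    idx <- function(ids) which(subject_ids %in% ids)
    fuse_block <- function(ids, normalizer = NULL) {
      fuse_features(micro[idx(ids), , drop = FALSE],
                    stat[idx(ids), , drop = FALSE], normalizer)
    }
    norm <- fit_normalizer(fuse_block(fold$train)$x)
    x_tr <- fuse_block(fold$train, norm)$x
    x_va <- fuse_block(fold$val, norm)$x
    x_te <- fuse_block(fold$test, norm)$x
    y_tr <- labels[idx(fold$train)]
    y_va <- labels[idx(fold$val)]
    y_te <- labels[idx(fold$test)]
    cfg <- config %||% cnngru_config(input_steps = ncol(x_tr))
    if (cfg$input_steps != ncol(x_tr)) {
      cfg$input_steps <- ncol(x_tr)
    }
    fit <- train_feedback(x_tr, y_tr, x_va, y_va, net_cfg = cfg,
                          fb_cfg = feedback, augment = augment,
                          seed = derive_seed(seed, 100L + f))
    prob <- cnngru_forward(fit$params, x_te, cfg, training = FALSE)$prob
    pred <- as.integer(prob >= 0.5)
    cnt <- confusion_counts(y_te, pred)
    m <- classification_metrics(cnt)
    m$rmse <- rmse_prob(y_te, prob)
    fold_metrics[[f]] <- data.frame(fold = f, as.data.frame(m))
    pooled <- Map(`+`, pooled, cnt)
    preds <- rbind(preds, data.frame(subject_id = subject_ids[idx(fold$test)],
                                     y = y_te, prob = prob, fold = f))
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.3f (n_test = %d)",
                      f, k, m$accuracy, length(y_te)))
    }
  }
  fm <- do.call(rbind, fold_metrics)
  agg <- data.frame(
    metric = setdiff(names(fm), "fold"),
    mean = vapply(setdiff(names(fm), "fold"), function(c) mean(fm[[c]]), 0),
    sd = vapply(setdiff(names(fm), "fold"), function(c) stats::sd(fm[[c]]), 0)
  )
  structure(
    list(fold_metrics = fm, aggregate = agg, pooled_counts = pooled,
         pooled_metrics = classification_metrics(pooled),
         predictions = preds, plan = plan, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold subject-independent CV, %d rows from %d subjects\n",
              length(x$plan), nrow(x$predictions),
              length(unique(x$predictions$subject_id))))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}
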