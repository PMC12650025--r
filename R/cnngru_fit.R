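# User-facing model interface in the classic R modelling idiom: one fitting
# function returning a classed object with print / summary / predict / plot
# methods.

#' Fit the CNN-GRU classifier on fused feature vectors
#'
#' The main fitting function. Splits off a validation fraction (by subject
#' when `subjects` is given), optionally expands the training split 3x with
#' noise and cutout copies, and trains with the performance-feedback loop.
#'
#' @param x numeric matrix of fused feature vectors (rows = samples).
#' @param y labels: 0/1 vector or a factor whose second level is the case
#'   class.
#' @param subjects optional subject id per row; the validation split is
#'   then subject-disjoint.
#' @param validation_fraction fraction of samples (or subjects) held out
#'   for validation feedback.
#' @param config a [cnngru_config()]; defaults to the package architecture
#'   at `input_steps = ncol(x)`.
#' @param feedback a [feedback_config()].
#' @param augment expand the training split via [build_augmented_set()].
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return object of class `cnngru`: the fitted parameters, configuration,
#'   training log and validation summary.
#' @export
cnngru <- function(x, y, subjects = NULL, validation_fraction = 0.2,
                   config = NULL, feedback = feedback_config(),
                   augment = TRUE, seed = 1L, verbose = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(as.factor(y)) - 1L
  }
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  if (length(y) != nrow(x)) stop("`x` rows and `y` length differ", call. = FALSE)
  if (is.null(config)) config <- cnngru_config(input_steps = ncol(x))

  idx_val <- with_seed(derive_seed(seed, 7L), {
    if (is.null(subjects)) {
      # stratified sample-level holdout
      unlist(lapply(unique(y), function(cl) {
        i <- which(y == cl)
        sample(i, max(1L, round(validation_fraction * length(i))))
      }))
    } else {
      subj <- unique(subjects)
      subj_y <- vapply(subj, function(s) y[match(s, subjects)], 0)
      hold <- unlist(lapply(unique(subj_y), function(cl) {
        s <- subj[subj_y == cl]
        sample(s, max(1L, round(validation_fraction * length(s))))
      }))
      which(subjects %in% hold)
    }
  })
  fit <- train_feedback(
    x[-idx_val, , drop = FALSE], y[-idx_val],
    x[idx_val, , drop = FALSE], y[idx_val],
    net_cfg = config, fb_cfg = feedback, augment = augment,
    seed = seed, verbose = verbose
  )
  structure(
    list(params = fit$params, config = fit$config, log = fit$log,
         best_val_acc = fit$best_val_acc, hparams = fit$hparams,
         n_train = nrow(x) - length(idx_val), n_val = length(idx_val),
         feature_names = colnames(x), seed = seed),
    class = "cnngru"
  )
}

#' Predict method for fitted CNN-GRU models
#'
#' @param object a fitted `cnngru` model.
#' @param newdata matrix of feature vectors (same columns as training).
#' @param type `"prob"` for case probabilities, `"class"` for 0/1 labels.
#' @param ... unused.
#' @return numeric vector of probabilities or integer labels.
#' @export
predict.cnngru <- function(object, newdata,
                           type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  prob <- cnngru_forward(object$params, newdata, object$config,
                         training = FALSE)$prob
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' @export
print.cnngru <- function(x, ...) {
  cat(sprintf(
    "<cnngru> %d-step input, %s trainable parameters\n",
    x$config$input_steps,
    format(cnngru_count_params(x$config), big.mark = ",")
  ))
  cat(sprintf("  trained %d epochs on %d samples (best val acc %.3f)\n",
              nrow(x$log), x$n_train, x$best_val_acc))
  invisible(x)
}

#' @export
summary.cnngru <- function(object, ...) {
  print(object)
  lg <- object$log
  cat(sprintf("  final loss weight w = %.3f; events: %s\n",
              lg$w[nrow(lg)],
              if (any(lg$event != "")) paste(table(lg$event[lg$event != ""]),
                                             names(table(lg$event[lg$event != ""])),
                                             collapse = ", ")
              else "none"))
  cat(sprintf("  hyperparameters: dropout %.2f, lr %g, l2 %g\n",
              object$hparams$dropout, object$hparams$lr, object$hparams$l2))
  invisible(object$log)
}

#' Training-curve plot for fitted models
#'
#' @param x a fitted `cnngru` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cnngru <- function(x, ...) {
  lg <- x$log
  graphics::plot(lg$epoch, lg$val_acc, type = "l", col = "navy",
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = c(0, 1), ...)
  graphics::lines(lg$epoch, pmin(lg$val_loss, 1), col = "firebrick", lty = 2)
  ev <- which(lg$event != "")
  if (length(ev)) graphics::abline(v = ev, col = "grey70", lty = 3)
  graphics::legend("bottomright", c("val accuracy", "val loss (capped)"),
                   col = c("navy", "firebrick"), lty = 1:2, bty = "n")
  invisible(x)
}
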