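# Performance-feedback training loop and feature-level augmentation.
#
# After every epoch a reward R = val_accuracy - val_loss is computed from the
# validation split; the loss weight w is nudged by eta * R and clipped to
# [0.5, 2.0]. When validation accuracy fails to improve on the running best
# by more than a tolerance for T consecutive epochs, the loop first applies
# a perturbation reset (w ~ U(0.7, 1.3)); if stagnation persists for another
# T epochs it resamples dropout / learning rate / L2 from fixed grids and
# reinitialises the network with a fresh seed. Training data are expanded
# 3x by Gaussian-noise and cutout copies before fitting.

#' Feedback-loop configuration
#'
#' @param eta step size of the loss-weight update.
#' @param epsilon improvement tolerance on validation accuracy.
#' @param t_stag consecutive non-improving epochs before a trigger.
#' @param w_init initial loss weight.
#' @param w_min,w_max clipping bounds for the loss weight.
#' @param max_epochs training epoch cap.
#' @param batch_size minibatch size.
#' @param lr_init initial Adam learning rate.
#' @param l2_init initial L2 coefficient.
#' @param patience early-stopping patience: training ends once the best
#'   validation accuracy has not improved for this many epochs; the counter
#'   restarts after a reinitialisation (a reinitialised network is a new
#'   training trajectory). `Inf` disables early stopping.
#' @param dropout_grid,lr_grid,l2_grid resampling grids.
#' @return list of class `feedback_config`.
#' @export
feedback_config <- function(eta = 0.1, epsilon = 0.001, t_stag = 10L,
                            w_init = 1, w_min = 0.5, w_max = 2,
                            max_epochs = 500L, batch_size = 64L,
                            lr_init = 1e-4, l2_init = 1e-4,
                            patience = 40L, max_reinits = 4L,
                            dropout_grid = c(0.4, 0.5, 0.6, 0.7),
                            lr_grid = c(1e-3, 1e-4, 5e-5),
                            l2_grid = c(1e-3, 5e-4, 1e-4)) {
  structure(
    list(eta = eta, epsilon = epsilon, t_stag = as.integer(t_stag),
         w_init = w_init, w_min = w_min, w_max = w_max,
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         lr_init = lr_init, l2_init = l2_init, patience = patience,
         max_reinits = as.integer(max_reinits),
         dropout_grid = dropout_grid, lr_grid = lr_grid, l2_grid = l2_grid),
    class = "feedback_config"
  )
}

#' Reward signal from validation performance
#'
#' R = validation accuracy - validation loss (may be negative and is
#' unbounded below).
#'
#' @param val_acc validation accuracy in [0, 1].
#' @param val_loss validation loss (>= 0, unweighted BCE).
#' @return scalar reward.
#' @export
compute_reward <- function(val_acc, val_loss) {
  if (val_acc < 0 || val_acc > 1) stop("`val_acc` must lie in [0,1]", call. = FALSE)
  if (val_loss < 0) stop("`val_loss` must be >= 0", call. = FALSE)
  val_acc - val_loss
}

#' Update the loss weight
#'
#' w <- clip(w + eta * R, w_min, w_max).
#'
#' @param w current loss weight.
#' @param reward reward signal R.
#' @param eta update step.
#' @param w_min,w_max clip bounds.
#' @return updated weight within the bounds.
#' @export
update_loss_weight <- function(w, reward, eta = 0.1, w_min = 0.5, w_max = 2) {
  min(max(w + eta * reward, w_min), w_max)
}

#' Weighted binary cross-entropy
#'
#' w * mean BCE; predictions are clamped to [1e-7, 1 - 1e-7] before the log.
#'
#' @param y_true 0/1 labels.
#' @param y_pred predicted probabilities.
#' @param w loss weight.
#' @return scalar loss.
#' @export
weighted_bce <- function(y_true, y_pred, w = 1) {
  p <- pmin(pmax(y_pred, 1e-7), 1 - 1e-7)
  w * mean(-y_true * log(p) - (1 - y_true) * log(1 - p))
}

#' Stagnation bookkeeping
#'
#' Counts consecutive epochs where validation accuracy fails to exceed the
#' running best by more than `epsilon`; improvement resets the counter and
#' updates the best. A trigger fires when the counter reaches `t_stag`.
#'
#' @param state list with `best_val_acc` and `stagnation_count` (use
#'   `list(best_val_acc = -Inf, stagnation_count = 0L)` to start).
#' @param val_acc this epoch's validation accuracy.
#' @param epsilon improvement tolerance.
#' @param t_stag trigger threshold.
#' @return state with updated fields plus `triggered` (logical); the counter
#'   resets to 0 when a trigger fires.
#' @export
check_stagnation <- function(state, val_acc, epsilon = 0.001, t_stag = 10L) {
  if (val_acc > state$best_val_acc + epsilon) {
    state$best_val_acc <- val_acc
    state$stagnation_count <- 0L
    state$triggered <- FALSE
  } else {
    if (val_acc > state$best_val_acc) state$best_val_acc <- val_acc
    state$stagnation_count <- state$stagnation_count + 1L
    state$triggered <- state$stagnation_count >= t_stag
    if (state$triggered) state$stagnation_count <- 0L
  }
  state
}

#' Resample training hyperparameters from the preset grids
#'
#' Uniform draws from dropout {0.4, 0.5, 0.6, 0.7},
#' learning rate {1e-3, 1e-4, 5e-5}, and L2 {1e-3, 5e-4, 1e-4}.
#'
#' @param seed integer seed.
#' @param cfg a [feedback_config()] supplying the grids.
#' @return list with `dropout`, `lr`, `l2`.
#' @export
resample_hparams <- function(seed = NULL, cfg = feedback_config()) {
  with_seed(seed, list(
    dropout = sample(cfg$dropout_grid, 1L),
    lr = sample(cfg$lr_grid, 1L),
    l2 = sample(cfg$l2_grid, 1L)
  ))
}

#' Perturbation reset of the loss weight
#'
#' Draws w ~ U(0.7, 1.3), applied when loss-weight updates alone fail to
#' improve validation accuracy for `t_stag` rounds.
#'
#' @param seed integer seed.
#' @return scalar in [0.7, 1.3].
#' @export
perturb_loss_weight <- function(seed = NULL) {
  with_seed(seed, stats::runif(1L, 0.7, 1.3))
}

#' Gaussian-noise augmentation
#'
#' Adds i.i.d. N(0, sigma^2) noise to every entry of the feature matrix.
#'
#' @param x numeric matrix or vector.
#' @param sigma noise SD (default 0.05, on the z-scored feature scale).
#' @param seed integer seed.
#' @return perturbed copy, same shape.
#' @export
augment_noise <- function(x, sigma = 0.05, seed = NULL) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) {
    return(x)
  }
  with_seed(seed, x + stats::rnorm(length(x), sd = sigma))
}

#' Cutout augmentation
#'
#' Zeroes one contiguous segment of length round(fraction * T) (at least 1)
#' starting at a uniformly random position of each feature vector.
#'
#' @param x numeric matrix (rows are masked independently) or vector.
#' @param fraction masked fraction of the vector length (default 0.1).
#' @param seed integer seed.
#' @return masked copy, same shape.
#' @export
augment_cutout <- function(x, fraction = 0.1, seed = NULL) {
  if (fraction < 0 || fraction >= 1) {
    stop("`fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) {
    return(x)
  }
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  Tn <- ncol(x)
  L <- max(1L, round(fraction * Tn))
  with_seed(seed, {
    for (i in seq_len(nrow(x))) {
      s <- sample.int(Tn - L + 1L, 1L)
      x[i, s:(s + L - 1L)] <- 0
    }
  })
  if (vec) drop(x) else x
}

#' Build the 3x augmented training set
#'
#' Concatenates the original samples with one Gaussian-noise copy and one
#' cutout copy, replicating the labels: N training samples become exactly
#' 3N. Applied to the training split only -- never to validation or test
#' data.
#'
#' @param x training feature matrix (rows = samples).
#' @param y labels.
#' @param sigma noise SD.
#' @param fraction cutout fraction.
#' @param seed integer seed.
#' @return list with `x` (3N rows; first N identical to the input) and `y`.
#' @export
build_augmented_set <- function(x, y, sigma = 0.05, fraction = 0.1,
                                seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(x) != length(y)) stop("`x` rows and `y` length differ", call. = FALSE)
  xn <- augment_noise(x, sigma, seed = derive_seed(seed, 1L))
  xc <- augment_cutout(x, fraction, seed = derive_seed(seed, 2L))
  list(x = rbind(x, xn, xc), y = c(y, y, y))
}

# Evaluate accuracy and unweighted BCE on a split (inference mode).
evaluate_split <- function(params, x, y, cfg) {
  prob <- cnngru_forward(params, x, cfg, training = FALSE)$prob
  list(acc = mean((prob >= 0.5) == (y == 1)),
       loss = weighted_bce(y, prob, w = 1),
       prob = prob)
}

#' Train the network with the performance-feedback loop
#'
#' Fits the CNN-GRU network on the (already augmented or raw) training
#' split with Adam, evaluating the validation split each epoch to drive the
#' reward-weighted loss, stagnation-triggered perturbation / resampling /
#' reinitialisation, and snapshotting of the best validation model. The
#' returned parameters are the best-validation-accuracy snapshot.
#'
#' @param x_train,y_train training features (rows) and 0/1 labels.
#' @param x_val,y_val validation split (never augmented).
#' @param net_cfg a [cnngru_config()]; its `input_steps` must equal
#'   `ncol(x_train)`.
#' @param fb_cfg a [feedback_config()].
#' @param augment logical: expand the training split 3x via
#'   [build_augmented_set()].
#' @param seed integer seed controlling all stochasticity (shuffling,
#'   dropout, initialisation, resampling).
#' @param verbose print a line per epoch.
#' @return list of class `feedback_fit`: `params`, `config`, `log`
#'   (per-epoch data.frame: epoch, train_loss, val_acc, val_loss, reward, w,
#'   event), `best_val_acc`, `hparams`.
#' @export
train_feedback <- function(x_train, y_train, x_val, y_val, net_cfg,
                           fb_cfg = feedback_config(), augment = TRUE,
                           seed = 1L, verbose = FALSE) {
  if (length(unique(y_train)) < 2L) {
    stop("training split holds a single class", call. = FALSE)
  }
  if (augment) {
    aug <- build_augmented_set(x_train, y_train, seed = derive_seed(seed, 3L))
    x_train <- aug$x
    y_train <- aug$y
  }
  hp <- list(dropout = net_cfg$dropout_rate, lr = fb_cfg$lr_init,
             l2 = fb_cfg$l2_init)
  reinit_counter <- 0L
  params <- cnngru_init(net_cfg, seed = derive_seed(seed, 4L))
  opt <- adam_init(params)
  w <- fb_cfg$w_init
  stag <- list(best_val_acc = -Inf, stagnation_count = 0L)
  pending <- "perturb"   # first trigger perturbs w, a repeat reinitialises
  best <- list(acc = -Inf, loss = Inf, params = params)
  since_best <- 0L
  n <- nrow(x_train)
  log_rows <- vector("list", fb_cfg$max_epochs)

  with_seed(derive_seed(seed, 5L), {
    for (epoch in seq_len(fb_cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_b <- 0L
      for (start in seq(1L, n, by = fb_cfg$batch_size)) {
        idx <- ord[start:min(start + fb_cfg$batch_size - 1L, n)]
        fw <- cnngru_forward(params, x_train[idx, , drop = FALSE], net_cfg,
                             training = TRUE, keep_cache = TRUE)
        bn <- attr(params, "bn_state")
        attr(params, "bn_state") <- fw$bn_update %||% bn
        bk <- cnngru_backward(params, fw$cache, y_train[idx], net_cfg,
                              loss_weight = w, l2 = hp$l2)
        upd <- adam_step(params, bk$grads, opt, lr = hp$lr)
        params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + bk$loss
        n_b <- n_b + 1L
      }
      ev <- evaluate_split(params, x_val, y_val, net_cfg)
      reward <- compute_reward(ev$acc, ev$loss)
      w <- update_loss_weight(w, reward, fb_cfg$eta, fb_cfg$w_min,
                              fb_cfg$w_max)
      improved <- ev$acc > best$acc
      since_best <- if (improved) 0L else since_best + 1L
      if (improved || (ev$acc == best$acc && ev$loss < best$loss)) {
        best <- list(acc = ev$acc, loss = ev$loss, params = params)
      }
      stag <- check_stagnation(stag, ev$acc, fb_cfg$epsilon, fb_cfg$t_stag)
      event <- ""
      if (stag$triggered && reinit_counter >= fb_cfg$max_reinits) {
        event <- "stagnant"
      } else if (stag$triggered) {
        if (pending == "perturb") {
          w <- perturb_loss_weight(seed = NULL)   # draw from the loop RNG
          event <- "perturb_w"
          pending <- "reinit"
        } else {
          reinit_counter <- reinit_counter + 1L
          hp <- resample_hparams(seed = NULL, cfg = fb_cfg)
          net_cfg$dropout_rate <- hp$dropout
          params <- cnngru_init(net_cfg,
                                seed = derive_seed(seed, 50L + reinit_counter))
          opt <- adam_init(params)
          event <- "reinit"
          pending <- "perturb"
          since_best <- 0L    # a reinitialised model is a new trajectory
        }
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n_b, val_acc = ev$acc,
        val_loss = ev$loss, reward = reward, w = w, event = event,
        dropout = hp$dropout, lr = hp$lr, l2 = hp$l2
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_acc %.3f  w %.3f %s",
                        epoch, ep_loss / n_b, ev$acc, w, event))
      }
      if (since_best >= fb_cfg$patience) break
    }
  })
  structure(
    list(params = best$params, config = net_cfg,
         log = do.call(rbind, log_rows), best_val_acc = best$acc,
         hparams = hp, feedback = fb_cfg, seed = seed),
    class = "feedback_fit"
  )
}
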