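# Analytic backward pass and Adam optimiser for the CNN-GRU network.
# Gradients are exact for the forward computation in cnngru_forward()
# (verified against finite differences in the test suite).

#' Loss and gradients for one batch
#'
#' Weighted binary cross-entropy (mean over the batch, scaled by the loss
#' weight `w`) plus optional L2 penalty on all weight matrices. Assumes the
#' cache was produced by [cnngru_forward()] with `keep_cache = TRUE`.
#'
#' @param params parameter list.
#' @param cache forward cache.
#' @param y 0/1 labels (batch vector).
#' @param cfg the [cnngru_config()].
#' @param loss_weight loss weight factor w.
#' @param l2 L2 regularisation coefficient (weights only, not biases).
#' @return list with `loss` and `grads` (same tensor names as `params`).
#' @export
cnngru_backward <- function(params, cache, y, cfg, loss_weight = 1,
                            l2 = 0) {
  B <- length(y)
  prob <- pmin(pmax(cache$prob, 1e-7), 1 - 1e-7)
  loss <- loss_weight * mean(-y * log(prob) - (1 - y) * log(1 - prob))

  grads <- lapply(params, function(p) p * 0)

  # head
  dlogit <- loss_weight * (prob - y) / B           # [B]
  grads$W2 <- crossprod(cache$a1d, matrix(dlogit, ncol = 1L))
  grads$b2 <- sum(dlogit)
  da1d <- tcrossprod(matrix(dlogit, ncol = 1L), params$W2)
  da1 <- if (is.null(cache$mask_head)) da1d else da1d * cache$mask_head
  da1_pre <- da1 * (cache$a1_pre > 0)
  grads$W1 <- crossprod(cache$fcat, da1_pre)
  grads$b1 <- colSums(da1_pre)
  dfcat <- tcrossprod(da1_pre, params$W1)

  Fc <- ncol(cache$fcat) - cfg$gru_units
  df_cnn <- dfcat[, seq_len(Fc), drop = FALSE]
  df_gru <- dfcat[, Fc + seq_len(cfg$gru_units), drop = FALSE]

  # GRU branch: BPTT from the last hidden state. Per-step gate gradients are
  # stacked into (B*T) x U buffers so all weight gradients reduce to single
  # large matrix products after the loop.
  dh <- if (is.null(cache$mask_gru)) df_gru else df_gru * cache$mask_gru
  Tn <- cfg$input_steps
  U <- cfg$gru_units
  dZ_pre <- matrix(0, B * Tn, U)
  dR_pre <- matrix(0, B * Tn, U)
  dHC_pre <- matrix(0, B * Tn, U)
  for (t in rev(seq_len(Tn))) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    z <- cache$Z_all[rows, , drop = FALSE]
    r <- cache$R_all[rows, , drop = FALSE]
    hc <- cache$HC_all[rows, , drop = FALSE]
    hprev <- cache$HP_all[rows, , drop = FALSE]
    dz <- dh * (hc - hprev)
    dhc <- dh * z
    dhprev <- dh * (1 - z)
    dhc_pre <- dhc * (1 - hc^2)
    d_rh <- tcrossprod(dhc_pre, params$Uh)
    dr <- d_rh * hprev
    dhprev <- dhprev + d_rh * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    dZ_pre[rows, ] <- dz_pre
    dR_pre[rows, ] <- dr_pre
    dHC_pre[rows, ] <- dhc_pre
    dh <- dhprev + tcrossprod(dz_pre, params$Uz) +
      tcrossprod(dr_pre, params$Ur)
  }
  grads$Wz <- crossprod(cache$xm, dZ_pre)
  grads$Wr <- crossprod(cache$xm, dR_pre)
  grads$Wh <- crossprod(cache$xm, dHC_pre)
  grads$Uz <- crossprod(cache$HP_all, dZ_pre)
  grads$Ur <- crossprod(cache$HP_all, dR_pre)
  grads$Uh <- crossprod(cache$R_all * cache$HP_all, dHC_pre)
  grads$bz <- colSums(dZ_pre)
  grads$br <- colSums(dR_pre)
  grads$bh <- colSums(dHC_pre)

  # convolutional branch (channel-first: F2 x (B*T) matrices)
  dflat <- if (is.null(cache$mask_cnn)) df_cnn else df_cnn * cache$mask_cnn
  Tp <- cache$Tp
  F2 <- cfg$conv_filters_2
  dim(dflat) <- c(B * Tp, F2)          # row = b + (tp-1)B (flatten inverse)
  dpool <- t(dflat)                    # F2 x (B*Tp)
  Tn <- cfg$input_steps
  dhcnn <- matrix(0, F2, B * Tn)
  for (j in seq_len(cfg$pool_size)) {
    sel <- cache$argmax == j
    cols <- cache$pool_cols[[j]]
    dhcnn[, cols] <- dhcnn[, cols, drop = FALSE] + dpool * sel
  }
  dhsum <- dhcnn * (cache$hsum > 0)

  # residual 1x1 path
  grads$res_w <- tcrossprod(cache$xc, dhsum)
  grads$res_b <- rowSums(dhsum)

  # second separable conv + BN
  bb2 <- bn_backward(cache$bn2, params$bn2_gamma, dhsum,
                     training = cache$training)
  grads$bn2_gamma <- bb2$dgamma
  grads$bn2_beta <- bb2$dbeta
  dp2 <- bb2$dx                        # F2 x (B*T)
  grads$pw2 <- tcrossprod(cache$z2, dp2)
  grads$cb2 <- rowSums(dp2)
  dz2 <- params$pw2 %*% dp2            # F1 x (B*T)
  dw2b <- dwconv_backward(cache$h1, params$dw2, dz2, B)
  grads$dw2 <- dw2b$dk
  dh1 <- dw2b$dx

  # first separable conv + BN + ReLU
  dbn1y <- dh1 * (cache$bn1$y > 0)
  bb1 <- bn_backward(cache$bn1, params$bn1_gamma, dbn1y,
                     training = cache$training)
  grads$bn1_gamma <- bb1$dgamma
  grads$bn1_beta <- bb1$dbeta
  dp1 <- bb1$dx
  grads$pw1 <- tcrossprod(cache$z1, dp1)
  grads$cb1 <- rowSums(dp1)
  dz1 <- params$pw1 %*% dp1            # D x (B*T)
  dw1b <- dwconv_backward(cache$xc, params$dw1, dz1, B)
  grads$dw1 <- dw1b$dk

  if (l2 > 0) {
    weight_names <- c("dw1", "pw1", "dw2", "pw2", "res_w",
                      "Wz", "Uz", "Wr", "Ur", "Wh", "Uh", "W1", "W2")
    for (nm in weight_names) {
      loss <- loss + l2 * sum(params[[nm]]^2)
      grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
    }
  }

  grads$W2 <- matrix(grads$W2, ncol = 1L)
  list(loss = loss, grads = grads)
}

#' Initialise Adam optimiser state
#'
#' @param params parameter list.
#' @return list of first/second moment accumulators and step counter.
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update
#'
#' @param params parameter list.
#' @param grads matching gradient list.
#' @param state Adam state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps standard Adam constants.
#' @return list with updated `params` (batch-norm running state preserved)
#'   and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bn <- attr(params, "bn_state")
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  attr(params, "bn_state") <- bn
  list(params = params, state = state)
}
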