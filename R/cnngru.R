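# The parallel CNN-GRU classifier: a separable-convolution branch with a
# residual 1x1 shortcut (local multi-scale temporal patterns) runs alongside
# a GRU branch (global temporal dependencies); their outputs are concatenated
# and passed through a dense ReLU layer to a single sigmoid unit giving the
# case-class probability. Implemented in base R with explicit forward and
# backward passes so training is fully self-contained and reproducible.
#
# Internal layout: the convolutional branch works channel-first, i.e. on
# C x (B*T) matrices whose column index is b + (t-1)*B. Per-channel
# parameters (kernel taps, batch-norm scale/shift, biases) are then plain
# row-recycled vector operations, which is the fast path in R.

#' CNN-GRU network configuration
#'
#' Kernel sizes are fixed (3 and 5 for the separable convolutions, 1 for the
#' residual shortcut). The fused feature vector enters as a length-T
#' sequence with D channels per step (D = 1 by default).
#'
#' @param input_steps sequence length T (>= 5, the largest kernel).
#' @param input_dim channels per step D.
#' @param conv_filters_1,conv_filters_2 filters of the two separable
#'   convolution layers.
#' @param pool_size max-pooling width.
#' @param gru_units GRU hidden size.
#' @param dense_units width of the dense head.
#' @param dropout_rate dropout probability in [0, 1), applied after
#'   flattening, on the final GRU state, and inside the head.
#' @return object of class `cnngru_config`.
#' @export
cnngru_config <- function(input_steps, input_dim = 1L, conv_filters_1 = 32L,
                          conv_filters_2 = 64L, pool_size = 2L,
                          gru_units = 64L, dense_units = 64L,
                          dropout_rate = 0.5) {
  if (input_steps < 5L) stop("`input_steps` must be >= 5", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  }
  widths <- c(input_dim, conv_filters_1, conv_filters_2, pool_size,
              gru_units, dense_units)
  if (any(widths < 1L)) stop("all widths must be >= 1", call. = FALSE)
  structure(
    list(input_steps = as.integer(input_steps),
         input_dim = as.integer(input_dim),
         conv_filters_1 = as.integer(conv_filters_1),
         conv_filters_2 = as.integer(conv_filters_2),
         pool_size = as.integer(pool_size),
         gru_units = as.integer(gru_units),
         dense_units = as.integer(dense_units),
         dropout_rate = dropout_rate,
         kernel_1 = 3L, kernel_2 = 5L),
    class = "cnngru_config"
  )
}

# Shapes of every trainable tensor, in a fixed order.
cnngru_shapes <- function(cfg) {
  Tn <- cfg$input_steps
  D <- cfg$input_dim
  F1 <- cfg$conv_filters_1
  F2 <- cfg$conv_filters_2
  U <- cfg$gru_units
  H <- cfg$dense_units
  Tp <- Tn %/% cfg$pool_size
  Fc <- Tp * F2
  list(
    dw1 = c(cfg$kernel_1, D), pw1 = c(D, F1), cb1 = F1,
    bn1_gamma = F1, bn1_beta = F1,
    dw2 = c(cfg$kernel_2, F1), pw2 = c(F1, F2), cb2 = F2,
    bn2_gamma = F2, bn2_beta = F2,
    res_w = c(D, F2), res_b = F2,
    Wz = c(D, U), Uz = c(U, U), bz = U,
    Wr = c(D, U), Ur = c(U, U), br = U,
    Wh = c(D, U), Uh = c(U, U), bh = U,
    W1 = c(Fc + U, H), b1 = H,
    W2 = c(H, 1L), b2 = 1L
  )
}

#' Count trainable parameters
#'
#' Exact count from shape arithmetic over every declared tensor
#' (convolution kernels, batch-norm scale/shift, GRU gates and biases,
#' dense head). Running batch-norm statistics are not trainable and are
#' excluded.
#'
#' @param cfg a [cnngru_config()].
#' @return integer parameter count.
#' @export
cnngru_count_params <- function(cfg) {
  sum(vapply(cnngru_shapes(cfg), prod, 0))
}

#' Initialise network weights
#'
#' Glorot-uniform weight matrices, zero biases, unit batch-norm scale.
#'
#' @param cfg a [cnngru_config()].
#' @param seed integer seed.
#' @return list of parameter tensors plus batch-norm running statistics in
#'   attribute `"bn_state"`.
#' @export
cnngru_init <- function(cfg, seed = 1L) {
  shapes <- cnngru_shapes(cfg)
  with_seed(seed, {
    params <- lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      if (length(sh) == 1L) {
        val <- if (grepl("gamma", nm)) rep(1, sh) else rep(0, sh)
        return(val)
      }
      limit <- sqrt(6 / (sh[1L] + sh[2L]))
      matrix(stats::runif(prod(sh), -limit, limit), sh[1L], sh[2L])
    })
    names(params) <- names(shapes)
    attr(params, "bn_state") <- list(
      bn1_mean = rep(0, cfg$conv_filters_1),
      bn1_var = rep(1, cfg$conv_filters_1),
      bn2_mean = rep(0, cfg$conv_filters_2),
      bn2_var = rep(1, cfg$conv_filters_2)
    )
    params
  })
}

# ---- channel-first helpers (C x (B*T) matrices, column = b + (t-1)*B) -----

# Per-column broadcast add (avoids sweep()'s aperm).
addcol <- function(m, v) m + rep(v, each = nrow(m))

# Zero-pad p time frames (blocks of B columns) on each side.
pad_cols <- function(m, B, p) {
  if (p == 0L) {
    return(m)
  }
  z <- matrix(0, nrow(m), p * B)
  cbind(z, m, z)
}

# Depthwise 'same' 1-D convolution over time; kernel is ksize x C, input
# C x (B*T). Row recycling applies kernel[j, ] per channel with no copy
# beyond the accumulator.
dwconv_forward <- function(x, kernel, B) {
  nbt <- ncol(x)
  ks <- nrow(kernel)
  p <- (ks - 1L) %/% 2L
  xp <- pad_cols(x, B, p)
  out <- matrix(0, nrow(x), nbt)
  for (j in seq_len(ks)) {
    out <- out + xp[, ((j - 1L) * B + 1L):((j - 1L) * B + nbt), drop = FALSE] *
      kernel[j, ]
  }
  out
}

dwconv_backward <- function(x, kernel, dout, B) {
  nbt <- ncol(x)
  ks <- nrow(kernel)
  p <- (ks - 1L) %/% 2L
  xp <- pad_cols(x, B, p)
  dk <- kernel * 0
  dxp <- matrix(0, nrow(x), ncol(xp))
  for (j in seq_len(ks)) {
    cols <- ((j - 1L) * B + 1L):((j - 1L) * B + nbt)
    dk[j, ] <- rowSums(xp[, cols, drop = FALSE] * dout)
    dxp[, cols] <- dxp[, cols, drop = FALSE] + dout * kernel[j, ]
  }
  dx <- dxp[, (p * B + 1L):(p * B + nbt), drop = FALSE]
  list(dx = dx, dk = dk)
}

# Batch norm per channel (= per row in channel-first layout).
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training, momentum = 0.99, eps = 1e-3) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    new_mean <- momentum * running_mean + (1 - momentum) * mu
    new_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean
    v <- running_var
    new_mean <- running_mean
    new_var <- running_var
  }
  xhat <- (x - mu) / sqrt(v + eps)
  list(y = xhat * gamma + beta, xhat = xhat, var = v,
       new_mean = new_mean, new_var = new_var)
}

bn_backward <- function(cache, gamma, dout, eps = 1e-3, training = TRUE) {
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * gamma
  inv_sd <- 1 / sqrt(cache$var + eps)
  if (training) {
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv_sd
  } else {
    dx <- dxhat * inv_sd
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_mask <- function(dim_, rate, training) {
  if (!training || rate <= 0) {
    return(NULL)
  }
  array(stats::rbinom(prod(dim_), 1L, 1 - rate) / (1 - rate), dim = dim_)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- forward pass ---------------------------------------------------------

#' Forward pass of the CNN-GRU network
#'
#' @param params parameter list from [cnngru_init()].
#' @param x input array `[batch, T, D]` or a `[batch, T]` matrix (D = 1).
#' @param cfg the network's [cnngru_config()].
#' @param training logical; training mode enables dropout and batch-statistic
#'   normalisation (draws from the current RNG stream).
#' @param keep_cache keep intermediate activations for the backward pass.
#' @return list with `prob` (batch vector of case probabilities), `f_cnn`,
#'   `f_gru`, and (if requested) `cache`.
#' @export
cnngru_forward <- function(params, x, cfg, training = FALSE,
                           keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  d <- dim(x)
  B <- d[1L]
  Tn <- d[2L]
  if (Tn != cfg$input_steps || d[3L] != cfg$input_dim) {
    stop("input shape does not match the configuration", call. = FALSE)
  }
  if (any(!vapply(params, function(p) all(is.finite(p)), TRUE))) {
    stop("non-finite network weights", call. = FALSE)
  }
  bn <- attr(params, "bn_state")
  rate <- cfg$dropout_rate

  # channel-first view of the input: D x (B*T)
  xm <- x
  dim(xm) <- c(B * Tn, d[3L])
  xc <- t(xm)

  # -- convolutional branch
  z1 <- dwconv_forward(xc, params$dw1, B)
  p1 <- crossprod(params$pw1, z1) + params$cb1        # F1 x (B*T)
  bn1 <- bn_forward(p1, params$bn1_gamma, params$bn1_beta,
                    bn$bn1_mean, bn$bn1_var, training)
  h1 <- bn1$y * (bn1$y > 0)

  z2 <- dwconv_forward(h1, params$dw2, B)
  p2 <- crossprod(params$pw2, z2) + params$cb2        # F2 x (B*T)
  bn2 <- bn_forward(p2, params$bn2_gamma, params$bn2_beta,
                    bn$bn2_mean, bn$bn2_var, training)

  hres <- crossprod(params$res_w, xc) + params$res_b
  hsum <- bn2$y + hres
  hcnn <- hsum * (hsum > 0)

  ps <- cfg$pool_size
  Tp <- Tn %/% ps
  F2 <- cfg$conv_filters_2
  # column sets of the j-th frame inside each pooling window
  pool_cols <- lapply(seq_len(ps), function(j) {
    as.vector(outer(seq_len(B), (seq(j, by = ps, length.out = Tp) - 1L) * B,
                    "+"))
  })
  pooled <- matrix(-Inf, F2, B * Tp)
  argmax <- matrix(1L, F2, B * Tp)
  for (j in seq_len(ps)) {
    slice <- hcnn[, pool_cols[[j]], drop = FALSE]
    better <- slice > pooled
    pooled[better] <- slice[better]
    argmax[better] <- j
  }
  # flatten to [B, Tp*F2]: row b, column tp + (f-1)*Tp
  flat <- t(pooled)                   # (B*Tp) x F2, row = b + (tp-1)B
  dim(flat) <- c(B, Tp * F2)
  mask_cnn <- dropout_mask(dim(flat), rate, training)
  f_cnn <- if (is.null(mask_cnn)) flat else flat * mask_cnn

  # -- GRU branch (input projections for all steps batched up front;
  #    rows of the projection matrices follow the b + (t-1)*B layout)
  U <- cfg$gru_units
  h <- matrix(0, B, U)
  xz_all <- addcol(xm %*% params$Wz, params$bz)
  xr_all <- addcol(xm %*% params$Wr, params$br)
  xh_all <- addcol(xm %*% params$Wh, params$bh)
  if (keep_cache) {
    Z_all <- matrix(0, B * Tn, U)
    R_all <- matrix(0, B * Tn, U)
    HC_all <- matrix(0, B * Tn, U)
    HP_all <- matrix(0, B * Tn, U)
  }
  for (t in seq_len(Tn)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    zt <- sigmoid(xz_all[rows, , drop = FALSE] + h %*% params$Uz)
    rt <- sigmoid(xr_all[rows, , drop = FALSE] + h %*% params$Ur)
    hc <- tanh(xh_all[rows, , drop = FALSE] + (rt * h) %*% params$Uh)
    hnew <- (1 - zt) * h + zt * hc
    if (keep_cache) {
      Z_all[rows, ] <- zt
      R_all[rows, ] <- rt
      HC_all[rows, ] <- hc
      HP_all[rows, ] <- h
    }
    h <- hnew
  }
  mask_gru <- dropout_mask(dim(h), rate, training)
  f_gru <- if (is.null(mask_gru)) h else h * mask_gru

  # -- head
  fcat <- cbind(f_cnn, f_gru)
  a1_pre <- fcat %*% params$W1 + rep(params$b1, each = B)
  a1 <- a1_pre * (a1_pre > 0)
  mask_head <- dropout_mask(dim(a1), rate, training)
  a1d <- if (is.null(mask_head)) a1 else a1 * mask_head
  logit <- drop(a1d %*% params$W2 + params$b2)
  prob <- sigmoid(logit)

  out <- list(prob = prob, f_cnn = f_cnn, f_gru = f_gru)
  if (training) {
    out$bn_update <- list(bn1_mean = bn1$new_mean, bn1_var = bn1$new_var,
                          bn2_mean = bn2$new_mean, bn2_var = bn2$new_var)
  }
  if (keep_cache) {
    out$cache <- list(
      xc = xc, xm = xm, z1 = z1, bn1 = bn1, h1 = h1, z2 = z2, bn2 = bn2,
      hsum = hsum, argmax = argmax, Tp = Tp, pool_cols = pool_cols, B = B,
      mask_cnn = mask_cnn, h_last = h, mask_gru = mask_gru,
      Z_all = Z_all, R_all = R_all, HC_all = HC_all, HP_all = HP_all,
      fcat = fcat, a1_pre = a1_pre, mask_head = mask_head, a1d = a1d,
      prob = prob, training = training
    )
  }
  out
}
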