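# Multi-source feature fusion: z-score normalisation fitted on training data
# only, then concatenation [microstate block, statistical block] into the
# fused classifier input.

#' Fit a z-score normaliser
#'
#' Per-dimension mean and population SD from training vectors only.
#' Constant dimensions (SD = 0) are flagged and later dropped from the model
#' input so downstream scaling never divides by zero.
#'
#' @param x numeric matrix, rows = training vectors, named columns.
#' @return object of class `fusion_normalizer`: `mean`, `sd`, `constant`
#'   (logical flag per dimension).
#' @export
fit_normalizer <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training vectors", call. = FALSE)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population SD
  constant <- sdv == 0
  if (any(constant)) {
    warning(sprintf("%d constant dimension(s) flagged and excluded: %s",
                    sum(constant),
                    paste(utils::head(colnames(x)[constant], 5L),
                          collapse = ", ")))
  }
  structure(list(mean = mu, sd = sdv, constant = constant),
            class = "fusion_normalizer")
}

#' Apply a fitted normaliser
#'
#' @param x matrix (or vector) with the same columns the normaliser was
#'   fitted on.
#' @param normalizer a `fusion_normalizer`.
#' @return z-scored matrix with constant dimensions removed.
#' @export
apply_normalizer <- function(x, normalizer) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(normalizer$mean)) {
    stop("dimension mismatch against fitted normalizer", call. = FALSE)
  }
  keep <- !normalizer$constant
  z <- sweep(sweep(x, 2L, normalizer$mean), 2L,
             pmax(normalizer$sd, 1e-300), "/")
  z[, keep, drop = FALSE]
}

#' Fuse microstate and statistical feature blocks
#'
#' Concatenates the two blocks (microstate first) row-wise, optionally
#' fitting and/or applying a z-score normaliser. The fused dimension is
#' whatever the two blocks supply (28 + 40 = 68 with package defaults) and
#' is recorded, never hard-coded.
#'
#' @param micro matrix of microstate features (rows = records).
#' @param stat matrix of statistical features (same row count).
#' @param normalizer optional fitted `fusion_normalizer`; when supplied the
#'   fused rows are z-scored with it (training statistics only -- never fit
#'   it on evaluation data).
#' @return list of class `fused_features`: `x` (rows x D_f matrix),
#'   `block_index` (named index ranges), `normalizer`.
#' @export
fuse_features <- function(micro, stat, normalizer = NULL) {
  if (!is.matrix(micro)) micro <- matrix(micro, nrow = 1L,
                                         dimnames = list(NULL, names(micro)))
  if (!is.matrix(stat)) stat <- matrix(stat, nrow = 1L,
                                       dimnames = list(NULL, names(stat)))
  if (nrow(micro) != nrow(stat)) {
    stop("`micro` and `stat` must describe the same records", call. = FALSE)
  }
  if (any(!is.finite(micro)) || any(!is.finite(stat))) {
    stop("feature blocks must be finite", call. = FALSE)
  }
  x <- cbind(micro, stat)
  block_index <- list(micro = seq_len(ncol(micro)),
                      stat = ncol(micro) + seq_len(ncol(stat)))
  if (!is.null(normalizer)) x <- apply_normalizer(x, normalizer)
  structure(list(x = x, block_index = block_index, normalizer = normalizer),
            class = "fused_features")
}
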